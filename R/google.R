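#' Build the Google matrix of a network
#'
#' Constructs the damped column-stochastic matrix G = alpha * S + (1 - alpha)/N
#' for the simple (unsigned, unweighted) network, or for its link-inverted
#' twin when `inverted = TRUE` (the CheiRank construction).  The adjacency is
#' binary: edge signs and multiplicities are ignored here.  Columns of
#' dangling nodes (no outgoing links) are the uniform column 1/N.
#'
#' The dense teleportation term is never materialized: the model stores the
#' sparse link-following part `S` (with zero columns for dangling nodes), the
#' dangling indicator, and `alpha`; products G v are evaluated analytically.
#'
#' @param network a [ppi_network], or a sparse non-negative matrix taken as a
#'   weighted adjacency with element (i, j) the weight of link j -> i.
#' @param alpha damping factor in (0, 1); 0.85 is the conventional choice.
#' @param inverted build the matrix of the link-inverted network.
#' @return an object of class `google_matrix`: list with `N`, `alpha`, `S`
#'   (sparse `dgCMatrix`), `dangling` (logical), `inverted`, `weighted`.
#' @export
google_matrix <- function(network, alpha = 0.85, inverted = FALSE) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must be a single number in (0, 1)")
  if (inherits(network, "ppi_network")) {
    if (network$N < 2) stop("need at least 2 nodes")
    e <- network$edges
    pair <- unique(data.frame(src = e$src, dst = e$dst))
    A <- Matrix::sparseMatrix(i = pair$dst, j = pair$src, x = 1,
                              dims = c(network$N, network$N))
    weighted <- FALSE
  } else {
    A <- methods::as(methods::as(network, "CsparseMatrix"), "generalMatrix")
    if (nrow(A) != ncol(A)) stop("adjacency must be square")
    if (nrow(A) < 2) stop("need at least 2 nodes")
    if (any(A@x < 0)) stop("adjacency weights must be non-negative")
    weighted <- TRUE
  }
  if (inverted) A <- Matrix::t(A)
  outw <- Matrix::colSums(A)
  dangling <- outw == 0
  scale <- ifelse(dangling, 0, 1 / pmax(outw, 1e-300))
  S <- A %*% Matrix::Diagonal(x = scale)
  structure(list(N = nrow(A), alpha = alpha,
                 S = methods::as(S, "CsparseMatrix"),
                 dangling = as.logical(dangling),
                 inverted = inverted, weighted = weighted),
            class = "google_matrix")
}

#' @export
print.google_matrix <- function(x, ...) {
  cat(sprintf(
    "google_matrix: N = %d, alpha = %g, dangling = %d%s%s (implicit form)\n",
    x$N, x$alpha, sum(x$dangling),
    if (x$inverted) ", inverted" else "",
    if (x$weighted) ", weighted" else ""))
  invisible(x)
}

# G %*% v without densifying: link part + dangling uniform + teleportation.
gm_apply <- function(model, v) {
  with(model, {
    tot <- sum(v)
    dang <- sum(v[dangling])
    as.numeric(alpha * (S %*% v)) +
      (alpha * dang + (1 - alpha) * tot) / N
  })
}

#' Compute PageRank (or CheiRank) by power iteration
#'
#' Iterates v <- G v from the uniform vector until the L1 change drops below
#' `tol`.  The rank index `K` orders nodes by decreasing probability, with
#' ties broken by ascending node index.  When the model was built with
#' `inverted = TRUE` the result is the CheiRank vector.
#'
#' @param model a [google_matrix].
#' @param tol L1 convergence tolerance (default 1e-14; small enough that the
#'   doubled-network PageRank identity holds to ~1e-13).
#' @param max_iter iteration cap.
#' @return an object of class `pagerank`: list with `P` (probabilities,
#'   sum 1), `K` (1-based rank index per node), `order` (node indices sorted
#'   by rank), `is_cheirank`, `iterations`, `residual`.
#' @export
pagerank <- function(model, tol = 1e-14, max_iter = 100000L) {
  stopifnot(inherits(model, "google_matrix"))
  v <- rep(1 / model$N, model$N)
  res <- Inf
  for (it in seq_len(max_iter)) {
    w <- gm_apply(model, v)
    w <- w / sum(w)
    res <- sum(abs(w - v))
    v <- w
    if (res < tol) break
  }
  if (res >= tol)
    stop(sprintf("PageRank power iteration did not converge: residual %.3e after %d iterations",
                 res, max_iter))
  ord <- order(-v, seq_along(v))
  K <- integer(model$N); K[ord] <- seq_len(model$N)
  structure(list(P = v, K = K, order = ord,
                 is_cheirank = model$inverted,
                 iterations = it, residual = res),
            class = "pagerank")
}

#' @export
print.pagerank <- function(x, n = 5L, ...) {
  lab <- if (x$is_cheirank) "CheiRank" else "PageRank"
  cat(sprintf("%s over %d nodes (%d iterations, residual %.2e)\n",
              lab, length(x$P), x$iterations, x$residual))
  top <- x$order[seq_len(min(n, length(x$P)))]
  cat("  top nodes:", paste(sprintf("#%d (P=%.4g)", top, x$P[top]),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Node density on the (ln K, ln K*) rank plane
#'
#' Bins nodes by the logarithms of their PageRank and CheiRank indices on a
#' `bins` x `bins` grid of log-equidistant cells spanning [0, ln N].  Each
#' cell value is the node count divided by the cell capacity: the number of
#' integer (K, K*) pairs whose logs fall in the cell.  Cells with zero
#' capacity are excluded; the grid is renormalized to total 1.
#'
#' @param K,K_star rank index vectors of equal length N (permutations of
#'   1..N).
#' @param bins number of cells per axis (default 100).
#' @return a `bins` x `bins` matrix of class `rank_density` (rows: K axis,
#'   columns: K* axis) with attributes `edges` (bin edges in log space) and
#'   `N`; entries sum to 1.
#' @export
rank_plane_density <- function(K, K_star, bins = 100L) {
  if (length(K) != length(K_star)) stop("K and K_star must have equal length")
  N <- length(K)
  if (N < 2) stop("rank plane needs at least 2 nodes (log range is empty)")
  edges <- seq(0, log(N), length.out = bins + 1L)
  cut_idx <- function(k) pmin(findInterval(log(k), edges,
                                           rightmost.closed = TRUE), bins)
  # per-axis capacity: how many integers 1..N land in each log bin
  cap1 <- tabulate(cut_idx(seq_len(N)), nbins = bins)
  capacity <- outer(cap1, cap1)
  counts <- matrix(0, bins, bins)
  ix <- cut_idx(K); iy <- cut_idx(K_star)
  for (j in seq_len(N)) counts[ix[j], iy[j]] <- counts[ix[j], iy[j]] + 1
  grid <- matrix(0, bins, bins)
  ok <- capacity > 0
  grid[ok] <- counts[ok] / capacity[ok]
  grid <- grid / sum(grid)
  structure(grid, class = c("rank_density", "matrix"),
            edges = edges, N = N)
}

#' @export
plot.rank_density <- function(x, ...) {
  edges <- attr(x, "edges")
  graphics::image(edges, edges, unclass(x)^0.25,
                  xlab = "ln K", ylab = "ln K*",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
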