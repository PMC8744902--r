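#' Reduced Google matrix (REGOMAX) of a node subset
#'
#' Computes the effective Google matrix GR of a subset of Nr nodes embedded
#' in a network of N >> Nr nodes,
#' GR = Grr + Grs (1 - Gss)^-1 Gsr, where r/s index the subset and the
#' complementary "scattering" nodes.  GR is column-stochastic and keeps the
#' relative PageRank probabilities of the subset fixed.  It decomposes as
#' GR = Grr + Gpr + Gqr: direct transitions, the rank-1 background from the
#' leading eigenvector of Gss (whose eigenvalue lambda_c is close to but
#' below 1), and the deviations carrying the indirect pathways.  Gqr may
#' contain (informative) negative entries; GR, Grr, Gpr are non-negative.
#'
#' Two routes are implemented.  `dense_solve` evaluates the Schur-complement
#' formula with one sparse LU factorization of (I - alpha * Sss), handling
#' the teleportation + dangling rank-1 correction by the Sherman-Morrison
#' identity, and then splits off Gpr using the leading eigenvectors of Gss.
#' `spectral_series` computes Gqr by the projected matrix series
#' Grs [sum_l Qc (Gss Qc)^l] Gsr with Qc = 1 - psiR psiL^T, truncated when
#' the current term's max-norm falls below `series_tol`.  Both agree to
#' ~1e-10 elementwise and exist mainly to cross-validate each other.
#'
#' @param model a [google_matrix] of the full network.
#' @param subset integer node indices (distinct, 2 <= Nr <= N).  With
#'   Nr = N the degenerate contract applies: GR = Grr = G, Gpr = Gqr = 0.
#' @param method `"dense_solve"` (default) or `"spectral_series"`.
#' @param P optional precomputed global PageRank vector of `model`; computed
#'   on the fly when missing.
#' @param eig_tol L1 tolerance of the power iterations for the leading
#'   right/left eigenvectors of Gss.
#' @param series_tol truncation threshold (max-norm of the current series
#'   term) for the spectral series.
#' @param max_terms hard cap on the number of series terms.
#' @return an object of class `reduced_google`: list with `subset`, dense
#'   matrices `GR`, `Grr`, `Gpr`, `Gqr`, `Gqr_nd` (Gqr with zeroed
#'   diagonal), `lambda_c`, `weights` (W_R, W_rr, W_pr, W_qr, W_qr_nd),
#'   `Pr` (subset-restricted renormalized PageRank), `n_negative_qr`,
#'   `method`.
#' @export
reduced_google <- function(model, subset,
                           method = c("dense_solve", "spectral_series"),
                           P = NULL, eig_tol = 1e-14, series_tol = 1e-12,
                           max_terms = 10000L) {
  stopifnot(inherits(model, "google_matrix"))
  method <- match.arg(method)
  subset <- as.integer(subset)
  N <- model$N
  if (anyDuplicated(subset)) stop("subset indices must be distinct")
  if (any(subset < 1 | subset > N)) stop("subset indices out of range")
  Nr <- length(subset)
  if (Nr < 2) stop("subset must contain at least 2 nodes")
  if (is.null(P)) P <- pagerank(model)$P
  Pr <- P[subset] / sum(P[subset])

  alpha <- model$alpha
  cvec <- (alpha * model$dangling + (1 - alpha)) / N

  if (Nr == N) {
    # degenerate full-subset contract: GR is the full Google matrix
    G <- alpha * as.matrix(model$S) +
      matrix(cvec, N, N, byrow = TRUE)
    G <- G[subset, subset, drop = FALSE]
    zero <- matrix(0, Nr, Nr)
    return(new_reduced_google(subset, GR = G, Grr = G, Gpr = zero,
                              Gqr = zero, lambda_c = NA_real_, Pr = Pr,
                              method = method))
  }

  r <- subset
  s <- setdiff(seq_len(N), r)
  Ns <- length(s)
  S <- model$S
  Srr <- S[r, r, drop = FALSE]
  Srs <- S[r, s, drop = FALSE]
  Ssr <- S[s, r, drop = FALSE]
  Sss <- S[s, s, drop = FALSE]
  cr <- cvec[r]; cs <- cvec[s]

  Grr <- alpha * as.matrix(Srr) + matrix(cr, Nr, Nr, byrow = TRUE)
  Gsr <- alpha * as.matrix(Ssr) + matrix(cr, Ns, Nr, byrow = TRUE)

  grs_mult <- function(B) {  # Grs %*% B without forming Grs densely
    alpha * as.matrix(Srs %*% B) +
      matrix(as.vector(Matrix::crossprod(cs, B)), Nr, ncol(B), byrow = TRUE)
  }
  gss_mult <- function(B) {
    alpha * as.matrix(Sss %*% B) +
      matrix(as.vector(Matrix::crossprod(cs, B)), Ns, ncol(B), byrow = TRUE)
  }

  # leading right/left eigenvectors of Gss (power iteration; Gss >= 0)
  psiR <- rep(1 / Ns, Ns)
  lambda_c <- NA_real_
  for (it in seq_len(100000L)) {
    w <- alpha * as.numeric(Sss %*% psiR) + sum(cs * psiR)
    lambda_c <- sum(w)
    w <- w / lambda_c
    if (sum(abs(w - psiR)) < eig_tol) { psiR <- w; break }
    psiR <- w
  }
  psiL <- rep(1 / Ns, Ns)
  for (it in seq_len(100000L)) {
    w <- alpha * as.numeric(Matrix::crossprod(Sss, psiL)) + cs * sum(psiL)
    w <- w / sum(w)
    if (sum(abs(w - psiL)) < eig_tol) { psiL <- w; break }
    psiL <- w
  }
  if (!(lambda_c > 0 && lambda_c < 1))
    stop(sprintf("leading eigenvalue of Gss is %g, outside (0, 1); subset has no escape coupling", lambda_c))
  psiL <- psiL / sum(psiL * psiR)  # biorthonormalization psiL^T psiR = 1

  Gpr <- outer(alpha * as.numeric(Srs %*% psiR) + sum(cs * psiR),
               as.numeric(Matrix::crossprod(psiL, Gsr))) / (1 - lambda_c)

  if (method == "dense_solve") {
    # (I - Gss)^{-1} Gsr via one sparse LU + Sherman-Morrison rank-1 update
    M <- Matrix::Diagonal(Ns) - alpha * Sss
    lu <- Matrix::lu(M)
    Y0 <- as.matrix(Matrix::solve(lu, Gsr))
    y1 <- as.numeric(Matrix::solve(lu, rep(1, Ns)))
    denom <- 1 - sum(cs * y1)
    X <- Y0 + y1 %*% ((cs %*% Y0) / denom)
    GR <- Grr + grs_mult(X)
    Gqr <- GR - Grr - Gpr
  } else {
    Tm <- Gsr - psiR %*% crossprod(psiL, Gsr)  # Qc Gsr
    Gqr <- matrix(0, Nr, Nr)
    converged <- FALSE
    for (l in seq_len(max_terms)) {
      incr <- grs_mult(Tm)
      Gqr <- Gqr + incr
      if (max(abs(incr)) < series_tol) { converged <- TRUE; break }
      Tm <- gss_mult(Tm)
      Tm <- Tm - psiR %*% crossprod(psiL, Tm)
    }
    if (!converged)
      stop(sprintf("spectral series not converged after %d terms (lambda_c = %.6f, last term %.3e)",
                   max_terms, lambda_c, max(abs(incr))))
    GR <- Grr + Gpr + Gqr
  }

  new_reduced_google(subset, GR = GR, Grr = Grr, Gpr = Gpr, Gqr = Gqr,
                     lambda_c = lambda_c, Pr = Pr, method = method)
}

new_reduced_google <- function(subset, GR, Grr, Gpr, Gqr, lambda_c, Pr,
                               method) {
  Nr <- length(subset)
  Gqr_nd <- Gqr; diag(Gqr_nd) <- 0
  structure(list(
    subset = subset, Nr = Nr,
    GR = GR, Grr = Grr, Gpr = Gpr, Gqr = Gqr, Gqr_nd = Gqr_nd,
    lambda_c = lambda_c,
    weights = list(W_R = sum(GR) / Nr, W_rr = sum(Grr) / Nr,
                   W_pr = sum(Gpr) / Nr, W_qr = sum(Gqr) / Nr,
                   W_qr_nd = sum(Gqr_nd) / Nr),
    Pr = Pr,
    n_negative_qr = sum(Gqr < 0),
    method = method
  ), class = "reduced_google")
}

#' @export
print.reduced_google <- function(x, ...) {
  w <- x$weights
  cat(sprintf("reduced_google: Nr = %d (method %s), lambda_c = %s\n",
              x$Nr, x$method,
              if (is.na(x$lambda_c)) "NA (full subset)" else
                format(x$lambda_c, digits = 8)))
  cat(sprintf("  weights: W_R = %.6f, W_rr = %.4f, W_pr = %.4f, W_qr = %.4f (nd %.4f)\n",
              w$W_R, w$W_rr, w$W_pr, w$W_qr, w$W_qr_nd))
  cat(sprintf("  negative Gqr entries: %d of %d\n", x$n_negative_qr, x$Nr^2))
  invisible(x)
}

#' Component weights of a reduced Google matrix
#'
#' The weight of a component is the sum of all its elements divided by the
#' subset size Nr; W_R equals 1 by column-sum normalization of GR.
#'
#' @param rs a [reduced_google] object.
#' @return list with `W_R`, `W_rr`, `W_pr`, `W_qr`, `W_qr_nd`.
#' @export
component_weights <- function(rs) {
  stopifnot(inherits(rs, "reduced_google"))
  Nr <- rs$Nr
  list(W_R = sum(rs$GR) / Nr, W_rr = sum(rs$Grr) / Nr,
       W_pr = sum(rs$Gpr) / Nr, W_qr = sum(rs$Gqr) / Nr,
       W_qr_nd = sum(rs$Gqr_nd) / Nr)
}

# PageRank of a dense column-stochastic matrix by power iteration
dense_pagerank <- function(G, tol = 1e-14, max_iter = 100000L) {
  n <- nrow(G)
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(G %*% v)
    w <- w / sum(w)
    if (sum(abs(w - v)) < tol) return(w)
    v <- w
  }
  stop("dense PageRank power iteration did not converge")
}

#' Local PageRank/CheiRank indices of a subset
#'
#' Ranks the subset nodes by the PageRank of its reduced Google matrix GR
#' (local index K) and by the PageRank of the reduced matrix GR* of the
#' link-inverted network (local index K*).  Ties break by ascending subset
#' position (the global-table order).
#'
#' @param model,model_inverted [google_matrix] objects built from the same
#'   network with `inverted = FALSE` / `TRUE`.
#' @param subset integer node indices.
#' @param ... passed to [reduced_google].
#' @return list with `K_local`, `K_star_local`, `P_local`, `P_star_local`
#'   and the two [reduced_google] objects (`rs`, `rs_star`).
#' @export
local_rank_indices <- function(model, model_inverted, subset, ...) {
  if (!isTRUE(model_inverted$inverted))
    stop("model_inverted must be built with inverted = TRUE")
  rs <- reduced_google(model, subset, ...)
  rs_star <- reduced_google(model_inverted, subset, ...)
  p <- dense_pagerank(rs$GR)
  ps <- dense_pagerank(rs_star$GR)
  rank_of <- function(v) {
    K <- integer(length(v)); K[order(-v, seq_along(v))] <- seq_along(v); K
  }
  list(K_local = rank_of(p), K_star_local = rank_of(ps),
       P_local = p, P_star_local = ps, rs = rs, rs_star = rs_star)
}
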