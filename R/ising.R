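#' Doubled bifunctional ("Ising") network of a signed network
#'
#' Splits every node j into an activated copy (j,+) and an inhibited copy
#' (j,-) and replaces each signed link by a 2x2 sigma-block acting on the
#' (target, source) label pair:
#' sigma_plus = \[\[1,1\],\[0,0\]\] for activation (both source labels feed the
#' (+) copy of the target), sigma_minus = \[\[0,0\],\[1,1\]\] for inhibition,
#' and sigma_0 = 1/2 * \[\[1,1\],\[1,1\]\] for neutral links.  Multiplicities
#' add their sigma-blocks, making the doubled adjacency weighted.  The
#' doubled node order is interleaved: (1,+), (1,-), (2,+), (2,-), ...
#'
#' @param network a [ppi_network].
#' @return an object of class `ising_network`: list with `base_N`, `NI`
#'   (= 2N), `W` (sparse 2N x 2N weighted adjacency, element (i,j) = weight
#'   of doubled link j -> i), `NI_links` (nonzero entries), `node_ids`.
#' @export
ising_network <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  e <- network$edges
  N <- network$N
  plus <- function(j) 2L * j - 1L
  minus <- function(j) 2L * j
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  act <- e$sign == 1L
  inh <- e$sign == -1L
  neu <- e$sign == 0L
  if (any(act)) {  # sigma_plus: target (+) row, both source columns
    add(plus(e$dst[act]), plus(e$src[act]), e$mult[act])
    add(plus(e$dst[act]), minus(e$src[act]), e$mult[act])
  }
  if (any(inh)) {  # sigma_minus: target (-) row, both source columns
    add(minus(e$dst[inh]), plus(e$src[inh]), e$mult[inh])
    add(minus(e$dst[inh]), minus(e$src[inh]), e$mult[inh])
  }
  if (any(neu)) {  # sigma_0: all four entries at weight 1/2
    add(plus(e$dst[neu]), plus(e$src[neu]), e$mult[neu] / 2)
    add(plus(e$dst[neu]), minus(e$src[neu]), e$mult[neu] / 2)
    add(minus(e$dst[neu]), plus(e$src[neu]), e$mult[neu] / 2)
    add(minus(e$dst[neu]), minus(e$src[neu]), e$mult[neu] / 2)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2L * N, 2L * N))
  structure(list(base_N = N, NI = 2L * N, W = W,
                 NI_links = Matrix::nnzero(W),
                 node_ids = network$node_ids),
            class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  cat(sprintf("ising_network: NI = %d doubled nodes, %d weighted links (base N = %d)\n",
              x$NI, x$NI_links, x$base_N))
  invisible(x)
}

#' Split PageRank and magnetization of the doubled network
#'
#' Builds the Google matrix of the weighted doubled adjacency in the usual
#' way (columns normalized by their weighted sums; zero columns uniform
#' 1/(2N)), computes its PageRank, and reads off the activated/inhibited
#' components P+(j), P-(j) of every base node.  The magnetization is
#' M(j) = (P+(j) - P-(j)) / (P+(j) + P-(j)), in \[-1, 1\]: positive for
#' nodes reached predominantly through activation links.  For
#' multiplicity-free networks the sum P+ + P- reproduces the simple-network
#' PageRank exactly (to power-iteration precision).
#'
#' @param inet an [ising_network].
#' @param alpha damping factor.
#' @param tol power-iteration L1 tolerance.
#' @return an object of class `magnetization`: list with vectors `P_plus`,
#'   `P_minus`, `P_sum`, `M` over base nodes, plus `node_ids` and the
#'   doubled `pagerank` object as `rank`.
#' @export
ising_pagerank <- function(inet, alpha = 0.85, tol = 1e-14) {
  stopifnot(inherits(inet, "ising_network"))
  model <- google_matrix(inet$W, alpha = alpha)
  pr <- pagerank(model, tol = tol)
  odd <- seq(1L, inet$NI, by = 2L)
  P_plus <- pr$P[odd]
  P_minus <- pr$P[odd + 1L]
  structure(list(P_plus = P_plus, P_minus = P_minus,
                 P_sum = P_plus + P_minus,
                 M = (P_plus - P_minus) / (P_plus + P_minus),
                 node_ids = inet$node_ids, rank = pr),
            class = "magnetization")
}

#' @export
print.magnetization <- function(x, n = 5L, ...) {
  cat(sprintf("magnetization over %d nodes: M in [%.4f, %.4f]\n",
              length(x$M), min(x$M), max(x$M)))
  o <- order(-abs(x$M))[seq_len(min(n, length(x$M)))]
  cat("  strongest |M|:",
      paste(sprintf("%s (%.3f)", x$node_ids[o], x$M[o]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.magnetization <- function(x, ...) {
  data.frame(node_id = x$node_ids, P_plus = x$P_plus, P_minus = x$P_minus,
             P_sum = x$P_sum, M = x$M)
}

#' Reduced Google matrix on the doubled network
#'
#' Expands a base-node subset to its interleaved (+)/(-) pairs (preserving
#' the subset order) and delegates to [reduced_google] on the Google matrix
#' of the weighted doubled adjacency.  Columns of the resulting 2Nr x 2Nr
#' matrices are identical for the two labels of a source node, a structural
#' property of the sigma-blocks.
#'
#' @param inet an [ising_network].
#' @param subset base-node indices.
#' @param alpha damping factor.
#' @param ... passed to [reduced_google].
#' @return a [reduced_google] object over the 2 * length(subset) doubled
#'   nodes, with an extra element `base_subset`.
#' @export
reduced_google_ising <- function(inet, subset, alpha = 0.85, ...) {
  stopifnot(inherits(inet, "ising_network"))
  subset <- as.integer(subset)
  if (any(subset < 1 | subset > inet$base_N)) stop("subset out of range")
  model <- google_matrix(inet$W, alpha = alpha)
  doubled <- as.integer(rbind(2L * subset - 1L, 2L * subset))
  rs <- reduced_google(model, doubled, ...)
  rs$base_subset <- subset
  rs
}
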