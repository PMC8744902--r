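#' Single-link perturbation of a reduced Google matrix
#'
#' Applies the link-boost rule: element (a, b) of GR is multiplied by
#' (1 + eps) and column b is then renormalized by 1 / (1 + eps * GR(a, b)),
#' leaving all other columns untouched.  The result stays
#' column-stochastic; zero elements and columns concentrated at (a, b)
#' are fixed points of the rule.
#'
#' @param GR a dense column-stochastic matrix.
#' @param a,b row (target) and column (source) indices of the perturbed
#'   transition b -> a.
#' @param eps perturbation strength.
#' @return the perturbed matrix.
#' @export
perturb_reduced <- function(GR, a, b, eps) {
  g <- GR[a, b]
  out <- GR
  out[, b] <- GR[, b] / (1 + eps * g)
  out[a, b] <- g * (1 + eps) / (1 + eps * g)
  out
}

# deflated system matrix M = I - GR + Pr 1^T; unique solve on the
# zero-sum subspace of (I - GR) x = rhs when 1^T rhs = 0
deflated_matrix <- function(GR, Pr) {
  diag(nrow(GR)) - GR + Pr %*% t(rep(1, nrow(GR)))
}

#' Exact PageRank sensitivity to one link of the reduced matrix
#'
#' The logarithmic derivative D(b->a)(j) = (1/Pr(j)) dPr_eps(j)/d eps at
#' eps = 0, where Pr_eps is the PageRank of the perturbed matrix of
#' [perturb_reduced].  Evaluated exactly (no finite differences): the
#' derivative of the perturbed matrix has the single nonzero column
#' E(., b) = GR(a,b) (e_a - GR(., b)), and the PageRank derivative P' solves
#' (I - GR) P' = E Pr on the zero-sum subspace, made nonsingular by
#' deflating the unit eigenvalue with the rank-1 term Pr 1^T.
#'
#' @param rs a [reduced_google] object (its `GR` and `Pr` are used).
#' @param a,b perturbed transition b -> a.
#' @return numeric vector D(b->a)(.) of length Nr; it satisfies
#'   sum_j D(j) Pr(j) = 0 exactly (normalization is preserved).
#' @export
pagerank_sensitivity <- function(rs, a, b) {
  stopifnot(inherits(rs, "reduced_google"))
  GR <- rs$GR; Pr <- rs$Pr
  g <- GR[a, b]
  if (g == 0) return(numeric(length(Pr)))
  rhs <- -GR[, b]
  rhs[a] <- rhs[a] + 1
  rhs <- rhs * (g * Pr[b])
  Pprime <- solve(deflated_matrix(GR, Pr), rhs)
  as.numeric(Pprime / Pr)
}

#' Full sensitivity matrix D
#'
#' D\[a, b\] = D(b->a)(a): the self-component of the PageRank sensitivity of
#' node a to a boost of the transition b -> a.  All Nr^2 entries come from
#' one LU factorization of the deflated system: with
#' M = I - GR + Pr 1^T and B = M^-1 GR,
#' D\[a, b\] = Pr(b) GR(a, b) (M^-1\[a, a\] - B\[a, b\]) / Pr(a).
#' Diagonal entries are computed (the perturbation rule is well-defined
#' there) but the reporting helpers exclude them from rankings.
#'
#' @param rs a [reduced_google] object.
#' @return an object of class `ppi_sensitivity`: list with the Nr x Nr
#'   matrix `D`, `Pr`, and `subset` carried over from `rs`.
#' @export
sensitivity_matrix <- function(rs) {
  stopifnot(inherits(rs, "reduced_google"))
  GR <- rs$GR; Pr <- rs$Pr
  Minv <- solve(deflated_matrix(GR, Pr))
  B <- Minv %*% GR
  D <- GR * (matrix(diag(Minv), nrow(GR), ncol(GR)) - B)
  D <- D * outer(1 / Pr, Pr)
  structure(list(D = D, Pr = Pr, subset = rs$subset),
            class = "ppi_sensitivity")
}

#' @export
print.ppi_sensitivity <- function(x, ...) {
  off <- x$D; diag(off) <- NA
  cat(sprintf("ppi_sensitivity: %d x %d matrix, off-diagonal range [%.4g, %.4g]\n",
              nrow(x$D), ncol(x$D), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE)))
  invisible(x)
}

#' Group aggregates of the sensitivity matrix
#'
#' Computes, for a sensitivity matrix aligned with a group table (row/column
#' i = Kg = i):
#' the seed-group sensitivity Ds_t(a) = sum over b in the t-subgroup of
#' D\[a, b\] for every up/down protein a, with its descending rank Ks_t;
#' the global responder sum Ds_ud(b) = sum over a in the u/d subgroups of
#' D\[a, b\] for every t or x protein b, with rank; and the full descending
#' ranking `pairs` of all (a in u/d, b in t/x) matrix elements.
#'
#' @param sens a [sensitivity_matrix] result.
#' @param groups a `protein_groups` table with nrow equal to `nrow(D)`.
#' @return an object of class `sensitivity_aggregates`: list of data frames
#'   `Ds_t` (a-side), `Ds_ud` (b-side), `pairs` (ranked (a, b, Dab) list).
#' @export
aggregate_sensitivity <- function(sens, groups) {
  stopifnot(inherits(sens, "ppi_sensitivity"))
  D <- sens$D
  if (nrow(groups) != nrow(D))
    stop("group table has ", nrow(groups), " rows but D is ", nrow(D), " x ",
         ncol(D))
  rows_ud <- which(groups$subgroup %in% c("u", "d"))
  cols_t <- which(groups$subgroup == "t")
  cols_tx <- which(groups$subgroup %in% c("t", "x"))
  if (!length(rows_ud) || !length(cols_t))
    stop("group table must contain u/d rows and t columns")

  Ds_t <- rowSums(D[rows_ud, cols_t, drop = FALSE])
  ord <- order(-Ds_t, rows_ud)
  Ds_t_df <- data.frame(Kg = rows_ud,
                        subgroup = groups$subgroup[rows_ud],
                        subgroup_index = groups$subgroup_index[rows_ud],
                        protein = groups$protein_name[rows_ud],
                        Ds_t = Ds_t)
  Ds_t_df$Ks_t <- integer(nrow(Ds_t_df)); Ds_t_df$Ks_t[ord] <- seq_along(ord)

  Ds_ud <- colSums(D[rows_ud, cols_tx, drop = FALSE])
  ordb <- order(-Ds_ud, cols_tx)
  Ds_ud_df <- data.frame(Kg = cols_tx,
                         subgroup = groups$subgroup[cols_tx],
                         subgroup_index = groups$subgroup_index[cols_tx],
                         protein = groups$protein_name[cols_tx],
                         Ds_ud = Ds_ud,
                         Pr = sens$Pr[cols_tx])
  Ds_ud_df$rank <- integer(nrow(Ds_ud_df)); Ds_ud_df$rank[ordb] <- seq_along(ordb)
  Ds_ud_df <- Ds_ud_df[order(Ds_ud_df$rank), , drop = FALSE]
  rownames(Ds_ud_df) <- NULL

  grid <- expand.grid(a = rows_ud, b = cols_tx)
  grid$Dab <- D[cbind(grid$a, grid$b)]
  grid <- grid[order(-grid$Dab, grid$a, grid$b), , drop = FALSE]
  pairs <- data.frame(Ks = seq_len(nrow(grid)),
                      Kg_a = grid$a,
                      protein_a = groups$protein_name[grid$a],
                      Kg_b = grid$b,
                      protein_b = groups$protein_name[grid$b],
                      Dab = grid$Dab)
  rownames(pairs) <- NULL

  structure(list(Ds_t = Ds_t_df, Ds_ud = Ds_ud_df, pairs = pairs),
            class = "sensitivity_aggregates")
}

#' @export
print.sensitivity_aggregates <- function(x, ...) {
  cat("sensitivity aggregates:\n")
  cat(sprintf("  %d (a, b) ranked pairs; top: %s <- %s (Dab = %.6f)\n",
              nrow(x$pairs), x$pairs$protein_a[1], x$pairs$protein_b[1],
              x$pairs$Dab[1]))
  cat(sprintf("  Ds_ud rank 1: %s (%.6f)\n",
              x$Ds_ud$protein[1], x$Ds_ud$Ds_ud[1]))
  invisible(x)
}
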