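#' Select external influencer (X) proteins by aggregate sensitivity
#'
#' Implements the external-protein determination procedure: starting from an
#' internal group (seed t-proteins plus experimentally ranked up/down
#' responders), (i) enumerate every node outside the group with at least one
#' direct link into the top `n_top_up` up-proteins or top `n_top_down`
#' down-proteins; (ii) form the intermediary subset of the internals (in
#' table order) followed by the candidates ordered by global PageRank
#' index; (iii) compute its reduced Google matrix and sensitivity matrix;
#' (iv) score every candidate b by
#' Ds_5p5(b) = sum over the top-response rows a of D\[a, b\]; and (v) keep
#' the `n_select` highest-scoring candidates, ordered by local PageRank as
#' the new x-subgroup.
#'
#' @param network a [ppi_network].
#' @param groups the internal group table (`protein_groups`, subgroups
#'   t/u/d) resolving into `network`.
#' @param alpha damping factor.
#' @param n_top_up,n_top_down how many top up-/down-proteins define the
#'   target set (defaults 5 and 5).
#' @param n_select how many external proteins to keep (default 10).
#' @param count_neutral whether neutral-sign links count as "a link into the
#'   targets" (default `TRUE`: the simple network is unsigned).
#' @param model,model_P optional precomputed [google_matrix] and its
#'   PageRank vector.
#' @param method REGOMAX route, see [reduced_google].
#' @return an object of class `x_selection`: list with `candidates` (data
#'   frame: node_id, global rank `K_global`, `links_to_targets`,
#'   `Ds_5p5`), `n_candidates`, `n_links`, `selected` (data frame with
#'   `Kx`, node_id, `Ds_5p5`, local PageRank `Pr_local`), `groups`
#'   (input table with the x rows appended), `rs` (the intermediary
#'   [reduced_google]), and `sens`.
#' @export
select_x_proteins <- function(network, groups, alpha = 0.85,
                              n_top_up = 5L, n_top_down = 5L,
                              n_select = 10L, count_neutral = TRUE,
                              model = NULL, model_P = NULL,
                              method = "dense_solve") {
  stopifnot(inherits(network, "ppi_network"))
  groups <- as_protein_groups(as.data.frame(groups), network)
  if (any(groups$subgroup == "x"))
    stop("group table already contains an x subgroup")
  internal <- groups$node_index
  up_rows <- group_rows(groups, "u", seq_len(n_top_up))
  down_rows <- group_rows(groups, "d", seq_len(n_top_down))
  target_rows <- c(up_rows, down_rows)
  targets <- groups$node_index[target_rows]

  e <- network$edges
  if (!count_neutral) e <- e[e$sign != 0L, , drop = FALSE]
  into <- e[e$dst %in% targets, c("src", "dst")]
  into <- unique(into)                      # binary link counting
  into <- into[!(into$src %in% internal), , drop = FALSE]
  if (nrow(into) == 0)
    stop("no external candidates: no node outside the group links into the top-response proteins")
  cand <- sort(unique(into$src))
  links_per_cand <- as.integer(table(factor(into$src, levels = cand)))
  n_links <- nrow(into)

  if (is.null(model)) model <- google_matrix(network, alpha = alpha)
  if (is.null(model_P)) {
    pr <- pagerank(model)
    model_P <- pr$P; Kglob <- pr$K
  } else {
    Kglob <- integer(network$N)
    Kglob[order(-model_P, seq_along(model_P))] <- seq_len(network$N)
  }
  ord <- order(Kglob[cand], network$node_ids[cand])
  cand <- cand[ord]; links_per_cand <- links_per_cand[ord]

  subset <- c(internal, cand)
  rs <- reduced_google(model, subset, method = method, P = model_P)
  sens <- sensitivity_matrix(rs)
  n_int <- length(internal)
  cand_pos <- n_int + seq_along(cand)
  Ds <- colSums(sens$D[target_rows, cand_pos, drop = FALSE])

  n_select <- min(n_select, length(cand))
  pick <- order(-Ds, seq_along(Ds))[seq_len(n_select)]
  # x rows are ordered by local PageRank within the intermediary reduction
  pick <- pick[order(-rs$Pr[cand_pos[pick]], pick)]

  selected <- data.frame(
    Kx = seq_len(n_select),
    node_id = network$node_ids[cand[pick]],
    node_index = cand[pick],
    Ds_5p5 = Ds[pick],
    Pr_local = rs$Pr[cand_pos[pick]],
    K_global = Kglob[cand[pick]])

  xrows <- data.frame(Kg = nrow(groups) + seq_len(n_select),
                      subgroup = "x",
                      subgroup_index = seq_len(n_select),
                      node_id = selected$node_id,
                      protein_name = selected$node_id)
  base <- as.data.frame(groups)
  keep <- intersect(names(base), names(xrows))
  out_groups <- rbind(base[keep], xrows[keep])
  out_groups <- as_protein_groups(out_groups, network)

  structure(list(
    candidates = data.frame(node_id = network$node_ids[cand],
                            node_index = cand,
                            K_global = Kglob[cand],
                            links_to_targets = links_per_cand,
                            Ds_5p5 = Ds),
    n_candidates = length(cand),
    n_links = n_links,
    selected = selected,
    groups = out_groups,
    rs = rs, sens = sens,
    target_rows = target_rows
  ), class = "x_selection")
}

#' @export
print.x_selection <- function(x, ...) {
  cat(sprintf("x_selection: %d candidates carrying %d links into the targets\n",
              x$n_candidates, x$n_links))
  cat(sprintf("  intermediary reduction: Nr = %d\n", x$rs$Nr))
  cat("  selected:",
      paste(sprintf("%s (Ds=%.4g)", x$selected$node_id, x$selected$Ds_5p5),
            collapse = ", "), "\n")
  invisible(x)
}
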