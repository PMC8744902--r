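#' Signed directed interaction networks
#'
#' A `ppi_network` stores a directed network whose links carry a sign:
#' `+1` for activation, `-1` for inhibition, `0` for neutral/unknown
#' interactions.  Nodes are identified by character ids; edges are kept as
#' integer index pairs together with their sign and a multiplicity counting
#' repeated identical (source, target, sign) records.  Self-loops are
#' excluded: the analyses in this package are defined on networks counted
#' without self-connections.
#'
#' The simple (unsigned) network used for PageRank and the reduced Google
#' matrix treats the adjacency as binary, ignoring both sign and
#' multiplicity; multiplicity matters only for the Ising doubling, where
#' repeated interactions add their sigma-blocks.
#'
#' @param edges a data frame with character columns `source`, `target` and a
#'   `sign` column holding `activation` / `inhibition` / `neutral` tokens
#'   (case-insensitive) or the numeric codes `+1`, `-1`, `0`.
#' @param node_ids optional character vector fixing the node set and its
#'   order; defaults to first-appearance order over sources then targets.
#' @param drop_self_loops drop edges with `source == target` (default `TRUE`).
#' @return an object of class `ppi_network` with elements `node_ids`,
#'   `edges` (data frame `src`, `dst`, `sign`, `mult` with 1-based indices),
#'   `N`, and the per-sign distinct-edge counts `N_plus`, `N_minus`,
#'   `N_neutral`.
#' @export
ppi_network <- function(edges, node_ids = NULL, drop_self_loops = TRUE) {
  stopifnot(is.data.frame(edges))
  need <- c("source", "target", "sign")
  if (!all(need %in% names(edges)))
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  src_id <- as.character(edges$source)
  dst_id <- as.character(edges$target)
  sgn <- parse_sign(edges$sign)
  if (is.null(node_ids))
    node_ids <- unique(c(src_id, dst_id))
  else {
    node_ids <- as.character(node_ids)
    missing <- setdiff(unique(c(src_id, dst_id)), node_ids)
    if (length(missing))
      stop("edges reference nodes absent from node_ids: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  src <- match(src_id, node_ids)
  dst <- match(dst_id, node_ids)
  if (drop_self_loops) {
    keep <- src != dst
    src <- src[keep]; dst <- dst[keep]; sgn <- sgn[keep]
  } else if (any(src == dst)) {
    stop("self-loops present and drop_self_loops = FALSE is not supported")
  }
  # aggregate identical (src, dst, sign) triples into a multiplicity
  if (length(src)) {
    key <- paste(src, dst, sgn)
    tab <- table(factor(key, levels = unique(key)))
    first <- !duplicated(key)
    e <- data.frame(src = src[first], dst = dst[first], sign = sgn[first],
                    mult = as.integer(tab))
    o <- order(e$src, e$dst, e$sign)
    e <- e[o, , drop = FALSE]
    rownames(e) <- NULL
  } else {
    e <- data.frame(src = integer(0), dst = integer(0), sign = integer(0),
                    mult = integer(0))
  }
  structure(list(
    node_ids = node_ids,
    edges = e,
    N = length(node_ids),
    N_plus = sum(e$sign == 1L),
    N_minus = sum(e$sign == -1L),
    N_neutral = sum(e$sign == 0L)
  ), class = "ppi_network")
}

parse_sign <- function(x) {
  if (is.numeric(x)) {
    s <- as.integer(x)
    if (!all(s %in% c(-1L, 0L, 1L))) stop("numeric signs must be -1, 0 or +1")
    return(s)
  }
  tok <- tolower(trimws(as.character(x)))
  s <- c(activation = 1L, inhibition = -1L, neutral = 0L)[tok]
  if (anyNA(s)) {
    bad <- which(is.na(s))[1]
    stop(sprintf("unknown sign token '%s' at edge record %d", tok[bad], bad))
  }
  unname(s)
}

sign_token <- function(s) c("inhibition", "neutral", "activation")[s + 2L]

#' Read a signed edge list from a TSV file
#'
#' The expected dialect is tab-separated with a `source`, `target`, `sign`
#' header; sign tokens are `activation`, `inhibition`, `neutral`
#' (case-insensitive).  Repeated identical lines become edge multiplicity.
#'
#' @param path file path.
#' @param drop_self_loops remove self-loops while reading (default `TRUE`).
#' @return a [ppi_network].
#' @export
read_edge_list <- function(path, drop_self_loops = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          quote = "", comment.char = "")
  if (nrow(df) == 0) stop("empty edge list: ", path)
  # report parse errors with the 1-based data line (header is line 1)
  tok <- tolower(trimws(df$sign))
  bad <- which(!tok %in% c("activation", "inhibition", "neutral"))
  if (length(bad))
    stop(sprintf("unknown sign token '%s' at line %d of %s",
                 df$sign[bad[1]], bad[1] + 1L, path))
  ppi_network(df, drop_self_loops = drop_self_loops)
}

#' Write a network back to the edge-list TSV dialect
#'
#' Multiplicity is expanded into repeated lines so that reading the file
#' reproduces the identical edge multiset.
#'
#' @param network a [ppi_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  e <- network$edges
  idx <- rep(seq_len(nrow(e)), e$mult)
  out <- data.frame(source = network$node_ids[e$src[idx]],
                    target = network$node_ids[e$dst[idx]],
                    sign = sign_token(e$sign[idx]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a signed directed network
#'
#' @param network a [ppi_network].
#' @return a list with `N`, `links` (distinct signed links), per-sign counts,
#'   `multi_links` (links with multiplicity > 1), and `mean_links`
#'   (links per node, `links / N`).
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  links <- nrow(network$edges)
  list(N = network$N,
       links = links,
       N_plus = network$N_plus,
       N_minus = network$N_minus,
       N_neutral = network$N_neutral,
       multi_links = sum(network$edges$mult > 1L),
       mean_links = links / network$N)
}

#' @export
print.ppi_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("ppi_network: %d nodes, %d signed links (%.2f per node)\n",
              s$N, s$links, s$mean_links))
  cat(sprintf("  activation %d | inhibition %d | neutral %d | multi-edges %d\n",
              s$N_plus, s$N_minus, s$N_neutral, s$multi_links))
  invisible(x)
}

#' @export
summary.ppi_network <- function(object, ...) network_summary(object)

#' Read a protein group annotation table
#'
#' The table mirrors the fibrosis study layout: a contiguous global index
#' `Kg`, a subgroup letter (`t` for the TGF-beta seeds, `u`/`d` for up- and
#' down-regulated responders, `x` for external influencers), the index
#' within the subgroup, a node id resolving into the network, and a display
#' name.  Additional annotation columns (e.g. global rank indices) are
#' carried through untouched.
#'
#' @param path TSV file with header columns `Kg`, `subgroup`,
#'   `subgroup_index`, `node_id`, `protein_name`.
#' @param network optional [ppi_network]; when given, every `node_id` must
#'   resolve to a network node and a `node_index` column is attached.
#' @return a data frame of class `protein_groups`, ordered by `Kg`.
#' @export
read_group_table <- function(path, network = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  as_protein_groups(df, network)
}

#' Validate a group annotation data frame
#'
#' @param df data frame with the [read_group_table] columns.
#' @inheritParams read_group_table
#' @return a `protein_groups` data frame.
#' @export
as_protein_groups <- function(df, network = NULL) {
  need <- c("Kg", "subgroup", "subgroup_index", "node_id", "protein_name")
  if (!all(need %in% names(df)))
    stop("group table must have columns: ", paste(need, collapse = ", "))
  df$Kg <- as.integer(df$Kg)
  df$subgroup <- tolower(as.character(df$subgroup))
  df$subgroup_index <- as.integer(df$subgroup_index)
  df$node_id <- as.character(df$node_id)
  df <- df[order(df$Kg), , drop = FALSE]
  rownames(df) <- NULL
  if (!identical(df$Kg, seq_len(nrow(df))))
    stop("Kg values must be contiguous 1..", nrow(df))
  if (!all(df$subgroup %in% c("t", "u", "d", "x")))
    stop("subgroup labels must be one of t, u, d, x")
  for (g in unique(df$subgroup)) {
    idx <- df$subgroup_index[df$subgroup == g]
    if (!identical(sort(idx), seq_along(idx)))
      stop("subgroup_index not contiguous within subgroup '", g, "'")
  }
  if (anyDuplicated(df$node_id)) stop("node_id values must be unique")
  if (!is.null(network)) {
    stopifnot(inherits(network, "ppi_network"))
    hit <- match(df$node_id, network$node_ids)
    if (anyNA(hit))
      stop("group table node ids absent from network: ",
           paste(df$node_id[is.na(hit)], collapse = ", "))
    df$node_index <- hit
  }
  class(df) <- c("protein_groups", "data.frame")
  df
}

#' Write a group table in the package TSV dialect
#'
#' @param groups a `protein_groups` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(groups, path) {
  utils::write.table(as.data.frame(groups), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# row indices (into the Kg-ordered table) of one subgroup, ordered by index
group_rows <- function(groups, subgroup, indices = NULL) {
  r <- which(groups$subgroup == subgroup)
  r <- r[order(groups$subgroup_index[r])]
  if (!is.null(indices)) {
    r <- r[match(indices, groups$subgroup_index[r])]
    if (anyNA(r))
      stop("missing ", subgroup, "-subgroup indices: ",
           paste(indices[is.na(match(indices, groups$subgroup_index[groups$subgroup == subgroup]))],
                 collapse = ", "))
  }
  r
}
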