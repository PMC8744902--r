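#' Friend/follower interaction diagram
#'
#' Builds the effective-network diagram from a reduced-matrix component `g`
#' (either GR or Grr + Gqr_nd): matrix element g\[a, b\] is the strength of
#' the link b -> a, so the "friends" of node n are the `branch` strongest
#' entries of column n (nodes n points to most strongly) and its
#' "followers" the `branch` strongest entries of row n.  Strength is the
#' modulus of the matrix element; the signed value is kept as an edge
#' attribute.  Expansion starts from five (or any number of) level-0 top
#' nodes and is repeated for `levels` stages; nodes already placed get an
#' edge but no new placement.  Links whose two endpoints both belong to the
#' seed/external (t and x) subgroups are skipped.  Ties in strength break by
#' ascending table position (Kg).
#'
#' @param g an Nr x Nr matrix aligned with `groups` (row/column i = Kg i).
#' @param groups a `protein_groups` table with `nrow(groups) == nrow(g)`.
#' @param top_labels character labels of the level-0 nodes, in subgroup
#'   notation: `"U1"`, `"D2"`, `"X9"`, `"T1"`, ...
#' @param mode `"friend"` or `"follower"`.
#' @param branch how many strongest partners to take per node (default 4).
#' @param levels number of expansion stages beyond level 0 (default 2).
#' @return an object of class `ppi_diagram`: list with data frames `nodes`
#'   (`id` = Kg, `label`, `level`, `parent`, `color`) and `edges`
#'   (`from`, `to` as Kg, `stage`, `strength` signed), plus `mode`.
#' @export
build_diagram <- function(g, groups, top_labels,
                          mode = c("friend", "follower"),
                          branch = 4L, levels = 2L) {
  mode <- match.arg(mode)
  Nr <- nrow(groups)
  if (!all(dim(g) == Nr)) stop("matrix g must be ", Nr, " x ", Nr)
  lab <- diagram_labels(groups)
  top <- match(toupper(top_labels), lab)
  if (anyNA(top))
    stop("unknown top node label(s): ",
         paste(top_labels[is.na(top)], collapse = ", "))
  red <- groups$subgroup %in% c("t", "x")

  nodes <- data.frame(id = top, label = lab[top], level = 0L,
                      parent = NA_integer_)
  edges <- data.frame(from = integer(0), to = integer(0),
                      stage = character(0), strength = numeric(0))
  placed <- top
  frontier <- top
  for (lev in seq_len(levels)) {
    stage <- if (lev == 1L) "primary" else "secondary"
    new_frontier <- integer(0)
    for (a in frontier) {
      strength <- if (mode == "friend") g[, a] else g[a, ]
      strength[a] <- 0
      if (red[a]) strength[red] <- 0   # no links internal to the t/x group
      ord <- order(-abs(strength), seq_len(Nr))
      ord <- ord[abs(strength[ord]) > 0]
      pick <- utils::head(ord, branch)
      for (b in pick) {
        edges <- rbind(edges, data.frame(
          from = if (mode == "friend") a else b,
          to = if (mode == "friend") b else a,
          stage = stage, strength = strength[b]))
        if (!(b %in% placed)) {
          nodes <- rbind(nodes, data.frame(id = b, label = lab[b],
                                           level = lev, parent = a))
          placed <- c(placed, b)
          new_frontier <- c(new_frontier, b)
        }
      }
    }
    frontier <- new_frontier
    if (!length(frontier)) break
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mode = mode,
                 branch = branch, levels = levels),
            class = "ppi_diagram")
}

diagram_labels <- function(groups) {
  paste0(toupper(groups$subgroup), groups$subgroup_index)
}

#' Color diagram nodes by subgroup allegiance
#'
#' Seed (t) and external (x) proteins are red.  An up-protein Uj is olive
#' when it is a stronger follower of U1 than of U2 with respect to the
#' direct-plus-indirect matrix `g_nd` = Grr + Gqr_nd, i.e. when
#' g_nd\[row(U1), col(Uj)\] > g_nd\[row(U2), col(Uj)\], and green
#' otherwise (ties fall to green: the comparison is a strict inequality).
#' Down-proteins are cyan (closer to D1) or blue (closer to D2) the same
#' way.  U1/U2/D1/D2 keep their own colors.  Coloring always uses
#' Grr + Gqr_nd, whatever matrix the diagram was built from.
#'
#' @param graph a `ppi_diagram`.
#' @param g_nd the Grr + Gqr_nd matrix aligned with `groups`.
#' @param groups the `protein_groups` table.
#' @return the diagram with a `color` column filled in.
#' @export
color_diagram <- function(graph, g_nd, groups) {
  stopifnot(inherits(graph, "ppi_diagram"))
  u1 <- group_rows(groups, "u", 1L); u2 <- group_rows(groups, "u", 2L)
  d1 <- group_rows(groups, "d", 1L); d2 <- group_rows(groups, "d", 2L)
  col <- character(nrow(graph$nodes))
  for (k in seq_len(nrow(graph$nodes))) {
    i <- graph$nodes$id[k]
    sg <- groups$subgroup[i]
    col[k] <- switch(sg,
      t = , x = "red",
      u = if (i == u1) "olive"
          else if (i == u2) "green"
          else if (g_nd[u1, i] > g_nd[u2, i]) "olive" else "green",
      d = if (i == d1) "cyan"
          else if (i == d2) "blue"
          else if (g_nd[d1, i] > g_nd[d2, i]) "cyan" else "blue")
  }
  graph$nodes$color <- col
  graph
}

#' @export
print.ppi_diagram <- function(x, ...) {
  cat(sprintf("ppi_diagram (%s): %d nodes (levels %s), %d edges\n",
              x$mode, nrow(x$nodes),
              paste(range(x$nodes$level), collapse = "-"), nrow(x$edges)))
  invisible(x)
}

diagram_igraph <- function(graph) {
  nodes <- graph$nodes
  v <- data.frame(name = as.character(nodes$id),
                  label = nodes$label,
                  level = nodes$level,
                  parent = ifelse(is.na(nodes$parent), "",
                                  as.character(nodes$parent)))
  if (!is.null(nodes$color)) v$color <- nodes$color
  if (nrow(graph$edges)) {
    ed <- data.frame(from = as.character(graph$edges$from),
                     to = as.character(graph$edges$to),
                     stage = graph$edges$stage,
                     strength = graph$edges$strength)
  } else {
    ed <- data.frame(from = character(0), to = character(0),
                     stage = character(0), strength = numeric(0))
  }
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = v)
}

#' Export a diagram to DOT or GraphML
#'
#' Node attributes `label`, `level`, `parent`, `color` and edge attributes
#' `stage` (primary expansions vs. secondary) and `strength` (signed matrix
#' element) are written; layout is left to the renderer.
#'
#' @param graph a `ppi_diagram`.
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_diagram <- function(graph, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  ig <- diagram_igraph(graph)
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}
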