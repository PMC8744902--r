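# a small group table: 2 t, 4 u, 4 d, 2 x = 12 proteins
toy_groups <- function() {
  data.frame(Kg = 1:12,
             subgroup = c("t", "t", rep("u", 4), rep("d", 4), "x", "x"),
             subgroup_index = c(1:2, 1:4, 1:4, 1:2),
             node_id = paste0("p", 1:12),
             protein_name = paste0("p", 1:12))
}

toy_matrix <- function(seed = 1) {
  set.seed(seed)
  g <- matrix(stats::runif(144, 0, 0.1), 12, 12)
  diag(g) <- 0
  g
}

test_that("zero levels yield top nodes only", {
  dg <- build_diagram(toy_matrix(), toy_groups(),
                      c("U1", "U2", "D1", "D2", "X2"), levels = 0)
  expect_equal(nrow(dg$nodes), 5)
  expect_equal(nrow(dg$edges), 0)
  expect_equal(dg$nodes$level, rep(0L, 5))
})

test_that("friend expansion picks the strongest column entries", {
  g <- matrix(0, 12, 12)
  # column of U1 (Kg 3): strengths into rows 4, 5, 7, 8, 9
  g[c(4, 5, 7, 8, 9), 3] <- c(0.4, 0.3, 0.2, 0.1, 0.05)
  dg <- build_diagram(g, toy_groups(), "U1", branch = 4, levels = 1)
  picked <- dg$edges$to[dg$edges$from == 3]
  # brute-force sort of the column
  want <- order(-abs(g[, 3]))[1:4]
  expect_setequal(picked, want)
  expect_true(all(dg$edges$stage == "primary"))
  # follower mode reads the row instead
  gt <- t(g)
  df <- build_diagram(gt, toy_groups(), "U1", branch = 4, levels = 1,
                      mode = "follower")
  expect_setequal(df$edges$from[df$edges$to == 3], want)
})

test_that("edges internal to the seed/external group are excluded", {
  dg <- build_diagram(toy_matrix(2), toy_groups(),
                      c("T1", "X1", "U1", "D1", "D2"), levels = 2)
  red <- which(toy_groups()$subgroup %in% c("t", "x"))
  both_red <- dg$edges$from %in% red & dg$edges$to %in% red
  expect_equal(sum(both_red), 0)
  # branch bound: at most 4 expansion edges per (node, stage)
  per <- table(paste(dg$edges$from, dg$edges$stage))
  expect_true(all(per <= 4))
  # every non-root node has exactly one parent at the previous level
  nn <- dg$nodes[dg$nodes$level > 0, ]
  for (k in seq_len(nrow(nn))) {
    p <- dg$nodes$level[dg$nodes$id == nn$parent[k]]
    expect_equal(p, nn$level[k] - 1L)
  }
})

test_that("construction is deterministic and tie-broken by table order", {
  g <- toy_matrix(3)
  a <- build_diagram(g, toy_groups(), c("U1", "D1"), levels = 2)
  b <- build_diagram(g, toy_groups(), c("U1", "D1"), levels = 2)
  expect_identical(a, b)
  # exact ties resolve to the smaller Kg
  gt <- matrix(0, 12, 12)
  gt[c(7, 8), 3] <- 0.2
  dg <- build_diagram(gt, toy_groups(), "U1", branch = 1, levels = 1)
  expect_equal(dg$edges$to, 7)
  expect_error(build_diagram(gt, toy_groups(), "U9"), "unknown top")
})

test_that("colors follow the follower-allegiance rule", {
  groups <- toy_groups()
  g_nd <- matrix(0, 12, 12)
  u1 <- 3; u2 <- 4; d1 <- 7; d2 <- 8
  g_nd[u1, 5] <- 0.02; g_nd[u2, 5] <- 0.01   # U3 closer to U1 -> olive
  g_nd[u1, 6] <- 0.01; g_nd[u2, 6] <- 0.01   # tie -> green (strict >)
  g_nd[d1, 9] <- 0.00; g_nd[d2, 9] <- 0.03   # D3 closer to D2 -> blue
  dg <- build_diagram(toy_matrix(4), groups,
                      c("U1", "U2", "D1", "D2", "X1"), levels = 2)
  dg <- color_diagram(dg, g_nd, groups)
  col <- function(kg) dg$nodes$color[dg$nodes$id == kg]
  for (kg in which(groups$subgroup %in% c("t", "x")))
    if (kg %in% dg$nodes$id) expect_equal(col(kg), "red")
  expect_equal(col(u1), "olive"); expect_equal(col(u2), "green")
  expect_equal(col(d1), "cyan"); expect_equal(col(d2), "blue")
  if (5 %in% dg$nodes$id) expect_equal(col(5), "olive")
  if (6 %in% dg$nodes$id) expect_equal(col(6), "green")
  if (9 %in% dg$nodes$id) expect_equal(col(9), "blue")
  expect_error(color_diagram(dg, g_nd, groups[-3, ]))
})

test_that("exports round-trip through GraphML and emit DOT", {
  groups <- toy_groups()
  dg <- build_diagram(toy_matrix(5), groups,
                      c("U1", "U2", "D1", "D2", "X1"), levels = 2)
  dg <- color_diagram(dg, toy_matrix(6), groups)

  fdot <- withr::local_tempfile(fileext = ".dot")
  export_diagram(dg, fdot, "dot")
  txt <- readLines(fdot)
  expect_true(any(grepl("digraph", txt)))

  fml <- withr::local_tempfile(fileext = ".graphml")
  export_diagram(dg, fml, "graphml")
  ig <- igraph::read_graph(fml, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(dg$nodes))
  expect_equal(igraph::ecount(ig), nrow(dg$edges))
  expect_setequal(igraph::V(ig)$label, dg$nodes$label)
  expect_setequal(igraph::E(ig)$stage, dg$edges$stage)
  expect_equal(sort(igraph::E(ig)$strength), sort(dg$edges$strength),
               tolerance = 1e-12)
  # red-group exclusion survives export
  nm <- igraph::V(ig)$name
  red <- as.character(which(groups$subgroup %in% c("t", "x")))
  el <- igraph::as_edgelist(ig)
  expect_equal(sum(el[, 1] %in% red & el[, 2] %in% red), 0)
  expect_error(export_diagram(dg, fdot, "gml"), "arg")
})

test_that("levels=0 graphs export cleanly", {
  dg <- build_diagram(toy_matrix(), toy_groups(),
                      c("U1", "U2", "D1", "D2", "X2"), levels = 0)
  f <- withr::local_tempfile(fileext = ".dot")
  export_diagram(dg, f, "dot")
  ig <- diagram_igraph <- regomax:::diagram_igraph(dg)
  expect_equal(igraph::vcount(ig), 5)
  expect_equal(igraph::ecount(ig), 0)
})
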