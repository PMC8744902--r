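# reconstruct column j of the implicit G by applying it to a basis vector
g_column <- function(model, j) {
  v <- rep(0, model$N); v[j] <- 1
  regomax:::gm_apply(model, v)
}

test_that("Google matrix columns follow the damped-stochastic definition", {
  # all-dangling: every column uniform
  m0 <- google_matrix(edgeless_net(2), 0.85)
  expect_equal(g_column(m0, 1), c(0.5, 0.5))
  expect_equal(g_column(m0, 2), c(0.5, 0.5))

  # single edge 1 -> 2: hand evaluation of alpha*S + (1-alpha)/N
  m <- google_matrix(two_node_net(), 0.85)
  expect_equal(g_column(m, 1), c(0.075, 0.925))
  expect_equal(g_column(m, 2), c(0.5, 0.5))        # node 2 dangling

  # inverted construction flips the edge; node 1 becomes dangling
  mi <- google_matrix(two_node_net(), 0.85, inverted = TRUE)
  expect_equal(g_column(mi, 2), c(0.925, 0.075))
  expect_equal(g_column(mi, 1), c(0.5, 0.5))

  expect_error(google_matrix(two_node_net(), alpha = 1), "alpha")
  expect_error(google_matrix(two_node_net(), alpha = 0), "alpha")
})

test_that("implicit G matches a dense literal construction", {
  net <- generate_ppi_network(60, seed = 4, multi_edge_prob = 0.2)
  for (inv in c(FALSE, TRUE)) {
    model <- google_matrix(net, 0.85, inverted = inv)
    G <- dense_google_oracle(net, 0.85, inverted = inv)
    got <- vapply(seq_len(net$N), function(j) g_column(model, j),
                  numeric(net$N))
    expect_lt(max(abs(got - G)), 1e-14)
  }
})

test_that("PageRank solves GP = P with normalized positive entries", {
  # symmetric edgeless case
  expect_equal(pagerank(google_matrix(edgeless_net(2)))$P, c(0.5, 0.5))
  # 2x2 closed form: P1 = 0.5 / (1 + alpha - alpha/2)
  pr <- pagerank(google_matrix(two_node_net(), 0.85))
  expect_equal(pr$P, c(0.5 / 1.425, 1 - 0.5 / 1.425), tolerance = 1e-10)
  expect_equal(round(pr$P, 5), c(0.35088, 0.64912))
  expect_equal(pr$K, c(2L, 1L))

  net <- generate_ppi_network(200, seed = 6)
  model <- google_matrix(net)
  pr2 <- pagerank(model)
  expect_equal(sum(pr2$P), 1, tolerance = 1e-12)
  expect_true(all(pr2$P >= (1 - 0.85) / net$N - 1e-15))  # teleport floor
  expect_setequal(pr2$K, seq_len(net$N))
  # fixed point of the implicit operator
  expect_lt(sum(abs(regomax:::gm_apply(model, pr2$P) - pr2$P)), 1e-12)
  # agrees with the dense oracle
  expect_lt(max(abs(pr2$P - dense_power_oracle(dense_google_oracle(net)))),
            1e-12)
})

test_that("probability is conserved under the implicit operator", {
  net <- generate_ppi_network(150, seed = 8)
  model <- google_matrix(net)
  set.seed(1)
  for (i in 1:10) {
    v <- stats::runif(net$N); v <- v / sum(v)
    expect_equal(sum(regomax:::gm_apply(model, v)), 1, tolerance = 1e-12)
  }
})

test_that("CheiRank equals PageRank of the pre-flipped network", {
  net <- generate_ppi_network(120, seed = 10)
  e <- net$edges
  i <- rep(seq_len(nrow(e)), e$mult)
  flipped <- ppi_network(
    data.frame(source = net$node_ids[e$dst[i]],
               target = net$node_ids[e$src[i]],
               sign = e$sign[i]),
    node_ids = net$node_ids)
  a <- pagerank(google_matrix(net, inverted = TRUE))
  b <- pagerank(google_matrix(flipped))
  expect_true(a$is_cheirank)
  expect_equal(a$P, b$P, tolerance = 1e-13)
  expect_identical(a$K, b$K)
})

test_that("rank-plane density divides counts by cell capacity", {
  # brute-force oracle over 4 points on a 2x2 grid
  N <- 4; bins <- 2
  K <- 1:4; Ks <- 1:4
  edges <- seq(0, log(N), length.out = bins + 1)
  binof <- function(k) min(findInterval(log(k), edges,
                                        rightmost.closed = TRUE), bins)
  cap <- counts <- matrix(0, bins, bins)
  for (i in 1:N) for (j in 1:N)
    cap[binof(i), binof(j)] <- cap[binof(i), binof(j)] + 1
  for (n in 1:N)
    counts[binof(K[n]), binof(Ks[n])] <- counts[binof(K[n]), binof(Ks[n])] + 1
  want <- ifelse(cap > 0, counts / cap, 0); want <- want / sum(want)

  grid <- rank_plane_density(K, Ks, bins = bins)
  expect_equal(unclass(grid), want, ignore_attr = TRUE)
  expect_true(all(grid[row(grid) != col(grid)] == 0))  # diagonal input
  expect_equal(sum(grid), 1)

  # any valid input normalizes to 1
  net <- generate_ppi_network(100, seed = 12)
  pr <- pagerank(google_matrix(net))
  cr <- pagerank(google_matrix(net, inverted = TRUE))
  g2 <- rank_plane_density(pr$K, cr$K, bins = 10)
  expect_equal(sum(g2), 1, tolerance = 1e-12)

  expect_error(rank_plane_density(1:4, 1:5), "equal length")
  expect_error(rank_plane_density(1, 1), "at least 2")
})
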