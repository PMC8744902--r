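test_that("link perturbation rescales one column and stays stochastic", {
  GR <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2)
  # hand evaluation: column 2 becomes (0.66, 0.4)/1.06
  out <- perturb_reduced(GR, 1, 2, 0.1)
  expect_equal(out[, 2], c(0.66, 0.4) / 1.06, tolerance = 1e-14)
  expect_equal(out[, 1], GR[, 1])
  expect_equal(colSums(out), c(1, 1), tolerance = 1e-14)

  # zero element: fixed point for any eps
  GRz <- matrix(c(0.3, 0.7, 0, 1), 2, 2)
  expect_equal(perturb_reduced(GRz, 1, 2, 0.3), GRz)
  # concentrated column: (1+eps)/(1+eps) = 1
  expect_equal(perturb_reduced(GRz, 2, 2, 0.5), GRz)
})

test_that("exact derivative matches central finite differences", {
  set.seed(21)
  worst <- 0
  for (case in 1:5) {
    GR <- random_stochastic(20, seed = 100 + case)
    rs <- fake_reduced(GR)
    pairs <- cbind(sample(20, 20, TRUE), sample(20, 20, TRUE))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      eps <- 1e-6
      pe <- dense_power_oracle(perturb_reduced(GR, a, b, eps))
      pm <- dense_power_oracle(perturb_reduced(GR, a, b, -eps))
      fd <- (pe[a] - pm[a]) / (2 * eps * rs$Pr[a])
      Dab <- pagerank_sensitivity(rs, a, b)[a]
      rel <- abs(Dab - fd) / max(abs(fd), 1e-12)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("sensitivity respects sparsity and normalization", {
  GR <- random_stochastic(10, seed = 5)
  GR[3, 7] <- 0; GR <- sweep(GR, 2, colSums(GR), "/")
  rs <- fake_reduced(GR)
  expect_equal(pagerank_sensitivity(rs, 3, 7), rep(0, 10))
  sm <- sensitivity_matrix(rs)
  expect_equal(sm$D[3, 7], 0)
  # zero-sum: perturbed PageRank stays normalized
  for (k in 1:20) {
    a <- ((k - 1) %% 10) + 1; b <- ((k * 3) %% 10) + 1
    v <- pagerank_sensitivity(rs, a, b)
    expect_lt(abs(sum(v * rs$Pr)), 1e-12)
  }
  # matrix route equals the vector route at j = a
  for (a in c(1, 4, 9)) for (b in c(2, 6, 10))
    expect_equal(sm$D[a, b], pagerank_sensitivity(rs, a, b)[a],
                 tolerance = 1e-12)
})

test_that("rank-1 reduced matrices give the closed-form sensitivity", {
  set.seed(9)
  Pr <- stats::rexp(15); Pr <- Pr / sum(Pr)
  GR <- matrix(Pr, 15, 15)              # every column equals Pr
  rs <- fake_reduced(GR, Pr = Pr)
  D <- sensitivity_matrix(rs)$D
  want <- outer(1 - Pr, Pr)
  off <- abs(D - want); diag(off) <- 0
  expect_lt(max(off), 1e-10)
})

test_that("off-diagonal sensitivities are positive on reduced networks", {
  net <- generate_ppi_network(300, seed = 13)
  model <- google_matrix(net)
  P <- pagerank(model)$P
  rs <- reduced_google(model, sort(order(-P)[1:20]), P = P)
  D <- sensitivity_matrix(rs)$D
  off <- D[row(D) != col(D) & rs$GR > 0]
  # coupled off-diagonal entries are expected positive; violations are
  # diagnostics, reported rather than failed hard
  n_neg <- sum(off < 0)
  if (n_neg > 0)
    message(sprintf("negative off-diagonal sensitivities: %d of %d",
                    n_neg, length(off)))
  expect_lt(n_neg / length(off), 0.05)
  # background law D[a,b] ~ (1 - Pr(a)) Pr(b): the Pr(b) trend must point
  # the right way; its strength depends on how dominant Gpr is, so the
  # observed correlation is logged, not bounded
  offm <- row(D) != col(D)
  cors <- stats::cor(as.vector(D[offm]),
                     as.vector(outer(rep(1, 20), rs$Pr))[offm])
  message(sprintf("background-law correlation cor(Dab, Pr(b)) = %.3f", cors))
  expect_gt(cors, 0)
})

test_that("group aggregates equal brute-force double loops", {
  net <- generate_ppi_network(400, seed = 2)
  groups54 <- internal44_groups(net)
  xids <- net$node_ids[301:310]
  groups54 <- rbind(groups54,
                    data.frame(Kg = 45:54, subgroup = "x",
                               subgroup_index = 1:10, node_id = xids,
                               protein_name = xids))
  groups54 <- as_protein_groups(groups54, net)
  model <- google_matrix(net)
  rs <- reduced_google(model, groups54$node_index)
  sm <- sensitivity_matrix(rs)
  agg <- aggregate_sensitivity(sm, groups54)

  D <- sm$D
  rows_ud <- 5:44; cols_t <- 1:4; cols_tx <- c(1:4, 45:54)
  for (b in cols_tx) {
    want <- 0
    for (a in rows_ud) want <- want + D[a, b]
    expect_equal(agg$Ds_ud$Ds_ud[agg$Ds_ud$Kg == b], want)
  }
  for (a in sample(rows_ud, 5)) {
    want <- sum(D[a, cols_t])
    expect_equal(agg$Ds_t$Ds_t[agg$Ds_t$Kg == a], want)
  }
  # 40 x 14 ranked pair list, descending
  expect_equal(nrow(agg$pairs), 560)
  expect_true(all(diff(agg$pairs$Dab) <= 0))
  expect_equal(agg$pairs$Dab[1], max(D[rows_ud, cols_tx]))
  # constant matrix degenerates to tie-break order and 40c sums
  smc <- sm; smc$D <- matrix(0.01, 54, 54)
  aggc <- aggregate_sensitivity(smc, groups54)
  expect_equal(aggc$Ds_ud$Ds_ud, rep(0.4, 14))
  expect_identical(aggc$pairs$Kg_a[1:14], rep(5L, 14))  # ascending a, then b
  expect_error(aggregate_sensitivity(sm, groups54[1:10, ]), "rows")
})
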