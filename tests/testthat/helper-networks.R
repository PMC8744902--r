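# Shared fixture builders; everything is generated in code.

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], target = m[, 2], sign = m[, 3])
}

# simple 3-cycle 1 -> 2 -> 3 -> 1
cycle3_net <- function() {
  ppi_network(edge_df("a", "b", "activation",
                      "b", "c", "activation",
                      "c", "a", "activation"))
}

two_node_net <- function() {
  ppi_network(edge_df("a", "b", "activation"))
}

edgeless_net <- function(n = 2) {
  ppi_network(data.frame(source = character(0), target = character(0),
                         sign = character(0)),
              node_ids = letters[seq_len(n)])
}

write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# independent dense Google matrix built by literal application of the
# definition: binary adjacency, column-normalize, uniform dangling columns,
# damping.  Used as the oracle against the sparse implicit representation.
dense_google_oracle <- function(net, alpha = 0.85, inverted = FALSE) {
  N <- net$N
  A <- matrix(0, N, N)
  e <- net$edges
  for (k in seq_len(nrow(e))) {
    if (inverted) A[e$src[k], e$dst[k]] <- 1 else A[e$dst[k], e$src[k]] <- 1
  }
  S <- A
  for (j in seq_len(N)) {
    cs <- sum(A[, j])
    S[, j] <- if (cs == 0) rep(1 / N, N) else A[, j] / cs
  }
  alpha * S + (1 - alpha) / N
}

# independent power iteration on a dense column-stochastic matrix
dense_power_oracle <- function(G, tol = 1e-15, max_iter = 200000) {
  v <- rep(1 / nrow(G), nrow(G))
  for (i in seq_len(max_iter)) {
    w <- as.numeric(G %*% v); w <- w / sum(w)
    if (sum(abs(w - v)) < tol) return(w)
    v <- w
  }
  stop("oracle did not converge")
}

# minimal stand-in reduced_google object for sensitivity-only tests
fake_reduced <- function(GR, Pr = NULL) {
  if (is.null(Pr)) Pr <- dense_power_oracle(GR)
  structure(list(GR = GR, Pr = Pr, Nr = nrow(GR), subset = seq_len(nrow(GR))),
            class = "reduced_google")
}

random_stochastic <- function(n, seed) {
  set.seed(seed)
  G <- matrix(stats::rexp(n * n), n, n)
  sweep(G, 2, colSums(G), "/")
}

# a 44-protein internal group table over the first 44 nodes of a network
internal44_groups <- function(net) {
  ids <- net$node_ids[1:44]
  data.frame(Kg = 1:44,
             subgroup = c(rep("t", 4), rep("u", 20), rep("d", 20)),
             subgroup_index = c(1:4, 1:20, 1:20),
             node_id = ids, protein_name = ids)
}

# planted-influencer instance: synthetic background plus 3 boosted externals
# wired into the top-5 up and top-5 down targets
planted_case <- function(seed, n = 600, boost = 10) {
  net <- generate_ppi_network(n, seed = seed)
  groups <- internal44_groups(net)
  internal <- groups$node_id
  targets <- c(groups$node_id[5:9], groups$node_id[25:29])
  tidx <- match(targets, net$node_ids)
  linked <- unique(net$edges$src[net$edges$dst %in% tidx])
  pool <- setdiff(45:n, linked)   # externals with no pre-existing target link
  planted <- net$node_ids[pool[1:3]]
  net2 <- plant_influencers(net, internal, targets, planted,
                            boost = boost, seed = seed + 1000L)
  list(net = net2, net0 = net, groups = groups, targets = targets,
       planted = planted)
}
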