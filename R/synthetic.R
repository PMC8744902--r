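#' Generate a MetaCore-like signed directed network
#'
#' Seeded generator of synthetic networks emulating the coarse statistics of
#' large curated interaction databases: N nodes, Poisson out-degrees
#' (truncated to \[1, N-1\]) around a target mean, link targets drawn by
#' preferential attachment on the current in-degree (probability
#' proportional to (in-degree + 1)^`attachment_exponent`), and link signs
#' i.i.d. from the activation/inhibition/neutral fractions.  The defaults
#' mirror the published network statistics: 7.3 links per node and sign
#' fractions (65157, 49321, 177713) / 292191.
#'
#' Self-loops are never drawn.  A duplicate target draw is kept as edge
#' multiplicity with probability `multi_edge_prob` and redrawn otherwise;
#' the default 0 yields a multiplicity-free network, matching the
#' "directed and nonweighted" simple-network convention.
#'
#' @param n node count (>= 2).
#' @param mean_out_degree target mean out-degree (< n - 1).
#' @param sign_fractions probabilities of (activation, inhibition, neutral),
#'   summing to 1 within 1e-12.
#' @param attachment_exponent exponent >= 0 of the in-degree preferential
#'   attachment; 0 gives uniform target choice.
#' @param multi_edge_prob probability in \[0, 1) of keeping a duplicate draw
#'   as multiplicity.
#' @param seed integer seed; one private RNG stream per call (the global
#'   RNG state is restored on exit).
#' @return a [ppi_network] with node ids `n0001`, `n0002`, ...
#' @export
generate_ppi_network <- function(n, mean_out_degree = 7.3,
                                 sign_fractions = c(65157, 49321, 177713) / 292191,
                                 attachment_exponent = 1,
                                 multi_edge_prob = 0,
                                 seed = 1L) {
  if (!(n >= 2)) stop("n must be >= 2")
  if (!(mean_out_degree > 0 && mean_out_degree < n - 1))
    stop("mean_out_degree must be in (0, n - 1)")
  if (length(sign_fractions) != 3 || any(sign_fractions < 0) ||
      abs(sum(sign_fractions) - 1) > 1e-12)
    stop("sign_fractions must be 3 non-negative values summing to 1")
  if (!(attachment_exponent >= 0)) stop("attachment_exponent must be >= 0")
  if (!(multi_edge_prob >= 0 && multi_edge_prob < 1))
    stop("multi_edge_prob must be in [0, 1)")
  n <- as.integer(n)
  ids <- sprintf("n%0*d", nchar(n), seq_len(n))

  with_seed(seed, {
    outdeg <- pmin(pmax(stats::rpois(n, mean_out_degree), 1L), n - 1L)
    indeg <- integer(n)
    w <- rep(1, n)  # (indeg + 1)^gamma
    src <- vector("list", n)
    dst <- vector("list", n)
    for (j in seq_len(n)) {
      k <- outdeg[j]
      got <- integer(0)
      guard <- 0L
      while (length(got) < k) {
        guard <- guard + 1L
        if (guard > 1000L) stop("target sampling failed to fill out-degree")
        cand <- sample.int(n, (k - length(got)) + 2L, replace = TRUE, prob = w)
        for (t in cand) {
          if (length(got) >= k) break
          if (t == j) next
          if (t %in% got &&
              (multi_edge_prob <= 0 || stats::runif(1) >= multi_edge_prob))
            next
          got <- c(got, t)
        }
      }
      src[[j]] <- rep.int(j, k)
      dst[[j]] <- got
      hit <- tabulate(got, nbins = n)
      touched <- which(hit > 0L)
      indeg[touched] <- indeg[touched] + hit[touched]
      w[touched] <- (indeg[touched] + 1)^attachment_exponent
    }
    src <- unlist(src); dst <- unlist(dst)
    sgn <- sample(c(1L, -1L, 0L), length(src), replace = TRUE,
                  prob = sign_fractions)
    ppi_network(data.frame(source = ids[src], target = ids[dst], sign = sgn),
                node_ids = ids, drop_self_loops = TRUE)
  })
}

# evaluate expr under a private RNG stream, restoring global state on exit
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}

#' Plant external influencer nodes into a network
#'
#' Test-harness construction for the influencer-selection procedure: each
#' planted node receives `boost` new direct activation links into distinct
#' members of `target_ids` (making it a strong direct actor on the
#' top-response group) and `boost` new incoming activation links from random
#' other nodes (raising its PageRank).  The input network is not modified;
#' an augmented copy is returned.  With `boost = 0` the copy is identical.
#'
#' @param network a [ppi_network].
#' @param internal_ids node ids playing the experimentally-defined internal
#'   group; planted influencers must not belong to it.
#' @param target_ids node ids of the top-response targets (the wiring
#'   destinations).
#' @param influencer_ids node ids to promote to planted influencers.
#' @param boost number of new outgoing-to-target and incoming links per
#'   influencer.
#' @param seed RNG seed for the random wiring.
#' @return the augmented [ppi_network].
#' @export
plant_influencers <- function(network, internal_ids, target_ids,
                              influencer_ids, boost = 10L, seed = 1L) {
  stopifnot(inherits(network, "ppi_network"))
  resolve <- function(idv, what) {
    i <- match(idv, network$node_ids)
    if (anyNA(i)) stop(what, " ids absent from network: ",
                       paste(idv[is.na(i)], collapse = ", "))
    i
  }
  internal <- resolve(internal_ids, "internal")
  targets <- resolve(target_ids, "target")
  planted <- resolve(influencer_ids, "influencer")
  bad <- intersect(planted, internal)
  if (length(bad))
    stop("planted influencers overlap internal_ids: ",
         paste(network$node_ids[bad], collapse = ", "))
  boost <- as.integer(boost)
  if (boost == 0L) return(network)

  e <- network$edges
  new_src <- integer(0); new_dst <- integer(0)
  with_seed(seed, {
    for (x in planted) {
      have_out <- unique(e$dst[e$src == x])
      avail <- setdiff(setdiff(targets, have_out), x)
      if (length(avail) < boost)
        stop("influencer ", network$node_ids[x],
             ": fewer than boost untouched targets available")
      newt <- avail[sample.int(length(avail), boost)]
      have_in <- unique(e$src[e$dst == x])
      pool <- setdiff(seq_len(network$N), c(have_in, x))
      if (length(pool) < boost)
        stop("influencer ", network$node_ids[x],
             ": fewer than boost available in-link sources")
      news <- pool[sample.int(length(pool), boost)]
      new_src <- c(new_src, rep.int(x, boost), news)
      new_dst <- c(new_dst, newt, rep.int(x, boost))
    }
  })
  idx <- rep(seq_len(nrow(e)), e$mult)
  df <- data.frame(
    source = network$node_ids[c(e$src[idx], new_src)],
    target = network$node_ids[c(e$dst[idx], new_dst)],
    sign = c(e$sign[idx], rep.int(1L, length(new_src))))
  ppi_network(df, node_ids = network$node_ids)
}
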