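#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end from a structured configuration:
#' load (or synthesize) the signed network; global PageRank/CheiRank;
#' optional external-influencer selection from a 44-style internal table;
#' REGOMAX reduction of the analysis group; sensitivity matrix and group
#' aggregates; linear and power-law influence-vs-PageRank fits;
#' friend/follower diagrams; and split PageRank/magnetization of the
#' doubled signed network.  Every numeric artifact is written as TSV into
#' `out_dir`; a `run_log.txt` records the configuration, seeds and
#' tolerances.  Any stage failure is rethrown with the stage name.
#'
#' Configuration fields (YAML file or list): `network` (either
#' `edges: <tsv path>` or `synthetic: {n, mean_out_degree, seed, ...}`),
#' `alpha` (default 0.85), `groups` (group-table TSV path, optional - when
#' absent only ranks and magnetization run), `select_x`
#' (`{enabled, n_top_up, n_top_down, n_select}`; needs a t/u/d-only group
#' table), `diagrams` (`{top: [labels], mode}`), `out_dir`.
#'
#' @param config a list or path to a YAML file.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return invisibly, a list with the computed objects (`network`, `ranks`,
#'   `selection`, `rs`, `sens`, `aggregates`, `fits`, `diagrams`,
#'   `magnetization`) and `files` (paths written).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha %||% 0.85
  files <- character(0)
  emit <- function(df, name, rown = FALSE) {
    p <- file.path(out_dir, name)
    utils::write.table(format(df, digits = 15, scientific = FALSE,
                              trim = TRUE),
                       p, sep = "\t", quote = FALSE, row.names = rown)
    files <<- c(files, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  net <- stage("network", {
    nc <- config$network %||% stop("config$network is required")
    if (!is.null(nc$edges)) read_edge_list(nc$edges)
    else if (!is.null(nc$synthetic))
      do.call(generate_ppi_network, nc$synthetic)
    else stop("network needs 'edges' or 'synthetic'")
  })

  ranks <- stage("ranks", {
    model <- google_matrix(net, alpha = alpha)
    model_star <- google_matrix(net, alpha = alpha, inverted = TRUE)
    pr <- pagerank(model)
    cr <- pagerank(model_star)
    emit(data.frame(node_id = net$node_ids, P = pr$P, K = pr$K,
                    P_star = cr$P, K_star = cr$K), "ranks.tsv")
    list(model = model, model_star = model_star, pr = pr, cr = cr)
  })

  groups <- NULL
  if (!is.null(config$groups))
    groups <- stage("groups", read_group_table(config$groups, net))

  selection <- NULL
  if (isTRUE(config$select_x$enabled)) {
    selection <- stage("select_x", {
      if (is.null(groups)) stop("select_x needs a group table")
      sx <- select_x_proteins(
        net, groups, alpha = alpha,
        n_top_up = config$select_x$n_top_up %||% 5L,
        n_top_down = config$select_x$n_top_down %||% 5L,
        n_select = config$select_x$n_select %||% 10L,
        model = ranks$model, model_P = ranks$pr$P)
      emit(sx$selected, "xlist.tsv")
      emit(sx$candidates, "x_candidates.tsv")
      sx
    })
    groups <- selection$groups
  }

  rs <- sens <- agg <- fits <- diagrams <- NULL
  if (!is.null(groups) && any(groups$subgroup == "x")) {
    rs <- stage("regomax", {
      lr <- local_rank_indices(ranks$model, ranks$model_star,
                               groups$node_index, P = ranks$pr$P)
      for (nm in c("GR", "Grr", "Gpr", "Gqr", "Gqr_nd")) {
        m <- lr$rs[[nm]]
        dimnames(m) <- list(groups$node_id, groups$node_id)
        emit(as.data.frame(m), paste0("gr_", nm, ".tsv"), rown = TRUE)
      }
      emit(as.data.frame(component_weights(lr$rs)), "gr_weights.tsv")
      emit(data.frame(node_id = groups$node_id, Kg = groups$Kg,
                      K_local = lr$K_local, K_star_local = lr$K_star_local,
                      Pr = lr$rs$Pr), "local_ranks.tsv")
      lr
    })
    sens <- stage("sensitivity", {
      sm <- sensitivity_matrix(rs$rs)
      m <- sm$D; dimnames(m) <- list(groups$node_id, groups$node_id)
      emit(as.data.frame(m), "D.tsv", rown = TRUE)
      sm
    })
    agg <- stage("aggregates", {
      a <- aggregate_sensitivity(sens, groups)
      tb <- report_tables(a)
      emit(tb$top_pairs, "top_pairs.tsv")
      emit(tb$influence, "influence.tsv")
      emit(tb$seed_ranking, "seed_ranking.tsv")
      a
    })
    fits <- stage("fits", {
      inf <- agg$Ds_ud
      lin <- fit_origin(inf$Pr, inf$Ds_ud)
      pow <- fit_powerlaw(inf$Pr, inf$Ds_ud)
      emit(data.frame(
        model = c("linear_origin", "powerlaw_loglog", "powerlaw_loglog"),
        parameter = c("eta", "eta_t", "kappa"),
        estimate = c(coef(lin)[["eta"]], coef(pow)[["eta_t"]],
                     coef(pow)[["kappa"]]),
        se = c(lin$se[["eta"]], pow$se[["eta_t"]], pow$se[["kappa"]])),
        "fits.tsv")
      list(linear = lin, powerlaw = pow)
    })
    if (!is.null(config$diagrams)) {
      diagrams <- stage("diagrams", {
        top <- config$diagrams$top %||% stop("diagrams need 'top' labels")
        g_nd <- rs$rs$Grr + rs$rs$Gqr_nd
        out <- list()
        for (mode in (config$diagrams$mode %||% c("friend", "follower"))) {
          dg <- build_diagram(rs$rs$GR, groups, top, mode = mode)
          dg <- color_diagram(dg, g_nd, groups)
          p <- file.path(out_dir, sprintf("diagram_%s_GR.dot", mode))
          export_diagram(dg, p, "dot")
          files <- c(files, p)
          out[[mode]] <- dg
        }
        out
      })
    }
  }

  mag <- NULL
  if (!identical(config$ising, FALSE)) {
    mag <- stage("ising", {
      m <- ising_pagerank(ising_network(net), alpha = alpha)
      emit(as.data.frame(m), "magnetization.tsv")
      m
    })
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("regomax %s | R %s", as.character(utils::packageVersion("regomax")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("alpha = %g; pagerank tol = 1e-14; eig tol = 1e-14; series tol = 1e-12",
            alpha),
    sprintf("network: N = %d, links = %d", net$N, nrow(net$edges)),
    if (!is.null(config$network$synthetic))
      sprintf("synthetic seed = %s",
              format(config$network$synthetic$seed %||% NA)),
    sprintf("stages: %s", paste(c("ranks",
      if (!is.null(selection)) "select_x",
      if (!is.null(rs)) c("regomax", "sensitivity", "aggregates", "fits"),
      if (!is.null(diagrams)) "diagrams",
      if (!is.null(mag)) "ising"), collapse = ", "))),
    log_path)
  files <- c(files, log_path)

  invisible(list(network = net, ranks = ranks, groups = groups,
                 selection = selection, rs = rs, sens = sens,
                 aggregates = agg, fits = fits, diagrams = diagrams,
                 magnetization = mag, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
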