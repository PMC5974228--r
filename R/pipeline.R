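#' Per-subject, per-session connectivity matrices for a study
#'
#' Runs preprocessing (optional), seed placement (once, on the shared
#' atlas) and the chosen connectivity method on every series of a
#' `study_set`, returning Fisher-z matrices ready for the paired
#' network-based statistic.
#'
#' @param study A `study_set` from [simulate_paired_study()] (or an
#'   equivalent list with `subjects`, `series`, `atlas`).
#' @param method `"msra"`, `"srcc"` or `"rcca"`.
#' @param q FDR level (default 0.05).
#' @param preprocess Apply [preprocess_bold()] first (default FALSE: the
#'   synthetic generator already produces band-unlimited stationary noise,
#'   and preprocessing choices belong to the caller for real data).
#' @param ... Passed to [preprocess_bold()].
#' @return List with `matrices` (list of Fisher-z `connectivity_matrix`,
#'   one per row of `study$subjects`), `subjects`, `seeds`.
#' @export
study_connectivity <- function(study, method = c("srcc", "msra", "rcca"),
                               q = 0.05, preprocess = FALSE, ...) {
  method <- match.arg(method)
  seeds <- if (method != "rcca") place_all_seeds(study$atlas) else NULL
  mats <- lapply(study$series, function(ser) {
    if (preprocess) ser <- preprocess_bold(ser, ...)
    cm <- switch(method,
      msra = msra_matrix(ser, study$atlas, seeds, q = q),
      srcc = srcc_matrix(ser, seeds, q = q),
      rcca = rcca_matrix(ser, study$atlas, q = q)$matrix)
    fisher_z(cm)
  })
  list(matrices = mats, subjects = study$subjects, seeds = seeds)
}

#' Paired network-based statistic on a study
#'
#' Convenience wrapper: builds per-subject difference matrices from the
#' per-session connectivity matrices, derives the analyzed connection set
#' (union of the four group-average session graphs at an average-degree
#' threshold, or all cells), and runs [pnbs_test()].
#'
#' @param conn Output of [study_connectivity()].
#' @param fraction,M,seed,tie Passed to [pnbs_test()].
#' @param edge_rule `"avg_degree"` (default) or `"all"` for every
#'   off-diagonal cell.
#' @param avg_degree Average degree for the universe graphs (default 20
#'   directed / 10 undirected).
#' @return A `pnbs` object.
#' @export
pnbs_study <- function(conn, fraction = 0.01, M = 5000L, seed,
                       edge_rule = c("avg_degree", "all"), avg_degree = NULL,
                       tie = c("gt", "ge")) {
  edge_rule <- match.arg(edge_rule)
  sub <- conn$subjects
  pre_i <- which(sub$session == "pre")
  post_i <- which(sub$session == "post")
  stopifnot(sub$subject[pre_i] == sub$subject[post_i])
  diffs <- difference_matrices(conn$matrices[pre_i], conn$matrices[post_i],
                               sub$group[pre_i])
  directed <- conn$matrices[[1]]$directed
  n_nodes <- nrow(conn$matrices[[1]]$values)
  connections <- if (edge_rule == "all") {
    all_connections(n_nodes, directed = directed)
  } else {
    if (is.null(avg_degree)) avg_degree <- if (directed) 20 else 10
    cells <- expand.grid(group = c("control", "experimental"),
                         session = c("pre", "post"),
                         stringsAsFactors = FALSE)
    graphs <- lapply(seq_len(nrow(cells)), function(k) {
      sel <- sub$group == cells$group[k] & sub$session == cells$session[k]
      avg <- Reduce(`+`, lapply(conn$matrices[sel], `[[`, "values")) /
        sum(sel)
      threshold_graph(
        connectivity_matrix(avg, directed = directed, scale = "fisher_z"),
        rule = "avg_degree", value = avg_degree)
    })
    connection_universe(graphs)
  }
  is_ctrl <- diffs_group(diffs) == "control"
  pnbs_test(diffs[is_ctrl], diffs[!is_ctrl], connections,
            fraction = fraction, M = M, seed = seed, tie = match.arg(tie))
}

diffs_group <- function(diffs) vapply(diffs, `[[`, character(1), "group")

#' Run the full pipeline from a configuration
#'
#' Wires simulate (or load) -> preprocess -> seeds -> connectivity ->
#' graph/communities -> pNBS, writing every stage's artifacts and a
#' machine-readable JSON summary into `outdir`. Each stage logs its
#' parameters and the md5 hashes of file inputs. Deterministic given the
#' config and its seeds.
#'
#' @param config Named list or path to a YAML file. Recognized fields:
#'   `outdir` (required); either `simulate` (list passed to
#'   [simulate_paired_study()] plus `n_regions`, `shape`) or `manifest` +
#'   `atlas` paths; `preprocess` (list: fwhm_mm, lowpass_hz,
#'   global_regression); `method`; `q`; `edge_rule` (avg_degree value);
#'   `target_communities`; `pnbs` (list: fraction, M, seed, edge_rule);
#'   `seed`.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("config needs 'outdir'", call. = FALSE)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(stage, ...) {
    line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste(..., collapse = " "))
    cat(line, "\n", file = log_path, append = TRUE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  summary <- list(seed = seed)

  # --- data: simulate or load -------------------------------------------
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    atlas <- make_toy_atlas(
      n_regions = sc$n_regions %||% 24L,
      shape = sc$shape %||% c(24L, 24L, 12L),
      min_region_voxels = sc$min_region_voxels %||% 5L,
      seed = seed)
    n_comm <- sc$n_communities %||% 4L
    spec <- community_spec(
      assignment = ((seq_len(n_regions(atlas)) - 1L) %% n_comm) + 1L,
      signal_gain = sc$signal_gain %||% 1,
      noise_sd = sc$noise_sd %||% 1,
      region_noise_sd = sc$region_noise_sd %||% 0.5)
    study <- simulate_paired_study(
      atlas, spec,
      planted_edges = sc$planted_edges,
      delta_r = sc$delta_r %||% 0,
      n_control = sc$n_control %||% 12L,
      n_experimental = sc$n_experimental %||% 13L,
      n_volumes = sc$n_volumes %||% 300L,
      tr = sc$tr %||% 2,
      seed = seed)
    logf("simulate", sprintf("n_regions=%d n_volumes=%d delta_r=%g seed=%d",
                             n_regions(atlas), sc$n_volumes %||% 300L,
                             sc$delta_r %||% 0, seed))
  } else {
    if (is.null(config$manifest) || is.null(config$atlas))
      stop("config needs either 'simulate' or 'manifest' + 'atlas'",
           call. = FALSE)
    for (p in c(config$manifest, config$atlas))
      if (!file.exists(p)) stop("missing input: ", p, call. = FALSE)
    atlas <- read_atlas_nifti(config$atlas)
    man <- read_manifest(config$manifest)
    for (p in man$path) if (!file.exists(p))
      stop("missing series: ", p, call. = FALSE)
    logf("load", "atlas", unname(tools::md5sum(config$atlas)))
    mask <- atlas$labels > 0L
    series <- lapply(man$path, function(p) {
      logf("load", p, unname(tools::md5sum(p)))
      read_bold_nifti(p, brain_mask = mask)
    })
    study <- structure(list(subjects = man[, c("subject", "group", "session")],
                            series = series, atlas = atlas,
                            planted_edges = normalize_edges(NULL, 0L),
                            delta_r = 0),
                       class = "study_set")
  }

  # --- preprocess --------------------------------------------------------
  pp <- config$preprocess
  do_pp <- !is.null(pp)
  if (do_pp) {
    study$series <- lapply(study$series, preprocess_bold,
                           fwhm_mm = pp$fwhm_mm %||% 1.17,
                           lowpass_hz = pp$lowpass_hz %||% 0.1,
                           global_regression = pp$global_regression %||% TRUE)
    logf("preprocess", sprintf("fwhm=%g lowpass=%g gsr=%s",
                               pp$fwhm_mm %||% 1.17, pp$lowpass_hz %||% 0.1,
                               pp$global_regression %||% TRUE))
  }

  # --- seeds + connectivity ---------------------------------------------
  method <- config$method %||% "srcc"
  q <- config$q %||% 0.05
  conn <- study_connectivity(study, method = method, q = q)
  if (!is.null(conn$seeds))
    utils::write.csv(seed_table(conn$seeds),
                     file.path(outdir, "seeds.csv"), row.names = FALSE)
  logf("connect", sprintf("method=%s q=%g", method, q))

  # --- group-average graph + communities --------------------------------
  directed <- conn$matrices[[1]]$directed
  avg <- Reduce(`+`, lapply(conn$matrices, `[[`, "values")) /
    length(conn$matrices)
  avg_cm <- connectivity_matrix(avg, directed = directed, scale = "fisher_z")
  deg <- config$edge_rule %||% if (directed) 20 else 10
  graph <- threshold_graph(avg_cm, rule = "avg_degree", value = deg)
  part <- detect_communities(graph, target_count = config$target_communities,
                             seed = seed)
  write_connectivity_csv(avg_cm, file.path(outdir, "average_matrix.csv"))
  utils::write.csv(
    data.frame(node = names(part$assignment),
               community = unname(part$assignment)),
    file.path(outdir, "communities.csv"), row.names = FALSE)
  utils::write.csv(export_layout(graph, part, seed = seed),
                   file.path(outdir, "layout.csv"), row.names = FALSE)
  logf("graph", sprintf("avg_degree=%g edges=%d communities=%d Q=%.4f",
                        deg, nrow(graph$edges), part$n_communities,
                        part$modularity))

  # --- pNBS --------------------------------------------------------------
  pn <- config$pnbs %||% list()
  res <- pnbs_study(conn,
                    fraction = pn$fraction %||% 0.01,
                    M = pn$M %||% 1000L,
                    seed = pn$seed %||% seed,
                    edge_rule = pn$edge_rule %||% "avg_degree",
                    avg_degree = pn$avg_degree)
  utils::write.csv(res$surviving_edges,
                   file.path(outdir, "pnbs_edges.csv"), row.names = FALSE)
  logf("pnbs", sprintf("fraction=%g M=%d k=%d p_fwe=%g",
                       pn$fraction %||% 0.01, res$n_permutations, res$k,
                       res$p_fwe))

  summary <- c(summary, list(
    method = method, q = q, n_regions = n_regions(study$atlas),
    n_subjects = length(unique(study$subjects$subject)),
    preprocessed = do_pp,
    graph_edges = nrow(graph$edges),
    n_communities = part$n_communities, modularity = part$modularity,
    fully_connected = is_fully_connected(graph),
    pnbs_k = res$k, pnbs_p_fwe = res$p_fwe,
    pnbs_threshold_p = res$threshold_p))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
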