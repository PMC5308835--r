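# Pipeline orchestration: ingest -> screen x2 -> intersect -> netbuild,
# driven by a flat YAML config, with a JSON run summary. The CLI script in
# inst/cli/ is a thin wrapper around these functions.

#' Assemble and validate a pipeline run configuration
#'
#' @param expression_1,expression_2 Paths to the two expression datasets.
#' @param annotation_1,annotation_2 Paths to feature annotation tables
#'   (optional; `annotation_2` defaults to `annotation_1`).
#' @param evidence Path to the interaction edge list.
#' @param seed Seed gene symbol or feature id.
#' @param format_1,format_2 `"tsv"` or `"series_matrix"`.
#' @param r_threshold,p_method,n_permutations,min_pairs,rng_seed Screen
#'   settings, see [screen_config()].
#' @param max_nodes,background_size Network settings, see [network_config()].
#' @param matching_level `"feature"` or `"symbol"`.
#' @param rank_method `"min_abs_r"` or `"mean_abs_r"`.
#' @param log2_transform Apply log2(x + 1) to both datasets on load.
#' @param out_dir Output directory for artifacts.
#' @return A validated `run_config` list.
#' @export
run_config <- function(expression_1, expression_2, evidence, seed,
                       annotation_1 = NULL, annotation_2 = annotation_1,
                       format_1 = "tsv", format_2 = "tsv",
                       r_threshold = 0.55, p_method = "analytic",
                       n_permutations = 10000L, min_pairs = 10L,
                       rng_seed = 1L, max_nodes = 35L,
                       background_size = NULL,
                       matching_level = "feature",
                       rank_method = "min_abs_r",
                       log2_transform = FALSE,
                       out_dir = "screenet_out") {
  paths <- c(expression_1 = expression_1, expression_2 = expression_2,
             evidence = evidence, annotation_1 = annotation_1,
             annotation_2 = annotation_2)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort_io(sprintf("input file(s) not found: %s",
                     paste(missing, collapse = ", ")))
  }
  if (!format_1 %in% c("tsv", "series_matrix") ||
      !format_2 %in% c("tsv", "series_matrix")) {
    abort_validation("expression formats must be 'tsv' or 'series_matrix'")
  }
  if (!matching_level %in% c("feature", "symbol")) {
    abort_validation("matching_level must be 'feature' or 'symbol'")
  }
  screen_cfg <- screen_config(seed, r_threshold = r_threshold,
                              p_method = p_method,
                              n_permutations = n_permutations,
                              min_pairs = min_pairs, rng_seed = rng_seed)
  net_cfg <- network_config(max_nodes = max_nodes,
                            background_size = background_size)
  structure(
    list(expression_1 = expression_1, expression_2 = expression_2,
         evidence = evidence, annotation_1 = annotation_1,
         annotation_2 = annotation_2, format_1 = format_1,
         format_2 = format_2, screen = screen_cfg, network = net_cfg,
         matching_level = matching_level, rank_method = rank_method,
         log2_transform = isTRUE(log2_transform), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys matching the arguments of [run_config()]. Values supplied in
#' `overrides` (e.g. parsed CLI flags) take precedence over the file.
#'
#' @param path Path to the YAML config.
#' @param overrides Named list of values overriding the file's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (!is.list(y)) abort_format("config file is not a key-value mapping")
  y[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort_validation(sprintf("unknown config key(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  do.call(run_config, y)
}

read_expression_any <- function(path, format, log2_transform) {
  if (format == "series_matrix") {
    read_series_matrix(path, log2_transform = log2_transform)
  } else {
    read_expression_tsv(path, log2_transform = log2_transform)
  }
}

#' Run the full discovery pipeline
#'
#' Ingests both datasets, screens each against the seed, intersects the
#' passing sets with concordance checking, ranks candidates, grows and
#' scores interaction networks from the candidates, and writes all
#' artifacts (screen TSVs, candidate table, network files, JSON summary) to
#' `config$out_dir`. Deterministic given the config.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return A `run_summary` list: per-dataset dimensions and passing counts,
#'   intersection/union counts, concordance fraction, per-network size,
#'   score and top hub, and stage timings (logged, never tested).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tick <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(code)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  ann1 <- if (!is.null(config$annotation_1)) read_annotation(config$annotation_1)
  ann2 <- if (!is.null(config$annotation_2)) read_annotation(config$annotation_2)
  expr1 <- tick("ingest_1", read_expression_any(config$expression_1,
                                                config$format_1,
                                                config$log2_transform))
  expr2 <- tick("ingest_2", read_expression_any(config$expression_2,
                                                config$format_2,
                                                config$log2_transform))
  evidence <- tick("evidence", read_edge_list(config$evidence))

  sr1 <- tick("screen_1", run_screen(expr1, ann1, config$screen))
  sr2 <- tick("screen_2", run_screen(expr2, ann2, config$screen))
  write_screen_tsv(sr1, file.path(config$out_dir, "screen_ds1.tsv"))
  write_screen_tsv(sr2, file.path(config$out_dir, "screen_ds2.tsv"))

  cs <- tick("meta", {
    cs <- intersect_screens(sr1, sr2, level = config$matching_level)
    rank_candidates(cs, method = config$rank_method)
  })
  write_candidate_table(cs, file.path(config$out_dir, "candidates.tsv"))

  nets <- tick("netbuild", {
    if (nrow(cs$records)) {
      signs <- stats::setNames(sign(cs$records$r_1), cs$records$gene_symbol)
      ns <- build_networks(cs$records$gene_symbol, evidence,
                           config = config$network, corr_sign = signs)
      score_networks(ns, n_focus_total = nrow(cs$records),
                     background_size = config$network$background_size,
                     evidence = evidence)
    } else {
      structure(list(networks = list(), singletons = character()),
                class = "network_set")
    }
  })
  for (i in seq_along(nets$networks)) {
    write_network(nets$networks[[i]],
                  file.path(config$out_dir, sprintf("network_%02d.graphml", i)),
                  format = "graphml")
    write_network(nets$networks[[i]],
                  file.path(config$out_dir, sprintf("network_%02d.sif", i)),
                  format = "sif")
  }

  net_summaries <- lapply(nets$networks, function(n) {
    hubs <- hub_rank(n)
    list(n_nodes = nrow(n$nodes), n_focus = sum(n$nodes$focus),
         n_edges = n$n_internal_edges, fisher_p = n$fisher_p,
         score = n$score, top_hub = hubs$gene[[1L]],
         top_hub_degree = hubs$degree[[1L]])
  })
  summary <- structure(
    list(
      seed = config$screen$seed,
      dataset_1 = list(id = expr1$dataset_id, n_features = nrow(expr1$values),
                       n_samples = ncol(expr1$values),
                       passing = cs$counts$passing_1),
      dataset_2 = list(id = expr2$dataset_id, n_features = nrow(expr2$values),
                       n_samples = ncol(expr2$values),
                       passing = cs$counts$passing_2),
      intersection = cs$counts$intersection,
      union = cs$counts$union,
      concordance_fraction = cs$concordance_fraction,
      matching_level = cs$matching_level,
      networks = net_summaries,
      singleton_focus_genes = nets$singletons,
      config = list(r_threshold = config$screen$r_threshold,
                    min_pairs = config$screen$min_pairs,
                    p_method = config$screen$p_method,
                    max_nodes = config$network$max_nodes,
                    matching_level = config$matching_level,
                    rank_method = config$rank_method,
                    rng_seed = config$screen$rng_seed),
      timings_sec = as.list(timings)
    ),
    class = "run_summary"
  )
  write_run_summary(summary, file.path(config$out_dir, "run_summary.json"))
  summary
}

#' Write a run summary as JSON
#'
#' @param summary A `run_summary` from [run_pipeline()].
#' @param path Output path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<run_summary> seed %s\n",
           "  %s: %d features x %d samples, %d passing\n",
           "  %s: %d features x %d samples, %d passing\n",
           "  intersection %d, union %d, concordance %s\n",
           "  %d network(s)%s\n"),
    x$seed,
    x$dataset_1$id, x$dataset_1$n_features, x$dataset_1$n_samples,
    x$dataset_1$passing,
    x$dataset_2$id, x$dataset_2$n_features, x$dataset_2$n_samples,
    x$dataset_2$passing,
    x$intersection, x$union,
    ifelse(is.na(x$concordance_fraction), "undefined",
           format(x$concordance_fraction, digits = 3)),
    length(x$networks),
    if (length(x$networks)) {
      sprintf(", best score %.1f, top hub %s",
              x$networks[[1L]]$score, x$networks[[1L]]$top_hub)
    } else ""
  ))
  invisible(x)
}
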