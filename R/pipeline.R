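#' Run the full ensemble-screen post-processing pipeline
#'
#' Orchestrates the stage sequence simulate (or load) -> filter -> combine ->
#' metrics -> diversity -> benchmark, and writes its reports under `out_dir`:
#' `ranked_<target>_<method>.tsv`, `metrics.json`, `benchmark.csv`,
#' `benchmark.json`, `diversity.json` (when chemotypes are available),
#' `filters.json` (conformers dropped and binders excluded), and
#' `provenance.json` (config, seed, package version, stage log). Outputs are
#' deterministic given the same config and seed; progress is logged to
#' stderr.
#'
#' @param config either a list, or the path of a JSON / YAML configuration
#'   file. Recognized entries:
#'   * `simulate`: list of [synthetic_config()] arguments (mutually exclusive
#'     with `scores`),
#'   * `scores`, `annotations`: input file paths, with optional `dialect`,
#'   * `filter`: list with logicals `drop_all_positive`, `drop_cognate`,
#'   * `methods`: combination protocols (default `mrc_score`, `mrc_rank`),
#'   * `metrics`, `chi_values`, `alpha`: benchmark settings,
#'   * `diversity_chi`: top fraction for the chemotype summary (default
#'     0.01).
#' @param out_dir output directory, created if missing; `NULL` computes
#'   everything but writes nothing.
#' @param seed overrides the config's simulation seed when not `NULL`.
#' @param dry_run validate the configuration, print the execution plan, and
#'   return without computing.
#' @return Invisibly, a list with `screens`, `ranked`, `metrics`,
#'   `benchmark`, `diversity`, `filters`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         dry_run = FALSE) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed) && !is.null(cfg$simulate)) cfg$simulate$seed <- seed
  plan <- c(
    if (!is.null(cfg$simulate)) "simulate" else "load",
    if (isTRUE(cfg$filter$drop_all_positive)) "drop_all_positive",
    if (isTRUE(cfg$filter$drop_cognate)) "drop_cognate",
    "combine", "metrics", "diversity", "benchmark")
  if (dry_run) {
    message("pipeline plan: ", paste(plan, collapse = " -> "))
    return(invisible(list(plan = plan)))
  }

  # stage: inputs
  if (!is.null(cfg$simulate)) {
    log_stage("simulate")
    sim <- generate_screen(do.call(synthetic_config, cfg$simulate))
    screens <- sim$screens
  } else {
    log_stage("load")
    if (is.null(cfg$scores))
      stop("pipeline stage load: config needs either a `simulate` block or ",
           "a `scores` path", call. = FALSE)
    if (is.null(cfg$annotations))
      stop("pipeline stage load: annotations required for score tables",
           call. = FALSE)
    dialect <- cfg$dialect %||% "tsv"
    lib <- read_ligand_annotations(cfg$annotations, dialect)
    screens <- read_score_table(cfg$scores, dialect, annotations = lib)
  }

  # stage: filters
  filters <- list()
  if (isTRUE(cfg$filter$drop_all_positive)) {
    log_stage("drop_all_positive")
    res <- lapply(screens, drop_all_positive_runs)
    filters$dropped_runs <- lapply(res, `[[`, "removed")
    filters$excluded_targets <- names(res)[vapply(res, `[[`, logical(1),
                                                  "excluded")]
    screens <- lapply(res[!vapply(res, `[[`, logical(1), "excluded")],
                      `[[`, "screen")
  }
  if (isTRUE(cfg$filter$drop_cognate)) {
    log_stage("drop_cognate")
    res <- lapply(screens, function(s) cognate_ligand_filter(s))
    filters$removed_binders <- lapply(res, `[[`, "removed_binders")
    keep <- !vapply(res, `[[`, logical(1), "excluded")
    filters$cognate_excluded_targets <- names(res)[!keep]
    screens <- Map(function(s, r) {
      s$library <- r$library
      s$scores <- s$scores[, r$library$ligand_id, drop = FALSE]
      s
    }, screens[keep], res[keep])
  }
  if (length(screens) == 0)
    stop("pipeline: no target survived filtering", call. = FALSE)

  # stage: combine + metrics
  log_stage("combine")
  methods <- cfg$methods %||% c("mrc_score", "mrc_rank")
  ranked <- lapply(screens, function(s)
    stats::setNames(lapply(methods, function(m) combine_screen(s, m)),
                    methods))
  log_stage("metrics")
  chi_values <- cfg$chi_values %||% c(0.01, 0.10)
  alpha <- cfg$alpha %||% 20
  metrics <- lapply(ranked, function(per_target)
    lapply(per_target, function(r)
      unclass(metric_report(r,
                            screens[[attr(r, "target_id")]]$library,
                            chi_values, alpha))))

  # stage: diversity (only when every binder is chemotyped)
  log_stage("diversity")
  diversity <- lapply(names(screens), function(tgt) {
    lib <- screens[[tgt]]$library
    if (any(lib$is_binder & is.na(lib$chemotype))) return(NULL)
    lapply(ranked[[tgt]], function(r)
      top_fraction_chemotypes(r, lib, cfg$diversity_chi %||% 0.01))
  })
  names(diversity) <- names(screens)
  diversity <- diversity[!vapply(diversity, is.null, logical(1))]

  log_stage("benchmark")
  bench <- benchmark_report(screens, methods = methods,
                            metrics = cfg$metrics %||% c("auac", "ef", "bedroc"),
                            chi_values = chi_values, alpha = alpha)

  result <- list(screens = screens, ranked = ranked, metrics = metrics,
                 benchmark = bench, diversity = diversity,
                 filters = filters, out_dir = out_dir)
  if (!is.null(out_dir)) write_pipeline_outputs(result, cfg, out_dir)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(name) message("[evls] stage: ", name)

load_pipeline_config <- function(config) {
  if (is.list(config)) return(config)
  if (!is.character(config) || !file.exists(config))
    stop("config must be a list or an existing file path", call. = FALSE)
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

write_pipeline_outputs <- function(result, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tgt in names(result$ranked))
    for (m in names(result$ranked[[tgt]]))
      write_ranked_list(result$ranked[[tgt]][[m]],
                        file.path(out_dir, sprintf("ranked_%s_%s.tsv", tgt, m)))
  jsonlite::write_json(result$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(result$benchmark, file.path(out_dir, "benchmark.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$benchmark, file.path(out_dir, "benchmark.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  if (length(result$diversity) > 0)
    jsonlite::write_json(result$diversity,
                         file.path(out_dir, "diversity.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$filters, file.path(out_dir, "filters.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  prov <- list(package = "evls",
               version = as.character(utils::packageVersion("evls")),
               config = cfg)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
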