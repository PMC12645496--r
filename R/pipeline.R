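#' Pipeline configuration
#'
#' Bundles all stage settings of the end-to-end run (cohort generation ->
#' enrichment -> with/without-features evaluation) plus output paths and the
#' global seed. Serializable to YAML for the command-line interface.
#'
#' @param out_dir output directory.
#' @param seed global seed; recorded in every output's metadata sidecar.
#' @param cohort a [cohort_config()].
#' @param spec a [feature_spec()].
#' @param params a [gct_params()] set (or path to a JSON/YAML file).
#' @param model_config a [gct_config()].
#' @param reps,hidden,folds evaluation settings (see [compare_enrichment()]).
#' @return A `gct_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = ".", seed = 1L,
                            cohort = cohort_config(seed = seed),
                            spec = feature_spec(),
                            params = gct_params(),
                            model_config = gct_config(),
                            reps = 20, hidden = 50, folds = 5) {
  if (is.character(params)) params <- read_params(params)
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 spec = spec, params = params, model_config = model_config,
                 reps = reps, hidden = hidden, folds = folds),
            class = "gct_pipeline_config")
}

run_meta <- function(config, path) {
  meta <- list(package_version = as.character(utils::packageVersion("gctov")),
               seed = config$seed,
               config_hash = rlang::hash(config))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(meta)
}

#' Simulate the reference protocol and write the trajectory
#'
#' @param config a [pipeline_config()].
#' @param horizon simulation horizon, days.
#' @param tumor_cells initial tumor burden, cells.
#' @return Path of the written trajectory CSV, invisibly.
#' @export
cmd_simulate <- function(config = pipeline_config(), horizon = 21,
                         tumor_cells = 1e9) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sch <- build_schedule(config$cohort$dose_mg, config$cohort$n_days,
                        config$cohort$moi, tumor_cells,
                        horizon = horizon, params = config$params)
  y0 <- initial_state(tumor_cells, params = config$params,
                      config = config$model_config)
  tr <- gct_simulate(config$params, config$model_config, y0, sch,
                     t_eval = if (horizon > 0) seq(0, horizon, by = 0.1) else 0)
  path <- file.path(config$out_dir, "trajectory.csv")
  readr::write_csv(tibble::as_tibble(tr), path)
  run_meta(config, path)
  invisible(path)
}

#' Run the local sensitivity sweep and write results
#'
#' @param config a [pipeline_config()].
#' @param ... passed to [local_sensitivity()].
#' @return Path of the written CSV, invisibly.
#' @export
cmd_sensitivity <- function(config = pipeline_config(), ...) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sens <- local_sensitivity(config$params, config$model_config, ...)
  path <- file.path(config$out_dir, "sensitivity.csv")
  readr::write_csv(tibble::as_tibble(sens), path)
  fig <- file.path(config$out_dir, "sensitivity_tornado.pdf")
  ggplot2::ggsave(fig, autoplot.gct_sensitivity(sens), width = 6, height = 5)
  run_meta(config, path)
  invisible(path)
}

#' Generate a synthetic cohort and write it
#'
#' @param config a [pipeline_config()].
#' @return Path of the written cohort CSV, invisibly.
#' @export
cmd_make_cohort <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (config$cohort$categorical) {
    generate_categorical_cohort(config$cohort, config$params, config$model_config)
  } else {
    generate_continuous_cohort(config$cohort, config$params, config$model_config)
  }
  path <- file.path(config$out_dir, "cohort.csv")
  write_cohort(cohort, path)
  run_meta(config, path)
  invisible(path)
}

#' Enrich a cohort CSV with model features
#'
#' @param config a [pipeline_config()].
#' @param cohort_path input cohort CSV (default: the one in `out_dir`).
#' @return Path of the enriched CSV, invisibly.
#' @export
cmd_enrich <- function(config = pipeline_config(),
                       cohort_path = file.path(config$out_dir, "cohort.csv")) {
  cohort <- read_cohort(cohort_path)
  enriched <- if ("SizeCategory" %in% names(cohort)) {
    enrich_categorical(cohort, config$params, config$model_config, config$spec,
                       seed = config$seed,
                       dose_mg = config$cohort$dose_mg,
                       n_days = config$cohort$n_days, moi = config$cohort$moi,
                       effect_map = config$cohort)
  } else {
    enrich_continuous(cohort, config$params, config$model_config, config$spec,
                      dose_mg = config$cohort$dose_mg,
                      n_days = config$cohort$n_days, moi = config$cohort$moi,
                      effect_map = config$cohort)
  }
  path <- file.path(config$out_dir, "enriched.csv")
  readr::write_csv(tibble::as_tibble(enriched), path)
  run_meta(config, path)
  invisible(path)
}

#' Evaluate prediction with vs. without model features
#'
#' @param config a [pipeline_config()].
#' @param enriched_path input enriched CSV.
#' @return Path of the comparison JSON, invisibly.
#' @export
cmd_evaluate <- function(config = pipeline_config(),
                         enriched_path = file.path(config$out_dir, "enriched.csv")) {
  enriched <- readr::read_csv(enriched_path, show_col_types = FALSE)
  cmp <- compare_enrichment(enriched, seed = config$seed, reps = config$reps,
                            hidden = config$hidden, folds = config$folds)
  path <- file.path(config$out_dir, "comparison.json")
  jsonlite::write_json(list(seed = config$seed,
                            comparison = tibble::as_tibble(cmp)),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  run_meta(config, path)
  invisible(path)
}

#' Run the full pipeline: generate, enrich, evaluate
#'
#' Stages run in order with a shared seed; every artifact gets a metadata
#' sidecar with the package version, seed and config hash, and the run is
#' byte-identical when repeated with the same config and seed.
#'
#' @param config a [pipeline_config()].
#' @return Named list of artifact paths.
#' @export
cmd_pipeline <- function(config = pipeline_config()) {
  cohort <- cmd_make_cohort(config)
  enriched <- cmd_enrich(config, cohort)
  comparison <- cmd_evaluate(config, enriched)
  list(cohort = cohort, enriched = enriched, comparison = comparison)
}
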