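#' Synthetic cohort generator configuration
#'
#' Describes a virtual-patient cohort: sample size, MRI observation grid,
#' covariate prevalences, covariate-to-parameter effect multipliers, the
#' baseline tumor-volume distribution, multiplicative measurement noise, and
#' the common treatment protocol. Covariates act on the mechanism: each
#' active binary covariate multiplies named model parameters, so the
#' generated outcome truly depends on the covariates through the dynamics —
#' the signal the downstream ML layer is supposed to find.
#'
#' @param n_patients cohort size.
#' @param n_timepoints 3 or 4 MRI time points.
#' @param times MRI observation days; defaults to `c(0, 7, 14, 21)` for 4
#'   points or `c(0, 10, 21)` for 3 — chosen on the model's response
#'   timescale (the treatment course), where successive observations have
#'   comparable magnitude.
#' @param prevalences named list of binary-covariate prevalences in `[0,1]`.
#' @param effects named list: for each covariate, a named vector of positive
#'   parameter multipliers applied when the covariate is present.
#' @param age_mean,age_sd age distribution (years), truncated to `[18, 90]`.
#' @param bmi_mean,bmi_sd BMI distribution, truncated to `[15, 50]`.
#' @param baseline_median_cc,baseline_sdlog log-normal baseline tumor volume
#'   (median in cc, sd in log units).
#' @param noise_sdlog log-normal multiplicative measurement noise (sd of the
#'   log; 0 disables noise).
#' @param dose_mg,n_days,moi common treatment protocol: daily oral PAC-1 and
#'   an optional virus inoculum at MOI `moi` against the patient's baseline
#'   cell count. The default is drug-only (`moi = 0`), emulating cohorts
#'   under systemic therapy; with an inoculum the model's immune response
#'   eliminates simulated tumors within days, which no longitudinal
#'   volume-measured cohort could exhibit.
#' @param categorical generate a categorical (tertile) cohort.
#' @param seed random seed; the whole cohort is reproducible from it.
#' @param max_retries bounded per-patient regeneration attempts on
#'   simulation failure.
#' @return A `gct_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 500, n_timepoints = 4, times = NULL,
                          prevalences = list(BRCA = 0.10, TP53 = 0.20,
                                             PIK3CA = 0.15, lymph_node = 0.30),
                          effects = list(lymph_node = c(a1 = 1.2),
                                         BRCA = c(d2 = 1.15),
                                         TP53 = c(d2 = 0.85),
                                         PIK3CA = c(a1 = 1.10)),
                          age_mean = 55, age_sd = 12,
                          bmi_mean = 27, bmi_sd = 5,
                          baseline_median_cc = 8, baseline_sdlog = 0.5,
                          noise_sdlog = 0.1,
                          dose_mg = 375, n_days = 21, moi = 0,
                          categorical = FALSE, seed = 1L, max_retries = 3L) {
  stopifnot(n_timepoints %in% c(3L, 4L))
  if (is.null(times)) {
    times <- if (n_timepoints == 4) c(0, 7, 14, 21) else c(0, 10, 21)
  }
  stopifnot(length(times) == n_timepoints)
  prev <- unlist(prevalences)
  if (any(prev < 0 | prev > 1)) stop("prevalences must lie in [0, 1]", call. = FALSE)
  if (any(unlist(effects) <= 0)) stop("effect multipliers must be positive", call. = FALSE)
  if (noise_sdlog < 0) stop("noise_sdlog must be non-negative", call. = FALSE)
  structure(list(n_patients = n_patients, n_timepoints = n_timepoints,
                 times = times, prevalences = prevalences, effects = effects,
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 baseline_median_cc = baseline_median_cc,
                 baseline_sdlog = baseline_sdlog, noise_sdlog = noise_sdlog,
                 dose_mg = dose_mg, n_days = n_days, moi = moi,
                 categorical = categorical, seed = as.integer(seed),
                 max_retries = max_retries),
            class = "gct_cohort_config")
}

#' Apply covariate effects to a base parameter set
#'
#' Each active binary covariate multiplies the model parameters named in the
#' effect map; effects of multiple covariates compose multiplicatively.
#'
#' @param base_params a [gct_params()] set.
#' @param covariates named logical (or 0/1) vector of covariate states.
#' @param config a [cohort_config()] carrying the effect map.
#' @return A `gct_params` with the per-patient parameter values.
#' @export
#' @examples
#' p <- apply_covariate_effects(gct_params(), c(lymph_node = TRUE), cohort_config())
#' p$a1  # 3.3498 * 1.2
apply_covariate_effects <- function(base_params, covariates, config = cohort_config()) {
  bad <- setdiff(names(covariates), names(config$effects))
  bad <- setdiff(bad, c("age", "BMI", "ethnicity", "laterality", "obesity"))
  if (length(bad)) stop("unknown covariate key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p <- unclass(base_params)
  p$Tprod <- NULL  # re-derive if T_star-affecting effects are ever configured
  for (nm in names(covariates)) {
    if (!isTRUE(as.logical(covariates[[nm]]))) next
    eff <- config$effects[[nm]]
    if (is.null(eff)) next
    for (par in names(eff)) p[[par]] <- p[[par]] * eff[[par]]
  }
  do.call(gct_params, c(p, list(validate = FALSE)))
}

draw_covariates <- function(n, config) {
  prev <- config$prevalences
  tibble::tibble(
    id = seq_len(n),
    age = pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 18), 90),
    BMI = pmin(pmax(stats::rnorm(n, config$bmi_mean, config$bmi_sd), 15), 50),
    ethnicity = sample(c("group_a", "group_b", "group_c"), n, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15)),
    laterality = sample(c("left", "right"), n, replace = TRUE),
    BRCA = stats::rbinom(n, 1, prev$BRCA),
    TP53 = stats::rbinom(n, 1, prev$TP53),
    PIK3CA = stats::rbinom(n, 1, prev$PIK3CA),
    lymph_node = stats::rbinom(n, 1, prev$lymph_node)
  ) |>
    dplyr::mutate(obesity = as.integer(.data$BMI >= 30))
}

#' Generate a continuous-volume synthetic cohort
#'
#' For each virtual patient: draw covariates and a baseline tumor volume,
#' derive patient-specific model parameters through the covariate effect
#' map, simulate the treated tumor from the baseline volume, record the
#' tumor volume at the MRI time grid, and apply multiplicative log-normal
#' measurement noise. The observed table has one row per patient with
#' covariates and `Volume1..VolumeK` (cc); the ground truth (per-patient
#' parameters and pre-noise volumes) is attached as the `"truth"` attribute
#' and available via [cohort_truth()].
#'
#' @param config a [cohort_config()].
#' @param params base model parameters.
#' @param model_config a [gct_config()].
#' @return A `gct_cohort` tibble.
#' @export
generate_continuous_cohort <- function(config = cohort_config(),
                                       params = gct_params(),
                                       model_config = gct_config()) {
  set.seed(config$seed)
  n <- config$n_patients
  cov <- draw_covariates(n, config)
  base_cc <- stats::rlnorm(n, log(config$baseline_median_cc), config$baseline_sdlog)
  noise <- matrix(stats::rnorm(n * length(config$times), 0, config$noise_sdlog),
                  nrow = n)

  cov_keys <- names(config$effects)
  sims <- vector("list", n)
  par_rows <- vector("list", n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    cv_i <- stats::setNames(unlist(cov[i, cov_keys]) != 0, cov_keys)
    p_i <- apply_covariate_effects(params, cv_i, config)
    ok <- FALSE
    for (try in seq_len(config$max_retries)) {
      res <- tryCatch(simulate_volumes(
        base_cc[i], config$times, p_i, model_config,
        schedule = build_schedule(config$dose_mg, config$n_days, config$moi,
                                  tumor_cells = base_cc[i] * p_i$cells_per_cc,
                                  horizon = max(config$times), params = p_i)),
        error = function(e) NULL)
      if (!is.null(res)) { ok <- TRUE; break }
      base_cc[i] <- stats::rlnorm(1, log(config$baseline_median_cc),
                                  config$baseline_sdlog)
    }
    if (!ok) { failed[i] <- TRUE; res <- rep(NA_real_, length(config$times)) }
    sims[[i]] <- res
    par_rows[[i]] <- tibble::tibble(id = i, baseline_cc = base_cc[i],
                                    a1 = p_i$a1, a2 = p_i$a2, d2 = p_i$d2,
                                    d3 = p_i$d3)
  }
  if (any(failed)) {
    warning(sum(failed), " patient(s) failed to simulate after retries",
            call. = FALSE)
  }
  true_vol <- do.call(rbind, sims)
  obs_vol <- true_vol * exp(noise)
  colnames(obs_vol) <- paste0("Volume", seq_along(config$times))
  truth <- dplyr::bind_rows(par_rows)
  truth[paste0("true_Volume", seq_along(config$times))] <- as.data.frame(true_vol)

  out <- dplyr::bind_cols(cov, tibble::as_tibble(as.data.frame(obs_vol)))
  structure(out, class = c("gct_cohort", class(out)),
            truth = truth, cohort_config = config, kind = "continuous")
}

#' Generate a categorical (tertile) synthetic cohort
#'
#' Generates latent continuous volumes exactly as
#' [generate_continuous_cohort()], then reports only a `SizeCategory` in
#' `{1, 2, 3}` given by the empirical tertile of the latent final volume.
#' The latent volumes stay in the truth side table.
#'
#' @inheritParams generate_continuous_cohort
#' @return A `gct_cohort` tibble with covariates and `SizeCategory`.
#' @export
generate_categorical_cohort <- function(config = cohort_config(categorical = TRUE),
                                        params = gct_params(),
                                        model_config = gct_config()) {
  cont <- generate_continuous_cohort(config, params, model_config)
  vol_cols <- grep("^Volume", names(cont), value = TRUE)
  final <- cont[[vol_cols[length(vol_cols)]]]
  truth <- attr(cont, "truth")
  truth[paste0("latent_", vol_cols)] <- as.data.frame(cont[vol_cols])
  out <- cont |>
    dplyr::select(-dplyr::all_of(vol_cols)) |>
    dplyr::mutate(SizeCategory = tertile_discretize(final))
  structure(out, class = c("gct_cohort", class(out)),
            truth = truth, cohort_config = config, kind = "categorical")
}

#' Ground-truth side table of a synthetic cohort
#'
#' @param cohort a `gct_cohort`.
#' @return Tibble with per-patient true parameters and pre-noise volumes.
#' @export
cohort_truth <- function(cohort) {
  attr(cohort, "truth")
}

#' Write / read a cohort as CSV
#'
#' The observed table and the hidden truth table are written as parallel
#' CSVs (`<path>` and `<path base>_truth.csv`).
#'
#' @param cohort a `gct_cohort`.
#' @param path CSV output path.
#' @return `path`, invisibly (`read_cohort()` returns a tibble).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path)
  truth <- cohort_truth(cohort)
  if (!is.null(truth)) {
    readr::write_csv(truth, sub("\\.csv$", "_truth.csv", path))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  tpath <- sub("\\.csv$", "_truth.csv", path)
  if (file.exists(tpath)) {
    attr(out, "truth") <- readr::read_csv(tpath, show_col_types = FALSE)
  }
  class(out) <- c("gct_cohort", class(out))
  out
}
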