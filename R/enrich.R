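#' Feature specification for mechanistic enrichment
#'
#' Which model variables to export as machine-learning features, and at which
#' times. `"burden"` denotes the total tumor burden (volume in cc); the other
#' names are state variables of the model (see [state_names()]).
#'
#' @param variables model quantities to export.
#' @param times sampling times, days.
#' @param prefix naming prefix; columns are named `<prefix><variable>_t<time>`.
#' @param categorical convert appended features to tertile indices {1,2,3}.
#' @return A `gct_feature_spec` list.
#' @export
feature_spec <- function(variables = c("burden", "I", "V", "C", "P", "PPAC", "T"),
                         times = c(7, 14, 21),
                         prefix = "mod_", categorical = FALSE) {
  known <- c("burden", state_names(gct_params(), gct_config()))
  bad <- setdiff(variables, known)
  if (length(bad)) stop("unknown feature variable(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(variables = variables, times = sort(unique(times)),
                 prefix = prefix, categorical = categorical),
            class = "gct_feature_spec")
}

feature_names <- function(spec) {
  if (!length(spec$variables)) return(character())
  as.vector(t(outer(spec$variables, spec$times,
                    function(v, t) paste0(spec$prefix, v, "_t", t))))
}

sample_features <- function(traj, spec, params) {
  burden <- tumor_burden(traj, params)$volume_cc
  vals <- lapply(spec$variables, function(v) {
    if (v == "burden") burden else traj[[v]]
  })
  m <- do.call(rbind, vals)  # variables x times, matching feature_names()
  as.vector(t(m))
}

#' Enrich a continuous cohort with mechanistic model features
#'
#' Implements the core individualization step: for each patient, the model is
#' seeded at their first observed MRI volume (`Volume1`, converted to cells),
#' simulated under the treatment protocol, and the requested model variables
#' at the requested times are appended as feature columns. The enrichment is
#' deterministic: it uses the shared base parameters, so two patients with
#' the same `Volume1` get identical features.
#'
#' @param cohort a tibble with a `Volume1` column (cc).
#' @param spec a [feature_spec()].
#' @param schedule treatment protocol; `NULL` (default) rebuilds the
#'   protocol per patient with the virus inoculum at MOI
#'   `moi` against the patient's own baseline cell count.
#' @param dose_mg,n_days,moi protocol used when `schedule` is `NULL`.
#' @param effect_map optional [cohort_config()] carrying a
#'   covariate-to-parameter effect map; when supplied, each patient is
#'   simulated with [apply_covariate_effects()] on their observed covariates
#'   (mechanistic individualization beyond the baseline size). `NULL` uses
#'   the shared base parameters for everyone.
#' @inheritParams gct_simulate
#' @return The cohort with appended feature columns and a logical
#'   `sim_failed` column; failed patients carry `NA` features.
#' @export
enrich_continuous <- function(cohort, params = gct_params(),
                              config = gct_config(), spec = feature_spec(),
                              schedule = NULL,
                              dose_mg = 375, n_days = 21, moi = 0,
                              effect_map = NULL) {
  if (!"Volume1" %in% names(cohort)) stop("cohort lacks Volume1", call. = FALSE)
  if (!length(spec$variables)) return(cohort)
  fn <- feature_names(spec)
  horizon <- max(spec$times, 1)
  n <- nrow(cohort)
  feats <- matrix(NA_real_, n, length(fn), dimnames = list(NULL, fn))
  failed <- logical(n)
  cov_keys <- if (is.null(effect_map)) character() else
    intersect(names(effect_map$effects), names(cohort))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    v1 <- cohort$Volume1[i]
    cv_i <- if (length(cov_keys)) {
      stats::setNames(unlist(cohort[i, cov_keys]) != 0, cov_keys)
    } else logical()
    key <- paste(format(v1, digits = 15), paste(as.integer(cv_i), collapse = ""))
    if (!is.null(cache[[key]])) { feats[i, ] <- cache[[key]]; next }
    res <- tryCatch({
      p_i <- if (length(cv_i)) apply_covariate_effects(params, cv_i, effect_map)
             else params
      sch <- if (is.null(schedule)) {
        build_schedule(dose_mg, n_days, moi,
                       tumor_cells = v1 * p_i$cells_per_cc,
                       horizon = horizon, params = p_i)
      } else schedule
      y0 <- initial_state(v1 * p_i$cells_per_cc, params = p_i,
                          config = config)
      traj <- gct_simulate(p_i, config, y0, sch, t_eval = spec$times)
      sample_features(traj, spec, p_i)
    }, error = function(e) NULL)
    if (is.null(res)) failed[i] <- TRUE else { feats[i, ] <- res; cache[[key]] <- res }
  }
  out <- dplyr::bind_cols(cohort, tibble::as_tibble(as.data.frame(feats)))
  out$sim_failed <- failed
  if (spec$categorical) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(fn), tertile_discretize))
  }
  keep_cohort_attrs(out, cohort)
}

#' Enrich a categorical cohort with mechanistic model features
#'
#' Each tertile group receives one shared random initial tumor size drawn
#' uniformly on (0, 100) cc; the model is solved from that size under the
#' treatment protocol, the requested variables are sampled, and every
#' appended feature column is converted to tertile indices {1, 2, 3} before
#' merging. A per-patient draw mode is available behind `per_patient`.
#'
#' @param cohort a tibble with a `SizeCategory` column in {1, 2, 3}.
#' @param seed random seed for the initial-size draws.
#' @param per_patient draw one initial size per patient instead of one per
#'   tertile group.
#' @inheritParams enrich_continuous
#' @return The cohort with appended categorical feature columns.
#' @export
enrich_categorical <- function(cohort, params = gct_params(),
                               config = gct_config(),
                               spec = feature_spec(categorical = TRUE),
                               schedule = NULL, seed = 1L,
                               dose_mg = 375, n_days = 21, moi = 0,
                               per_patient = FALSE, effect_map = NULL) {
  if (!"SizeCategory" %in% names(cohort)) stop("cohort lacks SizeCategory", call. = FALSE)
  if (!all(cohort$SizeCategory %in% 1:3)) stop("SizeCategory must be in {1,2,3}", call. = FALSE)
  set.seed(seed)
  tmp <- cohort
  if (per_patient) {
    tmp$Volume1 <- stats::runif(nrow(cohort), 0, 100)
  } else {
    draws <- stats::setNames(stats::runif(3, 0, 100), as.character(1:3))
    tmp$Volume1 <- unname(draws[as.character(cohort$SizeCategory)])
  }
  spec$categorical <- TRUE
  out <- enrich_continuous(tmp, params, config, spec, schedule,
                           dose_mg, n_days, moi, effect_map = effect_map)
  out$Volume1 <- NULL
  keep_cohort_attrs(out, cohort)
}

keep_cohort_attrs <- function(out, cohort) {
  attr(out, "truth") <- attr(cohort, "truth")
  attr(out, "cohort_config") <- attr(cohort, "cohort_config")
  attr(out, "kind") <- attr(cohort, "kind")
  if (inherits(cohort, "gct_cohort") && !inherits(out, "gct_cohort")) {
    class(out) <- c("gct_cohort", class(out))
  }
  out
}

#' Discretize a numeric vector into tertiles
#'
#' Cuts at the empirical 33.33% and 66.67% quantiles with lower-open,
#' upper-closed bins; values exactly on a boundary fall in the lower
#' category. With degenerate (tied) quantiles all tied values collapse into
#' the lowest applicable category, so a constant vector maps to category 1.
#'
#' @param values numeric vector (non-empty).
#' @return Integer vector of categories in {1, 2, 3}.
#' @export
#' @examples
#' tertile_discretize(1:9)
tertile_discretize <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  if (all(is.na(values))) return(rep(NA_integer_, length(values)))
  q <- stats::quantile(values, c(1 / 3, 2 / 3), names = FALSE, type = 7,
                       na.rm = TRUE)
  as.integer(1L + (values > q[1]) + (values > q[2]))
}
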