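#' Linear-regression report with RMSE and per-feature p-values
#'
#' Ordinary least squares with intercept for a continuous target. Reports
#' both a 5-fold cross-validated RMSE (default evaluation) and the in-sample
#' RMSE (divisor n), two-sided t-test p-values per coefficient, the overall
#' F-test p-value, and the features significant at `alpha`. Collinear
#' columns are dropped by the QR fit and flagged in the report.
#'
#' @param table data frame of observations.
#' @param target name of the numeric target column.
#' @param features character vector of feature column names.
#' @param folds number of cross-validation folds.
#' @param seed seed controlling the fold assignment.
#' @param alpha significance threshold for the `significant` list.
#' @return A `gct_linear_report` list with elements `target`, `features`,
#'   `rmse` (cross-validated), `rmse_insample`, `model_p`, `coefficients`
#'   (tibble), `significant`, `dropped`, `n`.
#' @export
fit_linear_report <- function(table, target, features, folds = 5, seed = 1L,
                              alpha = 0.05) {
  stopifnot(target %in% names(table), all(features %in% names(table)))
  df <- as.data.frame(table[c(target, features)])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n <= length(features) + 1) stop("too few rows for the requested features",
                                      call. = FALSE)
  if (!is.numeric(df[[target]])) stop("target must be numeric", call. = FALSE)
  fml <- stats::reformulate(if (length(features)) sprintf("`%s`", features) else "1",
                            response = sprintf("`%s`", target))
  fit <- stats::lm(fml, data = df)
  dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(dropped)) {
    warning("rank-deficient design; dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- tibble::tibble(term = rownames(sm$coefficients),
                          estimate = unname(sm$coefficients[, 1]),
                          std_error = unname(sm$coefficients[, 2]),
                          statistic = unname(sm$coefficients[, 3]),
                          p_value = unname(sm$coefficients[, 4]))
  model_p <- if (!is.null(sm$fstatistic)) {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  } else NA_real_
  rmse_in <- sqrt(mean(stats::residuals(fit)^2))

  rmse_cv <- NA_real_
  if (folds >= 2) {
    set.seed(seed)
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    sq <- numeric(0)
    for (k in seq_len(folds)) {
      tr <- df[fold_id != k, , drop = FALSE]
      te <- df[fold_id == k, , drop = FALSE]
      fk <- stats::lm(fml, data = tr)
      pr <- suppressWarnings(stats::predict(fk, newdata = te))
      sq <- c(sq, (te[[target]] - pr)^2)
    }
    rmse_cv <- sqrt(mean(sq))
  }
  sig <- coefs$term[coefs$p_value <= alpha & coefs$term != "(Intercept)"]
  structure(list(target = target, features = features,
                 rmse = rmse_cv, rmse_insample = rmse_in, model_p = model_p,
                 coefficients = coefs, significant = sig,
                 dropped = dropped, n = n, folds = folds, fit = fit),
            class = "gct_linear_report")
}

#' @export
print.gct_linear_report <- function(x, ...) {
  cat("<gct_linear_report> ", x$target, " ~ ", length(x$features),
      " features, n = ", x$n, "\n", sep = "")
  cat(sprintf("  RMSE (%d-fold CV): %.4g   RMSE (in-sample): %.4g   model p: %.3g\n",
              x$folds, x$rmse, x$rmse_insample, x$model_p))
  if (length(x$significant)) {
    cat("  significant: ", paste(x$significant, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.gct_linear_report <- function(x, ...) x$coefficients

#' @export
glance.gct_linear_report <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, rmse_insample = x$rmse_insample,
                 model_p = x$model_p, n = x$n, n_features = length(x$features))
}

#' Confusion-matrix classification metrics
#'
#' Accuracy is trace over total; recall, precision and F1 are macro-averaged
#' over classes (rows index true classes, columns predicted). A class never
#' predicted gets precision 0 (with a warning), a class never observed gets
#' recall 0 (with a warning); its F1 is 0.
#'
#' @param m square non-negative integer matrix of counts.
#' @return Named list `accuracy`, `recall`, `precision`, `f1`.
#' @export
#' @examples
#' confusion_metrics(diag(10, 3))
confusion_metrics <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  if (any(m < 0)) stop("confusion matrix must be non-negative", call. = FALSE)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  support <- rowSums(m)
  predicted <- colSums(m)
  rec <- ifelse(support > 0, tp / support, 0)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  if (any(support == 0)) warning("class with zero support; recall set to 0", call. = FALSE)
  if (any(predicted == 0)) warning("class never predicted; precision set to 0", call. = FALSE)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / total, recall = mean(rec),
       precision = mean(prec), f1 = mean(f1))
}

stratified_split <- function(y, frac) {
  idx_train <- integer(0)
  for (lv in unique(y)) {
    ii <- which(y == lv)
    n_tr <- max(1L, round(length(ii) * frac))
    idx_train <- c(idx_train, sample(ii, n_tr))
  }
  sort(idx_train)
}

#' Repeated single-hidden-layer neural-network classification
#'
#' The classification protocol: a one-hidden-layer network (default 50
#' units, [nnet::nnet()]), trained on stratified random splits and repeated
#' with fresh splits and initial weights; per-repetition confusion matrices
#' on the held-out data are summarized by accuracy and macro-averaged
#' recall, precision and F1, then averaged over repetitions. Numeric
#' features are standardized by the training-split mean and sd.
#'
#' @param table data frame of observations.
#' @param target_cat name of the categorical target column (>= 2 classes).
#' @param features feature column names.
#' @param hidden hidden-layer size.
#' @param reps number of repetitions.
#' @param split training fraction of each stratified split.
#' @param seed master seed; the whole procedure is reproducible from it.
#' @param maxit,decay [nnet::nnet()] training controls.
#' @return A `gct_class_report`: mean/sd of each metric over repetitions,
#'   the per-repetition tibble, and the aggregated confusion matrix.
#' @export
fit_nn_repeated <- function(table, target_cat, features, hidden = 50,
                            reps = 100, split = 0.7, seed = 1L,
                            maxit = 150, decay = 1e-3) {
  stopifnot(target_cat %in% names(table), all(features %in% names(table)),
            reps >= 1)
  df <- as.data.frame(table[c(target_cat, features)])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  y <- factor(df[[target_cat]])
  if (nlevels(y) < 2) stop("target must have at least 2 classes", call. = FALSE)
  X <- stats::model.matrix(~ . - 1, data = df[features])
  lv <- levels(y)
  agg <- matrix(0, nlevels(y), nlevels(y), dimnames = list(lv, lv))
  set.seed(seed)
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    tr_idx <- stratified_split(y, split)
    mu <- colMeans(X[tr_idx, , drop = FALSE])
    sd_ <- apply(X[tr_idx, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
    fit <- nnet::nnet(Xs[tr_idx, , drop = FALSE], nnet::class.ind(y[tr_idx]),
                      size = hidden, softmax = TRUE, maxit = maxit,
                      decay = decay, trace = FALSE, MaxNWts = 50000)
    pr <- predict(fit, Xs[-tr_idx, , drop = FALSE], type = "class")
    pr <- factor(pr, levels = lv)
    cm <- table(true = y[-tr_idx], predicted = pr)
    agg <- agg + as.matrix(unclass(cm))
    mets <- suppressWarnings(confusion_metrics(cm))
    per_rep[[r]] <- tibble::as_tibble(mets)
  }
  per_rep <- dplyr::bind_rows(per_rep, .id = "rep")
  summary <- per_rep |>
    tidyr::pivot_longer(-rep, names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(summary = summary, per_rep = per_rep, confusion = agg,
                 reps = reps, hidden = hidden, target = target_cat,
                 features = features, n = nrow(df)),
            class = "gct_class_report")
}

#' @export
print.gct_class_report <- function(x, ...) {
  cat("<gct_class_report> ", x$target, ", ", x$reps, " repetitions, ",
      x$hidden, " hidden units, n = ", x$n, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.gct_class_report <- function(x, ...) x$summary

#' @export
glance.gct_class_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("metric", "mean")],
                     names_from = "metric", values_from = "mean") |>
    dplyr::mutate(reps = x$reps, n = x$n)
}

#' Compare prediction with and without mechanistic features
#'
#' Runs each prediction task twice on identical evaluation schemes (shared
#' seeds, hence identical cross-validation folds and train/test splits):
#' once on the clinical columns alone and once with the model-derived
#' enrichment columns added, and reports the metric deltas.
#'
#' @param enriched an enriched cohort (e.g. from [enrich_continuous()]);
#'   enrichment columns are those matching `feature_prefix`.
#' @param tasks list of task lists, each with `name`, `target`, `features`
#'   (clinical feature columns) and `type` (`"regression"` or
#'   `"classification"`). Defaults to the standard volume-prediction tasks
#'   discovered from the available `Volume*` columns.
#' @param feature_prefix prefix identifying enrichment columns.
#' @param seed shared evaluation seed.
#' @param reps,hidden neural-network protocol settings (classification tasks).
#' @param folds cross-validation folds (regression tasks).
#' @return A `gct_comparison`: tibble with columns `task`, `type`, `metric`,
#'   `without`, `with`, `delta`, plus the full reports in attributes.
#' @export
compare_enrichment <- function(enriched, tasks = NULL, feature_prefix = "mod_",
                               seed = 1L, reps = 20, hidden = 50, folds = 5) {
  mod_cols <- grep(paste0("^", feature_prefix), names(enriched), value = TRUE)
  if (!length(mod_cols)) stop("no enrichment columns with prefix '",
                              feature_prefix, "'", call. = FALSE)
  # constant columns (e.g. immune states identical across patients under a
  # shared protocol) carry no signal; drop them up front
  keep <- vapply(mod_cols, function(cl) {
    v <- enriched[[cl]]
    is.numeric(v) && stats::sd(v, na.rm = TRUE) > 0
  }, logical(1))
  mod_cols <- mod_cols[keep]
  if (!length(mod_cols)) stop("all enrichment columns are constant", call. = FALSE)
  if (is.null(tasks)) tasks <- default_tasks(enriched)
  clinical <- c("age", "BMI", "ethnicity", "laterality", "BRCA", "TP53",
                "PIK3CA", "lymph_node", "obesity")
  clinical <- intersect(clinical, names(enriched))
  rows <- list()
  reports <- list()
  for (tk in tasks) {
    feats0 <- unique(c(clinical, tk$features))
    feats1 <- unique(c(feats0, mod_cols))
    if (identical(tk$type, "regression")) {
      r0 <- fit_linear_report(enriched, tk$target, feats0, folds = folds, seed = seed)
      r1 <- fit_linear_report(enriched, tk$target, feats1, folds = folds, seed = seed)
      rows[[tk$name]] <- tibble::tibble(task = tk$name, type = "regression",
                                        metric = "rmse_cv",
                                        without = r0$rmse, with = r1$rmse,
                                        delta = r1$rmse - r0$rmse)
    } else {
      r0 <- fit_nn_repeated(enriched, tk$target, feats0, hidden = hidden,
                            reps = reps, seed = seed)
      r1 <- fit_nn_repeated(enriched, tk$target, feats1, hidden = hidden,
                            reps = reps, seed = seed)
      g0 <- glance.gct_class_report(r0); g1 <- glance.gct_class_report(r1)
      mets <- c("accuracy", "recall", "precision", "f1")
      rows[[tk$name]] <- tibble::tibble(task = tk$name, type = "classification",
                                        metric = mets,
                                        without = unlist(g0[mets]),
                                        with = unlist(g1[mets]),
                                        delta = unlist(g1[mets]) - unlist(g0[mets]))
    }
    reports[[tk$name]] <- list(without = r0, with = r1)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("gct_comparison", class(out)), reports = reports)
}

default_tasks <- function(table) {
  vols <- sort(grep("^Volume[0-9]+$", names(table), value = TRUE))
  tasks <- list()
  if (all(c("Volume1", "Volume2") %in% vols)) {
    tasks <- c(tasks, list(list(name = "Volume2_from_Volume1", target = "Volume2",
                                features = "Volume1", type = "regression")))
  }
  if (all(c("Volume1", "Volume3") %in% vols)) {
    tasks <- c(tasks, list(list(name = "Volume3_from_Volume1", target = "Volume3",
                                features = "Volume1", type = "regression")))
  }
  if (all(c("Volume1", "Volume2", "Volume3") %in% vols)) {
    tasks <- c(tasks, list(list(name = "Volume3_from_Volume1_2", target = "Volume3",
                                features = c("Volume1", "Volume2"),
                                type = "regression")))
  }
  if ("SizeCategory" %in% names(table)) {
    tasks <- c(tasks, list(list(name = "SizeCategory", target = "SizeCategory",
                                features = character(), type = "classification")))
  }
  if (!length(tasks)) stop("no applicable prediction tasks found", call. = FALSE)
  tasks
}

#' Plot an enrichment comparison
#'
#' @param object a `gct_comparison`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gct_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("without", "with"),
                              names_to = "arm", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~task, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(without = "grey55", with = "#2c6fbb")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "model features")
}
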