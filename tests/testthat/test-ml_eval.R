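test_that("perfect linear relations give zero RMSE and tiny slope p", {
  df <- tibble::tibble(x = seq_len(50), y = 2 * seq_len(50))
  rep <- suppressWarnings(fit_linear_report(df, "y", "x"))  # exact fit warns
  expect_lt(rep$rmse_insample, 1e-10)
  expect_lt(rep$rmse, 1e-8)
  slope_p <- rep$coefficients$p_value[rep$coefficients$term == "x"]
  expect_lt(slope_p, 1e-12)
  expect_true("x" %in% rep$significant)
})

test_that("intercept-only RMSE equals the divisor-n standard deviation", {
  set.seed(4)
  y <- stats::rnorm(200, 10, 3)
  rep <- fit_linear_report(tibble::tibble(y = y), "y", character(), folds = 0)
  expect_equal(rep$rmse_insample, sqrt(mean((y - mean(y))^2)), tolerance = 1e-12)
})

test_that("rank-deficient designs are dropped with a warning and flagged", {
  df <- tibble::tibble(x1 = 1:30, x2 = 2 * (1:30),
                       y = 1:30 + stats::rnorm(30, 0, 0.1))
  expect_warning(rep <- fit_linear_report(df, "y", c("x1", "x2")), "rank-deficient")
  expect_true("x2" %in% rep$dropped)
})

test_that("null slope p-values are approximately uniform", {
  set.seed(12)
  pvals <- replicate(400, {
    df <- tibble::tibble(x = stats::rnorm(200), y = stats::rnorm(200))
    fit <- stats::lm(y ~ x, data = df)
    summary(fit)$coefficients["x", 4]
  })
  # package report must agree with the direct fit on one case
  df <- tibble::tibble(x = stats::rnorm(100), y = stats::rnorm(100))
  rep <- fit_linear_report(df, "y", "x", folds = 0)
  direct <- summary(stats::lm(y ~ x, df))$coefficients["x", 4]
  expect_equal(rep$coefficients$p_value[2], direct, tolerance = 1e-12)
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("linear-report p-values match a permutation test within MC error", {
  set.seed(77)
  df <- tibble::tibble(x = stats::rnorm(50))
  df$y <- 0.3 * df$x + stats::rnorm(50)
  rep <- fit_linear_report(df, "y", "x", folds = 0)
  p_t <- rep$coefficients$p_value[2]
  obs_t <- abs(rep$coefficients$statistic[2])
  perm <- replicate(1000, {
    fit <- stats::lm(sample(df$y) ~ df$x)
    abs(summary(fit)$coefficients[2, 3])
  })
  p_perm <- (1 + sum(perm >= obs_t)) / 1001
  expect_lt(abs(p_perm - p_t), 3 * sqrt(p_t * (1 - p_t) / 1000) + 2e-3)
})

test_that("confusion metrics follow their arithmetic", {
  m <- diag(10, 3)
  expect_equal(confusion_metrics(m),
               list(accuracy = 1, recall = 1, precision = 1, f1 = 1))
  m2 <- matrix(c(5, 5, 5, 5), 2)
  mets <- confusion_metrics(m2)
  expect_equal(unlist(mets), c(accuracy = 0.5, recall = 0.5,
                               precision = 0.5, f1 = 0.5))
  # degenerate column: class 2 never predicted
  m3 <- matrix(c(10, 10, 0, 0), 2)
  expect_warning(mets3 <- confusion_metrics(m3), "never predicted")
  expect_equal(mets3$accuracy, 0.5)
  expect_equal(mets3$precision, mean(c(10 / 20, 0)))
  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
  expect_error(confusion_metrics(matrix(1, 2, 3)), "square")
})

test_that("metrics are invariant to row order and label renaming", {
  set.seed(5)
  n <- 300
  df <- tibble::tibble(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  df$lab <- tertile_discretize(df$x1 + 0.5 * stats::rnorm(n))
  r1 <- fit_nn_repeated(df, "lab", c("x1", "x2"), hidden = 5, reps = 3, seed = 2)
  df_shuf <- df[sample(n), ]
  r2 <- fit_nn_repeated(df_shuf, "lab", c("x1", "x2"), hidden = 5, reps = 3, seed = 2)
  expect_equal(r1$summary$mean, r2$summary$mean, tolerance = 0.12)
  # macro averaging is symmetric: permuting class identities of the
  # confusion matrix leaves every metric unchanged
  m <- matrix(c(40, 3, 1, 5, 30, 6, 2, 4, 25), 3, 3)
  perm <- c(3, 1, 2)
  expect_equal(confusion_metrics(m), confusion_metrics(m[perm, perm]),
               tolerance = 1e-12)
})

test_that("repeated NN separates well-separated clusters and is seed-stable", {
  set.seed(8)
  n <- 200
  centers <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
  lab <- rep(1:3, each = n)
  X <- centers[lab, ] + matrix(stats::rnorm(3 * n * 2, 0, 0.5), 3 * n, 2)
  df <- tibble::tibble(x1 = X[, 1], x2 = X[, 2], lab = lab)
  rep1 <- fit_nn_repeated(df, "lab", c("x1", "x2"), hidden = 10, reps = 5, seed = 3)
  acc <- rep1$summary$mean[rep1$summary$metric == "accuracy"]
  expect_gt(acc, 0.95)
  rep2 <- fit_nn_repeated(df, "lab", c("x1", "x2"), hidden = 10, reps = 5, seed = 3)
  expect_identical(rep1$summary, rep2$summary)
  expect_identical(rep1$confusion, rep2$confusion)
})

test_that("permuted labels give chance-level accuracy on 3 balanced classes", {
  set.seed(10)
  n <- 300
  df <- tibble::tibble(x1 = stats::rnorm(n), x2 = stats::rnorm(n),
                       lab = sample(rep(1:3, each = n / 3)))
  rep <- fit_nn_repeated(df, "lab", c("x1", "x2"), hidden = 10, reps = 10, seed = 4)
  acc <- rep$summary$mean[rep$summary$metric == "accuracy"]
  sdv <- rep$summary$sd[rep$summary$metric == "accuracy"]
  expect_lt(abs(acc - 1 / 3), 3 * max(sdv / sqrt(10), 0.02))
})

test_that("enrichment comparison evaluates both arms on identical folds", {
  coh <- small_cohort(n = 60, seed = 19)
  enr <- enrich_continuous(coh, spec = small_spec())
  # replace enrichment column by pure noise: deltas must be small and the
  # reports must use the same number of rows and fold seed
  set.seed(1)
  enr$mod_burden_t7 <- stats::rnorm(60)
  enr$mod_burden_t14 <- stats::rnorm(60)
  cmp <- suppressWarnings(compare_enrichment(
    enr, seed = 5, reps = 0,
    tasks = list(list(name = "v2", target = "Volume2", features = "Volume1",
                      type = "regression"))))
  expect_equal(nrow(cmp), 1)
  reps <- attr(cmp, "reports")$v2
  expect_equal(reps$without$n, reps$with$n)
  expect_lt(abs(cmp$delta[1]) / cmp$without[1], 0.25)
  # leakage control: a feature equal to the target drives CV RMSE to ~0
  enr$mod_burden_t7 <- enr$Volume2
  cmp2 <- suppressWarnings(compare_enrichment(
    enr, seed = 5, reps = 0,
    tasks = list(list(name = "v2", target = "Volume2", features = "Volume1",
                      type = "regression"))))
  expect_lt(cmp2$with[1], 1e-8)
})

test_that("classification comparison runs end to end on a categorical cohort", {
  coh <- small_cohort(n = 45, seed = 33, categorical = TRUE)
  enr <- enrich_categorical(coh, spec = feature_spec(variables = "burden",
                                                     times = c(7, 14),
                                                     categorical = TRUE),
                            seed = 2)
  cmp <- suppressWarnings(compare_enrichment(enr, seed = 6, reps = 2, hidden = 5))
  expect_true(all(c("accuracy", "recall", "precision", "f1") %in% cmp$metric))
  expect_true(all(cmp$without >= 0 & cmp$without <= 1))
  expect_true(all(cmp$with >= 0 & cmp$with <= 1))
  expect_s3_class(autoplot(cmp), "ggplot")
})
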