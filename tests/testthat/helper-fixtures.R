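# shared small fixtures, built in code at test time

small_cohort <- function(n = 30, seed = 11, categorical = FALSE, ...) {
  cc <- cohort_config(n_patients = n, seed = seed, categorical = categorical, ...)
  if (categorical) generate_categorical_cohort(cc) else generate_continuous_cohort(cc)
}

small_spec <- function(...) feature_spec(variables = "burden", times = c(7, 14), ...)
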