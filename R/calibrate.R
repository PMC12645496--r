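#' Refit tumor growth parameters from observed trajectories
#'
#' Least-squares recovery of selected model parameters (default: the
#' quiescent-to-G1 transition rate `a1` and the G1 apoptotic rate `d2`) from
#' a set of observed tumor-volume trajectories. The residuals are the log
#' volumes across all trajectories; optimization is Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) on the log-parameter scale, which keeps rates
#' positive and handles the near-ridge geometry of jointly weakly
#' identified rate pairs.
#'
#' @param observed list of tibbles, one per trajectory, with columns `time`
#'   (days) and `volume_cc`; the volume at the earliest time seeds the
#'   simulation.
#' @param fit_par names of the parameters to refit.
#' @param start named numeric starting values; default 1.5x the current
#'   parameter values.
#' @param schedule common treatment protocol (`NULL`: the reference protocol
#'   scaled to each trajectory's baseline cells).
#' @param maxit,reltol iteration budget and convergence tolerance.
#' @inheritParams gct_simulate
#' @return A list with `estimate` (named vector), `start`, `objective`,
#'   `convergence`, and `relative_error` against `params` (the generating
#'   values, when those are the truth).
#' @export
fit_growth_params <- function(observed, params = gct_params(),
                              config = gct_config(),
                              fit_par = c("a1", "d2"), start = NULL,
                              schedule = NULL, maxit = 400, reltol = 1e-10) {
  stopifnot(length(observed) >= 1, all(fit_par %in% names(unclass(params))))
  truth <- unlist(unclass(params)[fit_par])
  if (is.null(start)) start <- truth * 1.5
  start <- start[fit_par]

  prep <- lapply(observed, function(ob) {
    ob <- ob[order(ob$time), ]
    list(times = ob$time, logv = log(ob$volume_cc), v0 = ob$volume_cc[1])
  })
  residuals_fn <- function(logpar) {
    pl <- unclass(params)
    pl[fit_par] <- exp(logpar)
    pl$Tprod <- NULL
    p2 <- do.call(gct_params, c(pl, list(validate = FALSE)))
    unlist(lapply(prep, function(tr) {
      sch <- if (is.null(schedule)) {
        build_schedule(375, 21, 0.03, tumor_cells = tr$v0 * p2$cells_per_cc,
                       horizon = max(tr$times, 1), params = p2)
      } else schedule
      pred <- tryCatch(
        simulate_volumes(tr$v0, tr$times, p2, config, schedule = sch),
        error = function(e) NULL)
      if (is.null(pred) || any(pred <= 0)) return(rep(1e3, length(tr$times)))
      log(pred) - tr$logv
    }))
  }
  opt <- minpack.lm::nls.lm(log(start), fn = residuals_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = min(maxit, 1024), ftol = reltol))
  est <- stats::setNames(exp(opt$par), fit_par)
  list(estimate = est, start = start, objective = opt$deviance,
       convergence = as.integer(opt$info > 4),
       relative_error = abs(est - truth) / truth)
}
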