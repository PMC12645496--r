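#' Build a treatment schedule
#'
#' Daily oral PAC-1 doses plus a single oncolytic-virus inoculum at time
#' zero. Doses are applied impulsively: the oral depot `PA` jumps by the dose
#' in ng, and the virion state `V` jumps by the inoculum in scaled
#' virion-units (`moi * tumor_cells / cells_per_unit`). The reference
#' protocol is 21 daily doses of 375 mg with MOI 0.03 on a 1e9-cell tumor.
#'
#' @param dose_mg daily oral PAC-1 dose, mg.
#' @param n_days number of daily doses (at t = 0, 1, ..., n_days - 1).
#' @param moi multiplicity of infection: initial virions per tumor cell.
#' @param tumor_cells tumor-cell count the MOI refers to.
#' @param horizon simulation horizon, days (defaults to the dosing span).
#' @inheritParams pd_effect
#' @return A `gct_schedule`: list with an `events` tibble (`time`, `target`,
#'   `amount`) and `horizon`.
#' @export
#' @examples
#' sch <- build_schedule(375, 21, 0.03, 1e9)
#' sch$events
build_schedule <- function(dose_mg = 375, n_days = 21, moi = 0.03,
                           tumor_cells = 1e9, horizon = NULL,
                           params = gct_params()) {
  if (dose_mg < 0 || n_days < 0 || moi < 0 || tumor_cells < 0) {
    stop("schedule inputs must be non-negative", call. = FALSE)
  }
  n_days <- as.integer(n_days)
  horizon <- if (is.null(horizon)) max(n_days, 1) else horizon
  oral <- if (n_days > 0) {
    tibble::tibble(time = as.numeric(seq_len(n_days) - 1),
                   target = "PA_oral",
                   amount = dose_mg * 1e6)  # mg -> ng
  } else {
    tibble::tibble(time = numeric(), target = character(), amount = numeric())
  }
  inoc <- tibble::tibble(time = 0,
                         target = "V_inoculum",
                         amount = moi * tumor_cells / params$cells_per_unit)
  events <- dplyr::arrange(dplyr::bind_rows(oral, inoc), time, target)
  # doses scheduled past the horizon are never administered
  events <- dplyr::filter(events, time <= horizon)
  if (any(events$time < 0)) {
    stop("event times must lie within [0, horizon]", call. = FALSE)
  }
  structure(list(events = events, horizon = horizon), class = "gct_schedule")
}

#' Untreated schedule (no doses, no virus)
#'
#' @param horizon simulation horizon, days.
#' @return A `gct_schedule` with no events.
#' @export
empty_schedule <- function(horizon = 21) {
  structure(list(events = tibble::tibble(time = numeric(), target = character(),
                                         amount = numeric()),
                 horizon = horizon),
            class = "gct_schedule")
}

#' Initial model state for a given tumor burden
#'
#' Distributes `total_cells` over the tumor compartments and places the
#' immune and TRAIL compartments at their homeostatic equilibria
#' ([immune_equilibrium()], derived TRAIL steady state). Drug, virus and
#' infected-cell states start at zero.
#'
#' `mode = "residence_time"` (default) splits cells across Q, G1 and the
#' active compartments proportionally to mean residence times
#' (1/a1, 1/(a2 + d2), and 1/ktr for each of the j transit stages), which
#' avoids a distribution transient; `"all_quiescent"` puts the whole burden
#' in Q.
#'
#' @param total_cells tumor-cell count (>= 0).
#' @param mode `"residence_time"` or `"all_quiescent"`.
#' @inheritParams pd_effect
#' @return Named state vector (see [state_names()]).
#' @export
initial_state <- function(total_cells, mode = c("residence_time", "all_quiescent"),
                          params = gct_params(), config = gct_config()) {
  mode <- match.arg(mode)
  if (total_cells < 0) stop("total_cells must be non-negative", call. = FALSE)
  p <- params
  units <- total_cells / p$cells_per_unit
  y <- make_state(params = p, config = config)
  if (mode == "all_quiescent") {
    y[["Q"]] <- units
  } else {
    w <- c(1 / p$a1, 1 / (p$a2 + p$d2), rep(1 / p$ktr, p$j))
    w <- w / sum(w)
    y[["Q"]] <- units * w[1]
    y[["G1"]] <- units * w[2]
    y[paste0("A", seq_len(p$j))] <- units * w[-(1:2)]
  }
  eq <- immune_equilibrium(p)
  tr <- trail_equilibrium(p)
  y[["C"]] <- eq$C_star
  y[["P"]] <- eq$P_star
  y[["T"]] <- tr$T
  y[["TP"]] <- tr$TP
  y[["TA"]] <- tr$TA
  if (config$variant_active_total == "ode_eq5") {
    y[["N"]] <- sum(y[paste0("A", seq_len(p$j))])
  }
  y
}

#' Simulate the model under a treatment schedule
#'
#' Integrates the derivative field with the adaptive Runge-Kutta 4(5) pair
#' (or any [deSolve::ode()] method), restarting the integration at every
#' dose event and applying the event as an instantaneous jump of the target
#' state (`PA` for oral doses, `V` for virus inocula).
#'
#' @param state0 initial state, e.g. from [initial_state()].
#' @param schedule a `gct_schedule` from [build_schedule()].
#' @param t_eval times (days) at which to report the state; defaults to a
#'   0.1-day grid over the schedule horizon.
#' @param method integration method; default from `config`
#'   (`"ode45"` = adaptive RK 4(5)). `"rk4"` with `dt` gives the fixed-step
#'   classic Runge-Kutta reference.
#' @param dt fixed step size in days (only used by fixed-step methods).
#' @param use_compiled integrate the compiled derivative core (default);
#'   `FALSE` uses the R reference [gct_rhs()].
#' @inheritParams pd_effect
#' @return A `gct_trajectory`: tibble with `time` and one column per state
#'   variable, carrying solver diagnostics in attributes.
#' @export
#' @examples
#' tr <- gct_simulate(state0 = initial_state(1e9),
#'                    schedule = build_schedule(375, 5, 0.03, 1e9),
#'                    t_eval = 0:5)
#' tr
gct_simulate <- function(params = gct_params(), config = gct_config(),
                         state0 = initial_state(1e9, params = params, config = config),
                         schedule = empty_schedule(),
                         t_eval = NULL, method = config$method, dt = NULL,
                         use_compiled = TRUE) {
  if (any(!is.finite(state0))) stop("initial state must be finite", call. = FALSE)
  horizon <- schedule$horizon
  if (is.null(t_eval)) t_eval <- seq(0, horizon, by = 0.1)
  t_eval <- sort(unique(as.numeric(t_eval)))
  if (any(t_eval < 0) || any(t_eval > horizon + 1e-12)) {
    stop("t_eval must lie within [0, horizon]", call. = FALSE)
  }
  ev <- schedule$events
  nm <- state_names(params, config)
  y <- stats::setNames(as.numeric(state0[nm]), nm)
  parms <- pack_parms(params, config)

  # segment boundaries: 0, each distinct event time, horizon
  bounds <- sort(unique(c(0, ev$time, horizon)))
  bounds <- bounds[bounds <= horizon]
  out <- matrix(NA_real_, nrow = length(t_eval), ncol = length(nm),
                dimnames = list(NULL, nm))
  steps <- 0L
  for (k in seq_along(bounds)) {
    t0 <- bounds[k]
    t1 <- if (k < length(bounds)) bounds[k + 1] else horizon
    here <- ev[abs(ev$time - t0) < 1e-12, ]
    if (nrow(here)) {
      for (r in seq_len(nrow(here))) {
        tgt <- if (here$target[r] == "PA_oral") "PA" else "V"
        y[[tgt]] <- y[[tgt]] + here$amount[r]
      }
    }
    idx <- which(t_eval >= t0 - 1e-12 & (t_eval < t1 - 1e-12 | (k == length(bounds) & t_eval <= t1 + 1e-12)))
    if (abs(t0 - horizon) < 1e-12 || t1 <= t0) {
      if (length(idx)) out[idx, ] <- matrix(y, nrow = length(idx), ncol = length(nm), byrow = TRUE)
      next
    }
    times <- sort(unique(c(t0, t_eval[idx], t1)))
    sol <- integrate_segment(y, times, parms, params, config, method, dt, use_compiled)
    if (any(!is.finite(sol))) {
      stop("solver failure: non-finite state in segment [", signif(t0, 6), ", ",
           signif(t1, 6), "]", call. = FALSE)
    }
    steps <- steps + nrow(sol)
    if (length(idx)) {
      rows <- match(round(t_eval[idx], 10), round(sol[, 1], 10))
      out[idx, ] <- sol[rows, -1, drop = FALSE]
    }
    y <- stats::setNames(sol[nrow(sol), -1], nm)
    if (config$clip_negative) y <- pmax(y, 0)
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  traj <- dplyr::bind_cols(tibble::tibble(time = t_eval), traj)
  structure(traj,
            class = c("gct_trajectory", class(traj)),
            params = params, config = config, schedule = schedule,
            diagnostics = list(status = "success", segments = length(bounds),
                               rows_integrated = steps, method = method))
}

integrate_segment <- function(y, times, parms, params, config, method, dt,
                              use_compiled) {
  if (length(times) < 2) times <- c(times, times + 1e-9)
  if (use_compiled) {
    args <- list(y = unname(y), times = times, func = "gctov_derivs",
                 parms = unname(parms), dllname = "gctov",
                 initfunc = "gctov_initmod",
                 method = method, rtol = config$rtol, atol = config$atol)
  } else {
    rfun <- function(t, state, parms2) {
      gct_rhs(t, stats::setNames(state, names(y)), params, config)
    }
    args <- list(y = unname(y), times = times, func = rfun, parms = NULL,
                 method = method, rtol = config$rtol, atol = config$atol)
  }
  if (!is.null(dt)) args$hini <- dt else args$hmax <- config$max_step
  sol <- suppressWarnings(do.call(deSolve::ode, args))
  unclass(sol)
}

#' Tumor burden of a state or trajectory
#'
#' Total tumor burden is the sum of the uninfected tumor compartments
#' (Q + G1 + sum of the active transit compartments), converted to a cell
#' count via `cells_per_unit` and to an MRI-style volume via `cells_per_cc`.
#'
#' @param state a named state vector, or a `gct_trajectory`.
#' @inheritParams pd_effect
#' @return For a state vector, a named list `cells`, `volume_cc`; for a
#'   trajectory, a tibble with `time`, `cells`, `volume_cc`.
#' @export
tumor_burden <- function(state, params = gct_params()) {
  if (inherits(state, "gct_trajectory")) {
    acols <- grep("^A[0-9]+$", names(state), value = TRUE)
    units <- state$Q + state$G1 + rowSums(as.matrix(state[acols]))
    cells <- units * params$cells_per_unit
    return(tibble::tibble(time = state$time, cells = cells,
                          volume_cc = cells / params$cells_per_cc))
  }
  acols <- grep("^A[0-9]+$", names(state), value = TRUE)
  units <- unname(state[["Q"]] + state[["G1"]] + sum(state[acols]))
  cells <- units * params$cells_per_unit
  list(cells = cells, volume_cc = cells / params$cells_per_cc)
}

#' Tumor volume at given times from one simulation
#'
#' Convenience wrapper: seed the model at a baseline volume (cc), simulate
#' under a schedule and return the tumor volume at the requested times.
#'
#' @param volume_cc baseline tumor volume in cc.
#' @param times observation times, days.
#' @inheritParams gct_simulate
#' @return Numeric vector of volumes (cc) at `times`.
#' @export
simulate_volumes <- function(volume_cc, times, params = gct_params(),
                             config = gct_config(),
                             schedule = build_schedule(params = params,
                                                       horizon = max(times))) {
  y0 <- initial_state(volume_cc * params$cells_per_cc, params = params,
                      config = config)
  tr <- gct_simulate(params, config, y0, schedule, t_eval = times)
  tumor_burden(tr, params)$volume_cc
}

#' @export
print.gct_trajectory <- function(x, ...) {
  d <- attr(x, "diagnostics")
  cat("<gct_trajectory> ", nrow(x), " time points, ",
      ncol(x) - 1, " state variables (", d$method, ")\n", sep = "")
  NextMethod()
}

#' Long-format view of a trajectory
#'
#' @param x a `gct_trajectory`.
#' @param ... unused.
#' @return Tibble with columns `time`, `variable`, `value`.
#' @export
tidy.gct_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -time,
                      names_to = "variable", values_to = "value")
}

#' Plot a trajectory
#'
#' Faceted time courses of selected state variables.
#'
#' @param object a `gct_trajectory`.
#' @param vars state variables to show (default: all).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gct_trajectory <- function(object, vars = NULL, ...) {
  long <- tidy.gct_trajectory(object)
  if (!is.null(vars)) long <- dplyr::filter(long, .data$variable %in% vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(color = "#2c6fbb") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL)
}

#' Export a trajectory as tidy CSV
#'
#' @param x a `gct_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  readr::write_csv(tidy.gct_trajectory(x), path)
  invisible(path)
}
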