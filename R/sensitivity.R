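#' Parameters included in the default sensitivity sweep
#'
#' All rate and concentration parameters of the model. Excluded by design:
#' the integer transit-compartment count `j` (scaling a count by -85% is
#' ill-defined) and `tau` (enters only through `ktr`); the Emax and Psi
#' pharmacodynamic parameters (bounded in (0,1), so a +/-85% scaling leaves
#' their admissible range); the derived `Tprod`; and the unit-scale
#' conventions.
#'
#' @return Character vector of parameter names.
#' @export
sweep_parameters <- function() {
  c("a1", "a2", "d2", "d3", "ktr", "kappa", "delta", "alpha", "omega",
    "kp", "kQ", "ks", "psi_half", "kcp", "eta_half", "C_half", "gamma_P",
    "Cprod_star", "Cprod_max", "k_elim",
    "ka", "V_PAC", "kep", "k12P", "k21P",
    "alpha_T", "kel", "kon", "R0", "k12", "k21", "V", "kint", "T_star",
    "gamma_PAC", "gamma_TRAIL", "EC50_PAC", "EC50_TRAIL")
}

#' Local one-at-a-time parameter sensitivity
#'
#' Re-simulates the reference treatment protocol while scaling one parameter
#' at a time over a symmetric grid of fractional perturbations (default
#' -85% to +85%), and scores each parameter by the maximal absolute relative
#' change of the final tumor burden against the unperturbed baseline.
#'
#' @param parameter_list parameters to sweep (default [sweep_parameters()]).
#' @param fractions numeric perturbation fractions; default `n_points` evenly
#'   spaced values spanning `range`.
#' @param range sweep endpoints as fractions (default c(-0.85, 0.85)).
#' @param n_points number of grid points (odd, so that 0 is on the grid).
#' @param schedule treatment protocol; default the reference 21-day course
#'   (375 mg PAC-1 daily, MOI 0.03 on 1e9 cells).
#' @param tumor_cells initial tumor burden, cells.
#' @inheritParams gct_simulate
#' @return A `gct_sensitivity` tibble: one row per (parameter, fraction) with
#'   the final burden, per-parameter `influence` (max |relative change|) and
#'   dense `rank` (1 = most influential; ties broken alphabetically).
#' @export
local_sensitivity <- function(params = gct_params(), config = gct_config(),
                              schedule = NULL,
                              parameter_list = sweep_parameters(),
                              range = c(-0.85, 0.85), n_points = 9,
                              fractions = NULL, tumor_cells = 1e9) {
  if (is.null(fractions)) {
    stopifnot(n_points >= 3, n_points %% 2 == 1)
    fractions <- seq(range[1], range[2], length.out = n_points)
    if (!any(fractions == 0)) fractions <- sort(c(fractions, 0))
  }
  bad <- setdiff(parameter_list, names(unclass(params)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(schedule)) {
    schedule <- build_schedule(375, 21, 0.03, tumor_cells, params = params)
  }
  run_final_burden <- function(p) {
    y0 <- initial_state(tumor_cells, params = p, config = config)
    tr <- gct_simulate(p, config, y0, schedule, t_eval = schedule$horizon)
    tumor_burden(tr, p)$cells[1]
  }
  baseline <- run_final_burden(params)

  rows <- purrr::map_dfr(parameter_list, function(nm) {
    purrr::map_dfr(fractions, function(f) {
      burden <- if (f == 0) {
        baseline
      } else {
        p2 <- unclass(params)
        p2[[nm]] <- p2[[nm]] * (1 + f)
        p2 <- do.call(gct_params, c(p2, list(validate = FALSE)))
        tryCatch(run_final_burden(p2), error = function(e) NA_real_)
      }
      tibble::tibble(parameter = nm, fraction = f, burden_cells = burden)
    })
  })
  rows <- rows |>
    dplyr::group_by(.data$parameter) |>
    dplyr::mutate(influence = max(abs(.data$burden_cells - baseline) / baseline,
                                  na.rm = TRUE)) |>
    dplyr::ungroup()
  ranking <- rank_parameters(rows)
  out <- dplyr::left_join(rows, ranking[, c("parameter", "rank")], by = "parameter")
  structure(out, class = c("gct_sensitivity", class(out)),
            baseline_cells = baseline, fractions = fractions)
}

#' Rank parameters by influence
#'
#' Orders parameters by decreasing influence score; ties broken
#' alphabetically by parameter name.
#'
#' @param results a `gct_sensitivity` tibble (or any tibble with `parameter`
#'   and `influence` columns).
#' @return Tibble with one row per parameter: `parameter`, `influence`,
#'   `rank`.
#' @export
rank_parameters <- function(results) {
  if (!nrow(results)) stop("empty sensitivity results", call. = FALSE)
  tibble::as_tibble(as.data.frame(results[c("parameter", "influence")])) |>
    dplyr::distinct() |>
    dplyr::arrange(dplyr::desc(.data$influence), .data$parameter) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Tornado plot of parameter influences
#'
#' @param object a `gct_sensitivity` result.
#' @param top number of parameters to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gct_sensitivity <- function(object, top = 15, ...) {
  ranking <- rank_parameters(object) |> dplyr::slice_head(n = top)
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = .data$influence,
                               y = stats::reorder(.data$parameter, .data$influence))) +
    ggplot2::geom_col(fill = "#b2452c") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "max |relative change| of day-21 burden (log scale)",
                  y = NULL, title = "Local parameter sensitivity")
}

#' @export
print.gct_sensitivity <- function(x, ...) {
  cat("<gct_sensitivity> ", dplyr::n_distinct(x$parameter), " parameters x ",
      dplyr::n_distinct(x$fraction), " fractions; baseline ",
      signif(attr(x, "baseline_cells"), 4), " cells\n", sep = "")
  NextMethod()
}
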