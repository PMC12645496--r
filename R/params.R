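#' Default model parameters
#'
#' Builds the full parameter set of the tumor / oncolytic-virus / PAC-1 / TRAIL
#' model: cell-cycle rates (quiescent -> G1 -> transit-compartment active
#' phases with mitotic doubling), viral infection and lysis, innate
#' cytokine-phagocyte response, two-compartment oral PAC-1 pharmacokinetics,
#' irreversible-binding target-mediated TRAIL disposition, and Emax/Hill
#' pharmacodynamics for the PAC-1 + TRAIL apoptotic effect.
#'
#' Tumor-cell, phagocyte and virion state variables are carried in scaled
#' units of `cells_per_unit` cells (default 1e10); MRI volumes convert at
#' `cells_per_cc` cells per cm^3 (default 1e9), so one scaled unit is 10 cc.
#'
#' The homeostatic TRAIL production rate `Tprod` is not a free constant: it is
#' derived so that the drug-free, tumor-free TRAIL subsystem has its
#' equilibrium at the homeostatic concentration `T_star`
#' (see [homeostatic_trail_production()]).
#'
#' @param ... named overrides of individual parameter values.
#' @param validate check invariants (positivity, Emax bounds, ktr = j/tau
#'   consistency). Set `FALSE` for deliberate out-of-range exploration such as
#'   wide sensitivity sweeps.
#' @return An object of class `gct_params`: a named list of numeric values.
#' @export
#' @examples
#' p <- gct_params()
#' p$a1
#' gct_params(a1 = 4)$a1
gct_params <- function(..., validate = TRUE) {
  p <- list(
    # tumor cell cycle (1/day unless noted)
    a1   = 3.3498,   # quiescent -> G1 transition
    a2   = 1.44,     # G1 -> first active compartment
    d2   = 0.2,      # G1 apoptotic rate
    d3   = 0.1732,   # active-phase apoptotic rate
    ktr  = 8.4540,   # transit rate through active compartments (= j/tau)
    j    = 6,        # number of transit compartments
    tau  = 0.7097,   # expected cell-cycle duration, days
    # oncolytic virus
    kappa    = 0.054,  # maximal virion infection rate, 1/day
    delta    = 2.48,   # infected-cell lysis rate, 1/day
    alpha    = 1.12,   # burst size, virions/cell
    omega    = 40.3,   # virion decay rate, 1/day
    eta_half = 0.51,   # virion half-effect level (scaled virions)
    # innate immunity
    kp         = 9.23,       # phagocyte-tumor contact kill rate, 1/day
    kQ         = 0.064,      # digestion saturation constant (quiescent)
    ks         = 0.064,      # digestion saturation constant (cycling)
    psi_half   = 0.00011,    # cytokine production half-effect (scaled cells)
    kcp        = 4.6754,     # maximal phagocyte production rate
    C_half     = 0.739,      # phagocyte production half-effect, ng/ml
    gamma_P    = 0.35,       # phagocyte death rate, 1/day
    Cprod_star = 3.9863e-4,  # homeostatic cytokine production, ng/ml/day
    Cprod_max  = 1.429,      # maximal cytokine production, ng/ml/day
    k_elim     = 0.16139,    # cytokine elimination rate, 1/day
    # PAC-1 pharmacokinetics
    ka    = 2.96,      # oral absorption rate, 1/day
    V_PAC = 3390.45,   # volume of distribution, ml
    kep   = 61.97,     # plasma elimination rate, 1/day
    k12P  = 183.49,    # plasma -> peripheral transfer, 1/day
    k21P  = 1.18,      # peripheral -> plasma transfer, 1/day
    # TRAIL pharmacokinetics (irreversible TMDD)
    alpha_T = 7.5837e-6, # TRAIL production per lysed scaled cell-unit, ng/ml
    kel     = 45,        # free TRAIL elimination rate, 1/day
    kon     = 0.026,     # receptor binding rate, 1/day
    R0      = 457.49,    # receptor pool, ng/ml
    k12     = 11.38,     # central -> peripheral transfer, 1/day
    k21     = 0.0043,    # peripheral -> central transfer, 1/day
    V       = 100.04,    # central TRAIL volume, ml
    kint    = 22.15,     # bound-complex internalization rate, 1/day
    T_star  = 0.08090,   # homeostatic TRAIL concentration, ng/ml
    # pharmacodynamics
    Emax_PAC    = 0.8764,
    Emax_TRAIL  = 0.438,
    EC50_PAC    = 1176.7,  # ng/ml
    EC50_TRAIL  = 5,       # ng/ml
    gamma_PAC   = 1.35,
    gamma_TRAIL = 0.874,
    Psi         = 0.8,     # PAC-1 x TRAIL interaction potency
    # unit-scale conventions
    cells_per_unit = 1e10, # cells per scaled model unit
    cells_per_cc   = 1e9   # cells per cm^3 of tumor volume
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(names(p), "Tprod"))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  if (is.null(p$Tprod)) p$Tprod <- homeostatic_trail_production(p)
  class(p) <- "gct_params"
  if (validate) validate_params(p)
  p
}

#' Validate a model parameter set
#'
#' @param p a `gct_params` object (or bare named list).
#' @return `p`, invisibly, if all invariants hold; otherwise an error.
#' @export
validate_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric parameter values", call. = FALSE)
  pos <- setdiff(names(p), c("Tprod", "T_star", "Psi"))
  vals <- unlist(p[pos])
  if (any(vals <= 0)) {
    stop("parameters must be strictly positive: ",
         paste(pos[unlist(p[pos]) <= 0], collapse = ", "), call. = FALSE)
  }
  if (p$j < 1 || p$j != round(p$j)) stop("j must be a positive integer", call. = FALSE)
  if (p$Emax_PAC <= 0 || p$Emax_PAC >= 1 || p$Emax_TRAIL <= 0 || p$Emax_TRAIL >= 1) {
    stop("Emax values must lie strictly in (0, 1)", call. = FALSE)
  }
  if (p$Psi < 0 || p$Psi > 1) stop("Psi must lie in [0, 1]", call. = FALSE)
  if (p$T_star < 0) stop("T_star must be non-negative", call. = FALSE)
  invisible(p)
}

#' Solver and model-variant configuration
#'
#' Resolves the typographic ambiguities of the printed equation system behind
#' explicit flags, so the corrected default and the literal readings can both
#' be simulated.
#'
#' @param variant_infection_sign `"corrected_plus"` (infection targets G1 plus
#'   all active cells; default) or `"literal_minus"` (the printed `G1 - N`,
#'   which can drive infected cells negative).
#' @param variant_g1_entry `"text_a2"` (entry into the first active
#'   compartment at rate `a2`, consistent with the G1 balance; default) or
#'   `"literal_a1"`.
#' @param variant_active_total `"algebraic_sum"` (total active cells N is the
#'   sum of the transit compartments; default) or `"ode_eq5"` (integrates the
#'   literal redundant N equation as an extra state).
#' @param pd_combination `"additive_synergy"` (E = E_P + E_T + Psi E_P E_T;
#'   default), `"bliss"` (E = E_P + E_T - E_P E_T) or `"pac_only"`.
#' @param clip_negative clip the state at zero before evaluating derivatives
#'   (guards the literal variants, which are not non-negativity preserving).
#' @param rtol,atol,max_step solver tolerances and maximal step (days).
#' @param method integration method tag passed to [deSolve::ode()]; the
#'   default `"ode45"` is the adaptive explicit Runge-Kutta 4(5) pair.
#' @return An object of class `gct_config`.
#' @export
gct_config <- function(variant_infection_sign = c("corrected_plus", "literal_minus"),
                       variant_g1_entry = c("text_a2", "literal_a1"),
                       variant_active_total = c("algebraic_sum", "ode_eq5"),
                       pd_combination = c("additive_synergy", "bliss", "pac_only"),
                       clip_negative = TRUE,
                       rtol = 1e-6, atol = 1e-9, max_step = 0.25,
                       method = "ode45") {
  stopifnot(rtol > 0, atol > 0, max_step > 0)
  cfg <- list(
    variant_infection_sign = match.arg(variant_infection_sign),
    variant_g1_entry = match.arg(variant_g1_entry),
    variant_active_total = match.arg(variant_active_total),
    pd_combination = match.arg(pd_combination),
    clip_negative = isTRUE(clip_negative),
    rtol = rtol, atol = atol, max_step = max_step, method = method
  )
  class(cfg) <- "gct_config"
  cfg
}

#' @export
print.gct_params <- function(x, ...) {
  cat("<gct_params> ", length(unclass(x)), " parameters\n", sep = "")
  df <- tibble::tibble(parameter = names(x), value = unlist(unname(x)))
  print(df, n = 15)
  invisible(x)
}

#' @export
print.gct_config <- function(x, ...) {
  cat("<gct_config>\n")
  for (nm in names(x)) cat("  ", nm, ": ", as.character(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x a `gct_params` object.
#' @param ... unused.
#' @return A tibble with columns `parameter` and `value`.
#' @export
tidy.gct_params <- function(x, ...) {
  tibble::tibble(parameter = names(x), value = unlist(unname(x)))
}

#' Read / write parameter sets
#'
#' Parameter sets serialize as flat JSON or YAML maps keyed by parameter name.
#' A bundled default file (`system.file("extdata", "default_params.json",
#' package = "gctov")`) reproduces the packaged defaults.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @param params a `gct_params` object.
#' @param validate validate on read.
#' @return `read_params()` returns a `gct_params`; `write_params()` the path,
#'   invisibly.
#' @export
read_params <- function(path, validate = TRUE) {
  stopifnot(file.exists(path))
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(vals)) vals <- as.list(vals)
  bad <- names(vals)[!vapply(vals, function(v) is.numeric(v) && length(v) == 1, logical(1))]
  if (length(bad)) {
    stop("non-scalar or non-numeric value for key(s): ",
         paste(bad, collapse = ", "), " in ", path, call. = FALSE)
  }
  do.call(gct_params, c(vals, list(validate = validate)))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  vals <- unclass(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path, precision = 15)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# pack parameters + config flags into the flat numeric vector shared with the
# compiled derivative core; order is part of the C interface, do not reorder
pack_parms <- function(params, config) {
  p <- params
  c(a1 = p$a1, a2 = p$a2, d2 = p$d2, d3 = p$d3, ktr = p$ktr,
    kappa = p$kappa, delta = p$delta, alpha = p$alpha, omega = p$omega,
    kp = p$kp, kQ = p$kQ, ks = p$ks,
    psi_half = p$psi_half, kcp = p$kcp, eta_half = p$eta_half,
    C_half = p$C_half, gamma_P = p$gamma_P,
    Cprod_star = p$Cprod_star, Cprod_max = p$Cprod_max, k_elim = p$k_elim,
    j = p$j, ka = p$ka, V_PAC = p$V_PAC, kep = p$kep,
    k12P = p$k12P, k21P = p$k21P,
    alpha_T = p$alpha_T, kel = p$kel, kon = p$kon, R0 = p$R0,
    k12 = p$k12, k21 = p$k21, V = p$V, kint = p$kint, Tprod = p$Tprod,
    Emax_PAC = p$Emax_PAC, Emax_TRAIL = p$Emax_TRAIL,
    gamma_PAC = p$gamma_PAC, gamma_TRAIL = p$gamma_TRAIL, Psi = p$Psi,
    EC50_PAC = p$EC50_PAC, EC50_TRAIL = p$EC50_TRAIL,
    f_infection = as.numeric(config$variant_infection_sign == "corrected_plus"),
    f_g1entry = as.numeric(config$variant_g1_entry == "text_a2"),
    f_ntotal = as.numeric(config$variant_active_total == "algebraic_sum"),
    f_pdcomb = switch(config$pd_combination,
                      additive_synergy = 0, bliss = 1, pac_only = 2),
    f_clip = as.numeric(config$clip_negative))
}
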