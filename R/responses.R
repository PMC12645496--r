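#' Combined PAC-1 / TRAIL pharmacodynamic effect
#'
#' Each drug contributes a Hill term E_x = Emax_x c^gamma_x / (EC50_x^gamma_x
#' + c^gamma_x). The combined apoptotic amplification E multiplies the basal
#' apoptosis rates as d(1 + E). The default combination is additive with a
#' potency-weighted interaction, E = E_P + E_T + Psi E_P E_T; Bliss
#' independence and a PAC-1-only reduction are available through the config.
#'
#' @param c_pac plasma PAC-1 concentration, ng/ml (vectorized).
#' @param c_trail free TRAIL concentration, ng/ml (vectorized).
#' @param params a [gct_params()] set.
#' @param config a [gct_config()]; selects the combination rule.
#' @return Dimensionless effect E >= 0, bounded by
#'   `Emax_PAC + Emax_TRAIL + Psi * Emax_PAC * Emax_TRAIL` under the default
#'   rule.
#' @export
#' @examples
#' p <- gct_params()
#' pd_effect(p$EC50_PAC, 0, p)  # half of Emax_PAC
pd_effect <- function(c_pac, c_trail, params = gct_params(), config = gct_config()) {
  if (any(c_pac < 0) || any(c_trail < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  ep <- hill(c_pac, params$Emax_PAC, params$EC50_PAC, params$gamma_PAC)
  et <- hill(c_trail, params$Emax_TRAIL, params$EC50_TRAIL, params$gamma_TRAIL)
  switch(config$pd_combination,
    additive_synergy = ep + et + params$Psi * ep * et,
    bliss = ep + et - ep * et,
    pac_only = ep
  )
}

hill <- function(conc, emax, ec50, gamma) {
  cg <- conc^gamma
  ifelse(conc <= 0, 0, emax * cg / (ec50^gamma + cg))
}

#' Per-cell viral infection hazard
#'
#' Mass-action contact between virions and susceptible cycling cells,
#' saturating at the virion half-effect level: hazard(V) = kappa V /
#' (eta_half + V), bounded by the maximal infection rate kappa.
#'
#' @param v free virions, scaled units (vectorized).
#' @inheritParams pd_effect
#' @return Per-cell infection rate, 1/day.
#' @export
infection_hazard <- function(v, params = gct_params()) {
  if (any(v < 0)) stop("virion level must be non-negative", call. = FALSE)
  params$kappa * v / (params$eta_half + v)
}

#' Cytokine production in response to infection
#'
#' Rises from the homeostatic rate `Cprod_star` towards the maximal rate
#' `Cprod_max` as infected cells accumulate:
#' Cprod(I) = Cprod_star + (Cprod_max - Cprod_star) I / (psi_half + I).
#'
#' @param i_infected infected cells, scaled units (vectorized).
#' @inheritParams pd_effect
#' @return Cytokine production rate, ng/ml/day.
#' @export
cytokine_production <- function(i_infected, params = gct_params()) {
  if (any(i_infected < 0)) stop("infected-cell level must be non-negative", call. = FALSE)
  params$Cprod_star +
    (params$Cprod_max - params$Cprod_star) * i_infected / (params$psi_half + i_infected)
}

#' Cytokine-driven phagocyte recruitment
#'
#' phi(C) = kcp C / (C_half + C): phagocyte production recruited by the
#' cytokine signal, saturating at the maximal production rate kcp.
#'
#' @param c cytokine concentration, ng/ml (vectorized).
#' @inheritParams pd_effect
#' @return Phagocyte recruitment rate, scaled cells/day.
#' @export
phagocyte_recruitment <- function(c, params = gct_params()) {
  if (any(c < 0)) stop("cytokine concentration must be non-negative", call. = FALSE)
  params$kcp * c / (params$C_half + c)
}

#' Homeostatic TRAIL production rate
#'
#' The tabulated quantity is the homeostatic free-TRAIL concentration
#' `T_star`, not the production rate. `Tprod` is derived so that the
#' drug-free, tumor-free TMDD subsystem is at equilibrium at `T_star`:
#' with bound complex TP* = kon R0 T* / (kint + kon T*), the central balance
#' requires Tprod = kel T* + kon T* (R0 - TP*); the peripheral exchange
#' cancels at its own equilibrium TA* = k12 V T* / k21.
#'
#' @inheritParams pd_effect
#' @return Production rate in ng/ml/day.
#' @export
#' @examples
#' homeostatic_trail_production(gct_params())  # ~4.60 ng/ml/day
homeostatic_trail_production <- function(params) {
  ts <- params$T_star
  if (ts == 0) return(0)
  tp_star <- params$kon * params$R0 * ts / (params$kint + params$kon * ts)
  params$kel * ts + params$kon * ts * (params$R0 - tp_star)
}

#' Infection-free immune equilibrium
#'
#' Closed form of the cytokine-phagocyte subsystem with no infected cells:
#' C* = Cprod_star / k_elim and P* = phi(C*) / gamma_P.
#'
#' @inheritParams pd_effect
#' @return A named list with `C_star` (ng/ml) and `P_star` (scaled cells).
#' @export
immune_equilibrium <- function(params = gct_params()) {
  c_star <- params$Cprod_star / params$k_elim
  p_star <- phagocyte_recruitment(c_star, params) / params$gamma_P
  list(C_star = c_star, P_star = p_star)
}

#' Equilibrium of the bound and peripheral TRAIL compartments
#'
#' @inheritParams pd_effect
#' @return Named list with `T` (= `T_star`), `TP` (bound complex, ng/ml) and
#'   `TA` (peripheral amount, ng).
#' @keywords internal
trail_equilibrium <- function(params) {
  ts <- params$T_star
  tp <- params$kon * params$R0 * ts / (params$kint + params$kon * ts)
  ta <- params$k12 * params$V * ts / params$k21
  list(T = ts, TP = tp, TA = ta)
}
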