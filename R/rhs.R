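#' State-variable names for a parameter set
#'
#' The dynamical state comprises quiescent cells `Q`, G1-phase cells `G1`,
#' `j` transit compartments of the active cell-cycle phases `A1..Aj`,
#' infected cells `I`, free virions `V`, cytokine `C`, phagocytes `P`, the
#' oral PAC-1 depot `PA` (ng), plasma PAC-1 `PPAC` (ng/ml), peripheral PAC-1
#' `Pe` (ng/ml), free TRAIL `T` (ng/ml), receptor-bound TRAIL `TP` (ng/ml)
#' and peripheral TRAIL amount `TA` (ng). Under the `ode_eq5` variant an
#' explicit total-active-cell state `N` is appended; under the default
#' `algebraic_sum` variant N is computed as `sum(A)`.
#'
#' @inheritParams pd_effect
#' @return Character vector of state names, in integration order.
#' @export
state_names <- function(params = gct_params(), config = gct_config()) {
  nm <- c("Q", "G1", paste0("A", seq_len(params$j)),
          "I", "V", "C", "P", "PA", "PPAC", "Pe", "T", "TP", "TA")
  if (config$variant_active_total == "ode_eq5") nm <- c(nm, "N")
  nm
}

#' Build a model state vector
#'
#' @param ... named state components; unnamed components default to 0.
#' @inheritParams pd_effect
#' @return Named numeric state vector in integration order.
#' @export
make_state <- function(..., params = gct_params(), config = gct_config()) {
  nm <- state_names(params, config)
  y <- stats::setNames(numeric(length(nm)), nm)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), nm)
    if (length(bad)) stop("unknown state component(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    y[names(dots)] <- unlist(dots)
  }
  y
}

#' Right-hand side of the model ODE system
#'
#' Reference R implementation of the coupled tumor-virus-immune-PK/PD
#' derivative field. The simulator uses a compiled translation of the same
#' field for speed; this function is the readable specification and the one
#' to use for inspection and debugging.
#'
#' @param t time, days (the field is autonomous; dosing is applied as state
#'   jumps by the simulator).
#' @param state named numeric state vector (see [state_names()]).
#' @inheritParams pd_effect
#' @return A list whose first element is the derivative vector, as expected
#'   by [deSolve::ode()].
#' @export
gct_rhs <- function(t, state, params = gct_params(), config = gct_config()) {
  if (any(!is.finite(state))) {
    stop("non-finite state passed to the derivative field", call. = FALSE)
  }
  y <- state
  if (config$clip_negative) y <- pmax(y, 0)
  p <- params
  j <- p$j
  A <- y[3:(2 + j)]
  I <- y[[3 + j]]; Vv <- y[[4 + j]]; C <- y[[5 + j]]; P <- y[[6 + j]]
  PA <- y[[7 + j]]; PPAC <- y[[8 + j]]; Pe <- y[[9 + j]]
  Tf <- y[[10 + j]]; TP <- y[[11 + j]]; TA <- y[[12 + j]]
  Q <- y[[1]]; G1 <- y[[2]]

  E <- pd_effect(PPAC, Tf, p, config)
  haz <- infection_hazard(Vv, p)
  killQ <- p$kp * P / (1 + p$kQ * Q)
  killS <- p$kp * P / (1 + p$ks * G1)
  lossA <- p$d3 * (1 + E) + haz + killS

  N <- if (config$variant_active_total == "ode_eq5") y[["N"]] else sum(A)
  target <- if (config$variant_infection_sign == "corrected_plus") G1 + N else G1 - N
  entryA1 <- if (config$variant_g1_entry == "text_a2") p$a2 * G1 else p$a1 * G1

  dQ <- 2 * p$ktr * A[[j]] - p$a1 * Q - killQ * Q
  dG1 <- p$a1 * Q - (p$a2 + p$d2 * (1 + E) + haz + killS) * G1
  dA <- numeric(j)
  dA[1] <- entryA1 - p$ktr * A[[1]] - lossA * A[[1]]
  if (j > 1) {
    for (i in 2:j) dA[i] <- p$ktr * (A[[i - 1]] - A[[i]]) - lossA * A[[i]]
  }
  dI <- haz * target - p$delta * I
  dV <- p$alpha * p$delta * I - p$omega * Vv - haz * target
  dC <- cytokine_production(I, p) - p$k_elim * C
  dP <- phagocyte_recruitment(C, p) - p$gamma_P * P
  dPA <- -p$ka * PA
  dPPAC <- p$ka * PA / p$V_PAC - (p$kep + p$k12P) * PPAC + p$k21P * Pe
  dPe <- p$k12P * PPAC - p$k21P * Pe
  dT <- p$alpha_T * p$delta * I - p$kel * Tf - p$kon * Tf * (p$R0 - TP) -
    p$k12 * Tf + p$k21 * TA / p$V + p$Tprod
  dTP <- p$kon * (p$R0 - TP) * Tf - p$kint * TP
  dTA <- p$k12 * p$V * Tf - p$k21 * TA

  dy <- c(dQ, dG1, dA, dI, dV, dC, dP, dPA, dPPAC, dPe, dT, dTP, dTA)
  if (config$variant_active_total == "ode_eq5") {
    dN <- p$a2 * G1 - p$ktr * A[[j]] - lossA * N
    dy <- c(dy, dN)
  }
  list(dy)
}
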