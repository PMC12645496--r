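# Independent term-by-term oracle for the derivative field, written directly
# from the model equations, one line per equation, sharing no code with the
# package implementation. States are passed as a named vector with j transit
# compartments A1..Aj; corrected default variants only (infection target
# G1 + N, A1 entry at a2*G1, N = sum(A), additive-synergy effect).
oracle_rhs <- function(state, p) {
  j <- p$j
  Q <- state[["Q"]]; G1 <- state[["G1"]]
  A <- unname(state[paste0("A", 1:j)])
  I <- state[["I"]]; Vv <- state[["V"]]; C <- state[["C"]]; P <- state[["P"]]
  PA <- state[["PA"]]; PPAC <- state[["PPAC"]]; Pe <- state[["Pe"]]
  Tt <- state[["T"]]; TP <- state[["TP"]]; TA <- state[["TA"]]

  EP <- p$Emax_PAC * PPAC^p$gamma_PAC / (p$EC50_PAC^p$gamma_PAC + PPAC^p$gamma_PAC)
  if (PPAC == 0) EP <- 0
  ET <- p$Emax_TRAIL * Tt^p$gamma_TRAIL / (p$EC50_TRAIL^p$gamma_TRAIL + Tt^p$gamma_TRAIL)
  if (Tt == 0) ET <- 0
  E <- EP + ET + p$Psi * EP * ET

  keta <- p$kappa * Vv / (p$eta_half + Vv)
  N <- sum(A)

  dQ <- 2 * p$ktr * A[j] - p$a1 * Q - (p$kp * P / (1 + p$kQ * Q)) * Q
  dG1 <- p$a1 * Q - (p$a2 + p$d2 * (1 + E) + keta + p$kp * P / (1 + p$ks * G1)) * G1
  dA <- numeric(j)
  dA[1] <- p$a2 * G1 - p$ktr * A[1] -
    (p$d3 * (1 + E) + keta + p$kp * P / (1 + p$ks * G1)) * A[1]
  for (i in seq_len(j)[-1]) {
    dA[i] <- p$ktr * (A[i - 1] - A[i]) -
      (p$d3 * (1 + E) + keta + p$kp * P / (1 + p$ks * G1)) * A[i]
  }
  dI <- keta * (G1 + N) - p$delta * I
  dV <- p$alpha * p$delta * I - p$omega * Vv - keta * (G1 + N)
  Cprod <- p$Cprod_star + (p$Cprod_max - p$Cprod_star) * I / (p$psi_half + I)
  dC <- Cprod - p$k_elim * C
  dP <- p$kcp * C / (p$C_half + C) - p$gamma_P * P
  dPA <- -p$ka * PA
  dPPAC <- p$ka * PA / p$V_PAC - (p$kep + p$k12P) * PPAC + p$k21P * Pe
  dPe <- p$k12P * PPAC - p$k21P * Pe
  dT <- p$alpha_T * p$delta * I - p$kel * Tt - p$kon * Tt * (p$R0 - TP) -
    p$k12 * Tt + p$k21 * TA / p$V + p$Tprod
  dTP <- p$kon * (p$R0 - TP) * Tt - p$kint * TP
  dTA <- p$k12 * p$V * Tt - p$k21 * TA

  c(Q = dQ, G1 = dG1, stats::setNames(dA, paste0("A", 1:j)),
    I = dI, V = dV, C = dC, P = dP, PA = dPA, PPAC = dPPAC, Pe = dPe,
    T = dT, TP = dTP, TA = dTA)
}

# random strictly positive state on heterogeneous scales
random_state <- function(p, config = gct_config()) {
  nm <- state_names(p, config)
  scales <- c(Q = 1, G1 = 1, stats::setNames(rep(0.5, p$j), paste0("A", 1:p$j)),
              I = 0.01, V = 0.05, C = 1, P = 1, PA = 1e8, PPAC = 1e4,
              Pe = 1e4, T = 0.5, TP = 50, TA = 1e4)
  if ("N" %in% nm) scales <- c(scales, N = 3)
  stats::setNames(stats::runif(length(nm), 1e-6, 1) * scales[nm], nm)
}
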