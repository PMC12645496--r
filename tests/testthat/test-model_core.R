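test_that("default parameters satisfy their structural invariants", {
  p <- gct_params()
  expect_s3_class(p, "gct_params")
  # transit chain consistency: ktr = j / tau
  expect_lt(abs(p$ktr - p$j / p$tau) / p$ktr, 1e-3)
  expect_true(p$Emax_PAC > 0 && p$Emax_PAC < 1)
  expect_true(p$Emax_TRAIL > 0 && p$Emax_TRAIL < 1)
  expect_true(p$Psi >= 0 && p$Psi <= 1)
  vals <- unlist(unclass(p))
  expect_true(all(vals[setdiff(names(vals), "Tprod")] > 0))
  expect_identical(p$j, 6)
})

test_that("parameter validation rejects bad values and unknown names", {
  expect_error(gct_params(a1 = -1), "positive")
  expect_error(gct_params(Emax_PAC = 1.2), "Emax")
  expect_error(gct_params(j = 2.5), "integer")
  expect_error(gct_params(nonexistent = 1), "unknown parameter")
  # validate = FALSE admits out-of-range values (sensitivity sweeps)
  expect_silent(p <- gct_params(Emax_PAC = 1.5, validate = FALSE))
  expect_equal(p$Emax_PAC, 1.5)
})

test_that("parameter sets round-trip through JSON and YAML", {
  p <- gct_params(a1 = 4.2)
  for (ext in c("json", "yaml")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    q <- read_params(f)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  }
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"a1": "oops"}', f)
  expect_error(read_params(f), "a1")
})

test_that("pd_effect matches its closed forms and stays bounded and monotone", {
  p <- gct_params()
  cfg <- gct_config()
  expect_identical(pd_effect(0, 0, p, cfg), 0)
  # Hill term at its EC50 gives half the maximal efficacy
  expect_equal(pd_effect(p$EC50_PAC, 0, p, cfg), p$Emax_PAC / 2, tolerance = 1e-12)
  # saturation limit of the interaction combination
  sat <- p$Emax_PAC + p$Emax_TRAIL + p$Psi * p$Emax_PAC * p$Emax_TRAIL
  expect_equal(pd_effect(1e6 * p$EC50_PAC, 1e6 * p$EC50_TRAIL, p, cfg), sat,
               tolerance = 1e-3)
  expect_equal(sat, 1.6215, tolerance = 1e-3)
  grid <- exp(seq(log(1e-3), log(1e6), length.out = 100))
  e <- pd_effect(grid, grid / 2, p, cfg)
  expect_true(all(diff(e) >= -1e-12))
  expect_true(all(e <= sat + 1e-12))
  expect_error(pd_effect(-1, 0, p, cfg), "non-negative")
  # alternative combinations
  bl <- gct_config(pd_combination = "bliss")
  expect_lt(pd_effect(1e6, 1e6, p, bl), 1)
  po <- gct_config(pd_combination = "pac_only")
  expect_equal(pd_effect(p$EC50_PAC, 1e3, p, po), p$Emax_PAC / 2, tolerance = 1e-12)
})

test_that("saturating response functions hit their half-effect and limit values", {
  p <- gct_params()
  # infection hazard
  expect_identical(infection_hazard(0, p), 0)
  expect_equal(infection_hazard(p$eta_half, p), p$kappa / 2, tolerance = 1e-12)
  expect_equal(infection_hazard(1e6 * p$eta_half, p), p$kappa, tolerance = 1e-4)
  expect_error(infection_hazard(-0.1, p), "non-negative")
  # cytokine production
  expect_equal(cytokine_production(0, p), 3.9863e-4, tolerance = 1e-12)
  expect_equal(cytokine_production(1e6 * p$psi_half, p), 1.429, tolerance = 1e-4)
  expect_equal(cytokine_production(p$psi_half, p), (3.9863e-4 + 1.429) / 2,
               tolerance = 1e-12)
  # phagocyte recruitment
  expect_identical(phagocyte_recruitment(0, p), 0)
  expect_equal(phagocyte_recruitment(p$C_half, p), p$kcp / 2, tolerance = 1e-12)
  expect_equal(phagocyte_recruitment(1e9, p), p$kcp, tolerance = 1e-6)
  # monotonicity on a grid
  for (f in list(function(x) infection_hazard(x, p),
                 function(x) cytokine_production(x, p),
                 function(x) phagocyte_recruitment(x, p))) {
    g <- f(seq(0, 10, length.out = 100))
    expect_true(all(diff(g) >= -1e-14))
  }
})

test_that("derived TRAIL production holds the homeostatic concentration", {
  p <- gct_params()
  expect_equal(p$Tprod, 4.6027, tolerance = 1e-4)
  expect_equal(homeostatic_trail_production(gct_params(kon = 1e-12)),
               45 * 0.08090, tolerance = 1e-6)
  expect_equal(homeostatic_trail_production(gct_params(T_star = 0, validate = FALSE)), 0)
})

test_that("immune equilibrium closed form zeroes the infection-free subsystem", {
  p <- gct_params()
  eq <- immune_equilibrium(p)
  expect_equal(eq$C_star, 3.9863e-4 / 0.16139, tolerance = 1e-6)
  expect_equal(eq$P_star, 4.6754 * eq$C_star / (0.739 + eq$C_star) / 0.35,
               tolerance = 1e-10)
  big <- immune_equilibrium(gct_params(k_elim = 1e9))
  expect_lt(big$C_star, 1e-10)
  # full field vanishes at the tumor-free equilibrium state
  y <- initial_state(0, params = p)
  d <- gct_rhs(0, y, p, gct_config())[[1]]
  expect_lt(max(abs(d)), 1e-10)
})

test_that("rhs at the zero state leaves only the constant sources", {
  p <- gct_params()
  cfg <- gct_config()
  y <- make_state(params = p, config = cfg)
  d <- stats::setNames(gct_rhs(0, y, p, cfg)[[1]], state_names(p, cfg))
  expect_equal(d[["C"]], p$Cprod_star, tolerance = 1e-14)
  expect_equal(d[["T"]], p$Tprod, tolerance = 1e-12)
  expect_true(all(abs(d[setdiff(names(d), c("C", "T"))]) < 1e-14))
})

test_that("rhs agrees with the independent term-by-term oracle on random states", {
  p <- gct_params()
  cfg <- gct_config()
  nm <- state_names(p, cfg)
  set.seed(42)
  worst <- 0
  for (k in 1:1000) {
    y <- random_state(p, cfg)
    d_pkg <- stats::setNames(gct_rhs(0, y, p, cfg)[[1]], nm)
    d_orc <- oracle_rhs(y, p)
    rel <- abs(d_pkg - d_orc[nm]) / pmax(abs(d_orc[nm]), 1e-30)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-12)
})

test_that("compiled derivative core agrees with the R reference field", {
  p <- gct_params()
  cfg <- gct_config()
  set.seed(7)
  # same initial states integrated by the compiled core and by the R field
  # must land on the same trajectory
  for (k in 1:10) {
    y <- random_state(p, cfg)
    t_eval <- c(0, 0.05, 0.1)
    tc <- gct_simulate(p, cfg, y, empty_schedule(0.1), t_eval = t_eval)
    tr <- gct_simulate(p, cfg, y, empty_schedule(0.1), t_eval = t_eval,
                       use_compiled = FALSE)
    expect_equal(as.matrix(tc[-1]), as.matrix(tr[-1]), tolerance = 1e-8)
  }
})

test_that("non-negativity-preserving field: components at zero never go negative", {
  p <- gct_params()
  cfg <- gct_config()
  nm <- state_names(p, cfg)
  set.seed(9)
  for (k in 1:100) {
    y <- random_state(p, cfg)
    i0 <- sample(seq_along(y), 3)
    y[i0] <- 0
    d <- stats::setNames(gct_rhs(0, y, p, cfg)[[1]], nm)
    expect_true(all(d[i0] >= -1e-14))
  }
})

test_that("literal model variants change the field as documented", {
  p <- gct_params()
  nm <- state_names(p, gct_config())
  y <- stats::setNames(rep(0.1, length(nm)), nm)
  y["V"] <- 0.3
  d_cor <- stats::setNames(gct_rhs(0, y, p, gct_config())[[1]], nm)
  d_lit <- stats::setNames(
    gct_rhs(0, y, p, gct_config(variant_infection_sign = "literal_minus"))[[1]], nm)
  haz <- infection_hazard(0.3, p)
  G1 <- 0.1; N <- 6 * 0.1
  expect_equal(d_cor[["I"]] - d_lit[["I"]], haz * ((G1 + N) - (G1 - N)),
               tolerance = 1e-12)
  d_a1 <- stats::setNames(
    gct_rhs(0, y, p, gct_config(variant_g1_entry = "literal_a1"))[[1]], nm)
  expect_equal(d_a1[["A1"]] - d_cor[["A1"]], (p$a1 - p$a2) * G1, tolerance = 1e-12)
  # explicit-N variant carries one extra state
  cfg5 <- gct_config(variant_active_total = "ode_eq5")
  y5 <- make_state(Q = 0.1, G1 = 0.1, N = 0.6, params = p, config = cfg5)
  expect_length(gct_rhs(0, y5, p, cfg5)[[1]], length(nm) + 1)
})

test_that("tumor-only subsystem grows when immune kill, virus and drugs are absent", {
  p <- gct_params(kp = 1e-12, validate = FALSE)
  cfg <- gct_config()
  y <- initial_state(1e9, params = p, config = cfg)
  d <- stats::setNames(gct_rhs(0, y, p, cfg)[[1]], state_names(p, cfg))
  burden_deriv <- d[["Q"]] + d[["G1"]] + sum(d[paste0("A", 1:p$j)])
  expect_gt(burden_deriv, 0)
  # and over a 21-day simulation the burden increases
  tr <- gct_simulate(p, cfg, y, empty_schedule(21), t_eval = c(0, 21))
  b <- tumor_burden(tr, p)
  expect_gt(b$cells[2], b$cells[1])
})

test_that("rhs refuses non-finite states", {
  p <- gct_params()
  y <- make_state(params = p)
  y[["Q"]] <- NaN
  expect_error(gct_rhs(0, y, p, gct_config()), "finite")
})
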