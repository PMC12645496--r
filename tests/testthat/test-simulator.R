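test_that("build_schedule lays out the reference protocol", {
  p <- gct_params()
  sch <- build_schedule(375, 21, 0.03, 1e9, params = p)
  oral <- dplyr::filter(sch$events, target == "PA_oral")
  expect_equal(nrow(oral), 21)
  expect_equal(oral$time, as.numeric(0:20))
  expect_true(all(oral$amount == 3.75e8))
  inoc <- dplyr::filter(sch$events, target == "V_inoculum")
  expect_equal(nrow(inoc), 1)
  expect_equal(inoc$time, 0)
  expect_equal(inoc$amount, 0.003)                       # scaled virion units
  expect_equal(inoc$amount * p$cells_per_unit, 3e7)      # = moi x cells
  # degenerate schedules
  z <- build_schedule(0, 21, 0, 1e9)
  expect_equal(sum(z$events$amount), 0)
  expect_equal(nrow(dplyr::filter(z$events, target == "PA_oral")), 21)
  one <- build_schedule(375, 1, 0.03, 1e9)
  expect_equal(nrow(dplyr::filter(one$events, target == "PA_oral")), 1)
  expect_error(build_schedule(-1, 21, 0.03, 1e9), "non-negative")
})

test_that("initial_state distributes the burden and seats the equilibria", {
  p <- gct_params()
  cfg <- gct_config()
  yq <- initial_state(1e9, "all_quiescent", p, cfg)
  expect_equal(yq[["Q"]], 0.1)
  expect_equal(sum(yq[paste0("A", 1:6)]) + yq[["G1"]], 0)
  yr <- initial_state(1e9, "residence_time", p, cfg)
  tumor <- yr[["Q"]] + yr[["G1"]] + sum(yr[paste0("A", 1:6)])
  expect_equal(tumor, 0.1, tolerance = 1e-12)
  w <- c(1 / p$a1, 1 / (p$a2 + p$d2), rep(1 / p$ktr, 6))
  expect_equal(unname(yr[["Q"]] / tumor), w[1] / sum(w), tolerance = 1e-12)
  # zero tumor: only equilibrium compartments populated
  y0 <- initial_state(0, params = p, config = cfg)
  eq <- immune_equilibrium(p)
  expect_equal(y0[["C"]], eq$C_star)
  expect_equal(y0[["P"]], eq$P_star)
  expect_equal(y0[["T"]], p$T_star)
  expect_equal(sum(y0[c("Q", "G1", paste0("A", 1:6), "I", "V", "PA", "PPAC", "Pe")]), 0)
  expect_error(initial_state(1e9, "bogus"), "arg")
  expect_error(initial_state(-5), "non-negative")
})

test_that("zero tumor state is invariant under the full treated simulation", {
  p <- gct_params()
  cfg <- gct_config()
  y0 <- initial_state(0, params = p, config = cfg)
  tr <- gct_simulate(p, cfg, y0, build_schedule(375, 21, 0.03, 1e9), t_eval = 0:21)
  tum <- c("Q", "G1", paste0("A", 1:6), "I")
  expect_true(all(as.matrix(tr[tum]) < 1e-12))
})

test_that("oral depot follows the first-order absorption closed form", {
  p <- gct_params()
  cfg <- gct_config()
  sch <- build_schedule(375, 1, 0, 1e9, horizon = 2)
  tr <- gct_simulate(p, cfg, initial_state(1e9, params = p), sch,
                     t_eval = seq(0, 2, by = 0.05))
  exact <- 3.75e8 * exp(-p$ka * tr$time)
  expect_lt(max(abs(tr$PA - exact) / exact), 1e-6)
})

test_that("PAC-1 plasma kinetics are linear: two simultaneous doses superpose", {
  p <- gct_params()
  cfg <- gct_config()
  y0 <- initial_state(0, params = p, config = cfg)
  run <- function(dose) {
    sch <- build_schedule(dose, 1, 0, 1e9, horizon = 3)
    gct_simulate(p, cfg, y0, sch, t_eval = seq(0, 3, by = 0.1))
  }
  single <- run(375)
  double <- run(750)
  for (col in c("PA", "PPAC", "Pe")) {
    expect_equal(double[[col]], 2 * single[[col]], tolerance = 1e-6)
  }
})

test_that("solver tolerances and sampling grids are consistent", {
  p <- gct_params()
  y0 <- initial_state(1e9, params = p)
  sch <- build_schedule(375, 5, 0.03, 1e9)
  b1 <- tumor_burden(gct_simulate(p, gct_config(), y0, sch, t_eval = 5), p)$cells
  b2 <- tumor_burden(gct_simulate(p, gct_config(rtol = 5e-7, atol = 5e-10),
                                  y0, sch, t_eval = 5), p)$cells
  expect_lt(abs(b1 - b2) / b1, 1e-3)
  # trajectory sampled on a subset grid matches the superset at shared points
  t_coarse <- c(0, 2, 5)
  t_fine <- c(0, 1, 2, 3, 4, 5)
  trc <- gct_simulate(p, gct_config(), y0, sch, t_eval = t_coarse)
  trf <- gct_simulate(p, gct_config(), y0, sch, t_eval = t_fine)
  shared <- match(t_coarse, t_fine)
  for (col in c("Q", "G1", "V", "PPAC", "T")) {
    expect_equal(trc[[col]], trf[[col]][shared], tolerance = 1e-6)
  }
})

test_that("therapy never increases day-21 burden relative to no treatment", {
  p <- gct_params()
  cfg <- gct_config()
  y0 <- initial_state(1e9, params = p, config = cfg)
  treated <- gct_simulate(p, cfg, y0, build_schedule(375, 21, 0.03, 1e9), t_eval = 21)
  untreated <- gct_simulate(p, cfg, y0, empty_schedule(21), t_eval = 21)
  expect_lte(tumor_burden(treated, p)$cells, tumor_burden(untreated, p)$cells)
})

test_that("trajectories stay non-negative from random non-negative starts", {
  p <- gct_params()
  cfg <- gct_config()
  set.seed(31)
  for (k in 1:20) {
    y <- random_state(p, cfg)
    tr <- gct_simulate(p, cfg, y, empty_schedule(2), t_eval = seq(0, 2, by = 0.25))
    expect_gt(min(as.matrix(tr[-1])), -cfg$atol)
  }
})

test_that("tumor burden converts scaled units to cells and volume", {
  p <- gct_params()
  y <- make_state(Q = 0.1, params = p)
  b <- tumor_burden(y, p)
  expect_equal(b$cells, 1e9)
  expect_equal(b$volume_cc, 1)
  y2 <- make_state(Q = 0.05, G1 = 0.03, A1 = 0.02, params = p)
  expect_equal(tumor_burden(y2, p)$cells, 1e9)
  expect_equal(tumor_burden(make_state(params = p), p)$cells, 0)
})

test_that("trajectory accessors and export behave", {
  p <- gct_params()
  tr <- gct_simulate(p, gct_config(), initial_state(1e9, params = p),
                     build_schedule(375, 2, 0.03, 1e9), t_eval = 0:2)
  expect_s3_class(tr, "gct_trajectory")
  expect_equal(tr$time, as.numeric(0:2))
  y0 <- initial_state(1e9, params = p)
  # first row reports the post-event state at t = 0
  expect_equal(tr$PA[1], 3.75e8)
  expect_equal(tr$V[1], 0.003)
  expect_equal(tr$Q[1], y0[["Q"]])
  expect_equal(tr$T[1], y0[["T"]])
  long <- tidy(tr)
  expect_named(long, c("time", "variable", "value"))
  expect_equal(nrow(long), 3 * 18)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  expect_true(file.exists(f))
  expect_s3_class(autoplot(tr, vars = c("Q", "V")), "ggplot")
})

test_that("solver failure is reported explicitly", {
  p <- gct_params(omega = -50, validate = FALSE)  # growing virus blows up
  cfg <- gct_config(clip_negative = FALSE)
  y <- make_state(Q = 1, G1 = 1, V = 1, I = 1, params = p, config = cfg)
  expect_error(
    gct_simulate(p, cfg, y, empty_schedule(200), t_eval = c(0, 200)),
    "solver|failure|finite")
})
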