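## cheap analytic surrogate standing in for the APD simulator: a smooth
## nonlinear response to the five scalers with targets generated at a known
## point.  Signature matches calibration_objective(scalers, targets, n_beats).
surrogate_factory <- function(truth) {
  respond <- function(s) {
    c(300 - 60 * log(s[1]) + 25 * log(s[2]) * log(s[1] + 1),
      260 - 40 * log(s[2]) + 30 * log(s[4]),
      250 - 30 * log(s[3]) + 10 * sqrt(s[5]),
      280 + 45 * log(s[4]) - 5 * s[1],
      240 + 35 * log(s[5]) + 8 * log(s[3]))
  }
  target_vals <- respond(truth)
  function(scalers, targets, n_beats) {
    sum((respond(scalers) - target_vals)^2)
  }
}

test_that("calibration targets validate and round-trip through CSV", {
  tg <- calibration_targets(condition = c("control", "e4031"),
                            cl = c(1000, 1000), fraction = 0.9,
                            apd_ms = c(270, 420), sd_ms = c(10, 20))
  expect_equal(tg$weight, c(1 / 100, 1 / 400))
  f <- tempfile(fileext = ".csv")
  write_calibration_targets(tg, f)
  tg2 <- read_calibration_targets(f)
  expect_equal(tg2$apd_ms, tg$apd_ms)
  expect_equal(tg2$weight, tg$weight)
  expect_error(calibration_targets("control", 1000, 0.9, 270, sd_ms = 0),
               "> 0")
  expect_error(calibration_targets("control", -5, 0.9, 270), "positive")
})

test_that("real-simulation objective is ~0 at the generating scalers and rises under perturbation", {
  gen <- conductance_scaling(IKr = 1.013, IKs = 1.87, IK1 = 1.698,
                             ICaL = 1.007, INaL = 2.661)
  sim <- simulate_calibration_apds(gen,
                                   calibration_targets(
                                     condition = c("control", "mexiletine"),
                                     cl = 1000, fraction = 0.9,
                                     apd_ms = 0),
                                   n_beats = 60)
  tg <- calibration_targets(condition = c("control", "mexiletine"),
                            cl = 1000, fraction = 0.9,
                            apd_ms = sim$apd_sim)
  expect_lt(calibration_objective(gen, tg, n_beats = 60), 1e-12)
  # INaL perturbation is visible on the INaL-rich mexiletine condition
  pert <- conductance_scaling(IKr = 1.013, IKs = 1.87, IK1 = 1.698,
                              ICaL = 1.007, INaL = 1.8)
  expect_gt(calibration_objective(pert, tg, n_beats = 60), 1)
})

test_that("equal-weight objective equals the plain SSE oracle", {
  tg <- calibration_targets(condition = "control", cl = 1000,
                            fraction = c(0.5, 0.9), apd_ms = c(200, 260))
  sim <- simulate_calibration_apds(scaling_optimized(), tg, n_beats = 30)
  sse <- sum((sim$apd_sim - tg$apd_ms)^2)
  expect_equal(calibration_objective(scaling_optimized(), tg,
                                     n_beats = 30),
               sse, tolerance = 1e-10)
})

test_that("optimizer recovers known scalers within 10% on surrogate targets", {
  truth <- c(1.0, 1.9, 1.7, 1.0, 2.7)
  obj <- surrogate_factory(truth)
  cfg <- optimizer_config(pop_size = 30, max_generations = 200,
                          conv_tol = 1e-4, conv_window = 30, seed = 99)
  res <- optimize_conductances(targets = NULL, config = cfg,
                               objective = obj)
  expect_true(all(abs(as.numeric(res$scaling) - truth) / truth < 0.10))
  # convergence trace is non-increasing (elitism)
  expect_true(all(diff(res$trace) <= 1e-12))
})

test_that("seeded optimizer runs are reproducible; collapsed bounds return the point", {
  obj <- surrogate_factory(c(1, 1.9, 1.7, 1, 2.7))
  cfg <- optimizer_config(pop_size = 10, max_generations = 20,
                          conv_window = 5, seed = 3)
  r1 <- optimize_conductances(NULL, cfg, objective = obj)
  r2 <- optimize_conductances(NULL, cfg, objective = obj)
  expect_identical(as.numeric(r1$scaling), as.numeric(r2$scaling))
  expect_identical(r1$trace, r2$trace)

  pt <- c(1.2, 1.2, 1.2, 1.2, 1.2)
  cfgp <- optimizer_config(lower = pt, upper = pt + 1e-12, pop_size = 5,
                           max_generations = 3, conv_window = 2, seed = 1)
  rp <- optimize_conductances(NULL, cfgp, objective = obj)
  expect_equal(as.numeric(rp$scaling), pt, tolerance = 1e-9)

  expect_error(optimizer_config(lower = c(0, 1, 1, 1, 1)), "bounds")
  expect_error(optimizer_config(pop_size = 2), "pop_size")
})

test_that("budget exhaustion warns and still returns the best-so-far", {
  obj <- surrogate_factory(c(1, 1.9, 1.7, 1, 2.7))
  cfg <- optimizer_config(pop_size = 8, max_generations = 3,
                          conv_window = 30, seed = 5)
  expect_warning(res <- optimize_conductances(NULL, cfg, objective = obj),
                 "budget")
  expect_false(res$converged)
  expect_equal(res$generations, 3)
  expect_true(is.finite(res$cost))
})
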