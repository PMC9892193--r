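cfg <- reactor_config()

test_that("nitrogen increments follow the interval-integrated balance", {
  # balanced in/out retains nothing
  expect_equal(nitrogen_increment(cfg, c_n_aq_out = feed_n_at(cfg, 1),
                                  c_n_px_out = 0, dt = 3.5, t = 1), 0)
  # direct arithmetic: F (c_in - c_aq - c_px) dt
  expect_equal(nitrogen_increment(cfg, 0.005, 0.001, dt = 3.5, t = 10),
               0.015 * (0.00748 - 0.005 - 0.001) * 3.5)
  expect_equal(nitrogen_increment(cfg, 0.005, 0.001, dt = 3.5, t = 10),
               7.77e-5, tolerance = 1e-10)
  # lysis regime: outflow nitrogen above feed gives a negative increment
  expect_lt(nitrogen_increment(cfg, 0.009, 0.0005, dt = 2, t = 170), 0)
  expect_error(nitrogen_increment(cfg, 0.005, 0.001, dt = 0),
               class = "nbalance_input_error")
})

test_that("a feed schedule is piecewise constant in time", {
  sched <- data.frame(t_start = c(0, 62), c_n_in = c(0.00748, 0.01496))
  cfg2 <- reactor_config(c_n_in = sched)
  expect_equal(feed_n_at(cfg2, c(0, 61.9, 62, 100)),
               c(0.00748, 0.00748, 0.01496, 0.01496))
  # the increment uses the schedule at the interval end
  d1 <- nitrogen_increment(cfg2, 0.005, 0, dt = 1, t = 50)
  d2 <- nitrogen_increment(cfg2, 0.005, 0, dt = 1, t = 70)
  expect_equal(d2 - d1, 0.015 * 0.00748)
})

test_that("biomass accumulation handles the no-exchange and stoichiometric cases", {
  cal <- calibration_model(0.0052, 0)
  # no net N exchange, no planktonic cells: flat trajectory at the inoculum
  s <- sample_series(t = seq(0, 20, by = 2), c_n_aq_out = 0.00748, od600 = 0)
  b <- accumulate_biomass(cfg, s, cal, n_x0 = 2.19e-3)
  expect_equal(b$n_x_total, rep(2.19e-3, nrow(b)))
  expect_equal(b$n_px, rep(0, nrow(b)))
  expect_equal(b$biofilm_fraction, rep(1, nrow(b)))
  expect_true(all(b$flag == ""))

  # one interval retaining 2 mmol N adds 2/0.2 = 10 mmol biomass
  # (a higher flow keeps the required outflow concentration non-negative)
  dt <- 2
  cfg_big <- reactor_config(f_in = 0.5)
  c_out <- 0.00748 - 0.002 / (cfg_big$f_in * dt)
  s2 <- sample_series(t = c(0, dt), c_n_aq_out = c(0.00748, c_out), od600 = 0)
  b2 <- accumulate_biomass(cfg_big, s2, cal, n_x0 = 2.19e-3)
  expect_equal(diff(b2$n_x_total), 0.002 / 0.2, tolerance = 1e-12)
})

test_that("nitrogen is conserved exactly: retained + exported = imported", {
  cal <- calibration_model(0.0052, -2e-5)
  set.seed(3)
  for (k in 1:5) {
    t <- cumsum(runif(15, 0.2, 1.5))
    s <- sample_series(t = t, c_n_aq_out = runif(15, 0, 0.01),
                       od600 = runif(15, 0, 0.5))
    b <- accumulate_biomass(cfg, s, cal)
    n <- length(t)
    dt <- diff(t)
    imported <- sum(cfg$f_in * feed_n_at(cfg, t[-1]) * dt)
    exported <- sum(cfg$f_in * (s$c_n_aq_out[-1] + b$c_n_px[-1]) * dt)
    expect_equal(b$cum_n_retained[n] + exported, imported, tolerance = 1e-14)
  }
})

test_that("biomass estimates scale inversely with the nitrogen coefficient", {
  cal <- calibration_model(0.0052, 0)
  t <- seq(0, 10, by = 1)
  s <- sample_series(t = t, c_n_aq_out = 0.004, od600 = 0.05)
  b1 <- accumulate_biomass(reactor_config(nu_nx = 0.2), s, cal, n_x0 = 0)
  b2 <- accumulate_biomass(reactor_config(nu_nx = 0.4), s, cal, n_x0 = 0)
  expect_equal(b1$n_x_total, 2 * b2$n_x_total, tolerance = 1e-12)
  expect_equal(b1$n_px, 2 * b2$n_px, tolerance = 1e-12)
})

test_that("the balance recovers simulator ground-truth biomass", {
  sim <- cached_sim("growth_plateau")
  b <- accumulate_biomass(cfg, sim$samples, sim_calibration(),
                          holdup_correction = TRUE)
  truth <- truth_at(sim, "n_x_total", b$t)
  rel <- abs(b$n_x_total - truth) / truth
  expect_lt(max(rel[b$t >= 5]), 0.02)
  # trapezoidal integration is strictly more accurate here
  bt <- accumulate_biomass(cfg, sim$samples, sim_calibration(),
                           integration = "trapz", holdup_correction = TRUE)
  relt <- abs(bt$n_x_total - truth) / truth
  expect_lt(max(relt[bt$t >= 5]), max(rel[b$t >= 5]))
  # late in the run, nearly all biomass sits in the biofilm
  late <- b$t >= 69
  expect_true(all(b$biofilm_fraction[late] > 0.99))
})

test_that("a planktonic-only reactor yields a near-zero biofilm partition", {
  sim <- cached_sim("planktonic_only")
  b <- accumulate_biomass(cfg, sim$samples, sim_calibration(),
                          holdup_correction = TRUE)
  expect_lte(max(b$biofilm_fraction, na.rm = TRUE), 0.05)
})

test_that("negative biofilm estimates are flagged, never clipped", {
  cal <- calibration_model(0.0052, 0)
  # high OD with no retained nitrogen forces n_px > n_x_total
  s <- sample_series(t = c(0, 1), c_n_aq_out = 0.00748, od600 = c(0, 2))
  b <- accumulate_biomass(cfg, s, cal, n_x0 = 1e-4)
  expect_lt(b$n_bx[2], 0)
  expect_identical(b$flag[2], "negative_biofilm")
  expect_true(is.na(b$biofilm_fraction[2]))
})

test_that("malformed series are rejected", {
  expect_error(sample_series(t = numeric(0), c_n_aq_out = 1, od600 = 0),
               class = "nbalance_input_error")
  expect_error(sample_series(t = c(0, 2, 1), c_n_aq_out = 0.005, od600 = 0),
               class = "nbalance_input_error")
  expect_error(sample_series(t = c(0, 1), c_n_aq_out = -0.1, od600 = 0),
               class = "nbalance_input_error")
})
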