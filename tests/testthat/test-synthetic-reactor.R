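cfg <- reactor_config()

test_that("pure washout matches the analytic CSTR exponential", {
  sim <- cached_sim("washout_only")
  np0 <- sim$truth$n_px[1]
  analytic <- np0 * exp(-sim$truth$t / hrt(cfg))
  expect_lt(max(abs(sim$truth$n_px - analytic) / np0), 1e-6)
  expect_true(all(sim$truth$c_acetate == 0))
  expect_true(all(sim$truth$n_bx == 0))
})

test_that("with ample nitrogen the biofilm saturates at its capacity", {
  cfg_rich <- reactor_config(c_n_in = 0.08)
  p <- sim_params(noise = 0, horizon = 150)
  sim <- simulate_reactor(cfg_rich, p)
  expect_equal(sim$truth$n_bx[nrow(sim$truth)], p$n_bx_max, tolerance = 0.02)
  # plateau: late growth is a small fraction of peak growth
  nb <- sim$truth$n_bx
  late_slope <- diff(tail(nb, 2)) / diff(tail(sim$truth$t, 2))
  expect_lt(late_slope, 0.01 * max(diff(nb) / diff(sim$truth$t)))
})

test_that("the simulator conserves elemental nitrogen to solver tolerance", {
  for (scen in c("growth_plateau", "washout_only", "planktonic_only")) {
    resid <- nitrogen_closure_residual(cached_sim(scen))
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("Faradaic efficiency closes at 100% with no parasitic sink", {
  expect_equal(fe_closure(cached_sim("growth_plateau")), 100,
               tolerance = 0.01)
  expect_equal(fe_closure(cached_sim("lag_then_production")), 100,
               tolerance = 0.01)
})

test_that("fixtures are deterministic per seed and scenario-faithful", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture("growth_plateau", seed = 7L, dir = d1)
  p2 <- make_fixture("growth_plateau", seed = 7L, dir = d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  d3 <- withr::local_tempdir()
  p3 <- make_fixture("growth_plateau", seed = 8L, dir = d3)
  expect_false(identical(readLines(p1[["measurements"]]),
                         readLines(p3[["measurements"]])))

  pw <- make_fixture("washout_only", seed = 7L, dir = d1)
  mw <- read_measurements(pw[["measurements"]])
  expect_true(all(mw$acetate == 0 & mw$butyrate == 0 & mw$hexanoate == 0))
  expect_error(make_fixture("no_such_scenario"),
               class = "nbalance_input_error")
})

test_that("production lag and chain-elongation thresholds gate the products", {
  sim <- cached_sim("lag_then_production")
  pre <- sim$truth$t < sim$params$t_lag_production
  expect_true(all(sim$truth$c_acetate[pre] == 0))
  expect_gt(sim$truth$c_acetate[nrow(sim$truth)], 0)

  p <- sim_params(noise = 0, horizon = 60, butyrate_threshold_g_l = 2.5)
  simt <- simulate_reactor(cfg, p)
  titer_c2 <- simt$truth$c_acetate * 60.05
  first_but <- min(simt$truth$t[simt$truth$c_butyrate > 0])
  expect_gte(titer_c2[match(first_but, simt$truth$t)], 2.5 * 0.99)
})

test_that("early-phase mu and steady-state q_p are recovered by the pipeline", {
  sim <- cached_sim("growth_plateau")
  b <- accumulate_biomass(cfg, sim$samples, sim_calibration(),
                          holdup_correction = TRUE)
  mu_hat <- specific_growth_rate(cfg, b)
  pk <- which.max(mu_hat$mu)
  mu_true <- truth_at(sim, "mu_inst", mu_hat$t_mid[pk])
  expect_equal(mu_hat$mu[pk], mu_true, tolerance = 0.10)

  rs <- rate_series(cfg, sim$samples, b)
  late <- rs$t_mid >= 60
  expect_equal(mean(rs$q_p_total[late]),
               mean(truth_at(sim, "q_p_total", rs$t_mid[late])),
               tolerance = 0.05)
})

test_that("biomass recovery is robust to 5% observation noise across seeds", {
  seeds <- 1:50
  med_err <- vapply(seeds, function(s) {
    sim <- simulate_reactor(cfg, sim_params(noise = 0.05, seed = s))
    b <- accumulate_biomass(cfg, sim$samples, sim_calibration(),
                            holdup_correction = TRUE)
    truth <- truth_at(sim, "n_x_total", b$t)
    keep <- b$t >= 10
    median(abs(b$n_x_total[keep] - truth[keep]) / truth[keep])
  }, numeric(1))
  expect_lte(median(med_err), 0.10)
})

test_that("a seeded simulation does not disturb the global RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_reactor(cfg, sim_params(noise = 0.05, seed = 9L,
                                             horizon = 5)))
  after <- runif(1)
  expect_identical(before, after)
})
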