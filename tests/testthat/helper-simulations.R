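# shared fixtures: simulations are moderately expensive, so noiseless runs
# used by several test files are memoized per scenario
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(scenario = "growth_plateau") {
  if (is.null(.sim_cache[[scenario]])) {
    .sim_cache[[scenario]] <-
      simulate_reactor(reactor_config(),
                       scenario_params(scenario, noise = 0))
  }
  .sim_cache[[scenario]]
}

# the OD600 line used to generate simulated observations
sim_calibration <- function() calibration_model(0.0052, -2e-5,
                                                r_squared = 0.9989)

# interpolate a ground-truth column onto arbitrary times
truth_at <- function(sim, column, t) {
  approx(sim$truth$t, sim$truth[[column]], xout = t)$y
}

# Faradaic-efficiency closure of a simulation over its full horizon,
# computed from the ground-truth cumulative integrals
fe_closure <- function(sim) {
  tr <- sim$truth
  n <- nrow(tr)
  v <- sim$config$v_tc
  produced <- c(
    acetate = tr$cum_exp_acetate[n] + v * tr$c_acetate[n],
    butyrate = tr$cum_exp_butyrate[n] + v * tr$c_butyrate[n],
    hexanoate = tr$cum_exp_hexanoate[n] + v * tr$c_hexanoate[n])
  biomass <- (tr$n_x_total[n] - tr$n_x_total[1]) +
    tr$cum_exp_n_px[n] / sim$config$nu_nx
  faradaic_efficiency(produced, biomass, tr$cum_charge_c[n])
}
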