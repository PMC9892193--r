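#' Named simulation scenarios
#'
#' Pre-defined parameter sets for [simulate_reactor()] covering the regimes
#' a nitrogen-balance pipeline must handle:
#' \describe{
#'   \item{`growth_plateau`}{default kinetics: biofilm colonization from a
#'     mostly planktonic inoculum, nitrogen drawdown, product accumulation
#'     toward a pseudo steady state.}
#'   \item{`washout_only`}{no growth, no attachment, no production: the
#'     planktonic inoculum washes out exponentially with the HRT.}
#'   \item{`lag_then_production`}{same kinetics as `growth_plateau` but
#'     product formation only switches on after a 20-day lag, emulating a
#'     reactor that grows and draws current long before organics appear.}
#'   \item{`planktonic_only`}{no biofilm compartment (no attached inoculum,
#'     no detachment sink): all biomass stays in suspension, for
#'     method-consistency checks of the biofilm partition.}
#' }
#'
#' @param name scenario id.
#' @param seed integer seed for the observation noise.
#' @param noise relative observation noise SD (default 0.05; set 0 for
#'   noiseless ground-truth checks).
#' @return a [sim_params()] object.
#' @export
scenario_params <- function(name, seed = 1L, noise = 0.05) {
  switch(name,
    growth_plateau = sim_params(noise = noise, seed = seed),
    washout_only = sim_params(mu_max = 0, k_det = 0, k_dec = 0,
                              q_p = c(acetate = 0, butyrate = 0,
                                      hexanoate = 0),
                              biofilm_inoculum_fraction = 0,
                              noise = noise, seed = seed),
    lag_then_production = sim_params(t_lag_production = 20,
                                     noise = noise, seed = seed),
    planktonic_only = sim_params(biofilm_inoculum_fraction = 0, k_det = 0,
                                 noise = noise, seed = seed),
    stop_input("unknown scenario: ", name)
  )
}

#' Write a simulated fixture to disk
#'
#' Runs a named scenario and writes three plain-text files to `dir`:
#' `<name>_config.yaml` (reactor configuration and inoculum),
#' `<name>_measurements.csv` (the noisy sample series, same schema as
#' [read_measurements()] expects), and `<name>_truth.csv` (the dense ground
#' truth). Deterministic per seed: the same call produces byte-identical
#' files.
#'
#' @param name scenario id (see [scenario_params()]).
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param noise relative observation noise SD.
#' @param config a [reactor_config()].
#' @return invisibly, the named character vector of paths written.
#' @export
make_fixture <- function(name, seed = 1L, dir = tempdir(), noise = 0.05,
                         config = reactor_config()) {
  params <- scenario_params(name, seed = seed, noise = noise)
  sim <- simulate_reactor(config, params)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(config = file.path(dir, paste0(name, "_config.yaml")),
             measurements = file.path(dir, paste0(name, "_measurements.csv")),
             truth = file.path(dir, paste0(name, "_truth.csv")))
  write_reactor_config(config, paths[["config"]],
                       extra = list(units = "mol", scenario = name,
                                    seed = seed))
  write_measurements(sim$samples, paths[["measurements"]])
  df <- as.data.frame(sim$truth)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            paths[["truth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
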