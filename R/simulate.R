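#' Simulation parameters for the synthetic biofilm reactor
#'
#' Kinetic and observation parameters for [simulate_reactor()]. The defaults
#' describe a biofilm electrosynthesis start-up: a maximum specific growth
#' rate of 0.15 d\eqn{^{-1}}, Monod limitation on dissolved nitrogen,
#' logistic space limitation as the cathode fills, slow detachment seeding
#' the planktonic phase, and a constant biomass-specific production spectrum
#' totalling 0.2 mol-C mol-X\eqn{^{-1}} d\eqn{^{-1}} split over acetate,
#' butyrate and hexanoate.
#'
#' @param mu_max maximum specific growth rate, d\eqn{^{-1}}.
#' @param k_n Monod half-saturation constant for dissolved nitrogen,
#'   mol L\eqn{^{-1}}.
#' @param n_bx_max biofilm capacity of the electrode, mol biomass.
#' @param k_det biofilm detachment rate constant, d\eqn{^{-1}}.
#' @param k_dec biomass decay (lysis) rate constant, d\eqn{^{-1}}; decayed
#'   biomass returns its nitrogen to solution.
#' @param q_p named vector of biomass-specific production rates,
#'   mol-C mol-X\eqn{^{-1}} d\eqn{^{-1}}, names from the stoichiometry
#'   table.
#' @param biofilm_inoculum_fraction fraction of the inoculum attached to
#'   the electrode at t = 0.
#' @param t_lag_production time before product formation switches on, days.
#' @param butyrate_threshold_g_l,hexanoate_threshold_g_l optional chain-
#'   elongation thresholds: butyrate production requires the acetate titer
#'   (g L\eqn{^{-1}}) to exceed the first, hexanoate requires the butyrate
#'   titer to exceed the second. `NULL` (default) disables them.
#' @param noise relative standard deviation of the multiplicative Gaussian
#'   observation noise applied to every observable (truncated at 0).
#' @param seed integer RNG seed; required when `noise > 0`.
#' @param dt_solver ODE output step, days.
#' @param sample_interval observation interval, days (\eqn{\ge}
#'   `dt_solver`).
#' @param horizon simulated duration, days.
#' @param calibration the [calibration_model()] whose inverse generates the
#'   OD600 observable.
#' @return an object of class `sim_params` (a named list).
#' @export
sim_params <- function(mu_max = 0.15,
                       k_n = 5e-4,
                       n_bx_max = 0.05,
                       k_det = 0.001,
                       k_dec = 0,
                       q_p = c(acetate = 0.12, butyrate = 0.06,
                               hexanoate = 0.02),
                       biofilm_inoculum_fraction = 0.1,
                       t_lag_production = 0,
                       butyrate_threshold_g_l = NULL,
                       hexanoate_threshold_g_l = NULL,
                       noise = 0.05,
                       seed = NULL,
                       dt_solver = 0.05,
                       sample_interval = 0.5,
                       horizon = 80,
                       calibration = calibration_model(0.0052, -2e-5,
                                                       r_squared = 0.9989)) {
  if (mu_max < 0 || k_n <= 0 || k_det < 0 || k_dec < 0)
    stop_input("rate constants must be >= 0 and k_n > 0")
  if (n_bx_max <= 0) stop_input("n_bx_max must be > 0")
  if (any(q_p < 0)) stop_input("q_p entries must be >= 0")
  if (biofilm_inoculum_fraction < 0 || biofilm_inoculum_fraction > 1)
    stop_input("biofilm_inoculum_fraction must be in [0, 1]")
  if (sample_interval < dt_solver)
    stop_input("sample_interval must be >= dt_solver")
  if (noise > 0 && is.null(seed))
    stop_input("a seed is required when observation noise > 0")
  structure(list(mu_max = mu_max, k_n = k_n, n_bx_max = n_bx_max,
                 k_det = k_det, k_dec = k_dec, q_p = q_p,
                 biofilm_inoculum_fraction = biofilm_inoculum_fraction,
                 t_lag_production = t_lag_production,
                 butyrate_threshold_g_l = butyrate_threshold_g_l,
                 hexanoate_threshold_g_l = hexanoate_threshold_g_l,
                 noise = noise, seed = seed, dt_solver = dt_solver,
                 sample_interval = sample_interval, horizon = horizon,
                 calibration = calibration),
            class = "sim_params")
}

# active q_p spectrum at time t given current product concentrations
.active_qp <- function(params, stoich, t, conc) {
  q <- params$q_p
  if (t < params$t_lag_production) q[] <- 0
  mm <- stoich_lookup(stoich, names(conc), "molar_mass")
  titer <- conc * mm
  if (!is.null(params$butyrate_threshold_g_l) &&
      "butyrate" %in% names(q) &&
      titer[["acetate"]] < params$butyrate_threshold_g_l)
    q[["butyrate"]] <- 0
  if (!is.null(params$hexanoate_threshold_g_l) &&
      "hexanoate" %in% names(q) &&
      titer[["butyrate"]] < params$hexanoate_threshold_g_l)
    q[["hexanoate"]] <- 0
  q
}

# instantaneous process rates from the state; shared by the ODE right-hand
# side and the ground-truth post-processing so the two cannot drift apart
.reactor_rates <- function(t, y, config, params, stoich) {
  nb <- y[["nb"]]; np <- y[["np"]]; c_n <- max(y[["c_n"]], 0)
  conc <- c(acetate = y[["c_acetate"]], butyrate = y[["c_butyrate"]],
            hexanoate = y[["c_hexanoate"]])
  v <- config$v_tc; f <- config$f_in
  monod <- c_n / (params$k_n + c_n)
  mu_b <- params$mu_max * monod * (1 - nb / params$n_bx_max)
  growth_gross <- mu_b * (nb + np)            # mol X / d
  growth_net_n <- growth_gross - params$k_dec * nb  # N uptake basis
  q <- .active_qp(params, stoich, t, conc)
  cn_i <- stoich_lookup(stoich, names(q), "carbon_number")
  e_i <- stoich_lookup(stoich, names(q), "electrons_per_mol")
  prod_rate <- q * (nb + np) / cn_i           # mol_i / d
  e_demand <- sum(prod_rate * e_i) + stoich$gamma_x * growth_gross
  current <- -.FARADAY * e_demand / .SEC_PER_DAY  # A, cathodic negative
  n_xt <- nb + np
  mu_inst <- if (n_xt > 0)
    (growth_gross - params$k_dec * nb) / n_xt else 0
  list(nb = nb, np = np, c_n = c_n, conc = conc, mu_b = mu_b,
       growth_gross = growth_gross, growth_net_n = growth_net_n,
       q = q, prod_rate = prod_rate, current = current,
       mu_inst = mu_inst, q_p_total = sum(q))
}

.reactor_ode <- function(t, y, parms) {
  config <- parms$config; params <- parms$params; stoich <- parms$stoich
  rr <- .reactor_rates(t, y, config, params, stoich)
  v <- config$v_tc; f <- config$f_in
  d <- f / v  # dilution rate, 1/d
  c_in <- feed_n_at(config, t)
  dnb <- (rr$mu_b - params$k_det - params$k_dec) * rr$nb
  dnp <- params$k_det * rr$nb + rr$mu_b * rr$np - d * rr$np
  dc_n <- d * (c_in - rr$c_n) - config$nu_nx * rr$growth_net_n / v
  dconc <- rr$prod_rate / v - d * rr$conc
  list(c(nb = dnb, np = dnp, c_n = dc_n,
         c_acetate = dconc[["acetate"]], c_butyrate = dconc[["butyrate"]],
         c_hexanoate = dconc[["hexanoate"]],
         q_c = abs(rr$current) * .SEC_PER_DAY,
         exp_acetate = f * rr$conc[["acetate"]],
         exp_butyrate = f * rr$conc[["butyrate"]],
         exp_hexanoate = f * rr$conc[["hexanoate"]],
         fed_n = f * c_in,
         exp_n_aq = f * rr$c_n,
         exp_n_px = f * config$nu_nx * rr$np / v))
}

#' Simulate a continuously fed biofilm electrosynthesis reactor
#'
#' Integrates a minimal mechanistic model of the cathode compartment —
#' biofilm and planktonic biomass, dissolved nitrogen, and three carboxylate
#' products in a well-mixed CSTR — and samples the observables a lab would
#' record (filtrate total nitrogen, OD600, product concentrations, current)
#' at regular intervals with seeded multiplicative noise.
#'
#' Model structure:
#' \itemize{
#'   \item biofilm grows at
#'     \eqn{\mu_b = \mu_{max}\frac{c_N}{k_N + c_N}(1 - n_{bX}/n_{bX,max})}
#'     (Monod on nitrogen, logistic space limitation), loses cells to
#'     detachment and decay;
#'   \item planktonic biomass gains detached cells, grows at \eqn{\mu_b},
#'     and washes out at the dilution rate;
#'   \item dissolved nitrogen follows the CSTR balance minus stoichiometric
#'     uptake \eqn{\nu_{N,X}} by net growth (decay lyses nitrogen back into
#'     solution, so elemental nitrogen is conserved exactly);
#'   \item products accumulate at \eqn{q_{p,i} n_{X,T}/C_i} and wash out;
#'   \item the current is exactly the stoichiometric electron demand of
#'     product formation plus biomass synthesis (no parasitic sink), so
#'     Faradaic-efficiency closure at 100\% is a model invariant.
#' }
#' The OD600 observable is generated by inverting the calibration line on
#' the true planktonic nitrogen concentration.
#'
#' @param config a [reactor_config()].
#' @param params a [sim_params()].
#' @return an object of class `reactor_simulation`: a list with `truth`
#'   (dense tibble of true states, instantaneous \eqn{\mu}, \eqn{q_p},
#'   current, and cumulative feed/export/charge integrals), `samples`
#'   (a [sample_series()] of noisy observations), and the inputs.
#' @export
simulate_reactor <- function(config, params = sim_params()) {
  stoich <- stoichiometry_table(nu_nx = config$nu_nx, mw_x = config$mw_x)
  n_x0 <- inoculum_biomass(config)
  y0 <- c(nb = params$biofilm_inoculum_fraction * n_x0,
          np = (1 - params$biofilm_inoculum_fraction) * n_x0,
          c_n = config$n_n0 / config$v_tc,
          c_acetate = 0, c_butyrate = 0, c_hexanoate = 0,
          q_c = 0, exp_acetate = 0, exp_butyrate = 0, exp_hexanoate = 0,
          fed_n = 0, exp_n_aq = 0, exp_n_px = 0)
  sample_t <- seq(0, params$horizon, by = params$sample_interval)
  times <- sort(unique(round(
    c(seq(0, params$horizon, by = params$dt_solver), sample_t), 10)))
  sol <- deSolve::ode(y = y0, times = times, func = .reactor_ode,
                      parms = list(config = config, params = params,
                                   stoich = stoich),
                      method = "lsoda", rtol = 1e-8, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop_compute("ODE solver failed; istate = ", attr(sol, "istate")[1])
  sol <- as.data.frame(sol)

  inst <- lapply(seq_len(nrow(sol)), function(k) {
    y <- unlist(sol[k, -1])
    rr <- .reactor_rates(sol$time[k], y, config, params, stoich)
    c(mu_inst = rr$mu_inst, q_p_total = rr$q_p_total, current = rr$current)
  })
  inst <- do.call(rbind, inst)

  truth <- tibble(
    t = sol$time, n_bx = sol$nb, n_px = sol$np,
    n_x_total = sol$nb + sol$np,
    c_n = sol$c_n, c_acetate = sol$c_acetate, c_butyrate = sol$c_butyrate,
    c_hexanoate = sol$c_hexanoate,
    mu_inst = inst[, "mu_inst"], q_p_total = inst[, "q_p_total"],
    current = inst[, "current"],
    cum_charge_c = sol$q_c, cum_fed_n = sol$fed_n,
    cum_exp_n_aq = sol$exp_n_aq, cum_exp_n_px = sol$exp_n_px,
    cum_exp_acetate = sol$exp_acetate, cum_exp_butyrate = sol$exp_butyrate,
    cum_exp_hexanoate = sol$exp_hexanoate)

  obs <- truth[match(round(sample_t, 10), round(truth$t, 10)), ]
  cal <- params$calibration
  c_n_px_true <- config$nu_nx * obs$n_px / config$v_tc
  od_true <- pmax(0, (c_n_px_true - cal$intercept) / cal$slope)

  noisy <- function(x, sd_rel) {
    if (sd_rel <= 0) return(x)
    pmax(0, x * (1 + rnorm(length(x), 0, sd_rel)))
  }
  if (params$noise > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(params$seed)
  }
  samples <- sample_series(
    t = obs$t,
    c_n_aq_out = noisy(obs$c_n, params$noise),
    od600 = noisy(od_true, params$noise),
    acetate = noisy(obs$c_acetate, params$noise),
    butyrate = noisy(obs$c_butyrate, params$noise),
    hexanoate = noisy(obs$c_hexanoate, params$noise),
    current = -noisy(abs(obs$current), params$noise))

  structure(list(truth = truth, samples = samples,
                 config = config, params = params),
            class = "reactor_simulation")
}

#' @export
print.reactor_simulation <- function(x, ...) {
  cat(sprintf(
    "<reactor_simulation> %g d horizon, %d samples, %d truth points\n",
    x$params$horizon, nrow(x$samples), nrow(x$truth)))
  cat(sprintf("  final biomass %.4g mol (%.1f%% biofilm)\n",
              x$truth$n_x_total[nrow(x$truth)],
              100 * x$truth$n_bx[nrow(x$truth)] /
                x$truth$n_x_total[nrow(x$truth)]))
  invisible(x)
}

#' Nitrogen closure residual of a simulation
#'
#' Elemental nitrogen entering with the feed must equal nitrogen exported
#' (dissolved + planktonic) plus the change in the dissolved inventory plus
#' the change in biomass-bound nitrogen. Returns the per-time-point residual
#' relative to cumulative feed (0 at t = 0 is reported as 0).
#'
#' @param sim a `reactor_simulation`.
#' @return numeric vector of relative residuals, one per truth row.
#' @export
nitrogen_closure_residual <- function(sim) {
  tr <- sim$truth
  v <- sim$config$v_tc
  nu <- sim$config$nu_nx
  d_inv <- v * (tr$c_n - tr$c_n[1])
  d_bio <- nu * (tr$n_x_total - tr$n_x_total[1])
  resid <- tr$cum_fed_n - tr$cum_exp_n_aq - tr$cum_exp_n_px - d_inv - d_bio
  ifelse(tr$cum_fed_n > 0, resid / tr$cum_fed_n, 0)
}
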