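#' Integrate cathodic charge over a time window
#'
#' Trapezoidal integration of the absolute current over `[t0, t1]`,
#' converted to coulombs. Cathodic currents are logged as negative; the
#' magnitude is integrated so the charge supplied to the cathodic reaction
#' is positive. Window bounds falling between logged points are handled by
#' linear interpolation, so the integral is exact for piecewise-linear
#' current.
#'
#' @param t times of the current log, days.
#' @param i current, A (cathodic negative).
#' @param t0,t1 window bounds, days; default the full record.
#' @return charge, C.
#' @examples
#' integrate_charge(c(0, 1), c(-0.055, -0.055))  # 4752 C
#' @export
integrate_charge <- function(t, i, t0 = min(t), t1 = max(t)) {
  if (t1 <= t0) stop_input("window must have t1 > t0")
  keep <- t >= t0 & t <= t1
  tt <- t[keep]; ii <- abs(i[keep])
  if (!(t0 %in% tt) && t0 > min(t))
    { tt <- c(t0, tt); ii <- c(approx(t, abs(i), t0)$y, ii) }
  if (!(t1 %in% tt) && t1 < max(t))
    { tt <- c(tt, t1); ii <- c(ii, approx(t, abs(i), t1)$y) }
  if (length(tt) < 2L) stop_input("fewer than 2 current points in window")
  pracma::trapz(tt, ii) * .SEC_PER_DAY
}

#' Faradaic efficiency (electron recovery)
#'
#' Fraction of the electric charge supplied to the cathode that is recovered
#' in the products of interest — organics and biomass:
#' \deqn{FE\% = 100\,\frac{F_{const}\left(\sum_i n_i e_i
#'   + n_X \gamma_X\right)}{Q_T}}
#' with \eqn{e_i} the electron demand per mole of product \eqn{i},
#' \eqn{\gamma_X} the biomass degree of reduction per C-mol, and
#' \eqn{F_{const}} = 96485 C mol\eqn{^{-1}}.
#'
#' @param produced named vector of net product amounts formed over the
#'   window, mol (export plus inventory change); names must match the
#'   stoichiometry table.
#' @param biomass_produced net biomass formed, C-mol (default 0).
#' @param q_t total charge supplied over the same window, C, > 0.
#' @param stoich a [stoichiometry_table()].
#' @return Faradaic efficiency, percent.
#' @examples
#' faradaic_efficiency(c(acetate = 0.001), q_t = 1543.76)  # 50%
#' @export
faradaic_efficiency <- function(produced, biomass_produced = 0, q_t,
                                stoich = stoichiometry_table()) {
  if (q_t <= 0) stop_input("q_t must be > 0")
  q_prod <- 0
  if (length(produced) > 0) {
    e <- stoich_lookup(stoich, names(produced), "electrons_per_mol")
    q_prod <- sum(produced * e)
  }
  q_prod <- q_prod + biomass_produced * stoich$gamma_x
  100 * .FARADAY * q_prod / q_t
}

#' Net production over a window from a sample series
#'
#' Net amount of each product (and of biomass) formed between two sampling
#' times: export with the outflow, \eqn{F \int c\,dt} (trapezoidal), plus
#' the inventory change \eqn{V_{TC}\,\Delta c}. Both terms follow from the
#' component mass balance with zero feed concentration.
#'
#' @param config a [reactor_config()].
#' @param series a [sample_series()].
#' @param biomass optionally, the matching `biomass_trajectory`; if given,
#'   net biomass production (accumulation + planktonic export) is included.
#' @param t0,t1 window bounds, days; default the full series.
#' @return a list with `produced` (named vector, mol per product) and
#'   `biomass_produced` (C-mol, 0 when `biomass` is `NULL`).
#' @export
net_production <- function(config, series, biomass = NULL,
                           t0 = min(series$t), t1 = max(series$t)) {
  keep <- series$t >= t0 & series$t <= t1
  if (sum(keep) < 2L) stop_input("fewer than 2 samples in window")
  tt <- series$t[keep]
  produced <- vapply(.PRODUCTS, function(p) {
    cc <- series[[p]][keep]
    config$f_out * pracma::trapz(tt, cc) + config$v_tc * (cc[length(cc)] - cc[1])
  }, numeric(1))
  biomass_produced <- 0
  if (!is.null(biomass)) {
    keep_b <- biomass$t >= t0 & biomass$t <= t1
    nb <- biomass$n_x_total[keep_b]
    cpx <- biomass$c_px[keep_b]
    tb <- biomass$t[keep_b]
    biomass_produced <- (nb[length(nb)] - nb[1]) +
      config$f_out * pracma::trapz(tb, cpx)
  }
  list(produced = produced, biomass_produced = biomass_produced)
}

#' Normalize a catholyte-volume production rate to electrode dimensions
#'
#' Reactor performance is conventionally reported per catholyte volume, per
#' electrode volume and per projected surface area (PSA). All three carry
#' the same extensive production (g d\eqn{^{-1}}); only the denominator
#' changes:
#' \itemize{
#'   \item electrode volume: `rate * v_tc / (electrode_volume in L)`,
#'     g L\eqn{_{cathode}^{-1}} d\eqn{^{-1}}
#'   \item PSA: `rate * v_tc / (electrode_psa in m^2)`,
#'     g m\eqn{^{-2}} d\eqn{^{-1}}
#' }
#'
#' @param config a [reactor_config()].
#' @param rate_catholyte production rate per catholyte volume,
#'   g L\eqn{^{-1}} d\eqn{^{-1}} (vectorized).
#' @return a tibble with `rate_catholyte`, `rate_electrode_volume`,
#'   `rate_psa`.
#' @examples
#' normalize_rates(reactor_config(), 0.74)
#' @export
normalize_rates <- function(config, rate_catholyte) {
  ev_l <- config$electrode_volume / 1000   # cm^3 -> L
  psa_m2 <- config$electrode_psa / 1e4     # cm^2 -> m^2
  if (ev_l <= 0 || psa_m2 <= 0) stop_input("electrode geometry must be > 0")
  tibble(rate_catholyte = rate_catholyte,
         rate_electrode_volume = rate_catholyte * config$v_tc / ev_l,
         rate_psa = rate_catholyte * config$v_tc / psa_m2)
}

#' Convert a PSA current density to a cathode-volume current density
#'
#' @param config a [reactor_config()].
#' @param current_density_psa current density per projected surface area,
#'   A m\eqn{^{-2}} (vectorized; sign preserved).
#' @return current density per cathode volume, kA m\eqn{^{-3}}.
#' @examples
#' normalize_current(reactor_config(), -75.17)  # -7.517 kA/m^3
#' @export
normalize_current <- function(config, current_density_psa) {
  th_m <- config$electrode_thickness / 100  # cm -> m
  if (th_m <= 0) stop_input("electrode thickness must be > 0")
  current_density_psa / th_m / 1000
}

#' Biofilm space occupancy of the electrode
#'
#' Compares the biomass concentration inside the electrode with the
#' theoretical maximum packing, obtained from the wet cell density and the
#' cell dry-weight fraction:
#' \deqn{c_{max} = \frac{\rho_{cell}\, f_{dry}}{MW_X}}
#' (about 13 mmol cm\eqn{^{-3}} with the defaults). The occupancy is the
#' percentage of the physical electrode space filled by biomass.
#'
#' @param config a [reactor_config()] (supplies `mw_x`).
#' @param biomass_conc_electrode biomass per electrode volume,
#'   mmol cm\eqn{^{-3}}.
#' @param cell_density wet cell density, g cm\eqn{^{-3}}.
#' @param dry_fraction cell dry-weight fraction, dimensionless.
#' @return a list with `theoretical_mmol_cm3` and `occupancy_percent`.
#' @examples
#' space_occupancy(reactor_config(), 8.1)
#' @export
space_occupancy <- function(config, biomass_conc_electrode,
                            cell_density = 1.09, dry_fraction = 0.30) {
  if (cell_density <= 0 || dry_fraction <= 0 ||
      any(biomass_conc_electrode <= 0))
    stop_input("all occupancy inputs must be > 0")
  theo <- cell_density * dry_fraction / config$mw_x * 1000  # mmol cm^-3
  list(theoretical_mmol_cm3 = theo,
       occupancy_percent = 100 * biomass_conc_electrode / theo)
}

#' Key-performance-indicator report over a pseudo-steady-state window
#'
#' Summarizes a run window in the conventional reactor-engineering currency:
#' mean titers, production rates normalized to catholyte volume, electrode
#' volume and PSA, current densities per PSA and per cathode volume,
#' Faradaic efficiency, and (when a biomass trajectory is supplied) the
#' biofilm space occupancy at the end of the window.
#'
#' Rates are computed per product from the mean of the per-interval
#' volumetric rates inside the window (mass balance with accumulation
#' term), converted to g L\eqn{^{-1}} d\eqn{^{-1}} with the product molar
#' masses.
#'
#' @param config a [reactor_config()].
#' @param series a [sample_series()] covering the window.
#' @param biomass optional `biomass_trajectory` for FE biomass credit and
#'   occupancy.
#' @param t0,t1 window bounds, days; default the full series.
#' @param stoich a [stoichiometry_table()].
#' @return a list with `per_product` (tibble: titer, three rate
#'   normalizations per product), `current_density_psa`,
#'   `current_density_volume`, `fe_percent`, `occupancy_percent`
#'   (`NA` without biomass).
#' @export
kpi_report <- function(config, series, biomass = NULL,
                       t0 = min(series$t), t1 = max(series$t),
                       stoich = stoichiometry_table()) {
  keep <- series$t >= t0 & series$t <= t1
  if (sum(keep) < 2L) stop_input("fewer than 2 samples in window")
  sub <- series[keep, , drop = FALSE]
  class(sub) <- class(series)
  mm <- stoich_lookup(stoich, .PRODUCTS, "molar_mass")
  rv <- volumetric_rates(config, sub)
  titer_g <- vapply(seq_along(.PRODUCTS), function(k)
    mean(sub[[.PRODUCTS[k]]]) * mm[k], numeric(1))
  rate_g <- vapply(seq_along(.PRODUCTS), function(k)
    mean(rv[[paste0("r_", .PRODUCTS[k])]]) * mm[k], numeric(1))
  norm <- normalize_rates(config, rate_g)
  per_product <- tibble(product = .PRODUCTS, titer_g_per_l = titer_g,
                        rate_catholyte = norm$rate_catholyte,
                        rate_electrode_volume = norm$rate_electrode_volume,
                        rate_psa = norm$rate_psa)

  cd_psa <- NA_real_; cd_vol <- NA_real_; fe <- NA_real_
  if (!all(is.na(sub$current))) {
    mean_i <- mean(sub$current, na.rm = TRUE)
    cd_psa <- mean_i / (config$electrode_psa / 1e4)
    cd_vol <- normalize_current(config, cd_psa)
    q_t <- integrate_charge(sub$t, sub$current)
    if (q_t > 0) {
      np <- net_production(config, series, biomass, t0, t1)
      fe <- faradaic_efficiency(np$produced, np$biomass_produced, q_t, stoich)
    }
  }
  occ <- NA_real_
  if (!is.null(biomass)) {
    nb_end <- biomass$n_bx[max(which(biomass$t <= t1))]
    conc_mmol_cm3 <- nb_end * 1000 / config$electrode_volume
    if (conc_mmol_cm3 > 0)
      occ <- space_occupancy(config, conc_mmol_cm3)$occupancy_percent
  }
  list(per_product = per_product,
       current_density_psa = cd_psa, current_density_volume = cd_vol,
       fe_percent = fe, occupancy_percent = occ)
}
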