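#' Reactor configuration
#'
#' Fixed operating parameters of a continuously fed biofilm electrochemical
#' reactor: liquid volume, flow, feed nitrogen, biomass stoichiometry and
#' electrode geometry. Defaults describe a bench-scale microbial
#' electrosynthesis cell: 0.12 L catholyte fed at 0.625 mL h\eqn{^{-1}}
#' (HRT 8 d), a 7.35 cm\eqn{^3} carbon-felt cathode of 7.35 cm\eqn{^2}
#' projected surface area and 1 cm thickness, and a feed carrying
#' 0.00748 mol L\eqn{^{-1}} dissolved nitrogen (0.4 g L\eqn{^{-1}}
#' NH\eqn{_4}Cl).
#'
#' The feed nitrogen concentration `c_n_in` may be a single number or a
#' data frame with columns `t_start` (days) and `c_n_in` (mol L\eqn{^{-1}})
#' describing a piecewise-constant feed schedule, e.g. a mid-run doubling of
#' the medium strength. [feed_n_at()] evaluates the schedule.
#'
#' @param v_tc total catholyte volume, L.
#' @param f_in feed flow rate, L d\eqn{^{-1}}.
#' @param f_out outflow rate, L d\eqn{^{-1}}; equal to `f_in` unless
#'   overridden (liquid level control keeps the inventory constant and the
#'   titrant flow is negligible).
#' @param c_n_in feed total dissolved nitrogen, mol L\eqn{^{-1}}, scalar or
#'   step schedule (see Details).
#' @param nu_nx stoichiometric nitrogen content of dry biomass,
#'   mol-N per C-mol biomass (0.2 for CH\eqn{_{1.8}}O\eqn{_{0.5}}N\eqn{_{0.2}}).
#' @param mw_x biomass molar mass on a C-mol basis, g mol\eqn{^{-1}}.
#' @param electrode_volume cathode volume, cm\eqn{^3}.
#' @param electrode_psa projected surface area of the cathode, cm\eqn{^2}.
#' @param electrode_thickness cathode thickness, cm.
#' @param inoculum_g_per_l inoculation biomass concentration, g L\eqn{^{-1}}
#'   dry weight; sets the default initial biomass amount
#'   `inoculum_g_per_l * v_tc / mw_x` (mol).
#' @param n_n0 initial dissolved nitrogen amount in the compartment, mol;
#'   defaults to feed-strength catholyte, `feed_n_at(config, 0) * v_tc`.
#'
#' @return an object of class `reactor_config` (a named list).
#' @examples
#' cfg <- reactor_config()
#' hrt(cfg)  # 8 days
#' @export
reactor_config <- function(v_tc = 0.12,
                           f_in = 0.625e-3 * 24,
                           f_out = f_in,
                           c_n_in = 0.00748,
                           nu_nx = 0.2,
                           mw_x = 25.25,
                           electrode_volume = 7.35,
                           electrode_psa = 7.35,
                           electrode_thickness = 1,
                           inoculum_g_per_l = 0.46,
                           n_n0 = NULL) {
  if (v_tc <= 0) stop_input("v_tc must be > 0")
  if (f_in <= 0) stop_input("f_in must be > 0")
  if (f_out <= 0) stop_input("f_out must be > 0")
  if (nu_nx <= 0) stop_input("nu_nx must be > 0")
  if (mw_x <= 0) stop_input("mw_x must be > 0")
  if (electrode_volume <= 0 || electrode_psa <= 0 || electrode_thickness <= 0)
    stop_input("electrode dimensions must be > 0")
  geom <- electrode_psa * electrode_thickness
  if (abs(geom - electrode_volume) > 0.01 * electrode_volume)
    stop_input("electrode_volume (", electrode_volume,
               " cm^3) is not within 1% of psa x thickness (", geom, " cm^3)")
  if (is.data.frame(c_n_in)) {
    if (!all(c("t_start", "c_n_in") %in% names(c_n_in)))
      stop_input("feed schedule needs columns t_start, c_n_in")
    if (is.unsorted(c_n_in$t_start, strictly = TRUE))
      stop_input("feed schedule t_start must be strictly increasing")
    if (any(c_n_in$c_n_in < 0)) stop_input("feed nitrogen must be >= 0")
  } else {
    if (length(c_n_in) != 1L || c_n_in < 0)
      stop_input("c_n_in must be a single non-negative number or a schedule")
  }
  cfg <- structure(
    list(v_tc = v_tc, f_in = f_in, f_out = f_out, c_n_in = c_n_in,
         nu_nx = nu_nx, mw_x = mw_x,
         electrode_volume = electrode_volume, electrode_psa = electrode_psa,
         electrode_thickness = electrode_thickness,
         inoculum_g_per_l = inoculum_g_per_l, n_n0 = n_n0),
    class = "reactor_config")
  if (is.null(cfg$n_n0)) cfg$n_n0 <- feed_n_at(cfg, 0) * v_tc
  cfg
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("<reactor_config>\n")
  cat(sprintf("  catholyte %g L, flow %g L/d (HRT %.3g d)\n",
              x$v_tc, x$f_in, hrt(x)))
  cat(sprintf("  electrode %g cm^3 (%g cm^2 PSA x %g cm)\n",
              x$electrode_volume, x$electrode_psa, x$electrode_thickness))
  if (is.data.frame(x$c_n_in)) {
    cat(sprintf("  feed N: %d-step schedule starting at %g mol/L\n",
                nrow(x$c_n_in), x$c_n_in$c_n_in[1]))
  } else {
    cat(sprintf("  feed N: %g mol/L\n", x$c_n_in))
  }
  cat(sprintf("  biomass: nu_N,X %g mol/mol, MW %g g/mol, inoculum %g g/L\n",
              x$nu_nx, x$mw_x, x$inoculum_g_per_l))
  invisible(x)
}

#' Feed nitrogen concentration at a given time
#'
#' Evaluates the (possibly piecewise-constant) feed nitrogen schedule of a
#' [reactor_config()]. Times before the first schedule step take the first
#' step's value.
#'
#' @param config a [reactor_config()].
#' @param t time, days (vectorized).
#' @return feed total dissolved nitrogen at `t`, mol L\eqn{^{-1}}.
#' @export
feed_n_at <- function(config, t) {
  sched <- config$c_n_in
  if (!is.data.frame(sched)) return(rep_len(sched, length(t)))
  idx <- findInterval(t, sched$t_start)
  idx[idx < 1L] <- 1L
  sched$c_n_in[idx]
}

#' Hydraulic retention time
#'
#' @param config a [reactor_config()].
#' @return catholyte volume / feed flow, days.
#' @export
hrt <- function(config) config$v_tc / config$f_in

#' Default initial biomass amount from the inoculation concentration
#'
#' @param config a [reactor_config()].
#' @return inoculum biomass amount, mol (C-mol basis).
#' @export
inoculum_biomass <- function(config) {
  config$inoculum_g_per_l * config$v_tc / config$mw_x
}

#' Product and biomass stoichiometry
#'
#' Carbon numbers, electron demands and molar masses of the carboxylate
#' products, plus the biomass degree of reduction. Electron demands are the
#' moles of electrons required per mole of product formed from CO2
#' (6n - 4 for the C\eqn{_n} straight-chain monocarboxylates: 8 for acetate,
#' 20 for butyrate, 32 for hexanoate). The biomass degree of reduction
#' `gamma_x` defaults to 4.2 electrons per C-mol, the standard value for
#' CH\eqn{_{1.8}}O\eqn{_{0.5}}N\eqn{_{0.2}} biomass grown on ammonium.
#'
#' @param gamma_x biomass degree of reduction, mol e\eqn{^-} per C-mol.
#' @param nu_nx biomass nitrogen content, mol-N per C-mol.
#' @param mw_x biomass molar mass, g per C-mol.
#' @return an object of class `stoichiometry_table`: a list with a
#'   `products` tibble (`product`, `carbon_number`, `electrons_per_mol`,
#'   `molar_mass`) and the biomass constants.
#' @export
stoichiometry_table <- function(gamma_x = 4.2, nu_nx = 0.2, mw_x = 25.25) {
  if (gamma_x <= 0 || nu_nx <= 0 || mw_x <= 0)
    stop_input("stoichiometric constants must be > 0")
  structure(
    list(
      products = tibble(
        product = c("acetate", "butyrate", "hexanoate"),
        carbon_number = c(2, 4, 6),
        electrons_per_mol = c(8, 20, 32),
        molar_mass = c(60.05, 88.11, 116.16)),
      gamma_x = gamma_x, nu_nx = nu_nx, mw_x = mw_x),
    class = "stoichiometry_table")
}

# look up one stoichiometry column for a vector of product names
stoich_lookup <- function(stoich, products, what) {
  i <- match(products, stoich$products$product)
  if (anyNA(i))
    stop_input("unknown product(s): ",
               paste(products[is.na(i)], collapse = ", "))
  stoich$products[[what]][i]
}
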