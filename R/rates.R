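#' Volumetric production rate over one sampling interval
#'
#' The well-mixed component mass balance
#' \eqn{dn_i/dt = F c_{i,in} - F c_{i,out} + r_i V_{TC}} rearranged for the
#' volume-specific production rate with \eqn{n_i = c_i V_{TC}} and the
#' outflow at the current catholyte concentration:
#' \deqn{r_i = \frac{(c_{next} - c_{prev})\,V_{TC}/\Delta t
#'        + F c_{next} - F c_{in}}{V_{TC}}}
#' At steady state this reduces to the dilution identity
#' \eqn{r_i = F c / V_{TC}}; in a batch (F = 0) it reduces to
#' \eqn{\Delta c / \Delta t}.
#'
#' @param config a [reactor_config()].
#' @param c_prev,c_next concentrations at the interval bounds,
#'   mol L\eqn{^{-1}}.
#' @param c_in feed concentration of the compound, mol L\eqn{^{-1}} (0 for
#'   products).
#' @param dt interval length, days, > 0.
#' @return volumetric rate, mol L\eqn{^{-1}} d\eqn{^{-1}} (vectorized).
#' @export
volumetric_rate <- function(config, c_prev, c_next, c_in = 0, dt) {
  if (any(dt <= 0)) stop_input("dt must be > 0")
  ((c_next - c_prev) * config$v_tc / dt +
     config$f_out * c_next - config$f_in * c_in) / config$v_tc
}

#' Volumetric rates for all products over a sample series
#'
#' Applies [volumetric_rate()] to each sampling interval of the series, for
#' each product column, with zero feed concentration.
#'
#' @param config a [reactor_config()].
#' @param series a [sample_series()] (\eqn{\ge} 2 samples).
#' @return a tibble with `t_mid` (interval midpoints, days) and one
#'   `r_<product>` column per product, mol L\eqn{^{-1}} d\eqn{^{-1}}.
#' @export
volumetric_rates <- function(config, series) {
  if (!inherits(series, "sample_series")) series <- as_sample_series(series)
  n <- nrow(series)
  if (n < 2L) stop_input("need at least 2 samples to form an interval")
  dt <- diff(series$t)
  out <- tibble(t_mid = (series$t[-1] + series$t[-n]) / 2)
  for (p in .PRODUCTS) {
    out[[paste0("r_", p)]] <-
      volumetric_rate(config, series[[p]][-n], series[[p]][-1],
                      c_in = 0, dt = dt)
  }
  out
}

# linear interpolation of total biomass onto interval midpoints
interp_biomass <- function(biomass, t_mid) {
  approx(biomass$t, biomass$n_x_total, xout = t_mid, rule = 2)$y
}

#' Biomass-specific production rates (q-values)
#'
#' Converts volumetric rates into biomass-specific rates on a carbon-mole
#' basis: \eqn{q_i = r_i V_{TC} C_i / n_{X,T}} with \eqn{C_i} the carbon
#' number of the product (acetate 2, butyrate 4, hexanoate 6). The total
#' \eqn{q_p} sums the three products jointly, so reactors with different
#' product spectra are comparable on the same electron/carbon currency.
#' Total biomass is interpolated linearly onto the interval midpoints.
#'
#' @param config a [reactor_config()].
#' @param rates a tibble from [volumetric_rates()].
#' @param biomass a `biomass_trajectory` from [accumulate_biomass()].
#' @param stoich a [stoichiometry_table()].
#' @return a tibble with `t_mid`, `n_x_mid`, the `r_*` columns, one
#'   `q_<product>` column per product (mol-C mol-X\eqn{^{-1}}
#'   d\eqn{^{-1}}), `q_p_total`, and `flag` (`"zero_biomass"` rows have
#'   `NA` q-values).
#' @export
specific_rates <- function(config, rates, biomass,
                           stoich = stoichiometry_table()) {
  n_x <- interp_biomass(biomass, rates$t_mid)
  bad <- n_x <= 0
  out <- tibble(t_mid = rates$t_mid, n_x_mid = n_x)
  q_total <- numeric(nrow(rates))
  for (p in .PRODUCTS) {
    ci <- stoich_lookup(stoich, p, "carbon_number")
    r <- rates[[paste0("r_", p)]]
    q <- ifelse(bad, NA_real_, r * config$v_tc * ci / n_x)
    out[[paste0("r_", p)]] <- r
    out[[paste0("q_", p)]] <- q
    q_total <- q_total + q
  }
  out$q_p_total <- q_total
  out$flag <- ifelse(bad, "zero_biomass", "")
  out
}

#' Biomass-specific growth rate
#'
#' The specific growth rate over each sampling interval, treating biomass as
#' a compound in the component mass balance with zero feed concentration:
#' \deqn{\mu = \frac{\Delta n_{X,T}/\Delta t + F c_{pX}}{n_{X,T}^{mid}}}
#' The washout term \eqn{F c_{pX}} (planktonic cells leaving with the
#' outflow, evaluated at the interval end) credits growth that is exported
#' rather than accumulated; setting `include_washout = FALSE` yields the
#' pure accumulation estimate \eqn{\Delta n_{X,T}/(\Delta t\, n^{mid})}.
#' Midpoint biomass is the mean of the two bounding samples, which makes the
#' estimator second-order accurate on smooth trajectories. A centered moving
#' average of odd width can be applied (`smooth_window`); the default of 1
#' applies none.
#'
#' Negative values are meaningful: they indicate net biomass loss by decay
#' or biofilm detachment exceeding growth.
#'
#' @param config a [reactor_config()].
#' @param biomass a `biomass_trajectory` from [accumulate_biomass()]
#'   (\eqn{\ge} 2 samples).
#' @param include_washout include the planktonic washout term (default
#'   `TRUE`).
#' @param smooth_window odd integer width of a centered moving average on
#'   the \eqn{\mu} series; 1 = no smoothing.
#' @return a tibble with `t_mid`, `mu` (d\eqn{^{-1}}) and `flag`
#'   (`"zero_biomass"` rows have `NA` mu).
#' @export
specific_growth_rate <- function(config, biomass, include_washout = TRUE,
                                 smooth_window = 1L) {
  n <- nrow(biomass)
  if (n < 2L) stop_input("need at least 2 biomass samples")
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop_input("smooth_window must be a positive odd integer")
  dt <- diff(biomass$t)
  dn <- diff(biomass$n_x_total)
  n_mid <- (biomass$n_x_total[-1] + biomass$n_x_total[-n]) / 2
  rx_v <- dn / dt
  if (include_washout) rx_v <- rx_v + config$f_out * biomass$c_px[-1]
  bad <- n_mid <= 0
  mu <- ifelse(bad, NA_real_, rx_v / n_mid)
  if (smooth_window > 1L) {
    k <- smooth_window %/% 2L
    sm <- mu
    for (i in seq_along(mu)) {
      w <- max(1L, i - k):min(length(mu), i + k)
      sm[i] <- mean(mu[w], na.rm = TRUE)
    }
    mu <- sm
  }
  tibble(t_mid = (biomass$t[-1] + biomass$t[-n]) / 2, mu = mu,
         flag = ifelse(bad, "zero_biomass", ""))
}

#' Assemble the full per-interval rate series
#'
#' Convenience wrapper chaining [volumetric_rates()], [specific_rates()] and
#' [specific_growth_rate()] onto one shared time grid.
#'
#' @inheritParams specific_rates
#' @inheritParams specific_growth_rate
#' @param series the [sample_series()] the biomass trajectory was computed
#'   from.
#' @return the [specific_rates()] tibble with an extra `mu` column.
#' @export
rate_series <- function(config, series, biomass,
                        stoich = stoichiometry_table(),
                        include_washout = TRUE, smooth_window = 1L) {
  r <- volumetric_rates(config, series)
  q <- specific_rates(config, r, biomass, stoich)
  m <- specific_growth_rate(config, biomass, include_washout, smooth_window)
  if (!isTRUE(all.equal(q$t_mid, m$t_mid)))
    stop_compute("rate and growth series are on different time grids")
  q$mu <- m$mu
  q$flag <- ifelse(q$flag == "", m$flag, q$flag)
  q
}
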