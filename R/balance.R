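#' Construct a sample series of raw reactor measurements
#'
#' An ordered table of the routine measurements taken from the catholyte:
#' sampling time, total dissolved nitrogen in the 0.2 um filtrate, optical
#' density of the unfiltered sample, product concentrations and the cathodic
#' current logged at the sampling moment. Internally all concentrations are
#' mol L\eqn{^{-1}}; [read_measurements()] handles unit conversion at the
#' file boundary.
#'
#' @param t sampling times, days from inoculation, strictly increasing,
#'   first value \eqn{\ge} 0.
#' @param c_n_aq_out dissolved total nitrogen in the filtrate,
#'   mol L\eqn{^{-1}}.
#' @param od600 optical density of the unfiltered catholyte.
#' @param acetate,butyrate,hexanoate product concentrations,
#'   mol L\eqn{^{-1}} (default 0).
#' @param current cathodic current, A, stored negative for a cathode
#'   (default `NA`).
#' @return a tibble of class `sample_series`.
#' @export
sample_series <- function(t, c_n_aq_out, od600,
                          acetate = 0, butyrate = 0, hexanoate = 0,
                          current = NA_real_) {
  n <- length(t)
  if (n == 0L) stop_input("sample series is empty")
  if (anyNA(t) || t[1] < 0 || (n > 1 && any(diff(t) <= 0)))
    stop_input("sample times must be strictly increasing and start at >= 0")
  s <- tibble(t = as.numeric(t),
              c_n_aq_out = rep_len(as.numeric(c_n_aq_out), n),
              od600 = rep_len(as.numeric(od600), n),
              acetate = rep_len(as.numeric(acetate), n),
              butyrate = rep_len(as.numeric(butyrate), n),
              hexanoate = rep_len(as.numeric(hexanoate), n),
              current = rep_len(as.numeric(current), n))
  neg <- c("c_n_aq_out", "od600", "acetate", "butyrate", "hexanoate")
  for (col in neg)
    if (any(s[[col]] < 0, na.rm = TRUE))
      stop_input(col, " must be non-negative")
  class(s) <- c("sample_series", class(s))
  s
}

# product columns of a sample series
.PRODUCTS <- c("acetate", "butyrate", "hexanoate")

#' Nitrogen retained over one sampling interval
#'
#' The elemental-nitrogen balance of the cathode compartment has no reaction
#' term: nitrogen can only flow in with the feed or out with the filtrate
#' (dissolved) and with planktonic cells. Integrated over a short sampling
#' interval with end-of-interval concentrations, the nitrogen retained in
#' the compartment is
#' \deqn{\Delta n_N = F\,(c_{N,in} - c_{N-aq,out} - c_{N-pX,out})\,\Delta t}
#' A positive value is net retention (uptake into biomass); a negative value
#' means more nitrogen leaves than enters, e.g. during cell lysis late in a
#' run.
#'
#' @param config a [reactor_config()].
#' @param c_n_aq_out dissolved nitrogen in the outflow, mol L\eqn{^{-1}}.
#' @param c_n_px_out nitrogen in planktonic cells in the outflow,
#'   mol L\eqn{^{-1}}.
#' @param dt interval length, days, > 0.
#' @param t time at which the feed schedule is evaluated (interval end),
#'   days.
#' @return nitrogen retained over the interval, mol.
#' @examples
#' cfg <- reactor_config()
#' nitrogen_increment(cfg, c_n_aq_out = 0.005, c_n_px_out = 0.001,
#'                    dt = 3.5, t = 10)
#' @export
nitrogen_increment <- function(config, c_n_aq_out, c_n_px_out, dt, t = 0) {
  if (any(dt <= 0)) stop_input("dt must be > 0")
  if (any(c_n_aq_out < 0) || any(c_n_px_out < 0))
    stop_input("concentrations must be >= 0")
  config$f_in * (feed_n_at(config, t) - c_n_aq_out - c_n_px_out) * dt
}

#' Convert retained nitrogen into a biomass trajectory
#'
#' Runs the full nitrogen-balance bookkeeping over a sample series:
#' the calibration converts OD600 into nitrogen held in planktonic cells;
#' the per-interval retained nitrogen ([nitrogen_increment()]) is summed to
#' a cumulative amount; dividing by the biomass nitrogen content
#' \eqn{\nu_{N,X}} converts nitrogen into biomass. Total biomass is
#' \deqn{n_{X,T}(t_k) = n_{X,0} + \frac{1}{\nu_{N,X}} \sum_{j \le k} \Delta n_{N,j}}
#' planktonic biomass is \eqn{n_{pX} = c_{pX} V_{TC}} with
#' \eqn{c_{pX} = c_{N\mathrm{-}pX}/\nu_{N,X}}, and biofilm biomass is the
#' difference \eqn{n_{bX} = n_{X,T} - n_{pX}}.
#'
#' Sign convention: retained nitrogen is positive, so biomass grows when the
#' compartment retains nitrogen. The first sample is the baseline; its
#' cumulative retention is zero.
#'
#' Under measurement noise \eqn{n_{bX}} can transiently go negative; such
#' points are reported as-is with `flag = "negative_biofilm"` (never
#' silently clipped) and their `biofilm_fraction` is `NA`.
#'
#' @param config a [reactor_config()].
#' @param series a [sample_series()].
#' @param calib a [calibration_model()] or [calibration_set()].
#' @param n_x0 initial biomass amount, mol; defaults to
#'   [inoculum_biomass()].
#' @param integration `"rect"` (default) takes each interval's
#'   concentrations from the end-of-interval sample; `"trapz"` averages the
#'   two bounding samples.
#' @param holdup_correction if `TRUE`, the change in the dissolved-nitrogen
#'   inventory of the catholyte, \eqn{V_{TC}\,\Delta c_{N-aq}}, is
#'   subtracted from the nitrogen assigned to biomass. The default `FALSE`
#'   neglects it, which is accurate when biofilm dominates and the dissolved
#'   pool changes slowly; the option exists for sensitivity analysis and for
#'   planktonic-dominated systems.
#' @return a tibble of class `biomass_trajectory` with one row per sample:
#'   `t`, `c_n_px`, `c_px`, `n_px`, `cum_n_retained`, `n_x_total`, `n_bx`,
#'   `biofilm_fraction`, `flag`.
#' @export
accumulate_biomass <- function(config, series, calib,
                               n_x0 = NULL,
                               integration = c("rect", "trapz"),
                               holdup_correction = FALSE) {
  integration <- match.arg(integration)
  if (!inherits(series, "sample_series")) series <- as_sample_series(series)
  if (nrow(series) == 0L) stop_input("sample series is empty")
  if (is.null(n_x0)) n_x0 <- inoculum_biomass(config)
  n <- nrow(series)
  t <- series$t

  c_n_px <- vapply(seq_len(n), function(i) {
    predict_planktonic_nitrogen(calibration_at(calib, t[i]), series$od600[i])
  }, numeric(1))

  dn <- numeric(n)  # dn[1] = 0, baseline
  if (n > 1) {
    dt <- diff(t)
    if (integration == "rect") {
      dn[-1] <- nitrogen_increment(config, series$c_n_aq_out[-1],
                                   c_n_px[-1], dt, t[-1])
    } else {
      c_aq_mid <- (series$c_n_aq_out[-1] + series$c_n_aq_out[-n]) / 2
      c_px_mid <- (c_n_px[-1] + c_n_px[-n]) / 2
      c_in_mid <- (feed_n_at(config, t[-1]) + feed_n_at(config, t[-n])) / 2
      dn[-1] <- config$f_in * (c_in_mid - c_aq_mid - c_px_mid) * dt
    }
  }
  if (holdup_correction && n > 1) {
    dn[-1] <- dn[-1] - config$v_tc * diff(series$c_n_aq_out)
  }
  cum_n <- cumsum(dn)
  n_x_total <- n_x0 + cum_n / config$nu_nx
  c_px <- c_n_px / config$nu_nx
  n_px <- c_px * config$v_tc
  n_bx <- n_x_total - n_px
  flag <- ifelse(n_bx < 0, "negative_biofilm", "")
  biofilm_fraction <- ifelse(n_bx >= 0 & n_x_total > 0,
                             n_bx / n_x_total, NA_real_)
  out <- tibble(t = t, c_n_px = c_n_px, c_px = c_px, n_px = n_px,
                cum_n_retained = cum_n, n_x_total = n_x_total,
                n_bx = n_bx, biofilm_fraction = biofilm_fraction,
                flag = flag)
  class(out) <- c("biomass_trajectory", class(out))
  attr(out, "config") <- config
  out
}

# coerce a plain data frame (with matching column names) to a sample_series
as_sample_series <- function(df) {
  df <- as.data.frame(df)
  need <- c("t", "c_n_aq_out", "od600")
  if (!all(need %in% names(df)))
    stop_input("need columns ", paste(need, collapse = ", "))
  get0_col <- function(col) if (col %in% names(df)) df[[col]] else 0
  sample_series(t = df$t, c_n_aq_out = df$c_n_aq_out, od600 = df$od600,
                acetate = get0_col("acetate"), butyrate = get0_col("butyrate"),
                hexanoate = get0_col("hexanoate"),
                current = if ("current" %in% names(df)) df$current
                          else NA_real_)
}
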