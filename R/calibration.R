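#' Construct an OD600-to-nitrogen calibration model
#'
#' A calibration model is the linear map from optical density at 600 nm of
#' the unfiltered catholyte to the nitrogen concentration contained in
#' planktonic cells, c_N-pX (mol L\eqn{^{-1}}). Use [fit_calibration()] to
#' fit one from a dilution series; this constructor is for models whose
#' coefficients are already known (e.g. an instrument-supplied line).
#'
#' @param slope mol-N L\eqn{^{-1}} per OD unit.
#' @param intercept mol-N L\eqn{^{-1}}.
#' @param r_squared coefficient of determination of the underlying fit, in
#'   \[0, 1\]; `NA` if unknown.
#' @param n_points number of calibration points; `NA` if unknown.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(slope, intercept, r_squared = NA_real_,
                              n_points = NA_integer_) {
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop_input("r_squared must lie in [0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n_points = n_points),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> c_N-pX = %.5g * OD600 %+.5g mol/L\n",
              x$slope, x$intercept))
  cat(sprintf("  R^2 = %s, n = %s\n",
              format(x$r_squared), format(x$n_points)))
  invisible(x)
}

#' Fit the OD600 to planktonic-nitrogen calibration line
#'
#' Ordinary least squares of nitrogen concentration in suspended biomass on
#' optical density, as obtained from a total-nitrogen analysis of a biomass
#' dilution series. The intercept is always estimated (it is typically a
#' small negative number, reflecting blank absorbance).
#'
#' @param points a data frame with columns `od600` (dimensionless) and
#'   `c_n_px` (mol-N L\eqn{^{-1}}), at least two rows, OD values not all
#'   identical.
#' @return a [calibration_model()] carrying the fitted slope, intercept,
#'   R\eqn{^2} and number of points.
#' @examples
#' pts <- data.frame(od600 = c(0.1, 0.5, 1), c_n_px = 0.0052 * c(0.1, 0.5, 1))
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("od600", "c_n_px") %in% names(points)))
    stop_input("calibration points need columns od600 and c_n_px")
  if (nrow(points) < 2L)
    stop_input("at least 2 calibration points are required")
  if (var(points$od600) == 0)
    stop_input("degenerate calibration: all od600 values identical")
  fit <- lm(c_n_px ~ od600, data = points)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((points$c_n_px - mean(points$c_n_px))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  calibration_model(slope = unname(coef(fit)["od600"]),
                    intercept = unname(coef(fit)["(Intercept)"]),
                    r_squared = min(max(r2, 0), 1),
                    n_points = nrow(points))
}

#' Predict planktonic-cell nitrogen concentration from OD600
#'
#' Evaluates the calibration line and clamps negative predictions to zero:
#' a negative nitrogen mass is non-physical, and the fitted intercept is
#' typically slightly negative so a blank sample would otherwise map below
#' zero.
#'
#' @param model a [calibration_model()].
#' @param od600 optical density readings, all \eqn{\ge} 0 (vectorized).
#' @return nitrogen concentration in planktonic cells, mol L\eqn{^{-1}}.
#' @export
predict_planktonic_nitrogen <- function(model, od600) {
  if (any(od600 < 0)) stop_input("od600 must be >= 0")
  pmax(0, model$slope * od600 + model$intercept)
}

#' Read a calibration table from CSV
#'
#' Expects a two-column CSV with header `od600,c_n_px_mol_per_l`.
#'
#' @param path file path.
#' @return a data frame with columns `od600`, `c_n_px` ready for
#'   [fit_calibration()].
#' @export
read_calibration_table <- function(path) {
  tab <- read.csv(path)
  need <- c("od600", "c_n_px_mol_per_l")
  if (!all(need %in% names(tab)))
    stop_input("calibration CSV must have columns ",
               paste(need, collapse = ", "))
  data.frame(od600 = tab$od600, c_n_px = tab$c_n_px_mol_per_l)
}

#' A dated set of calibration models
#'
#' OD-to-biomass calibrations drift over a long run; a remedy is to
#' re-calibrate periodically and apply, to each sample, the most recent
#' calibration obtained at or before the sampling time. `calibration_set()`
#' bundles models with validity start times; [calibration_at()] resolves the
#' model in force at a given time (nearest preceding model wins; times
#' before the first model's start fall back to the first model).
#'
#' @param models a list of [calibration_model()] objects.
#' @param valid_from numeric vector of start times (days), same length as
#'   `models`, strictly increasing.
#' @return an object of class `calibration_set`.
#' @export
calibration_set <- function(models, valid_from) {
  if (length(models) != length(valid_from) || length(models) == 0L)
    stop_input("models and valid_from must have equal positive length")
  if (is.unsorted(valid_from, strictly = TRUE))
    stop_input("valid_from must be strictly increasing")
  ok <- vapply(models, inherits, logical(1), "calibration_model")
  if (!all(ok)) stop_input("all elements must be calibration_model objects")
  structure(list(models = models, valid_from = valid_from),
            class = "calibration_set")
}

#' @rdname calibration_set
#' @param set a `calibration_set`.
#' @param t time, days (scalar).
#' @export
calibration_at <- function(set, t) {
  if (inherits(set, "calibration_model")) return(set)
  idx <- findInterval(t, set$valid_from)
  set$models[[max(idx, 1L)]]
}
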