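#' @include AllClasses.R decay_fit.R
NULL

#' Linear acceptor bleed-through fraction
#'
#' Doxorubicin emission detected in the donor channel scales
#' approximately linearly with concentration: about 1 % of total detected
#' photons per 1 uM. The linear model is an in-range approximation, so
#' the fraction is capped (default 0.5) with a warning.
#'
#' @param concentration_uM doxorubicin concentration(s), uM (>= 0).
#' @param bleed_coeff photon fraction per uM.
#' @param cap maximum fraction returned.
#' @return photon fraction(s) in \[0, cap\].
#' @examples
#' bleedThroughFraction(1)    # 0.01
#' bleedThroughFraction(5)    # 0.05
#' @export
bleedThroughFraction <- function(concentration_uM, bleed_coeff = 0.01,
                                 cap = 0.5) {
  stopIfNot(all(concentration_uM >= 0), "concentration must be >= 0")
  bt <- bleed_coeff * concentration_uM
  if (any(bt > cap)) {
    warning("bleed-through fraction capped at ", cap,
            ": the linear model is outside its valid range")
    bt <- pmin(bt, cap)
  }
  bt
}

#' Build a concentration look-up table
#'
#' Shape-preserving monotone interpolation of the FRETing population
#' fraction `f(C) = 1 - nonfret_fraction(C)` over the calibrated
#' concentrations, exact at the knots, with a bisection inverse defined
#' on `[f(0), f(C_max)]`.
#'
#' @param calib a [CalibrationTable-class] whose FRETing fractions are
#'   strictly increasing in concentration.
#' @return an object of class `"concentration_lut"`: a list with
#'   `f` (function C -> fraction), `f0`, `f_max`, `c_max` and the
#'   calibration it was built from.
#' @export
buildConcentrationLut <- function(calib) {
  stopifnot(is(calib, "CalibrationTable"))
  validObject(calib)
  tab <- calib@table
  f <- 1 - tab$nonfret_fraction
  if (any(diff(f) <= 0)) {
    bad <- which(diff(f) <= 0)
    stop("FRETing fraction is not strictly increasing between rows ",
         paste(bad, bad + 1L, sep = "-", collapse = ", "),
         " of the calibration table", call. = FALSE)
  }
  fn <- stats::splinefun(tab$concentration_uM, f, method = "hyman")
  structure(list(f = fn, f0 = f[1], f_max = f[length(f)],
                 c_max = max(tab$concentration_uM), calib = calib),
            class = "concentration_lut")
}

#' @export
print.concentration_lut <- function(x, ...) {
  cat(sprintf("concentration LUT: C in [0, %g] uM, f in [%.4g, %.4g]\n",
              x$c_max, x$f0, x$f_max))
  invisible(x)
}

#' Estimate doxorubicin concentration from a FRETing fraction
#'
#' Inverts the calibration look-up table by bisection (tolerance 1e-4
#' uM). Fractions below `f(0)` are censored at 0 (`below_range`);
#' fractions above `f(C_max)` - past the binding-saturation plateau -
#' are censored at the top calibrated concentration (`above_range`).
#'
#' @param fret_fraction FRETing population fraction(s) in \[0, 1\].
#' @param lut a look-up table from [buildConcentrationLut()].
#' @return data.frame with one row per input: `value` (uM), `censoring`
#'   (`"exact"`, `"below_range"` or `"above_range"`) and
#'   `fret_fraction_input`.
#' @export
estimateConcentration <- function(fret_fraction, lut) {
  stopifnot(inherits(lut, "concentration_lut"))
  stopIfNot(all(fret_fraction >= 0 & fret_fraction <= 1),
            "fret_fraction must lie in [0, 1]")
  one <- function(f) {
    if (f <= lut$f0)
      return(list(value = 0,
                  censoring = if (f < lut$f0) "below_range" else "exact"))
    if (f >= lut$f_max)
      return(list(value = lut$c_max,
                  censoring = if (f > lut$f_max) "above_range" else "exact"))
    root <- stats::uniroot(function(C) lut$f(C) - f, c(0, lut$c_max),
                           tol = 1e-4)
    list(value = root$root, censoring = "exact")
  }
  res <- lapply(fret_fraction, one)
  data.frame(value = vapply(res, `[[`, numeric(1), "value"),
             censoring = vapply(res, `[[`, character(1), "censoring"),
             fret_fraction_input = fret_fraction)
}

#' Forward simulation of mean lifetime versus concentration
#'
#' Predicts the intensity-weighted mean lifetime that would be measured
#' at each concentration from a three-component photon mixture:
#' non-FRETing donor at `tau_long`, FRETing donor at `tau_short` (with
#' population fraction `f(C)` from the calibration; forced to 0 when
#' `with_fret = FALSE`), and doxorubicin bleed-through at `dox_tau_ps`
#' with photon fraction `bleed_coeff * C`. Comparing the two modes
#' separates the lifetime decrease caused by FRET from the decrease
#' attributable to bleed-through alone.
#'
#' @param concentrations_uM concentration grid, uM.
#' @param calib a [CalibrationTable-class].
#' @param with_fret include the FRETing donor component.
#' @param dox_tau_ps assumed doxorubicin emission lifetime, ps.
#' @param allow_extrapolation permit concentrations above the calibrated
#'   range (otherwise an error).
#' @return data.frame with `concentration_uM`, `tau_mean_iw_ps`,
#'   `fret_fraction` and `bleed_fraction`.
#' @export
forwardMeanLifetimeCurve <- function(concentrations_uM, calib,
                                     with_fret = TRUE, dox_tau_ps = 1000,
                                     allow_extrapolation = FALSE) {
  stopifnot(is(calib, "CalibrationTable"))
  stopIfNot(dox_tau_ps > 0, "dox_tau_ps must be > 0")
  stopIfNot(all(concentrations_uM >= 0), "concentrations must be >= 0")
  c_max <- max(calib@table$concentration_uM)
  if (!allow_extrapolation && any(concentrations_uM > c_max))
    stop("concentration outside the calibrated range [0, ", c_max,
         "] uM; set allow_extrapolation = TRUE to override", call. = FALSE)
  lut <- buildConcentrationLut(calib)
  f <- if (with_fret) pmin(pmax(lut$f(concentrations_uM), 0), 1) else
    rep(0, length(concentrations_uM))
  bt <- bleedThroughFraction(concentrations_uM, calib@bleed_coeff)
  ws_rel <- popToPhotonWeight(f, calib@tau_short_ps, calib@tau_long_ps)
  w_s <- (1 - bt) * ws_rel
  w_l <- (1 - bt) * (1 - ws_rel)
  tau_mean <- w_l * calib@tau_long_ps + w_s * calib@tau_short_ps +
    bt * dox_tau_ps
  data.frame(concentration_uM = concentrations_uM,
             tau_mean_iw_ps = tau_mean, fret_fraction = f,
             bleed_fraction = bt)
}
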