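# Calibration lines, 3*sigma/slope detection limits, standard-addition
# quantification, recovery and RSD.

#' Fit a voltammetric calibration line and derive LOD/LOQ
#'
#' Ordinary least squares of peak current on concentration.  The detection
#' limit uses the 3*sigma/a criterion with sigma the standard error of the
#' fitted intercept and a the slope; the quantification limit uses
#' 10*sigma/a.  Units are whatever consistent pair you supply; with the
#' conventional uM vs uA inputs the slope is numerically in A/M and LOD/LOQ
#' are in uM.
#'
#' @param concentration Concentrations (>= 3 distinct values).
#' @param signal Peak currents (same length).
#' @param area Optional interfacial area in cm^2; when given, the
#'   area-normalized sensitivity `slope/area` is included.
#' @return An object of class `calibration_result` with fields `slope`,
#'   `intercept`, `sigma_intercept`, `r_squared`, `lod`, `loq`,
#'   `sensitivity`, `normalized_sensitivity` (or `NA`) and the `lm` fit.
#' @examples
#' conc <- c(10, 12.5, 15, 17.5, 20, 22.5, 25, 30)  # uM
#' fit_calibration(conc, 0.375 * conc + 1.3, area = pi * 0.65^2)
#' @export
fit_calibration <- function(concentration, signal, area = NULL) {
  if (length(concentration) != length(signal))
    abort_invalid("`concentration` and `signal` must have the same length")
  if (length(concentration) < 3L)
    abort_dof("need at least 3 calibration points")
  if (length(unique(concentration)) < 2L)
    ities_error("calibration concentrations have zero variance",
                "itieskit_singular_design")
  if (length(unique(concentration)) < 3L)
    abort_dof("need at least 3 distinct concentrations")
  fit <- stats::lm(signal ~ concentration)
  sm <- quiet_summary(fit)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  sigma_b <- unname(sm$coefficients[1, 2])
  norm_sens <- NA_real_
  if (!is.null(area)) {
    check_scalar(area, "area", positive = TRUE)
    norm_sens <- slope / area
  }
  structure(
    list(slope = slope, intercept = intercept, sigma_intercept = sigma_b,
         r_squared = sm$r.squared,
         lod = 3 * sigma_b / abs(slope), loq = 10 * sigma_b / abs(slope),
         sensitivity = slope, normalized_sensitivity = norm_sens,
         n = length(concentration), fit = fit),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration (n = %d): signal = %.4g x conc %+.4g\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f, sigma(intercept) = %.3g\n", x$r_squared, x$sigma_intercept))
  cat(sprintf("  LOD (3 sigma/a) = %.3g, LOQ (10 sigma/a) = %.3g\n", x$lod, x$loq))
  if (is.finite(x$normalized_sensitivity))
    cat(sprintf("  area-normalized sensitivity = %.3g per cm^2\n", x$normalized_sensitivity))
  invisible(x)
}

#' Area-normalized sensitivity
#'
#' Divides a calibration slope by the electroactive interfacial area, making
#' sensitivities comparable between macroscopic and microscopic cells.
#'
#' @param slope Calibration slope (e.g. A/M).
#' @param geometry A [cell_geometry()].
#' @return Slope per unit area (e.g. A M^-1 cm^-2).
#' @examples
#' normalize_sensitivity(0.375, cell_geometry("macro", 0.65))  # 0.283
#' @export
normalize_sensitivity <- function(slope, geometry) {
  check_scalar(slope, "slope")
  if (!inherits(geometry, "cell_geometry")) abort_invalid("`geometry` must be a cell_geometry")
  if (geometry$area <= 0) ities_error("geometry has nonpositive area", "itieskit_invalid_geometry")
  slope / geometry$area
}

#' Standard-addition quantification with dilution-chain back-calculation
#'
#' Fits signal against added concentration; the magnitude of the fitted
#' line's x-axis crossing, `|intercept/slope|`, is the analyte concentration
#' in the measured solution.  With a dilution factor, stock volume and molar
#' mass, the analyte mass in the original sample (e.g. a pill dissolved in
#' `stock_volume`) is back-calculated.
#'
#' With `volume_correction = TRUE` the nominal added concentrations are
#' recomputed from the actual addition volumes: starting from
#' `initial_volume` of sample, each of the successive additions adds
#' `addition_volume` of a standard at `standard_concentration`; signals are
#' rescaled by the total-volume ratio so that the x-intercept again reads the
#' undiluted sample concentration exactly.
#'
#' @param added_concentration Added analyte concentrations in measurement
#'   units (uM by convention); first point must be 0 (the unspiked sample).
#' @param signal Currents (uA/nA by convention), same length, >= 3 points.
#' @param dilution_factor Dilution of the stock before measurement
#'   (e.g. 20 uL into 980 uL -> 50).
#' @param stock_volume Stock (dissolution) volume in litres.
#' @param molar_mass Molar mass in g/mol.
#' @param volume_correction Recompute concentrations from addition volumes.
#' @param initial_volume,addition_volume Volumes (same unit, e.g. uL) used
#'   when `volume_correction = TRUE`; defaults 10 and 2.5.
#' @param standard_concentration Standard concentration (same unit as
#'   `added_concentration`) used when `volume_correction = TRUE`.
#' @return An object of class `standard_addition_result` with `slope`,
#'   `intercept`, `x_intercept_concentration` (measurement units),
#'   `content_mass` in grams (`NA` unless the dilution chain is given) and
#'   the `lm` fit.
#' @examples
#' # the x-intercept of y = 0.0128 x + 0.1941 is 15.16 uM
#' add <- c(0, 5, 10, 15, 20)
#' standard_addition(add, 0.0128 * add + 0.1941)
#' @export
standard_addition <- function(added_concentration, signal,
                              dilution_factor = NULL, stock_volume = NULL,
                              molar_mass = NULL, volume_correction = FALSE,
                              initial_volume = 10, addition_volume = 2.5,
                              standard_concentration = NULL) {
  if (length(added_concentration) != length(signal))
    abort_invalid("`added_concentration` and `signal` must have the same length")
  if (length(added_concentration) < 3L) abort_dof("need at least 3 standard-addition points")
  if (abs(added_concentration[1]) > 1e-12)
    abort_invalid("the first point must be the unspiked sample (added concentration 0)")

  if (volume_correction) {
    if (is.null(standard_concentration))
      abort_invalid("`standard_concentration` is required with volume_correction = TRUE")
    k <- seq_along(signal) - 1  # number of additions per point
    vtot <- initial_volume + k * addition_volume
    x <- standard_concentration * k * addition_volume / initial_volume
    y <- signal * vtot / initial_volume
  } else {
    x <- added_concentration
    y <- signal
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    abort_fit("standard-addition slope must be positive")
  x_int <- abs(intercept / slope)

  content <- NA_real_
  if (!is.null(dilution_factor) && !is.null(stock_volume) && !is.null(molar_mass)) {
    check_scalar(dilution_factor, "dilution_factor", positive = TRUE)
    check_scalar(stock_volume, "stock_volume", positive = TRUE)
    check_scalar(molar_mass, "molar_mass", positive = TRUE)
    # measurement units assumed uM -> mol/L, stock volume L, mass g
    content <- uM_to_M(x_int) * dilution_factor * stock_volume * molar_mass
  }
  structure(
    list(slope = slope, intercept = intercept,
         x_intercept_concentration = x_int,
         dilution_factor = dilution_factor, stock_volume = stock_volume,
         molar_mass = molar_mass, content_mass = content,
         volume_correction = volume_correction,
         r_squared = quiet_summary(fit)$r.squared, fit = fit),
    class = "standard_addition_result"
  )
}

#' @export
print.standard_addition_result <- function(x, ...) {
  cat(sprintf("Standard addition: y = %.4g x %+.4g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  x-intercept concentration = %.4g (measurement units)\n",
              x$x_intercept_concentration))
  if (is.finite(x$content_mass))
    cat(sprintf("  back-calculated content = %.4g mg\n", 1e3 * x$content_mass))
  invisible(x)
}

#' Spike recovery
#'
#' `100 * found / added` percent.
#'
#' @param added Spiked (known) concentration, > 0.
#' @param found Back-calculated concentration.
#' @return Recovery in percent.
#' @examples
#' recovery(30.0, 31.0)  # 103.3
#' @export
recovery <- function(added, found) {
  if (!is.numeric(added) || !is.numeric(found) || anyNA(added) || anyNA(found))
    abort_invalid("`added` and `found` must be numeric")
  if (any(added <= 0)) abort_invalid("`added` must be > 0")
  100 * found / added
}

#' Relative standard deviation
#'
#' `100 * sample SD / mean` percent over replicate measurements.
#'
#' @param values Numeric vector, length >= 2, with nonzero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(10, 10, 10.3))  # ~1.71
#' @export
rsd <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values))
    abort_invalid("`values` must be >= 2 numbers")
  m <- mean(values)
  if (m == 0) ities_error("RSD is undefined for zero mean", "itieskit_undefined_rsd")
  100 * stats::sd(values) / m
}
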