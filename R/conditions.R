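#' Experimental conditions: temperature and physical constants
#'
#' Bundles the absolute temperature with the gas constant and the Faraday
#' constant so that every potential-to-energy conversion in the package uses
#' one consistent set of values.  The default temperature is 293.15 K
#' (20 degrees C), the laboratory temperature that makes the logP values
#' computed from measured formal transfer potentials line up with reported
#' benzodiazepine lipophilicities; it is configurable everywhere.
#'
#' @param temperature Absolute temperature in kelvin; must lie in
#'   \[270, 330\] K.
#' @return An object of class `ities_conditions`: a list with elements
#'   `temperature` (K), `R` (8.314 J mol^-1 K^-1) and `F` (96485 C mol^-1).
#' @examples
#' cond <- ities_conditions()
#' nernst_slope(cond)  # ~0.0582 V per decade at 20 C
#' @export
ities_conditions <- function(temperature = 293.15) {
  check_scalar(temperature, "temperature")
  if (temperature < 270 || temperature > 330)
    abort_invalid("`temperature` must lie in [270, 330] K")
  structure(
    list(temperature = temperature, R = 8.314, F = 96485),
    class = "ities_conditions"
  )
}

#' @rdname ities_conditions
#' @param conditions An `ities_conditions` object.
#' @export
nernst_slope <- function(conditions) {
  stopifnot(inherits(conditions, "ities_conditions"))
  log(10) * conditions$R * conditions$temperature / conditions$F
}

# RT/F in volts
thermal_voltage <- function(conditions) {
  conditions$R * conditions$temperature / conditions$F
}

#' @export
print.ities_conditions <- function(x, ...) {
  cat(sprintf("ITIES conditions: T = %.2f K, R = %.3f J/mol/K, F = %d C/mol\n",
              x$temperature, x$R, x$F))
  cat(sprintf("  Nernst slope ln(10)RT/F = %.2f mV/decade\n", 1e3 * nernst_slope(x)))
  invisible(x)
}
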