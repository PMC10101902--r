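#' Cell geometry of a liquid-liquid interface
#'
#' The interface is assumed circular; the electroactive area is `pi r^2`.
#'
#' @param kind `"macro"` or `"micro"`.
#' @param radius Interface radius in cm (e.g. 0.65 cm for a macroscopic glass
#'   cell; 12.5e-4 cm for a 25 um capillary pore).
#' @return An object of class `cell_geometry` with fields `kind`, `radius`
#'   (cm) and `area` (cm^2).
#' @export
cell_geometry <- function(kind = c("macro", "micro"), radius) {
  kind <- match.arg(kind)
  check_scalar(radius, "radius", positive = TRUE)
  structure(list(kind = kind, radius = radius, area = pi * radius^2),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("%s ITIES: radius %.4g cm, area %.4g cm^2\n", x$kind, x$radius, x$area))
  invisible(x)
}

# Randles-Sevcik prefactor for a reversible diffusion-limited transfer
RS_FACTOR <- 0.4463

#' Randles-Sevcik peak current of a reversible ion transfer
#'
#' `I_p = 0.4463 z F A C sqrt(z F v D / (R T))` for a reversible,
#' diffusion-controlled transfer under linear diffusion.  All quantities use
#' the CGS-molar contract: area cm^2, concentration mol cm^-3, diffusion
#' cm^2 s^-1, scan rate V s^-1, current A.
#'
#' @param z Integer charge (> 0 magnitudes assumed).
#' @param area Interfacial area, cm^2.
#' @param concentration Bulk concentration, mol cm^-3 (>= 0).
#' @param diffusion Diffusion coefficient, cm^2 s^-1.
#' @param scan_rate Potential scan rate, V s^-1.
#' @param conditions An [ities_conditions()].
#' @return Peak current in amperes.
#' @examples
#' # 20 uM drug, 0.65 cm macro cell, 20 mV/s
#' randles_sevcik_peak_current(1, pi * 0.65^2, 2e-8, 14.1e-6, 0.02)
#' @export
randles_sevcik_peak_current <- function(z, area, concentration, diffusion,
                                        scan_rate, conditions = ities_conditions()) {
  check_scalar(z, "z", positive = TRUE)
  check_scalar(area, "area", positive = TRUE)
  check_scalar(concentration, "concentration", nonneg = TRUE)
  check_scalar(diffusion, "diffusion", positive = TRUE)
  check_scalar(scan_rate, "scan_rate", positive = TRUE)
  f <- conditions$F
  RS_FACTOR * z * f * area * concentration *
    sqrt(z * f * scan_rate * diffusion / (conditions$R * conditions$temperature))
}

#' Diffusion coefficient from a scan-rate series
#'
#' Ordinary least squares of peak current on sqrt(scan rate); the diffusion
#' coefficient is recovered from the slope through the Randles-Sevcik
#' relation.  The intercept is retained as a diagnostic only (experimental
#' series routinely have nonzero intercepts); D comes from the slope alone.
#'
#' @param scan_rate Scan rates, V s^-1 (>= 3 distinct values).
#' @param peak_current Peak currents, A.
#' @param z Integer charge.
#' @param area Interfacial area, cm^2.
#' @param concentration Bulk concentration, mol cm^-3.
#' @param conditions An [ities_conditions()].
#' @return A list with `diffusion` (cm^2 s^-1), `slope`, `intercept`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
diffusion_from_scan_rate_series <- function(scan_rate, peak_current, z, area,
                                            concentration,
                                            conditions = ities_conditions()) {
  if (length(scan_rate) != length(peak_current))
    abort_invalid("`scan_rate` and `peak_current` must have the same length")
  if (length(unique(scan_rate)) < 3L)
    abort_dof("need at least 3 distinct scan rates")
  check_scalar(z, "z", positive = TRUE)
  check_scalar(area, "area", positive = TRUE)
  check_scalar(concentration, "concentration", positive = TRUE)
  sqv <- sqrt(scan_rate)
  fit <- stats::lm(peak_current ~ sqv)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    abort_physical("fitted peak-current vs sqrt(scan rate) slope is not positive")
  f <- conditions$F
  k <- RS_FACTOR * z * f * area * concentration
  diffusion <- (slope / k)^2 * conditions$R * conditions$temperature / (z * f)
  list(
    diffusion = diffusion,
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = quiet_summary(fit)$r.squared,
    fit = fit
  )
}

#' Saito steady-state current and micro-interface radius
#'
#' For a disc-shaped micro liquid-liquid interface the steady-state limiting
#' current is `I_ss = 4 z F D C r`; `saito_radius()` is the exact algebraic
#' inverse `r = I_ss / (4 z F D C)` used as the fabrication quality-control
#' step (the measured radius of nominal 25 um capillaries).
#'
#' @param steady_state_current Steady-state (limiting) current, A.
#' @param radius Interface radius, cm.
#' @param z Integer charge.
#' @param diffusion Diffusion coefficient, cm^2 s^-1.
#' @param concentration Bulk concentration, mol cm^-3.
#' @param conditions An [ities_conditions()].
#' @return Radius in cm (`saito_radius`) or current in A (`saito_current`).
#' @examples
#' i <- saito_current(12e-4, 1, 13.8e-6, 5e-8)  # ~0.32 nA for 50 uM TMA+
#' saito_radius(i, 1, 13.8e-6, 5e-8)            # 12e-4 cm back
#' @export
saito_radius <- function(steady_state_current, z, diffusion, concentration,
                         conditions = ities_conditions()) {
  check_scalar(steady_state_current, "steady_state_current", positive = TRUE)
  check_scalar(z, "z", positive = TRUE)
  check_scalar(diffusion, "diffusion", positive = TRUE)
  check_scalar(concentration, "concentration", positive = TRUE)
  steady_state_current / (4 * z * diffusion * concentration * conditions$F)
}

#' @rdname saito_radius
#' @export
saito_current <- function(radius, z, diffusion, concentration,
                          conditions = ities_conditions()) {
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(z, "z", positive = TRUE)
  check_scalar(diffusion, "diffusion", positive = TRUE)
  check_scalar(concentration, "concentration", positive = TRUE)
  4 * z * conditions$F * diffusion * concentration * radius
}
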