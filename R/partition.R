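#' Ion partition model for an ionizable drug at a liquid-liquid interface
#'
#' Describes the boundary line of an ion partition diagram: below the pKa the
#' apparent transfer potential is pinned at the formal transfer potential of
#' the protonated drug (simple ion transfer); above it the boundary rises by
#' ~ln(10)RT/F per pH unit as the neutral form partitions into the organic
#' phase and the signal becomes a facilitated proton transfer.
#'
#' @param formal_potential Formal Galvani transfer potential of the protonated
#'   ion, in volts (aqueous -> organic).
#' @param pka Acid dissociation exponent of the relevant deprotonation step.
#' @param kd Distribution constant of the neutral form, organic/aqueous
#'   concentration ratio (larger = more lipophilic); must be >= 0.
#' @param z Integer charge of the transferring ion (nonzero).
#' @param conditions An [ities_conditions()] object.
#' @return An object of class `ion_partition_model`.
#' @examples
#' m <- ion_partition_model(0.150, pka = 4.6, kd = 0.1)
#' boundary_potential(m, ph = c(2, 4, 6, 8))
#' @export
ion_partition_model <- function(formal_potential, pka, kd, z = 1L,
                                conditions = ities_conditions()) {
  check_scalar(formal_potential, "formal_potential")
  check_scalar(pka, "pka")
  check_scalar(kd, "kd", nonneg = TRUE)
  if (!is.numeric(z) || length(z) != 1L || z == 0 || z != round(z))
    abort_invalid("`z` must be a nonzero integer")
  stopifnot(inherits(conditions, "ities_conditions"))
  structure(
    list(formal_potential = formal_potential, pka = pka, kd = kd,
         z = as.integer(z), conditions = conditions),
    class = "ion_partition_model"
  )
}

#' @export
print.ion_partition_model <- function(x, ...) {
  cat(sprintf(
    "Ion partition model: formal potential %.1f mV, pKa %.2f, KD %.4g, z %+d (T = %.2f K)\n",
    1e3 * x$formal_potential, x$pka, x$kd, x$z, x$conditions$temperature))
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted on %d points, residual norm %.3g V, se(log10 KD) %.3g\n",
                x$fit$n, x$fit$residual_norm, x$fit$se_log10_kd))
  }
  invisible(x)
}

#' Boundary line of the ion partition diagram
#'
#' Apparent transfer potential as a function of pH:
#' `formal_potential + (RT/F) * ln(1 + 10^(pH - pKa) * (1 + KD))`.
#' Flat at the formal potential well below the pKa; asymptotically linear
#' with slope ln(10)RT/F (~58 mV/pH at 20 C) well above it.  Evaluated via
#' `log1p` so very alkaline pH does not overflow.
#'
#' @param model An [ion_partition_model()].
#' @param ph pH value(s).
#' @return Potential(s) in volts.
#' @export
boundary_potential <- function(model, ph) {
  stopifnot(inherits(model, "ion_partition_model"))
  if (!is.numeric(ph) || anyNA(ph) || any(!is.finite(ph)))
    abort_invalid("`ph` must be finite numeric")
  vt <- thermal_voltage(model$conditions)
  a <- log(10) * (ph - model$pka) + log1p(model$kd)  # ln of 10^(ph-pka)(1+kd)
  lg <- ifelse(a > 35, a, log1p(exp(pmin(a, 35))))
  model$formal_potential + vt * lg
}

#' Fit an ion partition model to (pH, apparent potential) points
#'
#' Least-squares fit of [boundary_potential()] to measured boundary points.
#' KD is parameterized as log10(KD) to enforce positivity; for each candidate
#' KD the formal potential is the analytic least-squares offset, so the whole
#' problem reduces to a robust 1-D minimization.  Parameter standard errors
#' come from the Gauss-Newton approximation at the optimum.
#'
#' @param ph,potential Numeric vectors of pH and measured apparent transfer
#'   potential (V); at least 3 points.
#' @param pka Known acid dissociation exponent of the relevant step.
#' @param z Ion charge.
#' @param conditions An [ities_conditions()].
#' @param fit_formal_potential If `TRUE` (default) the formal potential is a
#'   free parameter; requires at least one point with `ph < pka` to pin the
#'   simple-transfer plateau.  If `FALSE`, supply `formal_potential`.
#' @param formal_potential Fixed formal potential (V) when
#'   `fit_formal_potential = FALSE`.
#' @param interval log10(KD) search interval.
#' @return The fitted `ion_partition_model`, with a `fit` element holding
#'   `n`, `residual_norm`, `se_log10_kd`, `se_formal_potential` and the
#'   residuals.
#' @export
fit_partition_model <- function(ph, potential, pka, z = 1L,
                                conditions = ities_conditions(),
                                fit_formal_potential = TRUE,
                                formal_potential = NULL,
                                interval = c(-8, 8)) {
  if (length(ph) != length(potential))
    abort_invalid("`ph` and `potential` must have the same length")
  keep <- is.finite(ph) & is.finite(potential)
  ph <- ph[keep]; potential <- potential[keep]
  n <- length(ph)
  n_par <- if (fit_formal_potential) 2L else 1L
  if (n < 3L) abort_dof("need at least 3 (pH, potential) points")
  if (n <= n_par) abort_dof("fewer points than free parameters")
  if (fit_formal_potential && !any(ph < pka))
    abort_invalid("need at least one point with ph < pka to pin the plateau when fitting the formal potential")
  if (!fit_formal_potential) {
    if (is.null(formal_potential))
      abort_invalid("supply `formal_potential` when fit_formal_potential = FALSE")
    check_scalar(formal_potential, "formal_potential")
  }

  vt <- thermal_voltage(conditions)
  shape <- function(l10kd) {            # boundary minus formal potential
    a <- log(10) * (ph - pka) + log1p(10^l10kd)
    vt * ifelse(a > 35, a, log1p(exp(pmin(a, 35))))
  }
  ssr <- function(l10kd) {
    g <- shape(l10kd)
    fp <- if (fit_formal_potential) mean(potential - g) else formal_potential
    sum((potential - fp - g)^2)
  }
  opt <- stats::optimize(ssr, interval = interval, tol = 1e-10)
  l10kd <- opt$minimum
  if (l10kd < interval[1] + 1e-6 || l10kd > interval[2] - 1e-6) {
    # boundary solution: either KD ~ 0 or the data do not constrain KD
    if (opt$objective > n * (5e-3)^2)
      abort_fit(sprintf("KD fit did not converge inside log10(KD) in [%g, %g]; SSR = %.3g V^2",
                        interval[1], interval[2], opt$objective))
  }
  g <- shape(l10kd)
  fp <- if (fit_formal_potential) mean(potential - g) else formal_potential
  res <- potential - fp - g
  dof <- n - n_par
  sigma2 <- sum(res^2) / max(dof, 1L)

  # Gauss-Newton covariance from the numeric Jacobian in (fp, log10 kd)
  h <- 1e-6
  dgd <- (shape(l10kd + h) - shape(l10kd - h)) / (2 * h)
  J <- if (fit_formal_potential) cbind(1, dgd) else cbind(dgd)
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(JtJ), error = function(e) matrix(NA_real_, n_par, n_par))
  se <- sqrt(pmax(diag(cov), 0))
  se_fp <- if (fit_formal_potential) se[1] else 0
  se_l10kd <- se[n_par]

  model <- ion_partition_model(fp, pka, 10^l10kd, z = z, conditions = conditions)
  model$fit <- list(
    n = n, log10_kd = l10kd, residual_norm = sqrt(sum(res^2)),
    sigma = sqrt(sigma2), se_log10_kd = se_l10kd, se_formal_potential = se_fp,
    residuals = res, converged = TRUE
  )
  model
}

#' logP of an ion from its formal transfer potential
#'
#' The standard Gibbs energy of ion transfer maps the formal Galvani transfer
#' potential onto a partition coefficient:
#' `logP = -formal_potential * z * F / (ln(10) * R * T)`.
#' A positive transfer potential for a cation therefore means a negative logP
#' (hydrophilic ion).
#'
#' @param formal_potential Formal transfer potential in volts.
#' @param z Nonzero integer charge.
#' @param conditions An [ities_conditions()].
#' @return Dimensionless logP (water -> organic).
#' @examples
#' logp_from_potential(0.150, 1)  # -2.58 for 7-aminonitrazepam cation
#' logp_from_potential(0.242, 1)  # -4.16 for nitrazepam cation
#' @export
logp_from_potential <- function(formal_potential, z, conditions = ities_conditions()) {
  if (!is.numeric(formal_potential) || anyNA(formal_potential) || any(!is.finite(formal_potential)))
    abort_invalid("`formal_potential` must be finite numeric")
  if (!is.numeric(z) || length(z) != 1L || z != round(z))
    abort_invalid("`z` must be an integer")
  if (z == 0) abort_invalid("`z` must be nonzero")
  -formal_potential * z / nernst_slope(conditions)
}

#' @rdname logp_from_potential
#' @param logp Dimensionless partition coefficient exponent.
#' @export
potential_from_logp <- function(logp, z, conditions = ities_conditions()) {
  if (!is.numeric(z) || length(z) != 1L || z != round(z))
    abort_invalid("`z` must be an integer")
  if (z == 0) abort_invalid("`z` must be nonzero")
  -logp * nernst_slope(conditions) / z
}

#' Interfacial charge-transfer mechanism at a given pH
#'
#' Classifies the regime of the partition boundary: where
#' `10^(pH - pKa) * (1 + KD) < 1` the boundary is flat and the measured
#' current is the simple transfer of the protonated drug ion; beyond that the
#' rising branch reflects proton transfer facilitated by the neutral drug
#' partitioned into the organic phase.  A point exactly at the crossover is
#' classified as facilitated (tie broken toward the high-pH regime).
#'
#' @param model An [ion_partition_model()].
#' @param ph pH value(s).
#' @return Character vector: `"simple_ion_transfer"` or
#'   `"facilitated_proton_transfer"`.
#' @export
mechanism_at <- function(model, ph) {
  stopifnot(inherits(model, "ion_partition_model"))
  if (!is.numeric(ph) || anyNA(ph) || any(!is.finite(ph)))
    abort_invalid("`ph` must be finite numeric")
  a <- log(10) * (ph - model$pka) + log1p(model$kd)
  ifelse(a < 0, "simple_ion_transfer", "facilitated_proton_transfer")
}
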