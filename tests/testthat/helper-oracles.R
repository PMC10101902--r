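# Independent oracles kept deliberately separate from the package's own
# computation paths.

# Brute-force acid-base equilibrium: solves the mass balance numerically for
# the most-protonated concentration at a fixed total, then chains the
# mass-action ratios.  Independent of the closed-form log-space evaluation
# used by species_fractions().
oracle_species_fractions <- function(pka, ph, total = 1e-3) {
  H <- 10^(-ph)
  Ka <- 10^(-pka)
  ratios <- cumprod(Ka / H)            # c_i / c_0 for i >= 1
  # solve the mass balance for log(c0) so minority most-protonated species
  # (c0 down to ~1e-20 of total) are still resolved to full relative precision
  mass_balance <- function(u) exp(u) * (1 + sum(ratios)) - total
  u <- stats::uniroot(mass_balance, lower = log(total) - 60, upper = log(total),
                      tol = 1e-14)$root
  conc <- exp(u) * c(1, ratios)
  conc / sum(conc)
}

# Closed-form two-parameter OLS via the normal equations, with the classic
# intercept standard error.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sigma2 <- sum(res^2) / (n - 2)
  se_intercept <- sqrt(sigma2 * (1 / n + mean(x)^2 / sxx))
  se_slope <- sqrt(sigma2 / sxx)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, se_intercept = se_intercept,
       se_slope = se_slope, r_squared = r2)
}

# Analytic intercept SE for known noise SD (no estimation), for LOD studies.
oracle_intercept_se <- function(x, sigma) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sigma * sqrt(1 / n + mean(x)^2 / sxx)
}
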