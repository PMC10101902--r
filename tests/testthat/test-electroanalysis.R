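test_that("a noiseless calibration line is fitted exactly with zero LOD", {
  conc <- macro_concentrations()
  cal <- fit_calibration(conc, 0.105 * conc)
  expect_equal(cal$slope, 0.105, tolerance = 1e-12)
  expect_equal(cal$sigma_intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$lod, 0, tolerance = 1e-9)
  expect_true(cal$loq >= cal$lod)
})

test_that("area-normalized sensitivities reproduce the macro-cell values", {
  geom <- macro_geometry()
  expect_equal(round(normalize_sensitivity(0.105, geom), 3), 0.079)
  expect_equal(round(normalize_sensitivity(0.375, geom), 3), 0.283)
  expect_equal(round(abs(normalize_sensitivity(-0.087, geom)), 3), 0.066)
  unit <- cell_geometry("macro", sqrt(1 / pi))  # unit area
  expect_equal(normalize_sensitivity(0.42, unit), 0.42, tolerance = 1e-12)

  cal <- fit_calibration(macro_concentrations(),
                         0.105 * macro_concentrations() + 0.156,
                         area = geom$area)
  expect_equal(cal$normalized_sensitivity, 0.105 / geom$area, tolerance = 1e-12)
})

test_that("calibration equals the closed-form OLS oracle", {
  set.seed(202)
  for (rep in 1:5) {
    x <- sort(runif(8, 2, 30))
    y <- 0.3 * x + 0.5 + rnorm(8, 0, 0.2)
    cal <- fit_calibration(x, y)
    or <- oracle_ols(x, y)
    expect_equal(cal$slope, or$slope, tolerance = 1e-10)
    expect_equal(cal$intercept, or$intercept, tolerance = 1e-10)
    expect_equal(cal$sigma_intercept, or$se_intercept, tolerance = 1e-10)
    expect_equal(cal$r_squared, or$r_squared, tolerance = 1e-10)
    expect_equal(cal$lod, 3 * or$se_intercept / abs(or$slope), tolerance = 1e-10)
    expect_equal(cal$loq, 10 * or$se_intercept / abs(or$slope), tolerance = 1e-10)
  }
})

test_that("calibration design errors are typed", {
  expect_error(fit_calibration(c(1, 2), c(1, 2)), class = "itieskit_dof_error")
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)),
               class = "itieskit_singular_design")
})

test_that("LOD and LOQ scale linearly with the injected noise SD", {
  conc <- macro_concentrations()
  sigmas <- c(0.02, 0.05, 0.1, 0.2)
  set.seed(77)
  n_rep <- 3000  # enough replicates to resolve the slope to ~2%
  mean_lod <- vapply(sigmas, function(s) {
    mean(replicate(n_rep, {
      tab <- simulate_calibration_table(0.375, conc, noise_sd = s)
      fit_calibration(tab$concentration, tab$signal)$lod
    }))
  }, numeric(1))
  # slope of mean LOD against sigma approaches 3 * se-factor * c4 / slope,
  # where c4 is the exact mean of the residual-SD estimator (df = n - 2)
  df <- length(conc) - 2
  c4 <- sqrt(2 / df) * gamma((df + 1) / 2) / gamma(df / 2)
  k <- coef(lm(mean_lod ~ sigmas))[2]
  expect_equal(unname(k), 3 * oracle_intercept_se(conc, 1) * c4 / 0.375,
               tolerance = 0.02)
})

test_that("standard addition reproduces the worked x-intercept and content", {
  # points generated exactly on y = 0.0128 x + 0.1941 (nA vs uM)
  add <- c(0, 5, 10, 15, 20)
  sa <- standard_addition(add, 0.0128 * add + 0.1941,
                          dilution_factor = 50, stock_volume = 0.025,
                          molar_mass = 281.27)
  expect_equal(sa$x_intercept_concentration, 15.1641, tolerance = 1e-4)
  expect_equal(round(sa$x_intercept_concentration), 15)
  # dilution chain: 15.16 uM x 50 x 25 mL x 281.27 g/mol -> 5.33 mg
  expect_equal(sa$content_mass, 5.3315e-3, tolerance = 1e-4)
})

test_that("standard addition is exact on noiseless synthetic data", {
  k <- 0.012  # response slope
  for (c_samp in c(5, 20, 33.3)) {
    add <- c(0, 4, 8, 12, 16)
    sa <- standard_addition(add, k * (c_samp + add))
    expect_equal(sa$x_intercept_concentration, c_samp, tolerance = 1e-12)
  }

  # volume-corrected chain: signals follow the physical dilution of both the
  # sample and the cumulative standard additions
  v0 <- 10; va <- 2.5; cs <- 80; c_samp <- 20
  kk <- 0:4
  ctot <- (c_samp * v0 + cs * kk * va) / (v0 + kk * va)
  sa2 <- standard_addition(cs * kk * va / (v0 + kk * va), k * ctot,
                           volume_correction = TRUE, initial_volume = v0,
                           addition_volume = va, standard_concentration = cs)
  expect_equal(sa2$x_intercept_concentration, c_samp, tolerance = 1e-12)
})

test_that("standard addition input contracts are enforced", {
  expect_error(standard_addition(c(1, 2, 3), c(1, 2, 3)),
               class = "itieskit_invalid_input")  # first point not zero
  expect_error(standard_addition(c(0, 5), c(1, 2)), class = "itieskit_dof_error")
  expect_error(standard_addition(c(0, 5, 10), c(3, 2, 1)),
               class = "itieskit_fit_error")      # negative slope
})

test_that("recovery and RSD match hand calculations", {
  expect_equal(recovery(30.0, 31.0), 103.3, tolerance = 0.05)
  expect_equal(recovery(30.0, 29.1), 97.0, tolerance = 0.05)
  expect_equal(recovery(12.5, 12.5), 100)
  for (x in c(0.1, 3, 42)) expect_equal(recovery(x, x), 100)
  expect_error(recovery(0, 1), class = "itieskit_invalid_input")

  expect_equal(rsd(c(10, 10, 10.3)), 1.7149, tolerance = 1e-4)
  expect_equal(rsd(c(7, 7, 7)), 0)
  expect_error(rsd(5), class = "itieskit_invalid_input")
  expect_error(rsd(c(-1, 1)), class = "itieskit_undefined_rsd")
})
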