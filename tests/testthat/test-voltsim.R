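test_that("macro simulation is deterministic for a fixed seed and config", {
  sp <- transfer_species("A", 1, 0.2, 1e-5, concentration = 20e-6)
  cfg <- sim_config(0, 0.45, geometry = macro_geometry(), n_space = 120,
                    noise_sd = 5e-8, seed = 123)
  v1 <- simulate_macro_itv(sp, cfg)
  v2 <- simulate_macro_itv(sp, cfg)
  expect_identical(v1$current, v2$current)
  expect_identical(v1$potential, v2$potential)

  # a different seed gives a different noise realization
  cfg2 <- sim_config(0, 0.45, geometry = macro_geometry(), n_space = 120,
                     noise_sd = 5e-8, seed = 124)
  expect_false(identical(simulate_macro_itv(sp, cfg2)$current, v1$current))
})

test_that("zero analyte concentration yields a background-only trace", {
  cfg <- sim_config(0, 0.45, geometry = macro_geometry(), n_space = 120,
                    wall_negative = -0.05, wall_positive = 0.5,
                    wall_amplitude = 1e-6)
  v <- simulate_macro_itv(transfer_species("A", 1, 0.2, 1e-5, concentration = 0),
                          cfg)
  # identical to the analytic (direction-independent) background model
  bg <- itieskit:::background_current(v$potential, 0, cfg)
  expect_equal(v$current, bg, tolerance = 1e-12)

  # the capacitive term offsets forward and backward sweeps symmetrically
  cfgc <- sim_config(0, 0.45, geometry = macro_geometry(), n_space = 120,
                     capacitance = 1e-6)
  vc <- simulate_macro_itv(transfer_species("A", 1, 0.2, 1e-5, concentration = 0),
                           cfgc)
  segs <- segment_sweeps(vc)
  expect_equal(mean(segs$forward$current) - mean(segs$backward$current),
               2 * 1e-6 * 0.02 * macro_geometry()$area, tolerance = 0.02)
})

test_that("the FD solver conserves mass over a full cycle", {
  sp <- transfer_species("A", 1, 0.2, 1e-5, concentration = 20e-6)
  cfg <- sim_config(0, 0.45, geometry = macro_geometry(), n_space = 300)
  v <- simulate_macro_itv(sp, cfg)
  expect_lt(attr(v, "mass_balance_error"), 1e-3)
})

test_that("simulated peak separation converges to the reversible 2.218 RT/F", {
  cond <- cond20()
  sp <- transfer_species("NIT+", 1, 0.242, 14.1e-6, concentration = 20e-6)
  sep_at <- function(n_space) {
    cfg <- sim_config(0, 0.55, geometry = macro_geometry(), n_space = n_space)
    v <- simulate_macro_itv(sp, cfg, cond, n_out = 5000)
    segs <- segment_sweeps(v)
    ef <- segs$forward$potential[which.max(segs$forward$current)]
    eb <- segs$backward$potential[which.min(segs$backward$current)]
    ef - eb
  }
  target <- 2.218 * cond$R * cond$temperature / cond$F
  sep_coarse <- sep_at(150)
  sep_fine <- sep_at(400)
  expect_lt(abs(sep_fine - target), 2e-3)
  # refinement moves the separation toward (or keeps it at) the theory value
  expect_lte(abs(sep_fine - target), abs(sep_coarse - target) + 2e-4)
})

test_that("peak current is grid-independent to 0.5% under refinement", {
  sp <- transfer_species("A", 1, 0.242, 14.1e-6, concentration = 20e-6)
  peak_at <- function(n_space) {
    cfg <- sim_config(0, 0.55, geometry = macro_geometry(), n_space = n_space)
    max(simulate_macro_itv(sp, cfg, cond20())$current)
  }
  p1 <- peak_at(300)
  p2 <- peak_at(600)
  expect_lt(abs(p2 - p1) / p2, 0.005)
})

test_that("micro simulation produces the Saito plateau and a return peak", {
  cond <- cond20()
  sp <- transfer_species("TMA+", 1, 0.160, 13.8e-6, concentration = 50e-6)
  cfg <- sim_config(-0.05, 0.45, geometry = micro_geometry(), n_space = 150,
                    seed = 3)
  v <- simulate_micro_itv(sp, cfg, cond, n_out = 4000)
  segs <- segment_sweeps(v)
  iss <- saito_current(12e-4, 1, 13.8e-6, 5e-8, cond)

  # forward plateau within 1% of the Saito current near the vertex
  i_top <- max(segs$forward$current)
  expect_lt(abs(i_top - iss) / iss, 0.01)

  # the backward branch has a clear negative (release) peak
  expect_lt(min(segs$backward$current), -0.5 * iss)

  # zero concentration: background only (flat zero without walls)
  v0 <- simulate_micro_itv(transfer_species("x", 1, 0.16, 13.8e-6,
                                            concentration = 0), cfg, cond)
  expect_lt(max(abs(v0$current)), 1e-15)
})

test_that("micro geometry is required for the pore simulator", {
  sp <- transfer_species("TMA+", 1, 0.160, 13.8e-6, concentration = 50e-6)
  cfg <- sim_config(-0.05, 0.45, geometry = macro_geometry())
  expect_error(simulate_micro_itv(sp, cfg), class = "itieskit_config_error")
  expect_error(sim_config(0, 0.4, lambda = 0.6), class = "itieskit_config_error")
  expect_error(sim_config(0.2, 0.2), class = "itieskit_config_error")
})

test_that("pH series follows the boundary line and the window-wall cutoff", {
  sys <- nit_system()
  model <- ion_partition_model(0.242, 3.2, 10, conditions = cond20())
  ph <- seq(2, 9, by = 0.5)

  # noiseless series reproduces the boundary exactly and KD is recovered
  res <- simulate_ph_series(sys, model, ph, cation_label = "NIT+")
  expect_equal(res$table$potential, boundary_potential(model, ph), tolerance = 1e-12)
  fit <- fit_partition_model(res$table$ph, res$table$potential, pka = 3.2,
                             conditions = cond20())
  expect_equal(fit$kd, 10, tolerance = 1e-6)

  # kd = 0 well below the pKa: constant at the formal potential
  flat <- simulate_ph_series(sys, ion_partition_model(0.242, 3.2, 0,
                                                      conditions = cond20()),
                             c(1, 1.25, 1.5), cation_label = "NIT+")
  expect_true(all(abs(flat$table$potential - 0.242) < 1e-3))

  # positive window wall: the signal is lost once the boundary crosses it
  cut <- simulate_ph_series(sys, model, ph, cation_label = "NIT+",
                            wall_positive = 0.45)
  expect_true(all(is.na(cut$table$potential[!cut$table$detectable])))
  expect_true(all(diff(cut$table$detectable) <= 0))  # once lost, stays lost
  expect_true(any(cut$table$detectable) && any(!cut$table$detectable))

  # potential noise is reproducible by seed
  n1 <- simulate_ph_series(sys, model, ph, cation_label = "NIT+",
                           noise_sd_potential = 2e-3, seed = 42)
  n2 <- simulate_ph_series(sys, model, ph, cation_label = "NIT+",
                           noise_sd_potential = 2e-3, seed = 42)
  expect_identical(n1$table$potential, n2$table$potential)
})

test_that("calibration tables are exact without noise and seeded with it", {
  conc <- macro_concentrations()
  tab <- simulate_calibration_table(0.375, conc, noise_sd = 0, intercept = 1.3)
  expect_equal(tab$signal, 0.375 * conc + 1.3, tolerance = 1e-15)

  t1 <- simulate_calibration_table(0.375, conc, noise_sd = 0.05, seed = 8)
  t2 <- simulate_calibration_table(0.375, conc, noise_sd = 0.05, seed = 8)
  expect_identical(t1$signal, t2$signal)

  expect_error(simulate_calibration_table(0.375, c(10, 10, 20)),
               class = "itieskit_invalid_input")
  # single concentration propagates to a typed singular-design error downstream
  one <- simulate_calibration_table(0.375, 10)
  expect_error(fit_calibration(rep(one$concentration, 3), rep(one$signal, 3)),
               class = "itieskit_singular_design")
})
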