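triangle_vg <- function(n_half = 100, vertex = 0.5, current = NULL) {
  pot <- c(seq(0, vertex, length.out = n_half), seq(vertex, 0, length.out = n_half))
  if (is.null(current)) current <- numeric(length(pot))
  voltammogram(pot, current, scan_rate = 0.02)
}

test_that("sweep segmentation splits a triangle and rejects degenerate programs", {
  v <- triangle_vg()
  segs <- segment_sweeps(v)
  expect_equal(length(segs$forward$potential), 100L)
  expect_equal(length(segs$backward$potential), 100L)
  expect_equal(max(segs$forward$potential), 0.5)

  # monotone ramp cannot be segmented
  ramp <- voltammogram(seq(0, 1, length.out = 50), numeric(50))
  expect_error(segment_sweeps(ramp), class = "itieskit_segmentation_error")

  # constant potential
  flat <- voltammogram(rep(0.1, 32), numeric(32))
  expect_error(segment_sweeps(flat), class = "itieskit_segmentation_error")

  # two cycles: first is used, with a warning
  two <- voltammogram(rep(c(seq(0, 0.5, length.out = 50),
                            seq(0.5, 0, length.out = 50)), 2), numeric(200))
  expect_warning(segs2 <- segment_sweeps(two), "first cycle")
  expect_equal(length(segs2$forward$potential) + length(segs2$backward$potential), 100L)
})

test_that("reference correction shifts potentials exactly and preserves currents", {
  v <- triangle_vg(current = sin(seq_len(200) / 10) * 1e-6)

  # measured TPrA+ midpoint -120 mV against its assigned -160 mV
  shifted <- reference_correct(v, -0.120, -0.160)
  expect_equal(shifted$potential, v$potential - 0.040)
  expect_equal(shifted$current, v$current)

  # zero shift is the identity; opposite application inverts
  expect_equal(reference_correct(v, 0.1, 0.1)$potential, v$potential)
  back <- reference_correct(shifted, -0.160, -0.120)
  expect_equal(back$potential, v$potential, tolerance = 1e-15)
})

test_that("peak extraction on a simulated reversible transfer matches theory", {
  cond <- cond20()
  geom <- macro_geometry()
  sp <- transfer_species("NIT+", 1, 0.242, 14.1e-6, concentration = 20e-6)
  cfg <- sim_config(0, 0.55, scan_rate = 0.02, geometry = geom)
  v <- simulate_macro_itv(sp, cfg, cond, n_out = 5000)

  # window opens ~150 mV before the formal potential so the pre-peak
  # baseline region stays on the flat foot
  pk <- extract_peaks(v, c(0.10, 0.40))

  # midpoint potential within 2 mV of the formal transfer potential
  expect_lt(abs(pk$midpoint_potential - 0.242), 2e-3)

  # reversible peak separation 2.218 RT/F (~56 mV at 20 C) within 2 mV
  sep <- abs(pk$forward_peak_potential - pk$backward_peak_potential)
  expect_lt(abs(sep - 2.218 * cond$R * cond$temperature / cond$F), 2e-3)

  # forward peak current within 3% of the Randles-Sevcik value
  rs <- randles_sevcik_peak_current(1, geom$area, 2e-8, 14.1e-6, 0.02, cond)
  expect_lt(abs(pk$forward_peak_current - rs) / rs, 0.03)
  expect_true(pk$forward_peak_current > 0, pk$backward_peak_current < 0)
  expect_equal(pk$midpoint_potential,
               (pk$forward_peak_potential + pk$backward_peak_potential) / 2)
})

test_that("a blank trace raises a typed no-peak error", {
  cfg <- sim_config(0, 0.55, scan_rate = 0.02, geometry = macro_geometry(),
                    wall_negative = -0.05, wall_positive = 0.60,
                    wall_amplitude = 1e-6, capacitance = 1e-6)
  blank <- simulate_macro_itv(
    transfer_species("none", 1, 0.242, 14.1e-6, concentration = 0), cfg, cond20())
  expect_error(extract_peaks(blank, c(0.10, 0.40)), class = "itieskit_no_peak")
})

test_that("wave extraction recovers the steady-state current and flags non-plateaus", {
  cond <- cond20()
  sp <- transfer_species("TMA+", 1, 0.160, 13.8e-6, concentration = 50e-6)
  cfg <- sim_config(-0.05, 0.45, scan_rate = 0.02, geometry = micro_geometry(),
                    n_space = 150)
  v <- simulate_micro_itv(sp, cfg, cond, n_out = 4000)
  w <- extract_wave(v, c(0.33, 0.42))

  iss_true <- saito_current(12e-4, 1, 13.8e-6, 5e-8, cond)
  expect_lt(abs(w$i_ss - iss_true) / iss_true, 0.02)
  # half-wave sits above the formal potential for transfer into the pore
  expect_gt(w$half_wave_potential, 0.160)
  expect_lt(w$half_wave_potential, 0.260)

  # zero-current input is not a plateau
  flat <- triangle_vg()
  expect_error(extract_wave(flat, c(0.3, 0.4)), class = "itieskit_not_a_plateau")

  # window narrower than 3 samples is a precondition error
  expect_error(extract_wave(v, c(0.400, 0.4003)), class = "itieskit_invalid_input")
})

test_that("potential window width recovers the generator wall positions", {
  mk_blank <- function(neg, pos) {
    cfg <- sim_config(neg - 0.1, pos + 0.1, scan_rate = 0.02,
                      geometry = macro_geometry(), wall_negative = neg,
                      wall_positive = pos, wall_amplitude = 1e-6,
                      noise_sd = 5e-9, seed = 11)
    simulate_macro_itv(transfer_species("none", 1, 0, 1e-5, concentration = 0),
                       cfg, cond20())
  }
  # model aqueous phase: walls at -0.25 / +0.55 V -> ~0.80 V window
  expect_equal(potential_window_width(mk_blank(-0.25, 0.55), 1e-6), 0.80,
               tolerance = 0.03)
  # urine-like matrix: walls at -0.20 / +0.40 V -> ~0.60 V window
  expect_equal(potential_window_width(mk_blank(-0.20, 0.40), 1e-6), 0.60,
               tolerance = 0.03)
  # threshold far above the walls: the whole forward scan qualifies
  b <- mk_blank(-0.25, 0.55)
  fwd <- segment_sweeps(b)$forward
  expect_equal(potential_window_width(b, 1), diff(range(fwd$potential)),
               tolerance = 1e-9)
})

# analytic gaussian-peak trace generator for fast detection tests
spike_vg <- function(amplitude, center = 0.24, noise_sd = 2e-9, seed = 5,
                     width = 0.03) {
  pot <- c(seq(0, 0.5, length.out = 250), seq(0.5, 0, length.out = 250))
  set.seed(seed)
  cur <- amplitude * exp(-(pot - center)^2 / (2 * width^2)) *
    c(rep(1, 250), rep(-0.8, 250)) + rnorm(500, 0, noise_sd)
  voltammogram(pot, cur, scan_rate = 0.02)
}

test_that("binary presence calls respond to amplitude and position", {
  blank <- spike_vg(0, seed = 5)
  expect_equal(detect_analyte(blank, blank, 0.24, 0.05), 0L)

  # spike 10x the noise SD at the expected potential
  expect_equal(detect_analyte(spike_vg(2e-8, seed = 6), blank, 0.24, 0.05), 1L)

  # same spike displaced 200 mV outside the tolerance window (paired with
  # the blank noise realization, as in a blank-subtracted measurement)
  displaced <- spike_vg(2e-8, center = 0.44, seed = 5)
  expect_equal(detect_analyte(displaced, blank, 0.24, 0.05), 0L)

  # monotone in amplitude under a fixed noise realization
  amps <- c(0, 1e-9, 5e-9, 2e-8, 1e-7)
  calls <- vapply(amps, function(a)
    detect_analyte(spike_vg(a, seed = 9), blank, 0.24, 0.05), integer(1))
  expect_true(all(diff(calls) >= 0))

  # non-overlapping grids are an alignment error
  far <- voltammogram(c(seq(2, 2.5, length.out = 50), seq(2.5, 2, length.out = 50)),
                      numeric(100))
  expect_error(detect_analyte(far, blank, 0.24, 0.05),
               class = "itieskit_alignment_error")
})

test_that("moving-average smoothing preserves length and flat signals", {
  v <- spike_vg(1e-8, seed = 3)
  sm <- smooth_voltammogram(v, 5)
  expect_equal(length(sm$current), length(v$current))
  flat <- voltammogram(c(seq(0, 1, length.out = 20), seq(1, 0, length.out = 20)),
                       rep(2e-9, 40))
  expect_equal(smooth_voltammogram(flat, 5)$current, rep(2e-9, 40))
  expect_error(smooth_voltammogram(v, 4), class = "itieskit_invalid_input")
})
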