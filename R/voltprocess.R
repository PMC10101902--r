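# Voltammogram signal processing: sweep segmentation, baseline-corrected
# peak/wave extraction, internal-reference correction, potential-window
# width, and binary presence calls.

#' Split a triangular-sweep voltammogram into forward and backward segments
#'
#' The split point is the potential extremum of the first cycle.  If the
#' potential program contains more than one cycle, only the first is used
#' and a warning is raised; a monotone (non-triangular) potential series is
#' an error.
#'
#' @param v A [voltammogram()].
#' @return A list with elements `forward` and `backward`, each a list with
#'   `potential`, `current` and the original sample `index`.
#' @export
segment_sweeps <- function(v) {
  stopifnot(inherits(v, "voltammogram"))
  pot <- v$potential
  d <- diff(pot)
  s <- sign(d)
  if (all(s == 0)) ities_error("potential series is constant; cannot segment sweeps",
                               "itieskit_segmentation_error")
  # forward-fill zero slopes with the previous direction
  if (s[1] == 0) s[1] <- s[s != 0][1]
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  turns <- which(s[-1] != s[-length(s)]) + 1L  # sample index starting a new direction
  if (length(turns) == 0L)
    ities_error("potential series is monotone; a triangular sweep is required",
                "itieskit_segmentation_error")
  if (length(turns) > 1L)
    warning("potential program contains multiple sweep cycles; using the first cycle")
  end1 <- turns[1] - 1L
  end2 <- if (length(turns) > 1L) turns[2] - 1L else length(pot)
  seg <- function(idx) list(potential = pot[idx], current = v$current[idx], index = idx)
  list(forward = seg(seq_len(end1)), backward = seg(seq.int(end1 + 1L, end2)))
}

# Robust noise SD: median absolute deviation (scaled to SD) of linearly
# detrended current.  stats::mad already applies the 1.4826 factor.
estimate_noise_sd <- function(potential, current) {
  if (length(current) < 5L) return(0)
  r <- stats::resid(stats::lm(current ~ potential))
  stats::mad(r, center = 0)
}

# Linear baseline over the pre-feature 30% of a segment; returns a function
# of potential plus the residual noise SD of the baseline region.
pre_feature_baseline <- function(seg, first_in, method) {
  pre_idx <- seq_len(max(first_in - 1L, 0L))
  k <- ceiling(0.3 * length(seg$potential))
  if (length(pre_idx) > k) pre_idx <- pre_idx[seq.int(length(pre_idx) - k + 1L, length(pre_idx))]
  noise_sd <- if (length(pre_idx) >= 5L)
    estimate_noise_sd(seg$potential[pre_idx], seg$current[pre_idx]) else 0
  if (method == "none" || length(pre_idx) < 3L) {
    return(list(predict = function(p) rep(0, length(p)), noise_sd = noise_sd,
                region = pre_idx))
  }
  fit <- stats::lm(current ~ potential,
                   data = list(current = seg$current[pre_idx], potential = seg$potential[pre_idx]))
  list(predict = function(p) unname(coef(fit)[1] + coef(fit)[2] * p),
       noise_sd = noise_sd, region = pre_idx)
}

#' Extract the forward/backward peak pair from a cyclic voltammogram
#'
#' Finds the baseline-corrected forward maximum and backward minimum inside a
#' potential search window.  The baseline is a least-squares line over (up
#' to) the 30% of the segment immediately preceding the window in scan
#' direction; residual noise in that region gates peak acceptance: an
#' extremum must exceed 3x the local noise SD, otherwise a no-peak error is
#' raised (the "absent signal" pathway of [detect_analyte()]).
#'
#' @param v A [voltammogram()].
#' @param search_window Numeric length-2 potential interval (V) inside the
#'   scanned range.
#' @param baseline `"linear_pre_peak"` (default) or `"none"`.
#' @return An object of class `peak_measurement`: forward/backward peak
#'   potentials (V) and baseline-corrected currents (A), the midpoint
#'   potential, and the baseline method used.
#' @export
extract_peaks <- function(v, search_window,
                          baseline = c("linear_pre_peak", "none")) {
  baseline <- match.arg(baseline)
  segs <- segment_sweeps(v)
  win <- sort(as.numeric(search_window))
  if (length(win) != 2L || anyNA(win)) abort_invalid("`search_window` must be 2 finite potentials")
  rng <- range(v$potential)
  if (win[1] < rng[1] - 1e-12 || win[2] > rng[2] + 1e-12)
    abort_invalid("search window must lie inside the scanned potential range")

  one <- function(seg, sense) {
    inwin <- seg$potential >= win[1] & seg$potential <= win[2]
    if (sum(inwin) < 3L) abort_invalid("fewer than 3 samples inside the search window")
    first_in <- which(inwin)[1]
    bl <- pre_feature_baseline(seg, first_in, baseline)
    corr <- seg$current[inwin] - bl$predict(seg$potential[inwin])
    i <- if (sense > 0) which.max(corr) else which.min(corr)
    height <- sense * corr[i]
    if (!(height > 3 * bl$noise_sd) || height <= 0)
      ities_error(sprintf("no %s peak exceeding 3x the local noise SD (%.3g A) in the window",
                          if (sense > 0) "forward" else "backward", bl$noise_sd),
                  "itieskit_no_peak")
    list(potential = seg$potential[inwin][i], current = corr[i], noise_sd = bl$noise_sd)
  }
  fwd <- one(segs$forward, +1)
  bwd <- one(segs$backward, -1)
  structure(
    list(forward_peak_potential = fwd$potential,
         forward_peak_current = fwd$current,
         backward_peak_potential = bwd$potential,
         backward_peak_current = bwd$current,
         midpoint_potential = (fwd$potential + bwd$potential) / 2,
         noise_sd = max(fwd$noise_sd, bwd$noise_sd),
         baseline_method = baseline),
    class = "peak_measurement"
  )
}

#' @export
print.peak_measurement <- function(x, ...) {
  cat(sprintf("Peaks: forward %.1f mV / %.4g A; backward %.1f mV / %.4g A\n",
              1e3 * x$forward_peak_potential, x$forward_peak_current,
              1e3 * x$backward_peak_potential, x$backward_peak_current))
  cat(sprintf("  midpoint %.1f mV, separation %.1f mV, baseline '%s'\n",
              1e3 * x$midpoint_potential,
              1e3 * abs(x$forward_peak_potential - x$backward_peak_potential),
              x$baseline_method))
  invisible(x)
}

#' Extract a steady-state wave from a micro-interface voltammogram
#'
#' The steady-state current is the mean baseline-corrected forward current
#' over a plateau window; the half-wave potential is where the corrected
#' forward current first crosses half of it.  The baseline is a line fitted
#' to the first 30% of the forward segment (the pre-wave foot).  If the
#' corrected current still slopes by more than 10% of the steady-state value
#' per 100 mV across the window — or the plateau is not positive — a
#' not-a-plateau error is raised.
#'
#' @param v A [voltammogram()].
#' @param plateau_window Numeric length-2 potential interval (V) on the
#'   plateau; must cover at least 3 samples of the forward segment.
#' @return An object of class `wave_measurement` with `i_ss` (A) and
#'   `half_wave_potential` (V).
#' @export
extract_wave <- function(v, plateau_window) {
  segs <- segment_sweeps(v)
  fwd <- segs$forward
  win <- sort(as.numeric(plateau_window))
  if (length(win) != 2L || anyNA(win)) abort_invalid("`plateau_window` must be 2 finite potentials")
  if (win[1] < min(fwd$potential) - 1e-12 || win[2] > max(fwd$potential) + 1e-12)
    abort_invalid("forward segment does not cover the plateau window")
  inwin <- fwd$potential >= win[1] & fwd$potential <= win[2]
  if (sum(inwin) < 3L) abort_invalid("plateau window narrower than 3 samples")

  # Baseline: straight line over the pre-wave region, defined as the part of
  # the forward segment scanned at least 150 mV (about 6 RT/F) before the raw
  # half-wave crossing, where a reversible wave contributes < 0.3% of the
  # plateau.  The crossing is located on a lightly smoothed trace so current
  # noise cannot truncate the region.  Falls back to no baseline correction
  # when fewer than 5 pre-wave samples exist.
  i_raw <- mean(fwd$current[inwin])
  csm <- as.numeric(stats::filter(fwd$current, rep(0.2, 5), sides = 2))
  csm[is.na(csm)] <- fwd$current[is.na(csm)]
  cross <- which(csm >= i_raw / 2)[1]
  pre_idx <- if (is.na(cross)) integer(0) else
    which(seq_along(fwd$potential) < cross &
            abs(fwd$potential - fwd$potential[cross]) >= 0.15)
  corr <- if (length(pre_idx) >= 5L) {
    fit <- stats::lm(current ~ potential,
                     data = list(current = fwd$current[pre_idx], potential = fwd$potential[pre_idx]))
    fwd$current - unname(coef(fit)[1] + coef(fit)[2] * fwd$potential)
  } else fwd$current

  i_ss <- mean(corr[inwin])
  pl_fit <- stats::lm(y ~ x, data = list(y = corr[inwin], x = fwd$potential[inwin]))
  pl_slope <- unname(coef(pl_fit)[2])   # A per V
  if (!(i_ss > 0) || abs(pl_slope) * 0.1 > 0.1 * i_ss)
    ities_error("selected window is not a steady-state plateau (zero or sloping current)",
                "itieskit_not_a_plateau")

  half <- i_ss / 2
  cross <- which(corr[-1] >= half & corr[-length(corr)] < half)
  half_wave <- if (length(cross)) {
    j <- cross[1]
    p1 <- fwd$potential[j]; p2 <- fwd$potential[j + 1]
    c1 <- corr[j]; c2 <- corr[j + 1]
    p1 + (half - c1) / (c2 - c1) * (p2 - p1)
  } else NA_real_

  structure(list(i_ss = i_ss, half_wave_potential = half_wave,
                 plateau_window = win),
            class = "wave_measurement")
}

#' @export
print.wave_measurement <- function(x, ...) {
  cat(sprintf("Wave: I_ss = %.4g A, half-wave potential = %.1f mV\n",
              x$i_ss, 1e3 * x$half_wave_potential))
  invisible(x)
}

#' Re-anchor the potential scale with an internal reference ion
#'
#' Shifts the whole potential axis by
#' `reference_formal_potential - reference_midpoint_measured`, so the
#' measured midpoint of the reference ion (e.g. TPrA+ assigned -160 mV)
#' lands on its assigned formal transfer potential.  Currents are untouched.
#'
#' @param v A [voltammogram()].
#' @param reference_midpoint_measured Measured reference-ion midpoint, V.
#' @param reference_formal_potential Assigned reference formal potential, V.
#' @return The shifted `voltammogram`.
#' @export
reference_correct <- function(v, reference_midpoint_measured,
                              reference_formal_potential) {
  stopifnot(inherits(v, "voltammogram"))
  check_scalar(reference_midpoint_measured, "reference_midpoint_measured")
  check_scalar(reference_formal_potential, "reference_formal_potential")
  shift <- reference_formal_potential - reference_midpoint_measured
  out <- v
  out$potential <- v$potential + shift
  out$metadata$reference_shift_V <- shift
  out
}

#' Width of the usable potential window of a blank voltammogram
#'
#' The largest contiguous potential interval of the forward sweep where the
#' absolute current stays below `current_threshold` — i.e. the range not yet
#' dominated by background-electrolyte transfer at the window walls.
#'
#' @param blank A blank [voltammogram()].
#' @param current_threshold Current magnitude threshold, A; should exceed the
#'   baseline noise SD.
#' @return Window width in volts (0, with a warning, if no sample is below
#'   threshold).
#' @export
potential_window_width <- function(blank, current_threshold) {
  stopifnot(inherits(blank, "voltammogram"))
  check_scalar(current_threshold, "current_threshold", positive = TRUE)
  fwd <- segment_sweeps(blank)$forward
  ok <- abs(fwd$current) < current_threshold
  if (!any(ok)) {
    warning("no potential region below the current threshold; returning width 0")
    return(0)
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  widths <- vapply(true_runs, function(i)
    abs(fwd$potential[ends[i]] - fwd$potential[starts[i]]), numeric(1))
  max(widths)
}

#' Binary presence call for an analyte signal against a blank
#'
#' Interpolates the blank's forward sweep onto the sample's potential grid,
#' subtracts it, and calls the analyte present (1) when the blank-subtracted
#' forward current within `expected_potential +/- tolerance` exceeds 3x the
#' blank's local noise SD, else absent (0).  A stated screening heuristic
#' mirroring qualitative real-sample analysis, not a validated classifier.
#'
#' @param sample,blank [voltammogram()] objects with overlapping potential
#'   ranges (the blank is resampled onto the sample grid).
#' @param expected_potential Expected transfer potential, V.
#' @param tolerance Half-width of the search window, V.
#' @return Integer 0 or 1.
#' @export
detect_analyte <- function(sample, blank, expected_potential, tolerance) {
  stopifnot(inherits(sample, "voltammogram"), inherits(blank, "voltammogram"))
  check_scalar(expected_potential, "expected_potential")
  check_scalar(tolerance, "tolerance", positive = TRUE)
  sf <- segment_sweeps(sample)$forward
  bf <- segment_sweeps(blank)$forward
  lo <- max(min(sf$potential), min(bf$potential))
  hi <- min(max(sf$potential), max(bf$potential))
  if (hi <= lo)
    ities_error("sample and blank potential ranges do not overlap",
                "itieskit_alignment_error")
  bl <- stats::approx(bf$potential, bf$current, xout = sf$potential, rule = 1,
                      ties = mean)$y
  diffc <- sf$current - bl
  inwin <- abs(sf$potential - expected_potential) <= tolerance & !is.na(diffc)
  if (sum(inwin) < 3L)
    ities_error("expected-potential window does not overlap the common potential grid",
                "itieskit_alignment_error")
  # local noise of the blank around the window (3x the window half width)
  near <- abs(bf$potential - expected_potential) <= 3 * tolerance
  noise <- if (sum(near) >= 5L)
    estimate_noise_sd(bf$potential[near], bf$current[near])
  else estimate_noise_sd(bf$potential, bf$current)
  stat <- max(diffc[inwin])
  as.integer(stat > 3 * noise && stat > 0)
}
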