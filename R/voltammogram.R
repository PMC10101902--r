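#' Voltammogram container
#'
#' A cyclic (triangular-sweep) ion-transfer voltammogram: a potential series
#' (V) and a current series (A) of equal length, with the scan rate and free-
#' form metadata (pH, analyte, concentration, cell kind, phase composition).
#'
#' @param potential Applied Galvani potential difference series, volts.
#' @param current Current series, amperes; same length as `potential`.
#' @param scan_rate Scan rate, V s^-1.
#' @param metadata Named list of free-form metadata.
#' @return An object of class `voltammogram`.
#' @export
voltammogram <- function(potential, current, scan_rate = NA_real_,
                         metadata = list()) {
  if (!is.numeric(potential) || !is.numeric(current))
    abort_invalid("`potential` and `current` must be numeric")
  if (length(potential) != length(current))
    abort_invalid("`potential` and `current` must have the same length")
  if (length(potential) < 16L)
    abort_invalid("a voltammogram needs at least 16 samples")
  if (anyNA(potential) || any(!is.finite(potential)))
    abort_invalid("`potential` must be finite")
  structure(
    list(potential = as.numeric(potential), current = as.numeric(current),
         scan_rate = scan_rate, metadata = metadata),
    class = "voltammogram"
  )
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("Voltammogram: %d samples, %.3f .. %.3f V", length(x$potential),
              min(x$potential), max(x$potential)))
  if (is.finite(x$scan_rate)) cat(sprintf(", scan rate %g V/s", x$scan_rate))
  cat("\n")
  if (length(x$metadata)) {
    keys <- names(x$metadata)
    vals <- vapply(x$metadata, function(v) paste(format(v), collapse = " "), "")
    cat(paste0("  ", keys, ": ", vals, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
plot.voltammogram <- function(x, xlab = "Galvani potential difference / V",
                              ylab = "current / A", type = "l", ...) {
  graphics::plot(x$potential, x$current, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
length.voltammogram <- function(x) length(x$potential)

#' @export
as.data.frame.voltammogram <- function(x, ...) {
  data.frame(potential = x$potential, current = x$current)
}

#' Moving-average smoothing of a voltammogram
#'
#' Adjacent-averaging with a centered window (default 5 points), the common
#' instrument-software smoother for micro-interface traces.  Endpoints keep
#' the largest centered window that fits.
#'
#' @param v A [voltammogram()].
#' @param n Odd window length in points.
#' @return A smoothed `voltammogram`.
#' @export
smooth_voltammogram <- function(v, n = 5L) {
  stopifnot(inherits(v, "voltammogram"))
  n <- as.integer(n)
  if (n < 1L || n %% 2L == 0L) abort_invalid("`n` must be a positive odd integer")
  if (n == 1L) return(v)
  cur <- v$current
  sm <- as.numeric(stats::filter(cur, rep(1 / n, n), sides = 2))
  half <- (n - 1L) %/% 2L
  len <- length(cur)
  for (i in seq_len(half)) {
    sm[i] <- mean(cur[1:(2 * i - 1)])
    sm[len - i + 1L] <- mean(cur[(len - 2 * i + 2L):len])
  }
  out <- v
  out$current <- sm
  out$metadata$smoothing <- sprintf("moving_average_%d", n)
  out
}
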