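#' Evenly sampled signal
#'
#' Container for an evenly sampled series: a tachogram (RR intervals on a
#' uniform grid, in ms) or a respiration waveform (arbitrary units). All
#' separation algorithms in this package operate on pairs of
#' `uniform_signal` objects sharing a sampling rate.
#'
#' @param samples Numeric vector of samples; all finite, length >= 2.
#' @param fs Sampling rate in Hz (default 4, the rate used throughout the
#'   separation pipeline).
#' @param units Unit label, `"ms"` for tachograms, `"au"` for respiration.
#' @param t0 Start time of the first sample, in seconds.
#' @return An object of class `uniform_signal`.
#' @examples
#' s <- uniform_signal(sin(2 * pi * 0.25 * seq(0, 60, by = 0.25)), fs = 4)
#' length(s$samples)
#' @export
uniform_signal <- function(samples, fs = 4, units = "au", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("uniform_signal needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("uniform_signal samples must all be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, units = as.character(units)[1L],
         t0 = as.numeric(t0)[1L]),
    class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("uniform_signal: %d samples @ %g Hz [%s], t0 = %g s (%.1f s)\n",
              length(x$samples), x$fs, x$units, x$t0,
              (length(x$samples) - 1L) / x$fs))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$samples)

#' Sample times of a uniform signal
#'
#' @param x A [uniform_signal()].
#' @return Numeric vector of sample instants in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

# internal: check two signals are comparable
check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$fs, b$fs)))
    stop("signals have different sampling rates", call. = FALSE)
  if (length(a$samples) != length(b$samples))
    stop("signals have different lengths", call. = FALSE)
  invisible(TRUE)
}

#' Beat series (RR intervals or beat times)
#'
#' Holds a raw beat-to-beat series before resampling. Either RR intervals in
#' milliseconds or strictly increasing beat instants in seconds may be given;
#' the other representation is derived. RR intervals outside the
#' physiological guard range \[200, 3000\] ms are flagged (with a warning and
#' a logical mask in `$guard_mask`), never silently dropped: ectopic-beat
#' correction is out of scope and left to the user.
#'
#' @param rr RR intervals in ms (strictly positive). Mutually exclusive with
#'   `beat_times`.
#' @param beat_times Strictly increasing beat instants in seconds.
#' @param guard_range Length-2 numeric, RR guard range in ms.
#' @return An object of class `beat_series` with fields `rr` (ms),
#'   `beat_times` (s) and `guard_mask` (TRUE where RR is outside the guard
#'   range).
#' @export
beat_series <- function(rr = NULL, beat_times = NULL,
                        guard_range = c(200, 3000)) {
  if (is.null(rr) == is.null(beat_times))
    stop("supply exactly one of rr or beat_times", call. = FALSE)
  if (is.null(rr)) {
    beat_times <- as.numeric(beat_times)
    if (anyNA(beat_times) || any(diff(beat_times) <= 0))
      stop("beat times must be strictly increasing", call. = FALSE)
    rr <- diff(beat_times) * 1000
    rr <- c(rr[1L], rr)  # first beat carries its following interval
  } else {
    rr <- as.numeric(rr)
    if (anyNA(rr) || any(rr <= 0))
      stop("RR intervals must be strictly positive", call. = FALSE)
    beat_times <- cumsum(c(0, rr[-1L])) / 1000
  }
  mask <- rr < guard_range[1L] | rr > guard_range[2L]
  if (any(mask))
    warning(sprintf("%d RR interval(s) outside guard range [%g, %g] ms",
                    sum(mask), guard_range[1L], guard_range[2L]),
            call. = FALSE)
  structure(list(rr = rr, beat_times = beat_times, guard_mask = mask),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("beat_series: %d beats over %.1f s, mean RR %.0f ms (%d flagged)\n",
              length(x$rr), diff(range(x$beat_times)), mean(x$rr),
              sum(x$guard_mask)))
  invisible(x)
}

#' Build a uniformly resampled tachogram from a beat series
#'
#' The RR value at each beat instant is interpolated by a natural cubic
#' spline onto a uniform grid spanning the beat span (no extrapolation
#' outside the first/last beat). 4 Hz is the conventional rate for HRV
#' spectral analysis and the default everywhere in this package.
#'
#' @param beats A [beat_series()], or a numeric vector of RR intervals (ms).
#' @param fs Target sampling rate in Hz.
#' @return A `"ms"`-unit [uniform_signal()] anchored at the first beat.
#' @examples
#' b <- beat_series(rr = 1000 + 50 * sin(2 * pi * 0.1 * (1:120)))
#' t4 <- build_tachogram(b)
#' @export
build_tachogram <- function(beats, fs = 4) {
  if (is.numeric(beats)) beats <- beat_series(rr = beats)
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$rr) < 4L)
    stop("need at least 4 beats to build a tachogram", call. = FALSE)
  tt <- beats$beat_times
  grid <- seq(tt[1L], tt[length(tt)], by = 1 / fs)
  f <- stats::splinefun(tt, beats$rr, method = "natural")
  uniform_signal(f(grid), fs = fs, units = "ms", t0 = tt[1L])
}

#' Zero-phase high-pass filter for respiration signals
#'
#' Removes baseline wander below `cutoff` with a 4th-order Butterworth
#' high-pass applied forward and backward (zero phase, so respiratory-to-RSA
#' delay estimates downstream are not distorted).
#'
#' @param r A [uniform_signal()].
#' @param cutoff High-pass cutoff in Hz (default 0.05).
#' @param order Butterworth order of the one-way filter.
#' @return The filtered [uniform_signal()].
#' @export
highpass_respiration <- function(r, cutoff = 0.05, order = 4) {
  stopifnot(inherits(r, "uniform_signal"))
  nyq <- r$fs / 2
  if (cutoff >= nyq)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  if (r$fs <= 2 * cutoff)
    stop("sampling rate too low for this cutoff", call. = FALSE)
  bw <- signal::butter(order, cutoff / nyq, type = "high")
  y <- signal::filtfilt(bw, r$samples - mean(r$samples))
  uniform_signal(y, fs = r$fs, units = r$units, t0 = r$t0)
}

#' Normalized root-mean-squared error
#'
#' RMSE of (estimate - reference) divided by the range of the reference
#' signal. This is the time-domain evaluation measure used by the benchmark
#' studies.
#'
#' @param estimate,reference [uniform_signal()]s of equal length, or plain
#'   numeric vectors.
#' @return Non-negative scalar.
#' @examples
#' nrmse(c(0.5, 1.5), c(0, 1))  # 0.5
#' @export
nrmse <- function(estimate, reference) {
  e <- if (inherits(estimate, "uniform_signal")) estimate$samples else as.numeric(estimate)
  r <- if (inherits(reference, "uniform_signal")) reference$samples else as.numeric(reference)
  if (length(e) != length(r))
    stop("estimate and reference must have equal length", call. = FALSE)
  rng <- max(r) - min(r)
  if (rng <= 0)
    stop("reference signal has zero range", call. = FALSE)
  sqrt(mean((e - r)^2)) / rng
}

#' Read RR intervals from a single-column text file
#'
#' One RR interval in milliseconds per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @return A [beat_series()].
#' @export
read_rr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rr <- suppressWarnings(as.numeric(lines))
  if (anyNA(rr))
    stop("non-numeric entries in RR file: ", path, call. = FALSE)
  beat_series(rr = rr)
}

#' Read a respiration waveform from a two-column CSV
#'
#' Columns: time in seconds, value (arbitrary units). If the time column is
#' not uniform, the signal is cubic-spline resampled at `fs`.
#'
#' @param path File path.
#' @param fs Target sampling rate if resampling is needed.
#' @return A [uniform_signal()] in `"au"`.
#' @export
read_respiration <- function(path, fs = 4) {
  d <- utils::read.csv(path, header = TRUE)
  if (ncol(d) < 2L)
    stop("expected a two-column CSV (time, value): ", path, call. = FALSE)
  tt <- as.numeric(d[[1L]]); v <- as.numeric(d[[2L]])
  if (anyNA(tt) || anyNA(v))
    stop("non-numeric entries in respiration file: ", path, call. = FALSE)
  dt <- diff(tt)
  if (any(dt <= 0))
    stop("time column must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1L])) < 1e-9 * dt[1L]) {
    uniform_signal(v, fs = 1 / dt[1L], units = "au", t0 = tt[1L])
  } else {
    grid <- seq(tt[1L], tt[length(tt)], by = 1 / fs)
    uniform_signal(stats::splinefun(tt, v, method = "natural")(grid),
                   fs = fs, units = "au", t0 = tt[1L])
  }
}

#' Write a separation result to CSV
#'
#' Columns: `time` (s), `original`, `respiratory`, `residual`.
#'
#' @param result A [separation_result()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_separation_csv <- function(result, path) {
  stopifnot(inherits(result, "separation_result"))
  d <- data.frame(
    time = signal_times(result$original),
    original = result$original$samples,
    respiratory = result$respiratory$samples,
    residual = result$residual$samples)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
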