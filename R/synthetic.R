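#' Synthetic cohort configuration
#'
#' Parameters of the ground-truth cardiorespiratory generator. The defaults
#' emulate a 6-minute seated baseline recording at 4 Hz: narrowband
#' respiration drifting inside 0.2-0.3 Hz with slow amplitude modulation; a
#' respiratory sinus arrhythmia (RSA) component produced by a short FIR
#' kernel acting on respiration (delayed vagal response, total gain ~40 ms,
#' a typical resting RSA amplitude); and an independent residual made of a
#' ~0.1 Hz oscillation (~30 ms, the Mayer-wave / baroreflex rhythm of the LF
#' band) plus AR(1) colored noise (pole 0.9, ~10 ms, 1/f-like background).
#' The tachogram is mean_rr_ms + RSA + residual. The residual stream is
#' generated independently of respiration so ground-truth separability is
#' well defined.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @param resp_rate_hz Length-2 range of the instantaneous breathing rate.
#' @param resp_rate_jitter Standard deviation of the slow rate drift (Hz).
#' @param rsa_kernel FIR kernel (<= 12 taps) mapping respiration to RSA;
#'   normalized internally to unit absolute sum so `rsa_gain_ms` sets the
#'   component's scale.
#' @param rsa_gain_ms RSA amplitude scale in ms.
#' @param lf_osc_hz Frequency of the residual's LF oscillation.
#' @param lf_gain_ms Amplitude of the LF oscillation in ms.
#' @param noise_sd_ms Standard deviation of the AR(1) noise in ms.
#' @param mean_rr_ms Mean RR interval in ms.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20, duration_s = 360, fs = 4,
                          resp_rate_hz = c(0.2, 0.3),
                          resp_rate_jitter = 0.02,
                          rsa_kernel = c(0.35, 0.3, 0.2, 0.1, 0.05),
                          rsa_gain_ms = 40, lf_osc_hz = 0.1,
                          lf_gain_ms = 30, noise_sd_ms = 10,
                          mean_rr_ms = 900, seed = 2014) {
  stopifnot(duration_s > 0, fs > 0,
            abs(duration_s * fs - round(duration_s * fs)) < 1e-9,
            length(resp_rate_hz) == 2, all(resp_rate_hz < fs / 2),
            length(rsa_kernel) <= 12, rsa_gain_ms >= 0, lf_gain_ms >= 0,
            noise_sd_ms >= 0, lf_osc_hz < fs / 2)
  structure(list(n_subjects = as.integer(n_subjects),
                 duration_s = duration_s, fs = fs,
                 resp_rate_hz = sort(resp_rate_hz),
                 resp_rate_jitter = resp_rate_jitter,
                 rsa_kernel = rsa_kernel / sum(abs(rsa_kernel)),
                 rsa_gain_ms = rsa_gain_ms, lf_osc_hz = lf_osc_hz,
                 lf_gain_ms = lf_gain_ms, noise_sd_ms = noise_sd_ms,
                 mean_rr_ms = mean_rr_ms, seed = as.integer(seed)),
            class = "cohort_config")
}

# smooth unit-variance low-pass noise (moving-average smoothed white noise)
.slow_noise <- function(n, smooth) {
  z <- stats::rnorm(n + 2 * smooth)
  z <- stats::filter(z, rep(1 / smooth, smooth), sides = 2)
  z <- z[(smooth + 1):(smooth + n)]
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0) z / s else z * 0
}

#' Generate a synthetic respiration signal
#'
#' Narrowband oscillation whose instantaneous frequency drifts slowly inside
#' `cfg$resp_rate_hz` (clipped random-walk style drift of standard deviation
#' `resp_rate_jitter`) with slow amplitude modulation, high-pass filtered at
#' 0.05 Hz so it is zero mean, as a recorded tidal-volume signal would be
#' after preprocessing.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#' @param amplitude Base amplitude (arbitrary units); 0 gives a zero signal.
#' @return A [uniform_signal()] in `"au"`.
#' @export
generate_respiration <- function(cfg, seed = cfg$seed, amplitude = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- round(cfg$duration_s * cfg$fs)
  set.seed(as.integer(seed))
  mid <- mean(cfg$resp_rate_hz)
  halfspan <- diff(cfg$resp_rate_hz) / 2
  drift <- if (cfg$resp_rate_jitter > 0 && halfspan > 0)
    pmin(pmax(.slow_noise(n, smooth = 8 * cfg$fs) * cfg$resp_rate_jitter,
              -halfspan), halfspan) else numeric(n)
  f_inst <- mid + drift
  phase <- 2 * pi * cumsum(f_inst) / cfg$fs
  am <- 1 + 0.2 * .slow_noise(n, smooth = 20 * cfg$fs)
  x <- amplitude * am * sin(phase + stats::runif(1, 0, 2 * pi))
  if (all(x == 0))
    return(uniform_signal(x + numeric(n), fs = cfg$fs, units = "au"))
  highpass_respiration(uniform_signal(x, fs = cfg$fs, units = "au"))
}

#' Generate one synthetic subject with known ground truth
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed for this subject.
#' @return Object of class `synthetic_subject`: `respiration`,
#'   `rsa_component` (ms), `residual_component` (ms), `tachogram`
#'   (mean_rr_ms + rsa + residual, ms), `truth` (generator parameters),
#'   `seed`.
#' @export
generate_subject <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- round(cfg$duration_s * cfg$fs)
  resp <- generate_respiration(cfg, seed = seed)
  # RSA: causal FIR of respiration
  k <- cfg$rsa_kernel * cfg$rsa_gain_ms
  rsa <- as.numeric(stats::filter(c(numeric(length(k) - 1), resp$samples),
                                  k, method = "convolution", sides = 1))
  rsa <- rsa[length(k):(length(k) + n - 1)]
  rsa[is.na(rsa)] <- 0
  # residual: LF oscillation + AR(1) noise, independent random stream
  set.seed(as.integer(seed) + 500000L)
  tt <- (seq_len(n) - 1) / cfg$fs
  lf <- cfg$lf_gain_ms * sin(2 * pi * cfg$lf_osc_hz * tt +
                               stats::runif(1, 0, 2 * pi))
  ar <- if (cfg$noise_sd_ms > 0) {
    z <- as.numeric(stats::arima.sim(list(ar = 0.9), n = n))
    cfg$noise_sd_ms * z / stats::sd(z)
  } else numeric(n)
  residual <- lf + ar
  tach <- cfg$mean_rr_ms + rsa + residual
  structure(list(
    respiration = resp,
    rsa_component = uniform_signal(rsa, fs = cfg$fs, units = "ms"),
    residual_component = uniform_signal(residual, fs = cfg$fs, units = "ms"),
    tachogram = uniform_signal(tach, fs = cfg$fs, units = "ms"),
    truth = cfg, seed = as.integer(seed)),
    class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("synthetic_subject (seed %d): %.0f s @ %g Hz, mean RR %.0f ms\n",
              x$seed, length(x$tachogram$samples) / x$tachogram$fs,
              x$tachogram$fs, mean(x$tachogram$samples)))
  cat(sprintf("  sd: rsa %.1f ms, residual %.1f ms\n",
              stats::sd(x$rsa_component$samples),
              stats::sd(x$residual_component$samples)))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are `cfg$seed + 1000 * i`; subject 1 is the designated
#' reference for the simulation study.
#'
#' @param cfg A [cohort_config()].
#' @return List of [generate_subject()] results, class `synthetic_cohort`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_subjects < 2L)
    stop("a cohort needs at least 2 subjects", call. = FALSE)
  subjects <- lapply(seq_len(cfg$n_subjects), function(i)
    generate_subject(cfg, seed = cfg$seed + 1000L * i))
  structure(subjects, class = "synthetic_cohort", config = cfg)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("synthetic_cohort: %d subjects, %.0f s @ %g Hz (seed %d)\n",
              length(x), cfg$duration_s, cfg$fs, cfg$seed))
  invisible(x)
}

#' Beat times from a continuous RR modulation (IPFM model)
#'
#' Integral pulse frequency modulation: a beat is emitted whenever the
#' integral of the instantaneous rate 1/RR(t) reaches 1. Used to turn a
#' synthetic subject's continuous tachogram into an RR series for
#' exercising [build_tachogram()].
#'
#' @param tachogram A [uniform_signal()] of RR values in ms.
#' @return A [beat_series()].
#' @export
ipfm_beats <- function(tachogram) {
  stopifnot(inherits(tachogram, "uniform_signal"))
  rr_s <- tachogram$samples / 1000
  fs <- tachogram$fs
  n <- length(rr_s)
  rate <- 1 / rr_s  # beats per second
  cum <- c(0, cumsum(rate) / fs)
  tt <- tachogram$t0 + (0:n) / fs
  beats <- stats::approx(cum, tt, xout = seq(0, floor(max(cum)), by = 1))$y
  beat_series(beat_times = beats)
}
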