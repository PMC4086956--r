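#' Welch power spectral density estimate
#'
#' Welch's averaged periodogram with the settings used throughout the HRV
#' feature extraction: the record is cut into `n_segments` equal sections
#' with 50% overlap (segment length floor(2N/(n_segments+1)) samples), each
#' section is demeaned, windowed with a periodic Hamming window and
#' transformed with an `nfft`-point FFT. The one-sided density is scaled so
#' that its trapezoidal integral approximates the signal variance.
#'
#' @param x A [uniform_signal()] or numeric vector (then `fs` is used).
#' @param fs Sampling rate, ignored when `x` is a [uniform_signal()].
#' @param nfft FFT length (default 1024).
#' @param n_segments Number of overlapping sections (default 8). If the
#'   record is too short for that many sections of at least 16 samples, the
#'   count is reduced with a warning.
#' @return Object of class `psd_estimate`: `freqs` (Hz), `density`
#'   (units^2/Hz), `fs`, `nfft`, `n_segments`, `segment_length`.
#' @export
welch_psd <- function(x, fs = 4, nfft = 1024, n_segments = 8) {
  if (inherits(x, "uniform_signal")) {
    fs <- x$fs
    v <- x$samples
  } else v <- as.numeric(x)
  n <- length(v)
  if (n < 16L)
    stop("record too short for spectral estimation", call. = FALSE)
  seg_len <- function(k) floor(2 * n / (k + 1))
  k <- n_segments
  while (k > 1L && seg_len(k) < 16L) k <- k - 1L
  if (k != n_segments)
    warning(sprintf("record too short for %d sections; using %d",
                    n_segments, k), call. = FALSE)
  L <- seg_len(k)
  hop <- floor(L / 2)
  # periodic Hamming window
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / L)
  nf <- max(nfft, L)
  half <- nf %/% 2 + 1L
  acc <- numeric(half)
  starts <- 1L + (0:(k - 1L)) * hop
  for (s in starts) {
    seg <- v[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- stats::fft(c(seg, numeric(nf - L)))
    pxx <- Mod(spec[seq_len(half)])^2 / (fs * sum(w^2))
    # fold the negative-frequency half onto the one-sided density
    if (nf %% 2 == 0) {
      pxx[2:(half - 1L)] <- 2 * pxx[2:(half - 1L)]
    } else {
      pxx[2:half] <- 2 * pxx[2:half]
    }
    acc <- acc + pxx
  }
  structure(list(freqs = (0:(half - 1L)) * fs / nf, density = acc / k,
                 fs = fs, nfft = nf, n_segments = k, segment_length = L),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "psd_estimate: Welch, %d x %d-sample sections (50%% overlap), nfft %d, 0-%g Hz\n",
    x$n_segments, x$segment_length, x$nfft, max(x$freqs)))
  invisible(x)
}

#' Band power from a PSD estimate
#'
#' Trapezoidal integral of the spectral density over \[lo, hi).
#'
#' @param psd A [welch_psd()] result.
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <= fs/2`.
#' @return Non-negative scalar power (units^2).
#' @export
band_power <- function(psd, lo, hi) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (!(lo >= 0 && lo < hi && hi <= psd$fs / 2 + 1e-12))
    stop("invalid band: need 0 <= lo < hi <= fs/2", call. = FALSE)
  sel <- psd$freqs >= lo & psd$freqs < hi
  f <- psd$freqs[sel]
  d <- psd$density[sel]
  if (length(f) < 2L) return(0)
  sum(diff(f) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
}

#' HRV spectral features
#'
#' Standard frequency-domain heart-rate-variability features from a Welch
#' PSD: low-frequency power LF (0.04-0.15 Hz), high-frequency power HF
#' (0.15-0.40 Hz), total power TP over the LF+HF span, normalized units
#' LFnu = LF/(LF+HF) and HFnu = HF/(LF+HF), and the LF/HF ratio. When
#' LF + HF is zero the normalized units and the ratio are `NA` (undefined,
#' not zero).
#'
#' @param x A [uniform_signal()] or numeric vector.
#' @param fs Sampling rate when `x` is a plain vector.
#' @param lf_band,hf_band Band edges in Hz.
#' @param tp_band Total-power band; defaults to the LF+HF span.
#' @param ... Forwarded to [welch_psd()].
#' @return Object of class `band_powers` with fields `lf`, `hf`, `tp`,
#'   `lf_nu`, `hf_nu`, `lf_hf_ratio`, `units`.
#' @export
hrv_features <- function(x, fs = 4, lf_band = c(0.04, 0.15),
                         hf_band = c(0.15, 0.40), tp_band = NULL, ...) {
  units <- if (inherits(x, "uniform_signal")) paste0(x$units, "^2") else "au^2"
  if (is.null(tp_band)) tp_band <- c(lf_band[1L], hf_band[2L])
  psd <- welch_psd(x, fs = fs, ...)
  lf <- band_power(psd, lf_band[1L], lf_band[2L])
  hf <- band_power(psd, hf_band[1L], hf_band[2L])
  tp <- band_power(psd, tp_band[1L], tp_band[2L])
  s <- lf + hf
  structure(list(
    lf = lf, hf = hf, tp = tp,
    lf_nu = if (s > 0) lf / s else NA_real_,
    hf_nu = if (s > 0) hf / s else NA_real_,
    lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
    units = units), class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf("band_powers [%s]: LF %.4g  HF %.4g  TP %.4g  LFnu %.3f  HFnu %.3f  LF/HF %.3f\n",
              x$units, x$lf, x$hf, x$tp, x$lf_nu, x$hf_nu, x$lf_hf_ratio))
  invisible(x)
}

#' @export
as.data.frame.band_powers <- function(x, ...) {
  data.frame(lf = x$lf, hf = x$hf, tp = x$tp, lf_nu = x$lf_nu,
             hf_nu = x$hf_nu, lf_hf_ratio = x$lf_hf_ratio)
}

#' Squared error of a band power between two signals
#'
#' The frequency-domain evaluation measure of the benchmark studies:
#' (P_band(estimate) - P_band(reference))^2 for the LF or HF band.
#'
#' @param est,ref [uniform_signal()]s with equal sampling rate.
#' @param band `"LF"` or `"HF"`.
#' @param ... Forwarded to [welch_psd()].
#' @return Non-negative scalar.
#' @export
power_squared_error <- function(est, ref, band = c("LF", "HF"), ...) {
  band <- match.arg(band)
  edges <- if (band == "LF") c(0.04, 0.15) else c(0.15, 0.40)
  if (inherits(est, "uniform_signal") && inherits(ref, "uniform_signal") &&
      !isTRUE(all.equal(est$fs, ref$fs)))
    stop("signals have different sampling rates", call. = FALSE)
  pe <- band_power(welch_psd(est, ...), edges[1L], edges[2L])
  pr <- band_power(welch_psd(ref, ...), edges[1L], edges[2L])
  (pe - pr)^2
}
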