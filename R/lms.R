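#' LMS adaptive filter configuration
#'
#' Defaults follow the 2 Hz design of the originating adaptive-filtering
#' work scaled to 4 Hz: filter length M = 126 taps and step size
#' mu = 0.1 x the stability bound of [lms_stability_bound()] (conservative
#' convergence). Both inputs are Savitzky-Golay smoothed (order 1, 5-sample
#' windows) before filtering; omitting this smoothing markedly degrades the
#' separation.
#'
#' @param n_taps Filter length M in samples.
#' @param mu Step size; `NULL` (default) means 0.1 x the stability bound
#'   computed from the respiration signal at run time.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window
#'   length applied to both inputs before filtering.
#' @param two_pass If `TRUE` (default) the filter is run twice: the first
#'   pass starts from zero weights to find converged coefficients over the
#'   whole record, the second pass re-runs the whole record starting from
#'   those coefficients.
#' @return An object of class `lms_config`.
#' @export
lms_config <- function(n_taps = 126, mu = NULL, sg_order = 1, sg_window = 5,
                       two_pass = TRUE) {
  stopifnot(n_taps >= 1, is.null(mu) || mu > 0)
  structure(list(n_taps = as.integer(n_taps), mu = mu,
                 sg_order = as.integer(sg_order),
                 sg_window = as.integer(sg_window),
                 two_pass = isTRUE(two_pass)),
            class = "lms_config")
}

#' LMS step-size stability bound
#'
#' Classical power-normalized bound on the LMS step size:
#' mu_max = 1 / ((M + 1) * P_r) with M the filter length and P_r the mean
#' power of the (smoothed) reference signal. Doubling the mean power halves
#' the bound; doubling the filter length approximately halves it.
#'
#' @param r Reference signal ([uniform_signal()] or numeric vector).
#' @param n_taps Filter length M.
#' @return Maximal admissible step size (positive scalar).
#' @export
lms_stability_bound <- function(r, n_taps) {
  v <- if (inherits(r, "uniform_signal")) r$samples else as.numeric(r)
  p <- mean(v^2)
  if (p <= 0)
    stop("reference signal has zero power", call. = FALSE)
  1 / ((n_taps + 1) * p)
}

# core LMS loop: returns list(y, w, err2). x is the (smoothed) reference,
# d the (smoothed) desired signal; w0 the initial weights.
.lms_run <- function(x, d, mu, w0) {
  n <- length(x)
  m <- length(w0)
  w <- w0
  y <- numeric(n)
  err2 <- numeric(n)
  xpad <- c(numeric(m - 1L), x)  # zero history before the first sample
  for (i in seq_len(n)) {
    xi <- xpad[(i + m - 1L):i]  # x(n), x(n-1), ..., x(n-M+1)
    y[i] <- sum(w * xi)
    e <- d[i] - y[i]
    err2[i] <- e * e
    w <- w + 2 * mu * e * xi
  }
  list(y = y, w = w, err2 = err2)
}

#' Separate the tachogram by LMS adaptive filtering of respiration
#'
#' The respiration signal is passed through an adaptive FIR filter whose
#' weights are updated by the least-mean-squares rule
#' w(n+1) = w(n) + 2 mu e(n) x(n), minimizing the mean-squared error between
#' the tachogram and the filter output; the converged output is the
#' respiratory component of the tachogram. Both inputs are Savitzky-Golay
#' smoothed first. With `two_pass`, the weights converged over the whole
#' record seed a second full-record pass, so the early samples are no longer
#' penalized by the zero initialization.
#'
#' @param t Tachogram ([uniform_signal()], ms).
#' @param r Respiration ([uniform_signal()], same grid).
#' @param cfg An [lms_config()].
#' @return A [separation_result()]; diagnostics carry the final weights
#'   (`weights`), per-sample squared error (`err2`) and the step size used.
#' @export
separate_lms <- function(t, r, cfg = lms_config()) {
  p <- as_signal_pair(t, r)
  stopifnot(inherits(cfg, "lms_config"))
  n <- length(p$t$samples)
  if (n < cfg$n_taps)
    stop("signal shorter than the LMS filter length", call. = FALSE)
  ts <- signal::sgolayfilt(p$t$samples, p = cfg$sg_order, n = cfg$sg_window)
  rs <- signal::sgolayfilt(p$r$samples, p = cfg$sg_order, n = cfg$sg_window)
  # adapt on the demeaned tachogram: the mean RR is not respiration-driven
  # and would otherwise dominate the error that drives the weight updates
  ts <- ts - mean(ts)
  bound <- lms_stability_bound(rs, cfg$n_taps)
  mu <- if (is.null(cfg$mu)) 0.1 * bound else cfg$mu
  if (mu >= bound)
    stop(sprintf("mu = %g exceeds the stability bound %g", mu, bound),
         call. = FALSE)
  pass1 <- .lms_run(rs, ts, mu, numeric(cfg$n_taps))
  final <- if (cfg$two_pass) .lms_run(rs, ts, mu, pass1$w) else pass1
  resp <- uniform_signal(final$y, fs = p$t$fs, units = p$t$units,
                         t0 = p$t$t0)
  separation_result(
    p$t, resp, method = "lms",
    params = list(n_taps = cfg$n_taps, mu = mu, sg_order = cfg$sg_order,
                  sg_window = cfg$sg_window, two_pass = cfg$two_pass),
    diagnostics = list(weights = final$w, err2 = final$err2,
                       stability_bound = bound))
}
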