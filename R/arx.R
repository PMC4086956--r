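#' Separate the tachogram with an FIR model of respiration
#'
#' Simplified ARMAX: the tachogram t(n) is modeled as a linear combination
#' of the current and the `order` previous respiration samples,
#' t(n) = sum_{k=0}^{p} b_k r(n-k) + residual. The coefficients are the
#' least-squares solution of the fully populated regressor rows (samples
#' p+1..N); fitted values over the whole record form the respiratory
#' component. The default order, 12 samples, corresponds to a delay of up to
#' 3 s at 4 Hz, long enough to capture all delayed respiratory effects on
#' the heart rate.
#'
#' The first `order` output samples are computed from zero-padded regressors
#' and flagged in `diagnostics$prefix_samples`; the benchmark studies
#' exclude them from their metrics.
#'
#' @param t Tachogram ([uniform_signal()], ms).
#' @param r Respiration ([uniform_signal()], same grid).
#' @param order Model order p (number of past samples; p+1 coefficients).
#' The least-squares fit carries an intercept that absorbs the mean RR; the
#' intercept is not part of the respiratory component (the mean heart rate
#' is not respiration-driven) and therefore stays in the residual.
#'
#' @return A [separation_result()]; diagnostics carry the coefficient
#'   vector `coeffs` (b_0..b_p), the fitted `intercept` and
#'   `prefix_samples = order`.
#' @examples
#' \dontrun{
#' res <- separate_armax(tachogram, respiration)  # order 12 at 4 Hz
#' res$diagnostics$coeffs
#' }
#' @export
separate_armax <- function(t, r, order = 12) {
  p <- as_signal_pair(t, r)
  n <- length(p$t$samples)
  order <- as.integer(order)
  if (n <= 4L * (order + 1L))
    stop("record too short for this model order", call. = FALSE)
  rv <- p$r$samples
  X <- sapply(0:order, function(k) c(numeric(k), rv[seq_len(n - k)]))
  rows <- (order + 1L):n  # fully populated regressor rows
  if (stats::sd(rv) == 0)
    warning("constant respiration signal: FIR fit is degenerate",
            call. = FALSE)
  # the fit carries an intercept absorbing the mean RR (not respiration-
  # driven, so it is excluded from the respiratory component and stays in
  # the residual); without it the large tachogram mean leaks into the
  # FIR coefficients through the regressors' small sample means
  qr_x <- qr(cbind(1, X[rows, , drop = FALSE]))
  if (qr_x$rank < order + 2L)
    warning("rank-deficient regressor; minimum-norm least-squares solution used",
            call. = FALSE)
  b <- qr.coef(qr_x, p$t$samples[rows])
  b[is.na(b)] <- 0  # unidentifiable directions -> minimum-norm choice
  resp <- uniform_signal(as.numeric(X %*% b[-1L]), fs = p$t$fs,
                         units = p$t$units, t0 = p$t$t0)
  separation_result(
    p$t, resp, method = "armax",
    params = list(order = order),
    diagnostics = list(coeffs = as.numeric(b[-1L]),
                       intercept = as.numeric(b[1L]),
                       prefix_samples = order))
}
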