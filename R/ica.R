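#' Separate the tachogram by two-channel independent component analysis
#'
#' Treats respiration r(n) and tachogram t(n) as a two-sensor mixture
#' \[r; t\] = A s of two independent sources: the respiratory component and
#' the residual. FastICA estimates the normalized (unit-variance) sources;
#' the source with the largest absolute correlation to the respiration is
#' labeled respiratory. Because ICA sources are scale-ambiguous, the
#' tachogram is regressed on the normalized sources (least squares via the
#' pseudoinverse, plus an intercept absorbing the mean RR) to recover the
#' scaling in ms; the respiratory component is the rescaled respiratory
#' source and the residual is forced to t - t_r so the decomposition
#' identity holds exactly.
#'
#' The method presupposes statistical independence between respiration and
#' the non-respiratory heart-rate variations, an assumption that does not
#' hold physiologically; it is included for comparison.
#'
#' @param t Tachogram ([uniform_signal()], ms).
#' @param r Respiration ([uniform_signal()], same grid).
#' @param seed Integer seed for the FastICA random initialization; the same
#'   seed gives bit-identical output.
#' @param max_restarts Additional attempts (with incremented seeds) before a
#'   convergence error is raised.
#' @return A [separation_result()]; diagnostics carry the mixing matrix,
#'   source-respiration correlations, scaling coefficients and the seed that
#'   succeeded.
#' @export
separate_ica <- function(t, r, seed = 1, max_restarts = 5) {
  p <- as_signal_pair(t, r)
  if (stats::sd(p$t$samples) == 0 || stats::sd(p$r$samples) == 0)
    stop("ICA needs non-constant inputs", call. = FALSE)
  X <- cbind(r = p$r$samples, t = p$t$samples)
  fit <- NULL
  last_err <- NULL
  for (k in 0:max_restarts) {
    set.seed(as.integer(seed) + k)
    fit <- tryCatch(ica::icafast(X, nc = 2, center = TRUE, maxit = 200,
                                 tol = 1e-6),
                    error = function(e) e)
    if (!inherits(fit, "error") && all(is.finite(fit$S))) {
      seed_used <- as.integer(seed) + k
      break
    }
    last_err <- if (inherits(fit, "error")) conditionMessage(fit) else
      "non-finite source estimates"
    fit <- NULL
  }
  if (is.null(fit))
    stop("FastICA failed to converge after ", max_restarts + 1, " attempts: ",
         last_err, call. = FALSE)
  S <- fit$S
  # normalize sources defensively (icafast returns whitened-rotation sources)
  S <- sweep(sweep(S, 2, colMeans(S)), 2, apply(S, 2, stats::sd), "/")
  cors <- as.numeric(stats::cor(p$r$samples, S))
  resp_idx <- which.max(abs(cors))
  # regression rescaling: t = c0 + c_r s_r + c_resid s_resid
  D <- cbind(1, S)
  cf <- qr.coef(qr(D), p$t$samples)
  cf[is.na(cf)] <- 0
  resp <- uniform_signal(cf[resp_idx + 1L] * S[, resp_idx],
                         fs = p$t$fs, units = p$t$units, t0 = p$t$t0)
  separation_result(
    p$t, resp, method = "ica",
    params = list(seed = seed, seed_used = seed_used),
    diagnostics = list(mixing = fit$M, source_resp_cor = cors,
                       respiratory_source = resp_idx,
                       scaling = as.numeric(cf)))
}
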