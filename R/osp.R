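#' Build the respiratory subspace basis for orthogonal subspace projection
#'
#' The basis X collects, for each of the `level` Daubechies-4 wavelet detail
#' signals of the respiration, `max_delay` delayed copies (lags
#' 0..max_delay-1 samples), plus one all-ones intercept column: with the
#' defaults (level 5, 12 delays) the basis has 5 x 12 + 1 = 61 columns. The
#' approximation signal is excluded (frequencies below fs/2^(level+1), i.e.
#' 0.0625 Hz at 4 Hz, are taken to carry no cardiorespiratory interaction).
#' Delayed columns wrap circularly at the start (matching the circular
#' wavelet transform); only rows from sample `max_delay` on are guaranteed
#' to contain past samples only, and the projection fit uses those rows
#' only.
#'
#' @param r Respiration ([uniform_signal()] or numeric vector).
#' @param level Wavelet decomposition depth.
#' @param max_delay Number of lag values per detail (lags 0..max_delay-1);
#'   12 samples = 3 s at 4 Hz.
#' @return An object of class `osp_basis`: `matrix` (N x (level*max_delay+1)),
#'   `row_start` (first fully populated row), `level`, `max_delay`,
#'   `delays` (0..max_delay-1).
#' @examples
#' \dontrun{
#' basis <- build_osp_basis(respiration)  # 61 columns
#' ncol(basis$matrix)
#' }
#' @export
build_osp_basis <- function(r, level = 5, max_delay = 12) {
  v <- if (inherits(r, "uniform_signal")) r$samples else as.numeric(r)
  n <- length(v)
  if (n <= max_delay + 2^level)
    stop("record too short for this basis (need > max_delay + 2^level samples)",
         call. = FALSE)
  dec <- wavelet_detail_signals(v, level = level)
  cols <- vector("list", level * max_delay)
  k <- 0L
  for (j in seq_len(level)) {
    dj <- dec$details[[j]]
    for (d in 0:(max_delay - 1L)) {
      k <- k + 1L
      # circular delay (consistent with the circular wavelet transform);
      # rows >= row_start contain past samples only, and only those rows
      # enter the projection fit
      cols[[k]] <- if (d == 0L) dj else c(dj[(n - d + 1L):n],
                                          dj[seq_len(n - d)])
    }
  }
  X <- cbind(do.call(cbind, cols), 1)
  colnames(X) <- c(paste0("D", rep(seq_len(level), each = max_delay),
                          "_lag", rep(0:(max_delay - 1L), level)),
                   "intercept")
  structure(list(matrix = X, row_start = as.integer(max_delay),
                 level = as.integer(level),
                 max_delay = as.integer(max_delay),
                 delays = 0:(max_delay - 1L)),
            class = "osp_basis")
}

#' @export
print.osp_basis <- function(x, ...) {
  cat(sprintf("osp_basis: %d x %d (levels %d x delays %d + intercept), rows from %d\n",
              nrow(x$matrix), ncol(x$matrix), x$level, x$max_delay,
              x$row_start))
  invisible(x)
}

#' Separate the tachogram by orthogonal subspace projection
#'
#' Projects the tachogram onto the respiratory subspace spanned by the
#' delayed wavelet-detail basis of [build_osp_basis()]:
#' t_r = X (X'X)^-1 X' t, computed by a QR least-squares solve rather than an
#' explicit inverse. The projection combines the multiscale view of MSPCA
#' with the delay modeling of the FIR approach. Coefficients are fit on the
#' rows whose delayed columns contain past samples only; the flagged leading
#' `max_delay - 1` samples are predicted from circularly wrapped columns and
#' excluded from benchmark metrics.
#'
#' @param t Tachogram ([uniform_signal()], ms).
#' @param r Respiration ([uniform_signal()], same grid).
#' @param level,max_delay Forwarded to [build_osp_basis()].
#' @param cond_cap Condition-number cap; above it a small ridge term
#'   (1e-8 x trace(X'X)/ncol) is added and recorded in diagnostics.
#' @return A [separation_result()]; diagnostics carry `condition_number`,
#'   `ridge` (0 when unused), `coeffs` and `prefix_samples`.
#' @export
separate_osp <- function(t, r, level = 5, max_delay = 12, cond_cap = 1e10) {
  p <- as_signal_pair(t, r)
  basis <- build_osp_basis(p$r, level = level, max_delay = max_delay)
  X <- basis$matrix
  rows <- basis$row_start:nrow(X)
  Xf <- X[rows, , drop = FALSE]
  sv <- svd(Xf, nu = 0, nv = 0)$d
  kappa <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  ridge <- 0
  if (is.finite(kappa) && kappa <= cond_cap) {
    beta <- qr.coef(qr(Xf), p$t$samples[rows])
    beta[is.na(beta)] <- 0
  } else {
    ridge <- 1e-8 * sum(Xf^2) / ncol(Xf)
    warning(sprintf(
      "ill-conditioned basis (condition number %.3g); ridge %.3g added",
      kappa, ridge), call. = FALSE)
    A <- crossprod(Xf) + diag(ridge, ncol(Xf))
    beta <- solve(A, crossprod(Xf, p$t$samples[rows]))
  }
  resp <- uniform_signal(as.numeric(X %*% beta), fs = p$t$fs,
                         units = p$t$units, t0 = p$t$t0)
  separation_result(
    p$t, resp, method = "osp",
    params = list(level = level, max_delay = max_delay),
    diagnostics = list(condition_number = kappa, ridge = ridge,
                       coeffs = as.numeric(beta),
                       prefix_samples = basis$row_start - 1L))
}
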