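# Benchmark studies: cross-validated simulation study and windowed
# stability study. Both score separations with the time-domain NRMSE and
# the squared errors of LF and HF band power. Samples flagged as
# zero-padded prefixes by the separators are excluded from the NRMSE and
# the spectral metrics are computed on the unflagged span.

.metric_row <- function(est, truth, prefix = 0L) {
  keep <- (prefix + 1L):length(est$samples)
  e <- uniform_signal(est$samples[keep], fs = est$fs, units = est$units)
  g <- uniform_signal(truth$samples[keep], fs = truth$fs, units = truth$units)
  c(nrmse = nrmse(e, g),
    se_lf = power_squared_error(e, g, "LF"),
    se_hf = power_squared_error(e, g, "HF"))
}

.result_prefix <- function(res) {
  p <- res$diagnostics$prefix_samples
  if (is.null(p)) 0L else as.integer(p)
}

#' Cross-validated simulation study of the separation algorithms
#'
#' Builds composite tachograms with known ground truth by splicing
#' subjects: for each generator algorithm `a`, (1) `a` extracts the
#' reference subject's respiratory component (the ground-truth t_r); (2) `a`
#' extracts each test subject's residual (the ground-truth t_resid); (3) the
#' composite tachogram t_resid + t_r is separated by every *other* algorithm
#' `b`, using the reference subject's respiration as input; (4) `b`'s two
#' components are scored against the ground truths. Excluding `b == a`
#' cross-validates over algorithms so no method is evaluated against its own
#' ground truth.
#'
#' @param cohort A [generate_cohort()] result, or any list whose elements
#'   have `$tachogram` and `$respiration` [uniform_signal()]s.
#' @param algorithms Named list of separators `f(t, r)`; default the five
#'   bundled algorithms of [separator_list()].
#' @param reference Index of the reference subject (default 1); the
#'   remaining subjects are the test subjects.
#' @return A `data.frame` of class `simulation_study_result`, one row per
#'   (generator, subject, evaluated) triple with `nrmse_residual`,
#'   `nrmse_respiratory`, `se_lf_residual`, `se_hf_residual`,
#'   `se_lf_respiratory`, `se_hf_respiratory`, and `failed` (TRUE where the
#'   evaluated separator raised an error; metric columns are then NA).
#' @export
run_simulation_study <- function(cohort, algorithms = separator_list(),
                                 reference = 1) {
  stopifnot(length(cohort) >= 2, length(algorithms) >= 2,
            !is.null(names(algorithms)))
  ref <- cohort[[reference]]
  tests <- setdiff(seq_along(cohort), reference)
  rows <- list()
  empty_row <- function(a, i, b) {
    data.frame(generator = a, subject = i, evaluated = b,
               nrmse_residual = NA_real_, nrmse_respiratory = NA_real_,
               se_lf_residual = NA_real_, se_hf_residual = NA_real_,
               se_lf_respiratory = NA_real_, se_hf_respiratory = NA_real_,
               failed = TRUE)
  }
  for (a in names(algorithms)) {
    ref_sep <- tryCatch(algorithms[[a]](ref$tachogram, ref$respiration),
                        error = function(e) e)
    if (inherits(ref_sep, "error")) {
      for (i in tests)
        for (b in setdiff(names(algorithms), a))
          rows[[length(rows) + 1L]] <- empty_row(a, i, b)
      next
    }
    t_r_ref <- ref_sep$respiratory
    pref_a <- .result_prefix(ref_sep)
    for (i in tests) {
      sub <- cohort[[i]]
      sub_sep <- tryCatch(algorithms[[a]](sub$tachogram, sub$respiration),
                          error = function(e) e)
      if (inherits(sub_sep, "error")) {
        for (b in setdiff(names(algorithms), a))
          rows[[length(rows) + 1L]] <- empty_row(a, i, b)
        next
      }
      resid_i <- sub_sep$residual
      pref_i <- max(pref_a, .result_prefix(sub_sep))
      composite <- uniform_signal(resid_i$samples + t_r_ref$samples,
                                  fs = t_r_ref$fs, units = "ms")
      for (b in setdiff(names(algorithms), a)) {
        row <- data.frame(generator = a, subject = i, evaluated = b,
                          nrmse_residual = NA_real_,
                          nrmse_respiratory = NA_real_,
                          se_lf_residual = NA_real_,
                          se_hf_residual = NA_real_,
                          se_lf_respiratory = NA_real_,
                          se_hf_respiratory = NA_real_, failed = TRUE)
        est <- tryCatch(algorithms[[b]](composite, ref$respiration),
                        error = function(e) e)
        if (!inherits(est, "error")) {
          pref <- max(pref_i, .result_prefix(est))
          m_res <- .metric_row(est$residual, resid_i, pref)
          m_resp <- .metric_row(est$respiratory, t_r_ref, pref)
          row[c("nrmse_residual", "se_lf_residual", "se_hf_residual")] <-
            as.list(m_res)
          row[c("nrmse_respiratory", "se_lf_respiratory",
                "se_hf_respiratory")] <-
            as.list(m_resp)
          row$failed <- FALSE
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("simulation_study_result", class(out))
  attr(out, "reference") <- reference
  out
}

#' Windowed stability study of the separation algorithms
#'
#' Assesses sensitivity to the analysis window: each algorithm's separation
#' of the full record (default 360 s) is the reference; the test signal is
#' the concatenation of separations of consecutive short segments (default
#' three 2-minute windows). Metrics (NRMSE and LF/HF squared errors) compare
#' the concatenated and full-window residuals, and likewise the respiratory
#' components.
#'
#' @param cohort As in [run_simulation_study()].
#' @param algorithms Named list of separators.
#' @param window_s Segment length in seconds.
#' @param full_s Full-record length in seconds; records are truncated to it.
#' @return A `data.frame` of class `stability_study_result`, one row per
#'   (subject, algorithm) with metrics for both components and `failed`.
#' @export
run_stability_study <- function(cohort, algorithms = separator_list(),
                                window_s = 120, full_s = 360) {
  stopifnot(length(cohort) >= 1, length(algorithms) >= 1,
            !is.null(names(algorithms)))
  n_seg <- full_s %/% window_s
  stopifnot(n_seg >= 2, n_seg * window_s == full_s)
  rows <- list()
  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    fs <- sub$tachogram$fs
    n_full <- round(full_s * fs)
    if (length(sub$tachogram$samples) < n_full)
      stop(sprintf("subject %d shorter than full_s = %g s", i, full_s),
           call. = FALSE)
    n_win <- round(window_s * fs)
    tv <- sub$tachogram$samples[seq_len(n_full)]
    rv <- sub$respiration$samples[seq_len(n_full)]
    for (a in names(algorithms)) {
      row <- data.frame(subject = i, algorithm = a,
                        nrmse_residual = NA_real_, se_lf_residual = NA_real_,
                        se_hf_residual = NA_real_,
                        nrmse_respiratory = NA_real_,
                        se_lf_respiratory = NA_real_,
                        se_hf_respiratory = NA_real_, failed = TRUE)
      out <- tryCatch({
        full <- algorithms[[a]](uniform_signal(tv, fs = fs, units = "ms"),
                                uniform_signal(rv, fs = fs, units = "au"))
        segs <- lapply(seq_len(n_seg), function(w) {
          sel <- ((w - 1L) * n_win + 1L):(w * n_win)
          algorithms[[a]](uniform_signal(tv[sel], fs = fs, units = "ms"),
                          uniform_signal(rv[sel], fs = fs, units = "au"))
        })
        cat_resid <- unlist(lapply(segs, function(s) s$residual$samples))
        cat_resp <- unlist(lapply(segs, function(s) s$respiratory$samples))
        pref <- max(c(.result_prefix(full),
                      vapply(segs, .result_prefix, integer(1))))
        m_res <- .metric_row(
          uniform_signal(cat_resid, fs = fs, units = "ms"),
          full$residual, pref)
        m_resp <- .metric_row(
          uniform_signal(cat_resp, fs = fs, units = "ms"),
          full$respiratory, pref)
        row[c("nrmse_residual", "se_lf_residual", "se_hf_residual")] <-
          as.list(m_res)
        row[c("nrmse_respiratory", "se_lf_respiratory",
              "se_hf_respiratory")] <- as.list(m_resp)
        row$failed <- FALSE
        row
      }, error = function(e) row)
      rows[[length(rows) + 1L]] <- out
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stability_study_result", class(out))
  out
}

#' Summarize benchmark study results per algorithm
#'
#' Median, quartiles (type-7 convention) and 1.5 IQR whisker range of every
#' metric, pooled per evaluated algorithm — the tabular counterpart of the
#' studies' boxplots.
#'
#' @param results A [run_simulation_study()] or [run_stability_study()]
#'   result (failed rows are dropped with a note).
#' @return A `data.frame` with columns algorithm, metric, median, q1, q3,
#'   lo, hi, n.
#' @export
summarize_study <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  key <- if ("evaluated" %in% names(results)) "evaluated" else "algorithm"
  if (any(results$failed)) {
    message(sum(results$failed), " failed row(s) dropped from summary")
    results <- results[!results$failed, , drop = FALSE]
  }
  metrics <- intersect(
    c("nrmse_residual", "nrmse_respiratory", "se_lf_residual",
      "se_hf_residual", "se_lf_respiratory", "se_hf_respiratory"),
    names(results))
  rows <- list()
  for (alg in unique(results[[key]])) {
    sel <- results[[key]] == alg
    for (m in metrics) {
      v <- results[[m]][sel]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3] - q[1]
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, metric = m, median = q[2], q1 = q[1], q3 = q[3],
        lo = min(v[v >= q[1] - 1.5 * iqr]),
        hi = max(v[v <= q[3] + 1.5 * iqr]), n = length(v))
    }
  }
  do.call(rbind, rows)
}
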