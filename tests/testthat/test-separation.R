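# Cross-cutting properties of the five separators, plus the ICA-, MSPCA-
# and ARX-specific behaviors (LMS and OSP have dedicated files).

test_that("every separator conserves original = respiratory + residual", {
  for (subject_seps in default_separations())
    for (res in subject_seps)
      expect_lt(conservation_error(res), 1e-9)
})

test_that("separation_result enforces shared grids", {
  a <- uniform_signal(rnorm(100), fs = 4, units = "ms")
  b <- uniform_signal(rnorm(50), fs = 4)
  expect_error(separation_result(a, b, "x"), "lengths")
  b2 <- uniform_signal(rnorm(100), fs = 2)
  expect_error(separation_result(a, b2, "x"), "sampling rates")
})

test_that("ICA recovers a proportional tachogram nearly exactly", {
  set.seed(41)
  r <- generate_respiration(cohort_config(), seed = 41)
  t2 <- uniform_signal(2 * r$samples, fs = r$fs, units = "ms")
  # the two observations are collinear; the ICA engine warns about rank
  res <- suppressWarnings(separate_ica(t2, r, seed = 1))
  expect_lt(nrmse(res$respiratory, t2), 0.02)
  expect_lt(stats::sd(res$residual$samples), 0.02 * stats::sd(t2$samples))
})

test_that("ICA unmixes a known super-Gaussian mixture", {
  set.seed(42)
  n <- 2000
  s1 <- rt(n, df = 3); s2 <- rt(n, df = 3)  # heavy-tailed sources
  A <- matrix(c(1, 0.6, 0.4, 1), 2, 2)
  X <- cbind(s1, s2) %*% t(A)
  r <- uniform_signal(X[, 1], fs = 4)
  t_sig <- uniform_signal(X[, 2], fs = 4, units = "ms")
  res <- separate_ica(t_sig, r, seed = 2)
  # the respiratory-labeled source must match one ground-truth source
  fit <- tryCatch(res, error = function(e) e)
  d <- res$diagnostics
  src <- (res$respiratory$samples - mean(res$respiratory$samples))
  cors <- abs(c(cor(src, s1), cor(src, s2)))
  expect_gt(max(cors), 0.95)
})

test_that("ICA is deterministic under a fixed seed", {
  s <- default_cohort()[[2]]
  a <- separate_ica(s$tachogram, s$respiration, seed = 7)
  b <- separate_ica(s$tachogram, s$respiration, seed = 7)
  expect_identical(a$respiratory$samples, b$respiratory$samples)
  expect_error(separate_ica(uniform_signal(rep(1, 100), units = "ms"),
                            uniform_signal(rnorm(100))),
               "non-constant")
})

test_that("ARX recovers a known generating kernel to machine precision", {
  cfg <- cohort_config(noise_sd_ms = 0, lf_gain_ms = 0,
                       rsa_kernel = c(0.5, 0.3, 0.2), rsa_gain_ms = 1)
  s <- generate_subject(cfg, seed = 43)
  res <- separate_armax(s$tachogram, s$respiration)
  k_true <- cfg$rsa_kernel * cfg$rsa_gain_ms
  expect_lt(max(abs(res$diagnostics$coeffs[1:3] - k_true)), 1e-6)
  expect_lt(max(abs(res$diagnostics$coeffs[4:13])), 1e-6)
  expect_equal(res$diagnostics$intercept, cfg$mean_rr_ms, tolerance = 1e-6)
  expect_identical(res$params$order, 12L)  # 3 s at 4 Hz
  expect_identical(res$diagnostics$prefix_samples, 12L)
})

test_that("ARX with zero respiration returns a zero respiratory component", {
  s <- default_cohort()[[3]]
  z <- uniform_signal(numeric(length(s$tachogram$samples)), fs = 4)
  # warns once about the degenerate regressor and once about its rank
  expect_warning(expect_warning(res <- separate_armax(s$tachogram, z),
                                "degenerate"), "rank-deficient")
  expect_equal(max(abs(res$respiratory$samples)), 0)
  expect_equal(res$residual$samples, s$tachogram$samples)
  short <- uniform_signal(s$tachogram$samples[1:40], fs = 4, units = "ms")
  shortr <- uniform_signal(s$respiration$samples[1:40], fs = 4)
  expect_error(separate_armax(short, shortr), "too short")
})

test_that("MSPCA keeps scales where the channels are proportional", {
  r <- generate_respiration(cohort_config(), seed = 44)
  drift <- 5 * sin(2 * pi * 0.01 * (seq_along(r$samples) - 1) / r$fs)
  t3 <- uniform_signal(3 * r$samples + drift, fs = r$fs, units = "ms")
  res <- separate_mspca(t3, r)
  expect_true(all(res$diagnostics$scales$retained))
  # oracle: the detail-only (approximation-free) part of t
  dec <- wavelet_detail_signals(t3, level = 5)
  detail_part <- Reduce(`+`, dec$details)
  expect_lt(nrmse(res$respiratory$samples, detail_part), 0.01)
})

test_that("MSPCA zeroes scales for independent white noise", {
  t_sig <- noise_signal(1440, seed = 45, units = "ms")
  r_sig <- noise_signal(1440, seed = 46)
  res <- separate_mspca(t_sig, r_sig)
  expect_false(any(res$diagnostics$scales$retained))
  expect_equal(max(abs(res$respiratory$samples)), 0)
  # eigenvalue-ratio oracle: 2x2 covariance of independent noise stays far
  # from the 90% threshold
  expect_true(all(res$diagnostics$scales$explained < 0.8))
  expect_error(separate_mspca(t_sig, r_sig, level = 15), "maximum feasible")
})

test_that("separator outputs are reproducible", {
  s <- default_cohort()[[4]]
  seps <- separator_list()
  for (nm in names(seps)) {
    a <- seps[[nm]](s$tachogram, s$respiration)
    b <- seps[[nm]](s$tachogram, s$respiration)
    expect_identical(a$respiratory$samples, b$respiratory$samples,
                     info = nm)
  }
})
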