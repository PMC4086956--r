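test_that("uniform_signal enforces its invariants", {
  expect_error(uniform_signal(1), "at least 2")
  expect_error(uniform_signal(c(1, NA)), "finite")
  expect_error(uniform_signal(c(1, 2), fs = 0), "positive")
  s <- uniform_signal(c(1, 2, 3), fs = 2, t0 = 1)
  expect_equal(signal_times(s), c(1, 1.5, 2))
})

test_that("beat_series round-trips RR and beat times and flags guard violations", {
  b <- beat_series(rr = c(800, 900, 1000, 1100))
  expect_equal(diff(b$beat_times), c(0.9, 1.0, 1.1))
  expect_error(beat_series(beat_times = c(0, 1, 0.5)),
               "strictly increasing")
  expect_error(beat_series(rr = c(800, -5, 900)), "positive")
  expect_warning(b2 <- beat_series(rr = c(800, 150, 900, 1000)),
                 "guard range")
  expect_equal(which(b2$guard_mask), 2L)
  expect_length(b2$rr, 4L)  # flagged, not dropped
})

test_that("build_tachogram maps a constant RR series to a constant signal", {
  b <- beat_series(rr = rep(1000, 360))
  tg <- build_tachogram(b, fs = 4)
  expect_equal(unique(tg$samples), 1000)
  expect_equal(tg$fs, 4)
  expect_equal(tg$units, "ms")
})

test_that("build_tachogram preserves the dominant oscillation frequency", {
  # beats ~1 s apart carrying a 0.25 Hz RR modulation; the resampled
  # tachogram's Welch peak must land in the bin nearest 0.25 Hz.
  beat_t <- cumsum(rep(1, 361))
  rr <- 1000 + 50 * sin(2 * pi * 0.25 * beat_t)
  b <- beat_series(beat_times = beat_t)
  b$rr <- rr  # modulated intervals at known instants
  tg <- build_tachogram(b, fs = 4)
  # oracle: direct DFT of the generated series
  v <- tg$samples - mean(tg$samples)
  sp <- Mod(stats::fft(v))^2
  freqs <- (seq_along(v) - 1) * tg$fs / length(v)
  half <- freqs <= tg$fs / 2
  expect_lt(abs(freqs[half][which.max(sp[half])] - 0.25),
            tg$fs / length(v) + 1e-12)
  p <- welch_psd(tg)
  expect_lt(abs(p$freqs[which.max(p$density)] - 0.25),
            tg$fs / p$nfft + 1e-12)
})

test_that("build_tachogram is exact on cubic polynomials of time", {
  tt <- sort(c(0, cumsum(runif(50, 0.7, 1.3))))
  f <- function(x) 900 + 5 * x - 0.3 * x^2 + 0.01 * x^3
  b <- beat_series(beat_times = tt)
  b$rr <- f(tt)
  tg <- build_tachogram(b, fs = 4)
  grid <- signal_times(tg)
  interior <- grid > tt[3] & grid < tt[length(tt) - 2]
  expect_equal(tg$samples[interior], f(grid)[interior], tolerance = 1e-6)
})

test_that("build_tachogram rejects bad input", {
  expect_error(build_tachogram(beat_series(rr = c(800, 900, 1000))),
               "at least 4")
  expect_error(beat_series(beat_times = c(0, 1, 0.5, 2)),
               "strictly increasing")
})

test_that("highpass_respiration removes DC and keeps the passband", {
  fs <- 4
  tt <- seq(0, 360 - 1 / fs, by = 1 / fs)
  const <- uniform_signal(rep(5, length(tt)), fs = fs)
  out <- highpass_respiration(const)
  expect_lt(max(abs(out$samples)), 1e-6 * 5)

  # oracle: least-squares sine fit amplitude at each frequency
  ls_amp <- function(x, f) {
    X <- cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
    sqrt(sum(stats::lm.fit(X, x)$coefficients^2))
  }
  pure <- uniform_signal(sin(2 * pi * 0.25 * tt), fs = fs)
  hp <- highpass_respiration(pure)
  expect_lt(abs(ls_amp(hp$samples, 0.25) - 1), 0.05)

  mix <- uniform_signal(sin(2 * pi * 0.01 * tt) + sin(2 * pi * 0.3 * tt),
                        fs = fs)
  hpm <- highpass_respiration(mix)
  expect_lt(ls_amp(hpm$samples, 0.01), 1 / 10)
  expect_gt(ls_amp(hpm$samples, 0.3), 0.95)
  expect_error(highpass_respiration(pure, cutoff = 2), "Nyquist")
})

test_that("nrmse matches the hand oracle and its invariances", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(0.5, 1.5), c(0, 1)), 0.5)
  expect_error(nrmse(c(1, 2), c(3, 3)), "zero range")
  expect_error(nrmse(c(1, 2), c(1, 2, 3)), "equal length")
  # shift invariance and 1/c scaling of the reference range
  set.seed(4)
  ref <- rnorm(100)
  est <- ref + rnorm(100, sd = 0.1)
  expect_equal(nrmse(est + 7, ref + 7), nrmse(est, ref))
  expect_equal(nrmse(5 * ref + (est - ref), 5 * ref),
               nrmse(est, ref) / 5)
})

test_that("text readers and the separation writer round-trip", {
  rr_file <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "800", "900", "1000", "950"), rr_file)
  b <- read_rr(rr_file)
  expect_equal(b$rr, c(800, 900, 1000, 950))

  resp_file <- withr::local_tempfile(fileext = ".csv")
  tt <- seq(0, 10, by = 0.25)
  utils::write.csv(data.frame(time = tt, value = sin(tt)), resp_file,
                   row.names = FALSE)
  r <- read_respiration(resp_file)
  expect_equal(r$fs, 4)
  expect_equal(r$samples, sin(tt))

  s <- generate_subject(cohort_config(duration_s = 60), seed = 3)
  res <- separate_armax(s$tachogram, s$respiration)
  out <- withr::local_tempfile(fileext = ".csv")
  write_separation_csv(res, out)
  d <- utils::read.csv(out)
  expect_equal(d$original, res$original$samples)
  expect_equal(d$respiratory + d$residual, d$original, tolerance = 1e-12)
})
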