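# Shared fixtures, built in code. Heavyweight objects (the default cohort
# and its separations) are computed once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# a clean sinusoid as a uniform_signal
sine_signal <- function(freq, duration_s = 360, fs = 4, amp = 1,
                        units = "au", phase = 0) {
  tt <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  uniform_signal(amp * sin(2 * pi * freq * tt + phase), fs = fs,
                 units = units)
}

noise_signal <- function(n = 1440, fs = 4, sd = 1, seed = 1, units = "au") {
  set.seed(seed)
  uniform_signal(stats::rnorm(n, sd = sd), fs = fs, units = units)
}

# default study cohort: 20 subjects, 360 s, fixed seed
default_cohort <- function() {
  memo("cohort20", generate_cohort(cohort_config(n_subjects = 20,
                                                 seed = 2014)))
}

# all five separations of every default-cohort subject
default_separations <- function() {
  memo("sep20", {
    seps <- separator_list()
    lapply(default_cohort(), function(s)
      lapply(seps, function(f) f(s$tachogram, s$respiration)))
  })
}

# NRMSE after removing each signal's mean: the constant mean-RR split
# between the two components is not identifiable across methods (OSP's
# intercept assigns it to the respiratory part, the others to the residual)
nrmse_demeaned <- function(estimate, reference, skip = 0L) {
  e <- if (inherits(estimate, "uniform_signal")) estimate$samples else estimate
  r <- if (inherits(reference, "uniform_signal")) reference$samples else reference
  if (skip > 0L) {
    e <- e[-seq_len(skip)]
    r <- r[-seq_len(skip)]
  }
  nrmse(e - mean(e), r - mean(r))
}
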