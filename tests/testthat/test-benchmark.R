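# The benchmark harness is validated with small cohorts and a mix of real
# and oracle separators; the full-scale study runs live in the acceptance
# tests.

small_cohort <- function(n = 4, duration_s = 120, seed = 81) {
  memo(sprintf("bench_cohort_%d_%d_%d", n, duration_s, seed),
       generate_cohort(cohort_config(n_subjects = n,
                                     duration_s = duration_s, seed = seed)))
}

test_that("a perfect oracle separator scores zero in the simulation study", {
  oracle <- oracle_gain_separator(gain = 25)
  res <- run_simulation_study(small_cohort(),
                              algorithms = list(oracle_a = oracle,
                                                oracle_b = oracle))
  expect_false(any(res$failed))
  metrics <- res[, c("nrmse_residual", "nrmse_respiratory",
                     "se_lf_residual", "se_hf_residual",
                     "se_lf_respiratory", "se_hf_respiratory")]
  expect_lt(max(abs(as.matrix(metrics))), 1e-12)
})

test_that("a window-independent oracle scores exactly zero in the stability study", {
  res <- run_stability_study(
    small_cohort(2, duration_s = 360, seed = 82),
    algorithms = list(oracle = oracle_gain_separator(10)),
    window_s = 120, full_s = 360)
  metrics <- as.matrix(res[, c("nrmse_residual", "se_lf_residual",
                               "se_hf_residual", "nrmse_respiratory",
                               "se_lf_respiratory", "se_hf_respiratory")])
  expect_identical(max(abs(metrics)), 0)
})

test_that("the composite tachogram satisfies the splicing identity", {
  cohort <- small_cohort()
  alg <- separator_list()[["armax"]]
  ref_sep <- alg(cohort[[1]]$tachogram, cohort[[1]]$respiration)
  sub_sep <- alg(cohort[[2]]$tachogram, cohort[[2]]$respiration)
  composite <- sub_sep$residual$samples + ref_sep$respiratory$samples
  expect_equal(composite - ref_sep$respiratory$samples,
               sub_sep$residual$samples, tolerance = 1e-12)
})

test_that("the simulation study emits (subjects-1) x k x (k-1) disjoint rows", {
  cohort <- small_cohort(5, duration_s = 120, seed = 83)
  algs <- separator_list()[c("armax", "osp", "mspca")]
  res <- run_simulation_study(cohort, algorithms = algs)
  expect_identical(nrow(res), 4L * 3L * 2L)
  expect_false(any(res$generator == res$evaluated))
  expect_setequal(unique(res$subject), 2:5)
  expect_true(all(res$nrmse_residual[!res$failed] >= 0))
})

test_that("a failing separator is recorded per-row and the study continues", {
  cohort <- small_cohort(3, duration_s = 120, seed = 84)
  bomb <- function(t, r) stop("boom")
  res <- run_simulation_study(
    cohort, algorithms = c(separator_list()[c("armax", "osp")],
                           list(bomb = bomb)))
  # rows touching the bomb in either role fail; the rest succeed
  touched <- res$generator == "bomb" | res$evaluated == "bomb"
  expect_true(all(res$failed[touched]))
  expect_false(any(res$failed[!touched]))
  expect_true(all(is.na(res$nrmse_residual[touched])))
  expect_identical(nrow(res), 2L * 3L * 2L)
})

test_that("per-segment refits differ from the full-window fit for ARX", {
  res <- run_stability_study(
    small_cohort(2, duration_s = 360, seed = 85),
    algorithms = separator_list()["armax"],
    window_s = 120, full_s = 360)
  expect_false(any(res$failed))
  expect_true(all(res$nrmse_residual > 0))
  # length bookkeeping: three 2-minute segments tile the 6-minute record
  expect_identical(3L * 120L * 4L, 360L * 4L)
})

test_that("summarize_study reports order statistics per algorithm", {
  one <- data.frame(subject = 1, algorithm = "a", nrmse_residual = 0.3,
                    failed = FALSE)
  s1 <- summarize_study(one)
  expect_equal(s1$median, 0.3)
  allsame <- data.frame(subject = 1:4, algorithm = "a",
                        nrmse_residual = rep(0.2, 4), failed = FALSE)
  s2 <- summarize_study(allsame)
  expect_equal(s2$q3 - s2$q1, 0)
  known <- data.frame(subject = 1:5, algorithm = "a",
                      nrmse_residual = c(1, 2, 3, 4, 5), failed = FALSE)
  s3 <- summarize_study(known)
  expect_equal(s3$median, 3)
  expect_equal(s3$q1, stats::quantile(1:5, 0.25, names = FALSE))
  expect_equal(s3$q3, stats::quantile(1:5, 0.75, names = FALSE))
  expect_error(summarize_study(data.frame()), "nrow")
})
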