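test_that("boundary-rate corrections follow the halfN and loglinear rules", {
  interior <- corrected_rates(sdt_counts(6, 3, 12, 12))
  expect_equal(interior$hit_rate, 0.5)
  expect_equal(interior$fa_rate, 0.25)
  expect_false(interior$correction_applied)

  ceilinged <- corrected_rates(sdt_counts(12, 3, 12, 12))
  expect_equal(ceilinged$hit_rate, 23 / 24) # 1 - 1/(2N)
  expect_true(ceilinged$correction_applied)
  floored <- corrected_rates(sdt_counts(0, 0, 12, 12))
  expect_equal(floored$hit_rate, 1 / 24)
  expect_equal(floored$fa_rate, 1 / 24)

  ll <- corrected_rates(sdt_counts(12, 0, 12, 12), method = "loglinear")
  expect_equal(ll$hit_rate, 12.5 / 13)
  expect_equal(ll$fa_rate, 0.5 / 13)

  # idempotence on interior rates: reconstructing counts changes nothing
  again <- corrected_rates(sdt_counts(6, 3, 12, 12))
  expect_identical(interior, again)
  expect_error(sdt_counts(13, 0, 12, 12))
})

test_that("d-prime is the quantile difference, antisymmetric and finite", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(pnorm(1), pnorm(-1)), 2, tolerance = 1e-12)
  expect_equal(dprime(0.8413, 0.1587), 2, tolerance = 1e-3)
  expect_equal(dprime(0.1587, 0.8413), -dprime(0.8413, 0.1587))
  expect_error(dprime(1, 0.5), "corrected_rates")
  # corrected boundary cases always yield finite d-prime
  for (h in c(0L, 12L)) for (f in c(0L, 12L)) {
    r <- dprime_from_counts(sdt_counts(h, f, 12, 12))
    expect_true(is.finite(r$dprime))
  }
})

test_that("two-cell chi-square reproduces the worked goodness-of-fit values", {
  a <- chi_square_gof(6, 5.34, 51)
  expect_equal(a$chi2, 0.091, tolerance = 0.005)
  b <- chi_square_gof(9, 10.48, 81)
  expect_equal(b$chi2, 0.240, tolerance = 0.005)
  ex <- chi_square_gof(7, 7, 40)
  expect_equal(ex$chi2, 0)
  expect_equal(ex$p, 1)
  expect_error(chi_square_gof(5, 0, 50), "strictly between")
})

test_that("two-cell chi-square equals the generic Pearson statistic", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(30:120, 1)
    e <- runif(1, 2, n - 2)
    o <- sample(seq(0, n), 1)
    ours <- chi_square_gof(o, e, n)
    generic <- suppressWarnings(
      stats::chisq.test(c(o, n - o), p = c(e / n, 1 - e / n)))
    expect_equal(ours$chi2, unname(generic$statistic), tolerance = 1e-12)
    expect_equal(ours$p, generic$p.value, tolerance = 1e-12)
  }
})

test_that("soft-ceiling analysis uses the interpolated percentile and both expected modes", {
  set.seed(10)
  d <- rnorm(51, 2, 0.45)
  res <- ceiling_analysis(d)
  expect_equal(res$threshold, unname(quantile(d, 0.9, type = 7)))
  expect_equal(res$observed, sum(d >= res$threshold))
  expect_equal(res$expected,
               51 * pnorm(res$threshold, mean(d), sd(d), lower.tail = FALSE))
  ff <- ceiling_analysis(d, expected_mode = "fixed_fraction")
  expect_equal(ff$expected, 5.1)
  expect_error(ceiling_analysis(rep(1, 51)), "zero standard deviation")
  expect_error(ceiling_analysis(rnorm(5)), "at least 10")
})

test_that("soft-ceiling test is conservative to nominal under a Gaussian null", {
  # with the threshold estimated from the sample itself the observed
  # tail count is nearly fixed, so rejections happen only when the
  # fitted normal tail drifts; the test should reject at most around
  # the nominal 5% rate
  set.seed(21)
  rej <- mean(replicate(1000, ceiling_analysis(rnorm(51))$p < 0.05))
  expect_lt(rej, 0.08)
  expect_gt(rej, 0.001)
})

test_that("per-speaker percent correct pools over participants by condition", {
  log <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:10), each = 3),
    version = "simple", order = "IE", phase_index = 1, task = "implicit",
    trial_type = "recognition", trial_index = 1:3,
    speaker_id = "L1", speaker_b = NA, snippet_id = paste0("s", 1:30),
    snippet_b = NA,
    truth = "old",
    response = rep(c("old", "old", "new"), 10), # 2 of 3 correct each
    stringsAsFactors = FALSE)
  pc <- percent_correct_by_speaker(log)
  expect_equal(nrow(pc), 1)
  expect_equal(pc$pc, 100 * 20 / 30, tolerance = 1e-12)

  log$response <- "old"
  expect_equal(percent_correct_by_speaker(log)$pc, 100)
  expect_false("L2" %in% percent_correct_by_speaker(log)$speaker_id)
})

test_that("recognition and discrimination scoring count hits and false alarms correctly", {
  log <- data.frame(
    participant_id = "P1", version = "simple", order = "IE",
    phase_index = 1, task = "implicit", trial_type = "recognition",
    trial_index = 1:6,
    speaker_id = c("a", "a", "a", "b", "b", "b"), speaker_b = NA,
    snippet_id = paste0("s", 1:6), snippet_b = NA,
    truth = c("old", "old", "old", "new", "new", "new"),
    response = c("old", "old", "new", "new", "old", "new"),
    stringsAsFactors = FALSE)
  s <- score_recognition(log)
  expect_equal(s$hits, 2)
  expect_equal(s$false_alarms, 1)
  expect_equal(s$dprime, dprime(2 / 3, 1 / 3))

  dlog <- log
  dlog$trial_type <- "discrimination"
  dlog$truth <- c("different", "different", "different", "same", "same", "same")
  dlog$response <- c("different", "same", "different", "same", "same", "same")
  sd_ <- score_discrimination(dlog)
  expect_equal(sd_$hits, 2)
  expect_equal(sd_$false_alarms, 0)
  expect_true(sd_$correction_applied)
})
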