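test_that("confusion counts and metrics reproduce brute-force recomputation", {
  truth <- make_truth(or = c(8, 7, 1.5, 9, 1.2, 0.9),
                      label = c("positive", "positive", "positive",
                                "negative", "negative", "negative"))
  cc <- confusion_counts(truth, truth$or > 5)
  expect_equal(unlist(cc), c(tp = 2L, fp = 1L, tn = 2L, fn = 1L))
  # flag nothing / flag everything
  expect_equal(unlist(confusion_counts(truth, rep(FALSE, 6))),
               c(tp = 0L, fp = 0L, tn = 3L, fn = 3L))
  expect_equal(unlist(confusion_counts(truth, rep(TRUE, 6))),
               c(tp = 3L, fp = 3L, tn = 0L, fn = 0L))
  expect_error(confusion_counts(truth, c(TRUE, NA, TRUE, TRUE, TRUE, TRUE)),
               class = "ps4_domain_error")

  # brute-force metric identities over random confusion counts
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:500, 4, replace = TRUE)
    m <- classification_metrics(n[1], n[2], n[3], n[4])
    expect_equal(m$accuracy, (n[1] + n[3]) / sum(n), tolerance = 1e-12)
    expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity),
                 tolerance = 1e-12)
  }
  # degenerate cases: undefined stays NA, never 0
  perfect <- classification_metrics(10, 0, 20, 0)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "ppv", "npv", "f1")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1,
                 ppv = 1, npv = 1, f1 = 1))
  nothing <- classification_metrics(0, 0, 20, 10)
  expect_true(is.na(nothing$ppv))
  expect_equal(nothing$specificity, 1)
  expect_equal(nothing$sensitivity, 0)
})

test_that("lr_plus_ci is deterministic in the point and seeded in the interval", {
  a <- lr_plus_ci(50, 14, 504, 30, B = 2000, seed = 42)
  b <- lr_plus_ci(50, 14, 504, 30, B = 2000, seed = 42)
  expect_identical(a, b)
  expect_equal(a$lr_plus, 23.125)
  expect_true(a$lr_lb < 23.125 && 23.125 < a$lr_ub)
  # perfect separation: +Inf point with one-sided lower bound
  p <- lr_plus_ci(30, 0, 300, 0, B = 500, seed = 1)
  expect_true(is.infinite(p$lr_plus))
  expect_true(is.finite(p$lr_lb) && p$lr_lb > 1)
  expect_true(is.infinite(p$lr_ub))
  # CI width shrinks as counts scale up x10
  small <- lr_plus_ci(50, 14, 504, 30, B = 3000, seed = 3)
  big <- lr_plus_ci(500, 140, 5040, 300, B = 3000, seed = 3)
  expect_lt(big$lr_ub - big$lr_lb, small$lr_ub - small$lr_lb)
  expect_error(lr_plus_ci(50, 14, 504, 30, B = 100), class = "ps4_config_error")
})

test_that("OR scan flags by strict cutoff with CI requirement and nests", {
  set.seed(14)
  n_pos <- 60; n_neg <- 120
  truth <- make_truth(
    or = c(rlnorm(n_pos, log(8), 0.4), rlnorm(n_neg, 0, 0.3)),
    label = rep(c("positive", "negative"), c(n_pos, n_neg))
  )
  tb <- build_calibration_table(n_pos / (n_pos + n_neg), 225, 1L)
  scan <- scan_or_cutoffs(truth, cutoffs = 1:10, table = tb, B = 400, seed = 5)
  expect_equal(nrow(scan), 10)
  # flagged sets nest: tp and fp monotone non-increasing in the cutoff
  expect_true(all(diff(scan$tp) <= 0))
  expect_true(all(diff(scan$fp) <= 0))
  expect_equal(scan$tp + scan$fn, rep(n_pos, 10))
  expect_equal(scan$fp + scan$tn, rep(n_neg, 10))
  # strict inequality: cutoff at an observed OR excludes that variant
  truth2 <- make_truth(or = c(4, 4, 1), label = c("positive", "positive", "negative"))
  s2 <- scan_or_cutoffs(truth2, cutoffs = 4, table = tb, B = 200, seed = 1)
  expect_equal(s2$tp, 0L)
  # enriched positives at true OR ~8 reach at least moderate strength mid-scan
  expect_true(any(scan$strength[scan$cutoff %in% 3:6] %in%
                    c("moderate", "strong", "very_strong")))
  # cutoff beyond all ORs: nothing flagged, strength undefined
  s3 <- scan_or_cutoffs(truth, cutoffs = 1e6, table = tb, B = 200, seed = 1)
  expect_equal(s3$tp + s3$fp, 0L)
  expect_true(is.na(s3$strength))
  # OR scan refuses control-absent variants
  bad <- make_truth(or = c(2, 3), label = c("positive", "negative"),
                    ac_control = 0L)
  expect_error(scan_or_cutoffs(bad, 1:2, tb, B = 100, seed = 1),
               class = "ps4_domain_error")
})

test_that("AC scan is inclusive and requires control absence", {
  truth <- make_truth(or = rep(1, 8), label = rep(c("positive", "negative"), 4),
                      ac_control = 0L,
                      ac_case = c(6L, 2L, 3L, 2L, 8L, 3L, 2L, 2L))
  tb <- build_calibration_table(0.5, 397, 3L)
  scan <- scan_ac_cutoffs(truth, cutoffs = 2:6, table = tb, B = 200, seed = 9)
  # inclusive cutoff: every variant has ac_case >= 2 -> sensitivity 1 at AC = 2
  expect_equal(scan$sensitivity[scan$cutoff == 2], 1)
  expect_equal(scan$tp[scan$cutoff == 3], 3L)  # 6, 3, 8
  expect_equal(scan$fp[scan$cutoff == 3], 1L)  # the single negative with 3
  expect_true(all(diff(scan$tp) <= 0))
  expect_error(scan_ac_cutoffs(make_truth(or = 1, label = "positive"),
                               2:3, tb, B = 100, seed = 1),
               class = "ps4_domain_error")
})

test_that("synthetic subsets with strongly enriched positives earn moderate strength", {
  # parameter-recovery property: positives carry true OR >= 8 at recoverable AFs
  cfg <- synthetic_config(n_variants = 400, frac_pathogenic = 0.3,
                          control_af_bounds = c(2e-4, 5e-3),
                          or_pathogenic = c(meanlog = log(8), sdlog = 0.2),
                          seed = 71)
  v <- generate_cohort(cfg)
  truth <- suppressWarnings(split_truth_subsets(build_truth_set(v)))
  s1 <- truth[truth$subset == 1L, ]
  s1 <- variant_association(s1)
  tb <- build_calibration_table(subset_prior(truth, 1L), 225, 1L)
  scan <- scan_or_cutoffs(s1, cutoffs = 3:6, table = tb, B = 500, seed = 8)
  expect_true(all(scan$strength %in% c("moderate", "strong", "very_strong")))
})
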