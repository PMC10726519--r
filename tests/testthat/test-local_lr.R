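test_that("interval_weight has the closed form and the identity at the empirical prior", {
  expect_equal(interval_weight(0.5, 10, 100), 0.1)
  expect_equal(interval_weight(0.0931, 186, 1811), 1.0005, tolerance = 1e-4)
  # weight is exactly 1 when the prior equals the subset proportion
  for (np in c(7, 100, 186)) for (nn in c(13, 900, 1811)) {
    expect_equal(interval_weight(np / (np + nn), np, nn), 1, tolerance = 1e-12)
  }
  expect_error(interval_weight(0, 10, 10), class = "ps4_domain_error")
  expect_error(interval_weight(0.5, 0, 10), class = "ps4_domain_error")
})

test_that("local posterior on a toy subset equals brute-force window evaluation", {
  # 6 variants with hand-checkable window membership, minimum counts relaxed
  truth <- make_truth(or = c(1.0, 1.005, 1.5, 1.52, 3.0, 3.005),
                      label = c("negative", "negative", "negative",
                                "positive", "positive", "positive"))
  prior <- 0.4
  curve <- local_posterior_curve(truth, half_width = 0.01, min_pos = 1,
                                 min_neg = 1, prior = prior)
  w <- interval_weight(prior, 3, 3)
  # brute force: for each unique OR, expand radius to cover >= 1 of each class
  oracle <- sapply(curve$or, function(o) {
    pos <- truth$or[truth$truth_label == "positive"]
    neg <- truth$or[truth$truth_label == "negative"]
    r <- max(0.01, min(abs(pos - o)), min(abs(neg - o)))
    np <- sum(abs(pos - o) <= r); nn <- sum(abs(neg - o) <= r)
    np / (np + w * nn)
  })
  expect_equal(curve$posterior, oracle, tolerance = 1e-12)
  # with the count minima fully relaxed the plain half-width window around a
  # positives-only cluster gives posterior 1
  c0 <- local_posterior_curve(truth, half_width = 0.01, min_pos = 0,
                              min_neg = 0, prior = prior)
  expect_equal(c0$posterior[c0$or == 3.0], 1)
  # lr_local is the exact odds transform of the posterior at every grid point
  podds <- prior / (1 - prior)
  expect_equal(curve$lr_local,
               (curve$posterior / (1 - curve$posterior)) / podds,
               tolerance = 1e-12)
})

test_that("curve equals the raw in-window positive fraction at the empirical prior", {
  set.seed(31)
  truth <- make_truth(or = c(rlnorm(40, log(3), 0.5), rlnorm(60, 0, 0.4)),
                      label = rep(c("positive", "negative"), c(40, 60)))
  curve <- local_posterior_curve(truth, half_width = 0.05, min_pos = 5, min_neg = 5)
  expect_equal(attr(curve, "weight"), 1, tolerance = 1e-12)
  # recompute raw fractions with the same expansion rule
  pos <- sort(truth$or[truth$truth_label == "positive"])
  neg <- sort(truth$or[truth$truth_label == "negative"])
  raw <- sapply(curve$or, function(o) {
    r <- max(0.05, sort(abs(pos - o))[5], sort(abs(neg - o))[5])
    np <- sum(abs(pos - o) <= r); nn <- sum(abs(neg - o) <= r)
    np / (np + nn)
  })
  expect_equal(curve$posterior, raw, tolerance = 1e-12)
})

test_that("curve is invariant to duplicate OR ordering and to row shuffling", {
  or <- c(1, 1, 1.2, 1.2, 2, 2, 2, 3)
  lab <- c("positive", "negative", "positive", "negative",
           "positive", "negative", "positive", "negative")
  t1 <- make_truth(or = or, label = lab)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  t2 <- t1[perm, ]
  c1 <- local_posterior_curve(t1, min_pos = 2, min_neg = 2)
  c2 <- local_posterior_curve(t2, min_pos = 2, min_neg = 2)
  expect_equal(c1$or, c2$or)
  expect_equal(c1$posterior, c2$posterior, tolerance = 1e-12)
})

test_that("bootstrap bound sits at or below the point estimate and is seeded", {
  set.seed(17)
  truth <- make_truth(or = c(rlnorm(50, log(3), 0.5), rlnorm(80, 0, 0.4)),
                      label = rep(c("positive", "negative"), c(50, 80)))
  curve <- local_posterior_curve(truth, min_pos = 10, min_neg = 10)
  b1 <- bootstrap_lower_bound(curve, B = 150, seed = 4)
  b2 <- bootstrap_lower_bound(curve, B = 150, seed = 4)
  expect_identical(b1$bound_posterior, b2$bound_posterior)
  expect_true(all(b1$bound_posterior <= b1$posterior + 0.05))
  expect_true(mean(b1$bound_posterior <= b1$posterior) > 0.9)
  # degenerate: identical ORs and homogeneous windows give zero variance
  td <- make_truth(or = rep(2, 20), label = rep(c("positive", "negative"), 10))
  cd <- local_posterior_curve(td, min_pos = 2, min_neg = 2)
  bd <- bootstrap_lower_bound(cd, B = 120, seed = 2)
  expect_equal(bd$bound_posterior, cd$posterior, tolerance = 1e-12)
  expect_error(bootstrap_lower_bound(curve, B = 0, seed = 1),
               class = "ps4_domain_error")
  expect_warning(bootstrap_lower_bound(cd, B = 50, seed = 1), "noisy")
})

test_that("threshold extraction finds the separation point of a constructed subset", {
  # positives all above OR 4, negatives all below 2 -> supporting threshold in (2, 4)
  set.seed(23)
  truth <- make_truth(
    or = c(runif(60, 4, 8), runif(90, 0.5, 2)),
    label = rep(c("positive", "negative"), c(60, 90))
  )
  curve <- local_posterior_curve(truth, min_pos = 10, min_neg = 10)
  curve <- bootstrap_lower_bound(curve, B = 200, seed = 6)
  tb <- build_calibration_table(attr(curve, "prior"), 387, 2L)
  thr <- extract_or_threshold(curve, tb, "supporting")
  # the grid only holds observed OR values, so the extracted threshold is the
  # first grid point past the separation gap (just above 4)
  expect_true(thr > 2 && thr < 4.5)
  # a flat curve below every threshold yields NA
  flat <- make_truth(or = rep(c(1, 1.01), 40),
                     label = rep(c("positive", "negative"), 40))
  fc <- local_posterior_curve(flat, min_pos = 30, min_neg = 30)
  fc <- bootstrap_lower_bound(fc, B = 120, seed = 7)
  tb_hi <- build_calibration_table(attr(fc, "prior"), 1e5, 2L)
  expect_true(is.na(extract_or_threshold(fc, tb_hi, "strong")))
  expect_error(extract_or_threshold(curve, tb, "overwhelming"))
  expect_error(extract_or_threshold(local_posterior_curve(truth, min_pos = 10,
                                                          min_neg = 10),
                                    tb, "supporting"),
               class = "ps4_validation_error")
})

test_that("subset too small for the window minima is refused by name", {
  truth <- make_truth(or = c(1, 2, 3), label = c("positive", "negative", "negative"))
  expect_error(local_posterior_curve(truth, min_pos = 100, min_neg = 100),
               "100", class = "ps4_domain_error")
})
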