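test_that("fisher_exact_p matches direct enumeration and known tables", {
  expect_equal(fisher_exact_p(5, 95, 5, 95), 1.0)
  expect_equal(fisher_exact_p(3, 7, 0, 10), 240 / 1140, tolerance = 1e-12)
  expect_equal(fisher_exact_p(0, 100, 0, 100), 1.0)
  expect_error(fisher_exact_p(-1, 5, 2, 3), class = "ps4_domain_error")

  # enumeration oracle sweep over random tables with total <= 200
  set.seed(11)
  for (i in 1:150) {
    n <- sample(4:200, 1)
    a <- sample(0:min(n - 3, 30), 1)
    rest <- n - a
    b <- sample(1:(rest - 2), 1)
    c <- sample(0:min(rest - b - 1, 30), 1)
    d <- rest - b - c
    if (d < 1) next
    expect_equal(fisher_exact_p(a, b, c, d), oracle_fisher_p(a, b, c, d),
                 tolerance = 1e-12)
  }
  # and exhaustively over all 2x2 tables with margins (6, 6, k)
  for (k in 1:6) for (a in max(0, k - 6):min(k, 6)) {
    expect_equal(fisher_exact_p(a, 6 - a, k - a, 6 - (k - a)),
                 oracle_fisher_p(a, 6 - a, k - a, 6 - (k - a)),
                 tolerance = 1e-12)
  }
})

test_that("p-value is invariant under row/column swaps", {
  set.seed(3)
  for (i in 1:25) {
    t <- sample(0:40, 4, replace = TRUE) + c(1, 1, 0, 1)
    p <- fisher_exact_p(t[1], t[2], t[3], t[4])
    expect_equal(fisher_exact_p(t[3], t[4], t[1], t[2]), p, tolerance = 1e-10)
    expect_equal(fisher_exact_p(t[2], t[1], t[4], t[3]), p, tolerance = 1e-10)
  }
})

test_that("conditional MLE odds ratio matches fisher.test and inverts its CI", {
  res <- odds_ratio_ci(14, 27676, 1, 13139)
  ft <- fisher.test(matrix(c(14, 27676, 1, 13139), 2, byrow = TRUE))
  # fisher.test solves the same inversion at a looser root tolerance, so the
  # cross-check is approximate; the exact inversion is asserted below at 1e-8
  expect_equal(res$or_estimate, unname(ft$estimate), tolerance = 1e-4)
  expect_equal(res$or_lb, ft$conf.int[1], tolerance = 5e-3)
  expect_equal(res$or_ub, ft$conf.int[2], tolerance = 5e-3)
  expect_equal(res$p_value, ft$p.value, tolerance = 1e-10)
  # sample OR for the same table has the closed form ad/bc
  woolf <- odds_ratio_ci(14, 27676, 1, 13139, method = "sample_or_woolf")
  expect_equal(woolf$or_estimate, 14 * 13139 / (27676 * 1), tolerance = 1e-12)

  # CI endpoints invert the exact one-sided tail tests to 1e-8
  tail_prob <- function(a, b, c, d, psi, upper) {
    m1 <- a + b; m2 <- c + d; k <- a + c
    xs <- max(0, k - m2):min(k, m1)
    lw <- lchoose(m1, xs) + lchoose(m2, k - xs) + xs * log(psi)
    w <- exp(lw - max(lw)); w <- w / sum(w)
    if (upper) sum(w[xs >= a]) else sum(w[xs <= a])
  }
  for (t in list(c(14, 27676, 1, 13139), c(8, 92, 3, 97), c(5, 20, 10, 15),
                 c(2, 8, 1, 9))) {
    r <- odds_ratio_ci(t[1], t[2], t[3], t[4])
    expect_equal(tail_prob(t[1], t[2], t[3], t[4], r$or_lb, upper = TRUE),
                 0.025, tolerance = 1e-8)
    expect_equal(tail_prob(t[1], t[2], t[3], t[4], r$or_ub, upper = FALSE),
                 0.025, tolerance = 1e-8)
  }
})

test_that("odds ratio honours zero-cell contracts and symmetric identities", {
  # cross-product identity: ad = bc -> sample OR exactly 1
  expect_equal(odds_ratio_ci(6, 9, 4, 6, method = "sample_or_woolf")$or_estimate, 1)
  # zero control count: +Inf sample OR; conditional MLE has finite lower bound
  r <- odds_ratio_ci(2, 8, 0, 10)
  expect_true(is.infinite(odds_ratio_ci(2, 8, 0, 10,
                                        method = "sample_or_woolf")$or_estimate))
  expect_true(is.infinite(r$or_estimate) || r$or_estimate > 1)
  expect_true(r$or_lb > 0 && is.finite(r$or_lb))
  expect_true(is.infinite(r$or_ub))
  # both alt cells zero -> undefined, flagged
  r0 <- odds_ratio_ci(0, 10, 0, 10)
  expect_true(r0$flagged)
  expect_true(is.na(r0$or_estimate))
  # all cells >= 10: conditional MLE and sample OR agree within 5%
  set.seed(5)
  for (i in 1:20) {
    t <- sample(10:60, 4, replace = TRUE)
    mle <- odds_ratio_ci(t[1], t[2], t[3], t[4])$or_estimate
    woolf <- (t[1] * t[4]) / (t[2] * t[3])
    expect_lt(abs(mle - woolf) / woolf, 0.05)
  }
})

test_that("variant_association builds the allele-level table per variant", {
  v <- make_variants(2, ac_case = c(5L, 5L), an_case = 1000L,
                     ac_control = c(5L, 1L), an_control = 1000L)
  got <- variant_association(v)
  expect_equal(got$or[1], 1, tolerance = 1e-6)  # identical frequencies
  expect_gt(got$or[2], 1)
  # zero-control variants are refused unless explicitly allowed
  vz <- make_variants(1, ac_control = 0L)
  expect_error(variant_association(vz), class = "ps4_domain_error")
  gz <- variant_association(vz, allow_zero_control = TRUE)
  expect_true(gz$or_flagged)

  # parametric recovery at the expected counts: the CI covers the generating
  # OR and the estimate sits close to it (coverage across random draws is
  # asserted in the acceptance property suite)
  q <- 0.002; or_true <- 5
  af <- or_true * q / (1 - q + or_true * q)
  vv <- make_variants(1, ac_case = as.integer(round(27690 * af)),
                      ac_control = as.integer(round(13140 * q)))
  g <- variant_association(vv)
  expect_true(g$or_lb < or_true && or_true < g$or_ub)
  expect_lt(abs(g$or - or_true) / or_true, 0.1)
})

test_that("min_af_simulation scans allele counts against a fixed control", {
  # exact check at one size: first k with Fisher p < 0.05 vs [1, 13139]
  got <- min_af_simulation(10000)
  k <- got$min_ac
  expect_lt(fisher_exact_p(k, 20000 - k, 1, 13139), 0.05)
  if (k > 1) expect_gte(fisher_exact_p(k - 1, 20000 - k + 1, 1, 13139), 0.05)
  expect_equal(got$min_af, k / 20000)
  expect_true(got$min_af > 3e-4 && got$min_af < 7e-4)

  # OR_LB criterion is also available and at least as strict as p < 0.05 here
  got_lb <- min_af_simulation(10000, criterion = "or_lb_gt_1")
  expect_gte(got_lb$min_ac, got$min_ac - 1L)

  # more controls at fixed control count -> easier significance (smaller min AF)
  a <- min_af_simulation(10000, n_controls = 6570)$min_af
  b <- min_af_simulation(10000, n_controls = 65700, control_ac = 10L)$min_af
  expect_lte(b, a)

  # unattainable criterion reported as NA
  un <- min_af_simulation(50, n_controls = 10, max_k = 3L)
  expect_true(is.na(un$min_af))
})
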