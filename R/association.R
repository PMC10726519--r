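# Exact 2x2 machinery on the noncentral hypergeometric distribution.
# Conditioning on both margins, the case alt-allele count x has support
# lo..hi with lo = max(0, k - m2), hi = min(k, m1), where m1 = case alleles,
# m2 = control alleles, k = total alt alleles. P(x | psi) is proportional to
# choose(m1, x) * choose(m2, k - x) * psi^x.

.nchg_support <- function(m1, m2, k) {
  lo <- max(0L, k - m2)
  hi <- min(k, m1)
  list(lo = lo, hi = hi, x = lo:hi,
       lw = lchoose(m1, lo:hi) + lchoose(m2, k - (lo:hi)))
}

# normalized probabilities at odds ratio psi (log-sum-exp for stability)
.nchg_prob <- function(sup, psi) {
  lp <- sup$lw + sup$x * log(psi)
  lp <- lp - max(lp)
  w <- exp(lp)
  w / sum(w)
}

.nchg_mean <- function(sup, psi) sum(sup$x * .nchg_prob(sup, psi))

# P(X >= a | psi): increasing in psi; P(X <= a | psi): decreasing in psi
.nchg_tail <- function(sup, psi, a, upper = TRUE) {
  p <- .nchg_prob(sup, psi)
  if (upper) sum(p[sup$x >= a]) else sum(p[sup$x <= a])
}

.nchg_root <- function(f) {
  # solve f(log psi) = 0 over an expanding bracket, tight tolerance
  lo <- -40; hi <- 40
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) return(NA_real_)
  exp(uniroot(f, c(lo, hi), tol = 1e-14)$root)
}

#' Two-sided Fisher exact p-value for a 2x2 allele table
#'
#' Standard minimum-likelihood convention: the p-value is the sum of central
#' hypergeometric probabilities, given both margins, over all tables whose
#' probability does not exceed that of the observed table (within a relative
#' tolerance of 1e-7, as in `stats::fisher.test`).
#'
#' @param a,b,c,d Cell counts: case alt, case ref, control alt, control ref.
#' @return The two-sided p-value in (0, 1\].
#' @export
fisher_exact_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("negative cell count", class = "ps4_domain_error")
  sup <- .nchg_support(a + b, c + d, a + c)
  if (length(sup$x) == 1L) return(1)
  p <- .nchg_prob(sup, 1)
  pobs <- p[match(a, sup$x)]
  sum(p[p <= pobs * (1 + 1e-7)])
}

#' Odds ratio with confidence interval for a 2x2 allele table
#'
#' Default method `"conditional_mle"`: the point estimate maximises the
#' noncentral hypergeometric likelihood conditional on both margins, and the
#' interval bounds invert the exact one-sided tail tests at `alpha/2` each
#' side (the construction used by `stats::fisher.test`). Zero cells give 0 or
#' `Inf` estimates with the appropriate one-sided interval. Method
#' `"sample_or_woolf"` is the cross-product estimate `ad/bc` with a Woolf
#' log-scale normal interval (no continuity correction; zero cells give
#' 0/`Inf` with infinite-width bounds).
#'
#' @inheritParams fisher_exact_p
#' @param method `"conditional_mle"` (default) or `"sample_or_woolf"`.
#' @param alpha Two-sided error rate; default 0.05.
#' @return A one-row tibble: `or_estimate`, `or_lb`, `or_ub`, `p_value`,
#'   `method`, `flagged` (TRUE when the odds ratio is undefined because both
#'   alt-allele cells are zero).
#' @export
odds_ratio_ci <- function(a, b, c, d,
                          method = c("conditional_mle", "sample_or_woolf"),
                          alpha = 0.05) {
  method <- match.arg(method)
  if (any(c(a, b, c, d) < 0)) abort("negative cell count", class = "ps4_domain_error")
  if (any(c(a + b, c + d) == 0)) abort("empty margin", class = "ps4_domain_error")
  pv <- fisher_exact_p(a, b, c, d)
  if (a == 0 && c == 0) {
    return(tibble::tibble(or_estimate = NA_real_, or_lb = NA_real_,
                          or_ub = NA_real_, p_value = pv, method = method,
                          flagged = TRUE))
  }
  if (method == "sample_or_woolf") {
    or <- (a * d) / (b * c)  # Inf or 0 with zero cells, NaN only if 0/0
    if (any(c(a, b, c, d) == 0)) {
      lb <- 0; ub <- Inf
    } else {
      se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
      z <- stats::qnorm(1 - alpha / 2)
      lb <- exp(log(or) - z * se); ub <- exp(log(or) + z * se)
    }
    return(tibble::tibble(or_estimate = or, or_lb = lb, or_ub = ub,
                          p_value = pv, method = method, flagged = FALSE))
  }
  sup <- .nchg_support(a + b, c + d, a + c)
  est <- if (a == sup$lo) 0 else if (a == sup$hi) Inf else
    .nchg_root(function(lp) .nchg_mean(sup, exp(lp)) - a)
  lb <- if (a == sup$lo) 0 else
    .nchg_root(function(lp) .nchg_tail(sup, exp(lp), a, upper = TRUE) - alpha / 2)
  ub <- if (a == sup$hi) Inf else
    .nchg_root(function(lp) .nchg_tail(sup, exp(lp), a, upper = FALSE) - alpha / 2)
  tibble::tibble(or_estimate = est, or_lb = lb, or_ub = ub,
                 p_value = pv, method = method, flagged = FALSE)
}

#' Per-variant case-control association statistics
#'
#' Builds the allele-level 2x2 table for every variant (`a = ac_case`,
#' `b = an_case - ac_case`, `c = ac_control`, `d = an_control - ac_control`)
#' and computes the Fisher exact p-value and odds ratio with confidence
#' interval. Variants absent from controls have no finite odds-ratio lower
#' bound; by default they are refused (use the allele-count pathway instead)
#' unless `allow_zero_control = TRUE`, in which case they are flagged.
#'
#' @param x A validated variant tibble.
#' @param method Odds-ratio method, see [odds_ratio_ci()].
#' @param allow_zero_control Allow variants with `ac_control = 0`.
#' @param alpha Two-sided error rate.
#' @return `x` with columns `or`, `or_lb`, `or_ub`, `p_value`, `or_flagged`.
#' @export
variant_association <- function(x, method = c("conditional_mle", "sample_or_woolf"),
                                allow_zero_control = FALSE, alpha = 0.05) {
  method <- match.arg(method)
  if (!allow_zero_control && any(x$ac_control == 0L)) {
    abort(paste0(sum(x$ac_control == 0L), " variant(s) absent from controls: ",
                 "no odds ratio; use the allele-count pathway or set ",
                 "allow_zero_control = TRUE"), class = "ps4_domain_error")
  }
  res <- purrr::pmap(
    list(x$ac_case, x$an_case - x$ac_case, x$ac_control, x$an_control - x$ac_control),
    function(a, b, c, d) odds_ratio_ci(a, b, c, d, method = method, alpha = alpha)
  )
  res <- dplyr::bind_rows(res)
  x$or <- res$or_estimate
  x$or_lb <- res$or_lb
  x$or_ub <- res$or_ub
  x$p_value <- res$p_value
  x$or_flagged <- res$flagged | x$ac_control == 0L
  x
}

#' Minimum detectable case allele frequency by cohort size
#'
#' For each case sample size `n`, scans the case alt-allele count
#' `k = 1, 2, ...` over the table `[[k, 2n - k], [control_ac,
#' 2 * n_controls - control_ac]]` and reports the smallest case allele
#' frequency `k / (2n)` at which the chosen significance criterion holds.
#' Raw values are reported; no monotonicity is imposed.
#'
#' @param case_sizes Integer vector of case cohort sizes (individuals).
#' @param n_controls Control cohort size (individuals); default 6570.
#' @param criterion `"p_lt_05"` (Fisher exact p < 0.05, default) or
#'   `"or_lb_gt_1"` (exact conditional CI lower bound > 1).
#' @param control_ac Simulated control alt-allele count; default 1, the most
#'   favourable non-zero control count.
#' @param max_k Scan ceiling for the case allele count (default 100).
#' @return A tibble with `n_cases`, `min_ac` and `min_af` (`NA` when the
#'   criterion is unattainable within `max_k`).
#' @export
min_af_simulation <- function(case_sizes, n_controls = 6570,
                              criterion = c("p_lt_05", "or_lb_gt_1"),
                              control_ac = 1L, max_k = 100L) {
  criterion <- match.arg(criterion)
  stopifnot(length(case_sizes) > 0, n_controls > 0)
  rows <- purrr::map(case_sizes, function(n) {
    an_case <- 2L * as.integer(n)
    an_ctrl <- 2L * as.integer(n_controls)
    for (k in seq_len(min(max_k, an_case))) {
      hit <- if (criterion == "p_lt_05") {
        fisher_exact_p(k, an_case - k, control_ac, an_ctrl - control_ac) < 0.05
      } else {
        ci <- odds_ratio_ci(k, an_case - k, control_ac, an_ctrl - control_ac)
        !is.na(ci$or_lb) && ci$or_lb > 1
      }
      if (hit) {
        return(tibble::tibble(n_cases = n, min_ac = k, min_af = k / an_case))
      }
    }
    tibble::tibble(n_cases = n, min_ac = NA_integer_, min_af = NA_real_)
  })
  dplyr::bind_rows(rows)
}
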