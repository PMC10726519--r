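#' Likelihood-ratio threshold for an evidence strength
#'
#' In the Bayesian reading of the ACMG/AMP combining rules, one unit of very
#' strong evidence corresponds to combined odds of pathogenicity `C`, and the
#' weaker strengths are successive square roots: strong `C^(1/2)`, moderate
#' `C^(1/4)`, supporting `C^(1/8)`. Values are returned at full precision;
#' rounding to the 2-4 significant figures used in report tables is a display
#' concern only.
#'
#' @param C Combined odds of pathogenicity for very strong evidence (`> 1`).
#' @param strength One of `"supporting"`, `"moderate"`, `"strong"`,
#'   `"very_strong"` (vectorised).
#' @return Numeric likelihood-ratio threshold(s).
#' @export
#' @examples
#' strength_lr(350, c("supporting", "moderate", "strong", "very_strong"))
strength_lr <- function(C, strength) {
  if (!is.numeric(C) || any(C <= 1)) {
    abort("C must be > 1", class = "ps4_domain_error")
  }
  strength <- match.arg(strength, .ps4_strengths, several.ok = TRUE)
  k <- match(strength, rev(.ps4_strengths)) - 1L  # very_strong=0 ... supporting=3
  C^(1 / 2^k)
}

#' Posterior probability of pathogenicity from a likelihood ratio
#'
#' Bayes' rule in odds form: `posterior = lr * prior / ((lr - 1) * prior + 1)`.
#' Monotone increasing in both arguments; `lr = 1` returns the prior.
#'
#' @param lr Combined positive likelihood ratio (>= 0); vectorised.
#' @param prior Prior probability of pathogenicity, in (0, 1).
#' @return Posterior probability in \[0, 1\].
#' @export
posterior_from_lr <- function(lr, prior) {
  if (any(!is.finite(prior)) || any(prior <= 0) || any(prior >= 1)) {
    abort("prior must be in (0, 1)", class = "ps4_domain_error")
  }
  if (any(lr < 0, na.rm = TRUE)) {
    abort("lr must be >= 0", class = "ps4_domain_error")
  }
  lr * prior / ((lr - 1) * prior + 1)
}

#' Solve for the combined odds of pathogenicity C
#'
#' Finds `C` such that a stated evidence combination reaches a target
#' posterior. The default constraint is the one that pins the likely
#' pathogenic boundary: one strong plus one moderate criterion (exponent
#' `1/2 + 1/4 = 0.75`) reaching posterior 0.90. Solved by bracketed
#' root-finding on `log(C)` over (1, 1e6) to relative tolerance 1e-9.
#'
#' @param prior Prior probability of pathogenicity, in (0, 1).
#' @param exponent Exponent of `C` for the constraining combination
#'   (`n_vs/1 + n_s/2 + n_m/4 + n_p/8`); default `0.75`.
#' @param target Target posterior for that combination; default `0.90`.
#' @return The solved `C`.
#' @export
solve_C <- function(prior, exponent = 0.75, target = 0.90) {
  if (prior <= 0 || prior >= 1) abort("prior must be in (0, 1)", class = "ps4_domain_error")
  stopifnot(exponent > 0, target > 0, target < 1)
  f <- function(logC) posterior_from_lr(exp(logC)^exponent, prior) - target
  lo <- log(1 + 1e-12); hi <- log(1e6)
  if (f(lo) * f(hi) > 0) {
    abort("no root for C in (1, 1e6) under this constraint", class = "ps4_solver_error")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  exp(root)
}

#' Combined likelihood ratio of an evidence combination
#'
#' `C^(n_vs/1 + n_s/2 + n_m/4 + n_p/8)`: the combined odds of pathogenicity
#' contributed by a multiset of pathogenic criteria.
#'
#' @param C Combined odds for one very strong criterion.
#' @param n_very_strong,n_strong,n_moderate,n_supporting Criterion counts.
#' @return The combined positive likelihood ratio.
#' @export
combined_lr <- function(C, n_very_strong = 0, n_strong = 0, n_moderate = 0,
                        n_supporting = 0) {
  if (C <= 1) abort("C must be > 1", class = "ps4_domain_error")
  C^(n_very_strong + n_strong / 2 + n_moderate / 4 + n_supporting / 8)
}

#' Build a calibration table for one truth subset
#'
#' Computes, for each evidence strength, the likelihood-ratio threshold
#' (`strength_lr`) and the posterior probability of pathogenicity it implies
#' at the subset's prior (`posterior_from_lr`).
#'
#' @param prior Prior probability of pathogenicity for the subset.
#' @param C Combined odds of pathogenicity; either a number or `"solve"` to
#'   derive it via [solve_C()] with the default constraint.
#' @param subset_id Optional integer label carried into the table.
#' @return A `ps4_calibration` object: a tibble with columns `strength`,
#'   `lr_threshold`, `posterior` (ordered supporting to very strong) and
#'   attributes `prior`, `C`, `subset_id`.
#' @export
#' @examples
#' build_calibration_table(80 / 598, C = 225)
build_calibration_table <- function(prior, C, subset_id = NA_integer_) {
  if (identical(C, "solve")) C <- solve_C(prior)
  if (!is.numeric(C) || C <= 1) abort("C must be > 1", class = "ps4_domain_error")
  if (prior <= 0 || prior >= 1) abort("prior must be in (0, 1)", class = "ps4_domain_error")
  lr <- strength_lr(C, .ps4_strengths)
  out <- tibble::tibble(
    strength = factor(.ps4_strengths, levels = .ps4_strengths),
    lr_threshold = lr,
    posterior = posterior_from_lr(lr, prior)
  )
  structure(out, prior = prior, C = C, subset_id = subset_id,
            class = c("ps4_calibration", class(out)))
}

#' Map an observed likelihood-ratio lower bound to an evidence strength
#'
#' Returns the highest strength whose threshold is at or below `lr_lb`
#' (threshold ties are inclusive), or `NA` when even the supporting threshold
#' is not reached.
#'
#' @param lr_lb Observed lower bound(s) of the positive likelihood ratio.
#' @param table A `ps4_calibration` object.
#' @return Character vector of strengths (`NA` where below supporting).
#' @export
strength_from_lr_lb <- function(lr_lb, table) {
  stopifnot(inherits(table, "ps4_calibration"))
  thr <- setNames(table$lr_threshold, as.character(table$strength))
  vapply(lr_lb, function(x) {
    if (is.na(x) || x < thr[["supporting"]]) return(NA_character_)
    hit <- .ps4_strengths[thr[.ps4_strengths] <= x]
    hit[length(hit)]
  }, character(1))
}

#' @export
print.ps4_calibration <- function(x, ...) {
  cat(sprintf("PS4 calibration table (subset %s): prior = %.4f, C = %.4g\n",
              attr(x, "subset_id"), attr(x, "prior"), attr(x, "C")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
tidy.ps4_calibration <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.ps4_calibration <- function(x, ...) {
  tibble::tibble(subset_id = attr(x, "subset_id"),
                 prior = attr(x, "prior"),
                 C = attr(x, "C"))
}

#' Calibrate all truth subsets
#'
#' Convenience wrapper building one calibration table per subset, at the
#' empirical subset prior. By default the combined-odds constants are the
#' cohort-scale values 225 / 387 / 397 for subsets 1-3; `C = "solve"`
#' derives each from the default likely-pathogenic boundary constraint
#' instead (note the solved value for subset 3 differs strongly from the
#' reported constant; see the methods vignette).
#'
#' @param truth A tibble from [split_truth_subsets()].
#' @param C Named or positional numeric vector of length 3, or `"solve"`.
#' @return A list of `ps4_calibration` objects indexed by subset id.
#' @export
calibrate_subsets <- function(truth, C = c(225, 387, 397)) {
  ids <- sort(unique(truth$subset))
  out <- list()
  for (id in ids) {
    Ci <- if (identical(C, "solve")) "solve" else C[[id]]
    out[[as.character(id)]] <-
      build_calibration_table(subset_prior(truth, id), Ci, subset_id = id)
  }
  out
}
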