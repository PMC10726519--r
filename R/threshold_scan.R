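#' Confusion counts for a binary enrichment rule on a truth subset
#'
#' True positives are P/LP variants flagged by the rule; false positives are
#' flagged non-pathogenic (BL-VUS/B/LB) variants; true negatives and false
#' negatives are the unflagged complements.
#'
#' @param truth A truth tibble with a `truth_label` column.
#' @param flagged Logical vector, one element per row of `truth`.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, flagged) {
  stopifnot(length(flagged) == nrow(truth))
  if (any(is.na(flagged))) {
    abort("rule evaluated to NA for some variants (odds ratio unavailable?)",
          class = "ps4_domain_error")
  }
  pos <- truth$truth_label == "positive"
  tibble::tibble(
    tp = sum(pos & flagged), fp = sum(!pos & flagged),
    tn = sum(!pos & !flagged), fn = sum(pos & !flagged)
  )
}

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy, PPV, NPV and F1. Any 0/0 ratio is
#' returned as `NA` (undefined), never silently as 0.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return A one-row tibble of the seven metrics (including `lr_plus`, the
#'   point estimate sensitivity / (1 - specificity); `Inf` at specificity 1).
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  acc <- div(tp + tn, tp + fp + tn + fn)
  f1 <- ifelse(is.na(ppv) | is.na(sens) | (ppv + sens) == 0, NA_real_,
               2 * ppv * sens / (ppv + sens))
  lr <- ifelse(is.na(sens) | is.na(spec), NA_real_,
               ifelse(spec == 1, ifelse(sens == 0, NA_real_, Inf),
                      sens / (1 - spec)))
  tibble::tibble(sensitivity = sens, specificity = spec, accuracy = acc,
                 ppv = ppv, npv = npv, f1 = f1, lr_plus = lr)
}

#' Positive likelihood ratio with bootstrap confidence interval
#'
#' Point estimate `sensitivity / (1 - specificity)`. The interval follows the
#' bootLR-style scheme: sensitivity and specificity are resampled
#' independently as binomial draws of sizes `tp + fn` and `fp + tn`, `B`
#' times, and the percentile interval of the resampled ratio is taken.
#' Replicates with resampled specificity 1 contribute `Inf` (or `NA` when the
#' resampled sensitivity is also 0; those are dropped). Observed proportions
#' sitting on a boundary (sensitivity 0 or 1, specificity 1) would make the
#' resampling degenerate, so for the resampling step only they are replaced
#' by their median-unbiased counterparts (`0.5^(1/n)` for an observed 1,
#' `1 - 0.5^(1/n)` for an observed 0), as bootLR does; point estimates are
#' not altered. At observed specificity 1 the point estimate is `Inf` and
#' only the lower bound is reported (one-sided at level `level`).
#'
#' @param tp,fp,tn,fn Confusion counts; `tp + fn > 0` and `fp + tn > 0`.
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Integer seed (required for reproducibility).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `lr_plus`, `lr_lb`, `lr_ub`.
#' @export
lr_plus_ci <- function(tp, fp, tn, fn, B = 10000, seed, level = 0.95) {
  stopifnot(tp + fn > 0, fp + tn > 0, B > 0)
  if (missing(seed)) abort("seed is required", class = "ps4_config_error")
  n_pos <- tp + fn; n_neg <- fp + tn
  sens <- tp / n_pos; spec <- tn / n_neg
  point <- if (spec == 1) {
    if (sens == 0) NA_real_ else Inf
  } else sens / (1 - spec)
  # median-unbiased replacements at the boundaries, for resampling only
  sens_b <- if (sens == 1) 0.5^(1 / n_pos) else if (sens == 0) 1 - 0.5^(1 / n_pos) else sens
  spec_b <- if (spec == 1) 0.5^(1 / n_neg) else if (spec == 0) 1 - 0.5^(1 / n_neg) else spec
  draws <- withr::with_seed(seed, {
    bs <- rbinom(B, n_pos, sens_b) / n_pos
    bp <- rbinom(B, n_neg, spec_b) / n_neg
    r <- bs / (1 - bp)
    r[bs == 0 & bp == 1] <- NA_real_
    r
  })
  if (all(is.na(draws))) {
    lb <- NA_real_; ub <- NA_real_
  } else if (spec == 1) {
    lb <- unname(quantile(draws, 1 - level, na.rm = TRUE, names = FALSE))
    ub <- Inf
  } else {
    qs <- quantile(draws, c((1 - level) / 2, (1 + level) / 2),
                   na.rm = TRUE, names = FALSE)
    lb <- qs[1]; ub <- qs[2]
  }
  tibble::tibble(lr_plus = point, lr_lb = lb, lr_ub = ub)
}

.scan_rows <- function(truth, cutoffs, flag_fn, table, B, seed, level) {
  rows <- purrr::imap(cutoffs, function(cut, i) {
    cc <- confusion_counts(truth, flag_fn(cut))
    met <- classification_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
    ci <- lr_plus_ci(cc$tp, cc$fp, cc$tn, cc$fn, B = B,
                     seed = seed + i, level = level)
    dplyr::bind_cols(tibble::tibble(cutoff = cut), cc,
                     met[setdiff(names(met), "lr_plus")], ci)
  })
  out <- dplyr::bind_rows(rows)
  out$strength <- strength_from_lr_lb(out$lr_lb, table)
  structure(out, calibration = table,
            class = c("ps4_scan", class(out)))
}

#' Scan odds-ratio cutoffs on a truth subset
#'
#' For each cutoff, a variant is flagged as enriched when its odds ratio
#' exceeds the cutoff (strict) and the lower bound of its 95% CI exceeds 1.
#' Each row carries the confusion counts, classification metrics, the
#' positive likelihood ratio with bootstrap CI, and the evidence strength
#' implied by the LR lower bound under the supplied calibration table.
#'
#' @param subset A truth tibble (subset 1 or 2) already passed through
#'   [variant_association()] (columns `or`, `or_lb`).
#' @param cutoffs Numeric cutoffs, sorted ascending (default 1:10).
#' @param table A `ps4_calibration` object for the subset.
#' @param B,seed,level Bootstrap parameters, see [lr_plus_ci()].
#' @return A `ps4_scan` tibble, one row per cutoff.
#' @export
scan_or_cutoffs <- function(subset, cutoffs = 1:10, table, B = 10000, seed,
                            level = 0.95) {
  stopifnot(!is.unsorted(cutoffs))
  if (!all(c("or", "or_lb") %in% names(subset))) {
    abort("run variant_association() first (or/or_lb columns missing)",
          class = "ps4_validation_error")
  }
  if (any(subset$ac_control == 0L)) {
    abort("odds-ratio scan requires control-present variants only",
          class = "ps4_domain_error")
  }
  .scan_rows(subset, cutoffs,
             function(cut) subset$or > cut & subset$or_lb > 1,
             table, B, seed, level)
}

#' Scan case allele-count cutoffs on the control-absent subset
#'
#' For each integer cutoff, a variant is flagged when its case allele count
#' is at or above the cutoff (inclusive). All variants must be absent from
#' controls.
#'
#' @param subset3 A truth tibble with `ac_control = 0` throughout.
#' @param cutoffs Integer cutoffs, sorted ascending (default 2:10).
#' @inheritParams scan_or_cutoffs
#' @return A `ps4_scan` tibble, one row per cutoff.
#' @export
scan_ac_cutoffs <- function(subset3, cutoffs = 2:10, table, B = 10000, seed,
                            level = 0.95) {
  stopifnot(!is.unsorted(cutoffs))
  if (any(subset3$ac_control != 0L)) {
    abort("allele-count scan requires variants absent from controls",
          class = "ps4_domain_error")
  }
  .scan_rows(subset3, cutoffs,
             function(cut) subset3$ac_case >= cut,
             table, B, seed, level)
}

#' @export
tidy.ps4_scan <- function(x, ...) tibble::as_tibble(x)

#' Plot a cutoff scan
#'
#' Classification metrics and the LR lower bound against the cutoff, with the
#' calibration strength thresholds as horizontal reference lines.
#'
#' @param object A `ps4_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps4_scan <- function(object, ...) {
  tab <- attr(object, "calibration")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("cutoff", "sensitivity", "specificity",
                                  "accuracy", "ppv", "npv", "f1")],
    -"cutoff", names_to = "metric", values_to = "value"
  )
  p1 <- ggplot2::ggplot(long, ggplot2::aes(.data$cutoff, .data$value,
                                           colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "cutoff", y = NULL, colour = NULL)
  if (!is.null(tab)) {
    p1 <- p1 + ggplot2::geom_hline(
      data = tibble::tibble(y = tab$posterior),
      ggplot2::aes(yintercept = .data$y), linetype = "dotted", colour = "grey50")
  }
  p1
}
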