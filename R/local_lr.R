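#' Class-imbalance weight for the local posterior
#'
#' `(1 - prior) * n_pos / (prior * n_neg)`, where `n_pos` and `n_neg` are the
#' subset-wide positive and negative counts. Multiplying in-window negative
#' counts by this weight makes the windowed positive fraction a posterior at
#' the chosen prior; when the prior equals the empirical subset proportion
#' the weight is exactly 1.
#'
#' @param prior Prior probability of pathogenicity, in (0, 1).
#' @param n_pos,n_neg Subset-wide positive / negative counts (> 0).
#' @return The scalar weight.
#' @export
interval_weight <- function(prior, n_pos, n_neg) {
  if (prior <= 0 || prior >= 1) abort("prior must be in (0, 1)", class = "ps4_domain_error")
  if (n_pos <= 0 || n_neg <= 0) abort("counts must be positive", class = "ps4_domain_error")
  (1 - prior) * n_pos / (prior * n_neg)
}

# Distance to the k-th nearest element of sorted vector xs from point o.
.kth_nearest_dist <- function(xs, o, k) {
  n <- length(xs)
  if (k >= n) return(max(abs(xs - o)))
  i <- findInterval(o, xs)  # xs[i] <= o < xs[i+1]
  lo <- i; hi <- i + 1L
  d <- 0
  for (step in seq_len(k)) {
    dl <- if (lo >= 1L) o - xs[lo] else Inf
    dr <- if (hi <= n) xs[hi] - o else Inf
    if (dl <= dr) { d <- dl; lo <- lo - 1L } else { d <- dr; hi <- hi + 1L }
  }
  d
}

# Core curve evaluation: posterior at each grid point given sorted class ORs.
.local_posterior_at <- function(grid, pos_or, neg_or, half_width,
                                min_pos, min_neg, min_mode, weight) {
  pos_or <- sort(pos_or); neg_or <- sort(neg_or)
  vapply(grid, function(o) {
    r <- half_width
    if (min_mode == "each") {
      r <- max(r, .kth_nearest_dist(pos_or, o, min_pos),
               .kth_nearest_dist(neg_or, o, min_neg))
    } else {
      all_or <- sort(c(pos_or, neg_or))
      r <- max(r, .kth_nearest_dist(all_or, o, min_pos + min_neg))
    }
    # count by distance so the boundary point defining r is always included
    np <- sum(abs(pos_or - o) <= r)
    nn <- sum(abs(neg_or - o) <= r)
    np / (np + weight * nn)
  }, numeric(1))
}

#' Local posterior probability curve over odds-ratio values
#'
#' Every unique odds-ratio value in the subset becomes a grid point at the
#' centre of a symmetric window of half-width `half_width` (in OR units). The
#' window is expanded symmetrically, in rank order of distance, until it
#' contains at least `min_pos` disease-causing and `min_neg` non-pathogenic
#' variants (boundary ties are included, making the curve invariant to the
#' ordering of duplicate OR values). The local posterior at each grid point
#' is the weighted in-window positive fraction,
#' `n_pos / (n_pos + weight * n_neg)`, with the subset-level weight of
#' [interval_weight()]; the local positive likelihood ratio is its odds
#' against the prior odds.
#'
#' @param subset A truth tibble (typically subset 2) with `or` and
#'   `truth_label` columns.
#' @param half_width Window half-width in OR units (default 0.01).
#' @param min_pos,min_neg Minimum in-window counts of each class (default 100
#'   each); `min_count_mode = "total"` instead requires `min_pos + min_neg`
#'   variants of any class.
#' @param prior Prior probability; defaults to the empirical subset
#'   proportion (weight exactly 1).
#' @param min_count_mode `"each"` (default) or `"total"`.
#' @return A `ps4_local_curve` tibble with columns `or`, `posterior`,
#'   `lr_local`; attributes `prior`, `weight`, `window` and the class OR
#'   vectors used (for bootstrapping).
#' @export
local_posterior_curve <- function(subset, half_width = 0.01, min_pos = 100,
                                  min_neg = 100, prior = NULL,
                                  min_count_mode = c("each", "total")) {
  min_count_mode <- match.arg(min_count_mode)
  if (!all(c("or", "truth_label") %in% names(subset))) {
    abort("subset needs or and truth_label columns", class = "ps4_validation_error")
  }
  pos_or <- subset$or[subset$truth_label == "positive"]
  neg_or <- subset$or[subset$truth_label == "negative"]
  if (length(pos_or) < min_pos || length(neg_or) < min_neg) {
    abort(sprintf("subset too small: need >= %d positives and >= %d negatives, have %d / %d",
                  min_pos, min_neg, length(pos_or), length(neg_or)),
          class = "ps4_domain_error")
  }
  n_pos <- length(pos_or); n_neg <- length(neg_or)
  if (is.null(prior)) prior <- n_pos / (n_pos + n_neg)
  w <- interval_weight(prior, n_pos, n_neg)
  grid <- sort(unique(subset$or))
  post <- .local_posterior_at(grid, pos_or, neg_or, half_width,
                              min_pos, min_neg, min_count_mode, w)
  prior_odds <- prior / (1 - prior)
  out <- tibble::tibble(or = grid, posterior = post,
                        lr_local = (post / (1 - post)) / prior_odds)
  structure(out, prior = prior, weight = w,
            window = list(half_width = half_width, min_pos = min_pos,
                          min_neg = min_neg, mode = min_count_mode),
            pos_or = pos_or, neg_or = neg_or,
            class = c("ps4_local_curve", class(out)))
}

#' One-sided bootstrap lower bound for the local curve
#'
#' Resamples the subset's variants with replacement, stratified by class
#' (class sizes preserved), recomputes the local posterior at the original
#' grid points `B` times, and takes the lower `1 - level` percentile at each
#' grid point.
#'
#' @param curve A `ps4_local_curve` object.
#' @param B Bootstrap replicates (default 10000; values below 100 warn).
#' @param seed Integer seed (required).
#' @param level One-sided confidence level (default 0.95).
#' @return The curve with added columns `bound_posterior` and `bound_lr`.
#' @export
bootstrap_lower_bound <- function(curve, B = 10000, seed, level = 0.95) {
  stopifnot(inherits(curve, "ps4_local_curve"))
  if (missing(seed)) abort("seed is required", class = "ps4_config_error")
  if (B <= 0) abort("B must be positive", class = "ps4_domain_error")
  if (B < 100) warn("B < 100 bootstrap replicates: bound will be noisy")
  win <- attr(curve, "window")
  pos_or <- attr(curve, "pos_or"); neg_or <- attr(curve, "neg_or")
  w <- attr(curve, "weight")
  grid <- curve$or
  boots <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      .local_posterior_at(
        grid,
        sample(pos_or, length(pos_or), replace = TRUE),
        sample(neg_or, length(neg_or), replace = TRUE),
        win$half_width, win$min_pos, win$min_neg, win$mode, w
      )
    }, numeric(length(grid)))
  })
  boots <- matrix(boots, nrow = length(grid))
  bound <- apply(boots, 1L, quantile, probs = 1 - level, names = FALSE)
  prior <- attr(curve, "prior")
  curve$bound_posterior <- bound
  curve$bound_lr <- (bound / (1 - bound)) / (prior / (1 - prior))
  curve
}

#' Extract an odds-ratio threshold for an evidence strength
#'
#' The smallest grid odds-ratio value at which the bootstrap lower bound of
#' the local posterior reaches the calibration posterior for the requested
#' strength and stays at or above it for all larger grid values (preventing
#' isolated-blip thresholds).
#'
#' @param curve A `ps4_local_curve` with `bound_posterior` (see
#'   [bootstrap_lower_bound()]).
#' @param table A `ps4_calibration` object sharing the curve's prior.
#' @param strength One of the four evidence strengths.
#' @return The threshold odds ratio, or `NA` if never reached.
#' @export
extract_or_threshold <- function(curve, table, strength) {
  stopifnot(inherits(curve, "ps4_local_curve"), inherits(table, "ps4_calibration"))
  strength <- match.arg(strength, .ps4_strengths)
  if (!"bound_posterior" %in% names(curve)) {
    abort("run bootstrap_lower_bound() first", class = "ps4_validation_error")
  }
  target <- table$posterior[as.character(table$strength) == strength]
  ok <- curve$bound_posterior >= target
  stays <- rev(cumprod(rev(ok))) == 1
  if (!any(stays)) return(NA_real_)
  curve$or[which(stays)[1]]
}

#' @export
tidy.ps4_local_curve <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.ps4_local_curve <- function(x, ...) {
  win <- attr(x, "window")
  tibble::tibble(prior = attr(x, "prior"), weight = attr(x, "weight"),
                 half_width = win$half_width, min_pos = win$min_pos,
                 min_neg = win$min_neg, n_grid = nrow(x))
}

#' Plot a local posterior curve
#'
#' Local posterior (and its one-sided bootstrap bound, when present) against
#' the odds ratio, with the calibration posterior thresholds as horizontal
#' lines.
#'
#' @param object A `ps4_local_curve` object.
#' @param table Optional `ps4_calibration` for threshold reference lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps4_local_curve <- function(object, table = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$or)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$posterior)) +
    ggplot2::labs(x = "odds ratio", y = "local posterior probability")
  if ("bound_posterior" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$bound_posterior),
                                colour = "grey50")
  }
  if (!is.null(table)) {
    p <- p + ggplot2::geom_hline(
      data = tibble::tibble(y = table$posterior,
                            strength = as.character(table$strength)),
      ggplot2::aes(yintercept = .data$y, linetype = .data$strength))
  }
  p
}
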