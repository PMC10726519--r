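#' Run the full PS4 calibration pipeline
#'
#' Orchestrates: inclusion filters, truth-set construction, the minimum-AF
#' simulation, the three-way subset split, per-subset Bayesian calibration,
#' per-variant association statistics, the odds-ratio cutoff scan (subset 1),
#' the local posterior curve with bootstrap bound and extracted thresholds
#' (subset 2), the allele-count cutoff scan (subset 3), PS4 assignment over
#' all filtered variants, and the before/after reclassification report. Any
#' stage lacking its inputs (e.g. an odds-ratio scan with no control-present
#' variants) is skipped with a logged reason instead of failing.
#'
#' @param variants A validated variant tibble (e.g. from
#'   [read_variant_table()] or [generate_cohort()]).
#' @param genes Gene allow-list for the inclusion filters; defaults to all
#'   genes present in the input.
#' @param min_af Case-AF boundary between subsets 1 and 2 (default 0.0005).
#' @param C Per-subset combined odds of pathogenicity (default
#'   `c(225, 387, 397)`), or `"solve"`.
#' @param or_cutoffs,ac_cutoffs Scan grids (defaults 1:10 and 2:10).
#' @param half_width,min_pos,min_neg Local-curve window parameters.
#' @param B Bootstrap replicates for every bootstrap in the run.
#' @param seed Mandatory integer seed governing all randomness.
#' @param min_af_case_sizes Case sizes for the minimum-AF table (default
#'   `seq(7000, 20000, by = 1000)`).
#' @param thresholds PS4 thresholds, see [ps4_thresholds()].
#' @param out_dir Optional directory: when given, every artifact is written
#'   as TSV plus a JSON manifest recording the configuration hash, seed and
#'   package version.
#' @return A `ps4_pipeline` list with elements `filtered`, `truth`,
#'   `min_af_table`, `calibration`, `or_scan`, `local_curve`,
#'   `local_thresholds`, `ac_scan`, `ps4`, `reclassification`, `log`.
#' @export
run_ps4_pipeline <- function(variants,
                             genes = unique(variants$gene),
                             min_af = 0.0005,
                             C = c(225, 387, 397),
                             or_cutoffs = 1:10,
                             ac_cutoffs = 2:10,
                             half_width = 0.01, min_pos = 100, min_neg = 100,
                             B = 10000, seed,
                             min_af_case_sizes = seq(7000, 20000, by = 1000),
                             thresholds = ps4_thresholds(),
                             out_dir = NULL) {
  if (missing(seed)) abort("seed is required", class = "ps4_config_error")
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  filtered <- apply_inclusion_filters(variants, genes = genes)
  say("filters: %d -> %d variants", nrow(variants), nrow(filtered))

  truth <- build_truth_set(filtered)
  say("truth set: %d variants (%d positives, %d negatives)", nrow(truth),
      sum(truth$truth_label == "positive"), sum(truth$truth_label == "negative"))

  min_af_table <- min_af_simulation(min_af_case_sizes)
  truth <- split_truth_subsets(truth, min_af = min_af)
  pri <- attr(truth, "priors")
  say("subsets: %s", paste(sprintf("%d (n=%d, prior=%.4f)", pri$subset,
                                   pri$n_pos + pri$n_neg, pri$prior), collapse = "; "))

  calib <- calibrate_subsets(truth, C = C)

  s1 <- truth[truth$subset == 1L, ]
  s2 <- truth[truth$subset == 2L, ]
  s3 <- truth[truth$subset == 3L, ]

  or_scan <- NULL
  assoc12 <- NULL
  if (nrow(s1) > 0 && !is.null(calib[["1"]])) {
    s1 <- variant_association(s1)
    or_scan <- scan_or_cutoffs(s1, or_cutoffs, calib[["1"]], B = B, seed = seed)
    say("subset 1: OR scan over %d cutoffs", length(or_cutoffs))
  } else {
    say("subset 1: OR scan skipped (no control-present variants)")
  }

  local_curve <- NULL
  local_thresholds <- NULL
  if (nrow(s2) > 0 && !is.null(calib[["2"]]) &&
      sum(s2$truth_label == "positive") >= min_pos &&
      sum(s2$truth_label == "negative") >= min_neg) {
    s2 <- variant_association(s2)
    local_curve <- local_posterior_curve(s2, half_width = half_width,
                                         min_pos = min_pos, min_neg = min_neg,
                                         prior = subset_prior(truth, 2L))
    local_curve <- bootstrap_lower_bound(local_curve, B = B, seed = seed + 1L)
    local_thresholds <- tibble::tibble(
      strength = .ps4_strengths,
      or_threshold = vapply(.ps4_strengths, function(s)
        extract_or_threshold(local_curve, calib[["2"]], s), numeric(1))
    )
    say("subset 2: local curve on %d grid points, B = %d", nrow(local_curve), B)
  } else {
    say("subset 2: local curve skipped (insufficient variants)")
  }

  ac_scan <- NULL
  if (nrow(s3) > 0 && !is.null(calib[["3"]])) {
    ac_scan <- scan_ac_cutoffs(s3, ac_cutoffs, calib[["3"]], B = B, seed = seed + 2L)
    say("subset 3: AC scan over %d cutoffs", length(ac_cutoffs))
  } else {
    say("subset 3: AC scan skipped (no control-absent variants)")
  }

  # PS4 assignment over all filtered variants, then before/after classification
  present <- filtered$ac_control > 0L
  with_or <- filtered
  if (any(present)) {
    assoc <- variant_association(filtered[present, ], allow_zero_control = FALSE)
    with_or$or <- NA_real_; with_or$or_lb <- NA_real_
    with_or$or_ub <- NA_real_; with_or$p_value <- NA_real_
    with_or[present, c("or", "or_lb", "or_ub", "p_value")] <-
      assoc[, c("or", "or_lb", "or_ub", "p_value")]
  }
  ps4 <- assign_ps4(with_or, thresholds = thresholds)
  say("PS4 assigned to %d of %d variants (%d OR pathway, %d AC pathway)",
      sum(!is.na(ps4$ps4_level)), nrow(ps4),
      sum(ps4$ps4_pathway == "OR", na.rm = TRUE),
      sum(ps4$ps4_pathway == "AC", na.rm = TRUE))

  before <- classify_variants(ps4, use_ps4 = FALSE)
  after <- classify_variants(ps4, use_ps4 = TRUE)
  reclass <- reclassification_report(before, after)

  out <- structure(list(filtered = filtered, truth = truth,
                        min_af_table = min_af_table, calibration = calib,
                        or_scan = or_scan, local_curve = local_curve,
                        local_thresholds = local_thresholds,
                        ac_scan = ac_scan, ps4 = ps4,
                        reclassification = reclass, log = log),
                   class = "ps4_pipeline")
  if (!is.null(out_dir)) {
    .write_pipeline(out, out_dir, seed = seed, B = B, min_af = min_af, C = C)
  }
  out
}

.write_pipeline <- function(res, out_dir, seed, B, min_af, C) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    utils::write.table(tibble::as_tibble(x), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(attr(res$truth, "priors"), "subset_priors.tsv")
  calib_tbl <- dplyr::bind_rows(purrr::map(res$calibration, function(tb) {
    dplyr::bind_cols(glance(tb), tidy(tb))
  }))
  wr(calib_tbl, "calibration.tsv")
  wr(res$min_af_table, "min_af.tsv")
  wr(res$or_scan, "or_scan.tsv")
  wr(res$local_curve, "local_curve.tsv")
  wr(res$local_thresholds, "local_thresholds.tsv")
  wr(res$ac_scan, "ac_scan.tsv")
  wr(res$ps4, "ps4_assignments.tsv")
  wr(res$reclassification$transitions, "reclassification.tsv")
  cfg <- list(seed = seed, B = B, min_af = min_af, C = C)
  manifest <- list(config = cfg, config_hash = rlang::hash(cfg),
                   package = "ps4calib",
                   version = as.character(utils::packageVersion("ps4calib")),
                   log = res$log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ps4_pipeline <- function(x, ...) {
  cat("PS4 calibration pipeline run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Cross-tabulate classification changes
#'
#' Summarises before/after ACMG classifications over the same variant
#' universe: a transition table plus counts of PS4 tags by level and pathway.
#'
#' @param before,after Variant tibbles with `variant_id` and `acmg_class`
#'   columns (and `ps4_level`/`ps4_pathway` on `after` for the tag summary).
#' @return A list with `transitions` (tibble `from`, `to`, `n`), `upgraded`,
#'   `downgraded` counts, and `ps4_summary`.
#' @export
reclassification_report <- function(before, after) {
  miss <- c(setdiff(before$variant_id, after$variant_id),
            setdiff(after$variant_id, before$variant_id))
  if (length(miss) > 0) {
    abort(paste0("variant universes differ; missing id(s): ",
                 paste(head(miss, 5L), collapse = ", ")),
          class = "ps4_validation_error")
  }
  m <- dplyr::inner_join(
    before[, c("variant_id", "acmg_class")],
    after[, c("variant_id", "acmg_class")],
    by = "variant_id", suffix = c("_before", "_after")
  )
  rank <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)
  trans <- dplyr::count(m, from = .data$acmg_class_before,
                        to = .data$acmg_class_after, name = "n")
  ps4_summary <- NULL
  if (all(c("ps4_level", "ps4_pathway") %in% names(after))) {
    ps4_summary <- dplyr::count(
      dplyr::filter(after, !is.na(.data$ps4_level)),
      level = .data$ps4_level, pathway = .data$ps4_pathway, name = "n")
  }
  list(
    transitions = trans,
    upgraded = sum(trans$n[rank[trans$to] > rank[trans$from]]),
    downgraded = sum(trans$n[rank[trans$to] < rank[trans$from]]),
    ps4_summary = ps4_summary
  )
}
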