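#' Read a case-control variant table
#'
#' Reads a tab-separated cohort variant table into a validated tibble, one row
#' per biallelic alt allele. Canonical columns are `variant_id`, `gene`,
#' `consequence`, `ac_case`, `an_case`, `ac_control`, `an_control`,
#' `curated_class`, `evidence_tags` (comma-separated ACMG codes, e.g.
#' `"PM2_Supporting,PM3,PP3"`) and `external_conflict` (0/1). Optional columns
#' `mean_gq`, `mean_dp` and `vus_temperature` are carried through when present.
#' All counting is allele-based: `an = 2 * genotyped individuals`, so allele
#' frequencies are `ac/an`.
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Optional named character vector remapping file column names to
#'   canonical names, e.g. `c(AC.cases = "ac_case")`.
#' @return A tibble of validated variant records with derived `af_case` and
#'   `af_control` columns.
#' @export
read_variant_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("variant table not found: ", path), class = "ps4_io_error")
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    hit <- names(raw) %in% names(schema)
    names(raw)[hit] <- unname(schema[names(raw)[hit]])
  }
  validate_variant_table(tibble::as_tibble(raw))
}

#' Validate a variant table
#'
#' Checks mandatory columns, coerces types, enforces the allele-count
#' invariants (`0 <= ac <= an`, `an > 0`) and recomputes `af_case` /
#' `af_control`. Malformed rows are reported with their row numbers.
#'
#' @param x A data frame of variant records.
#' @return A validated tibble.
#' @export
validate_variant_table <- function(x) {
  mandatory <- c("variant_id", "gene", "consequence", "ac_case", "an_case",
                 "ac_control", "an_control", "curated_class")
  missing <- setdiff(mandatory, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "ps4_schema_error")
  }
  x <- tibble::as_tibble(x)
  for (col in c("ac_case", "an_case", "ac_control", "an_control")) {
    v <- suppressWarnings(as.integer(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad) > 0) {
      abort(paste0("non-integer ", col, " in row(s): ",
                   paste(head(bad, 5L), collapse = ", ")),
            class = "ps4_validation_error")
    }
    x[[col]] <- v
  }
  if (!"evidence_tags" %in% names(x)) x$evidence_tags <- ""
  x$evidence_tags[is.na(x$evidence_tags)] <- ""
  if (!"external_conflict" %in% names(x)) x$external_conflict <- FALSE
  x$external_conflict <- as.logical(as.integer(x$external_conflict)) |
    x$external_conflict %in% c("TRUE", "true")

  bad_class <- which(!x$curated_class %in% .ps4_classes | is.na(x$curated_class))
  if (length(bad_class) > 0) {
    abort(paste0("curated_class must be one of P/LP/VUS/LB/B; bad row(s): ",
                 paste(head(bad_class, 5L), collapse = ", ")),
          class = "ps4_validation_error")
  }
  bad_cons <- which(!x$consequence %in% .ps4_consequences)
  if (length(bad_cons) > 0) x$consequence[bad_cons] <- "other"

  bad_an <- which(x$an_case <= 0L | x$an_control <= 0L)
  if (length(bad_an) > 0) {
    abort(paste0("allele number (an) must be positive; bad row(s): ",
                 paste(head(bad_an, 5L), collapse = ", ")),
          class = "ps4_validation_error")
  }
  bad_ac <- which(x$ac_case < 0L | x$ac_control < 0L |
                    x$ac_case > x$an_case | x$ac_control > x$an_control)
  if (length(bad_ac) > 0) {
    abort(paste0("allele counts must satisfy 0 <= ac <= an; offending variant(s): ",
                 paste(head(x$variant_id[bad_ac], 5L), collapse = ", "),
                 " (row ", paste(head(bad_ac, 5L), collapse = ", "), ")"),
          class = "ps4_validation_error")
  }
  x$af_case <- x$ac_case / x$an_case
  x$af_control <- x$ac_control / x$an_control
  x
}

#' Filter variants for PS4 threshold analysis
#'
#' Applies the cohort inclusion filters: control MAF ceiling, genotype-quality
#' and depth floors (skipped with a warning when the QC columns are absent),
#' gene allow-list, consequence allow-list, and presence in at least one case.
#' Curated P/LP variants bypass the consequence filter. Per-rule exclusion
#' counts are attached as the `"filter_log"` attribute.
#'
#' @param x A validated variant tibble.
#' @param genes Character vector of genes to keep (mandatory, non-empty).
#' @param max_control_maf Control minor-allele-frequency ceiling (default 0.01).
#' @param min_gq,min_dp Genotype-quality and depth floors (defaults 20 and 10),
#'   applied only when `mean_gq` / `mean_dp` columns exist.
#' @param consequences Allowed consequence classes; defaults to the
#'   protein-altering and splice-affecting set.
#' @return Filtered tibble; attribute `"filter_log"` holds per-rule counts.
#' @export
apply_inclusion_filters <- function(x,
                                    genes,
                                    max_control_maf = 0.01,
                                    min_gq = 20,
                                    min_dp = 10,
                                    consequences = setdiff(.ps4_consequences,
                                                           c("synonymous", "other"))) {
  if (missing(genes) || length(genes) == 0) {
    abort("gene allow-list must be non-empty", class = "ps4_config_error")
  }
  log <- list()
  keep <- rep(TRUE, nrow(x))

  r <- x$af_control < max_control_maf
  log$control_maf <- sum(keep & !r)
  keep <- keep & r

  if ("mean_gq" %in% names(x) && "mean_dp" %in% names(x)) {
    r <- (is.na(x$mean_gq) | x$mean_gq > min_gq) &
      (is.na(x$mean_dp) | x$mean_dp > min_dp)
    log$qc <- sum(keep & !r)
    keep <- keep & r
  } else {
    warn("mean_gq/mean_dp absent: genotype-quality and depth filter skipped")
    log$qc <- NA_integer_
  }

  r <- x$gene %in% genes
  log$gene <- sum(keep & !r)
  keep <- keep & r

  r <- x$ac_case >= 1L
  log$in_cases <- sum(keep & !r)
  keep <- keep & r

  # curated P/LP bypass the consequence class filter
  r <- x$consequence %in% consequences | x$curated_class %in% c("P", "LP")
  log$consequence <- sum(keep & !r)
  keep <- keep & r

  out <- x[keep, , drop = FALSE]
  attr(out, "filter_log") <- log
  out
}

# ACGS temperature from pathogenic-direction evidence counts.
# s counts strong (very strong included), m moderate, p supporting.
.acgs_temperature <- function(s, m, p) {
  if ((s >= 1 && p >= 1) || (m >= 2 && p >= 1) || (m >= 1 && p >= 3)) return("hot")
  if (s >= 1 || m >= 2 || (m >= 1 && p >= 2) || p >= 4) return("warm")
  if ((m >= 1 && p >= 1) || p >= 3) return("tepid")
  if (m >= 1 || p >= 2) return("cool")
  if (p >= 1) return("cold")
  "ice_cold"
}

#' Build the truth set of credibly classified variants
#'
#' Positives are curated P/LP variants without conflicting external
#' interpretation; negatives are B, LB and benign-leaning VUS (ACGS
#' temperature cool, cold or ice cold). Pathogenic-leaning VUS (hot, warm,
#' tepid) and any variant with an external interpretation conflict are
#' excluded. A precomputed `vus_temperature` column takes precedence over
#' temperatures derived from `evidence_tags`.
#'
#' @param x A validated variant tibble.
#' @return The truth-set tibble with a `truth_label` column
#'   (`"positive"` / `"negative"`); excluded rows are dropped.
#' @export
build_truth_set <- function(x) {
  if (any(is.na(x$curated_class))) {
    abort("curated_class missing for some records", class = "ps4_validation_error")
  }
  temp <- if ("vus_temperature" %in% names(x)) x$vus_temperature else rep(NA_character_, nrow(x))
  need <- which(x$curated_class == "VUS" & (is.na(temp) | temp == ""))
  if (length(need) > 0) {
    temp[need] <- vapply(x$evidence_tags[need], vus_temperature, character(1))
  }
  label <- rep(NA_character_, nrow(x))
  label[x$curated_class %in% c("P", "LP")] <- "positive"
  label[x$curated_class %in% c("B", "LB")] <- "negative"
  bl <- x$curated_class == "VUS" & temp %in% c("cool", "cold", "ice_cold")
  label[bl] <- "negative"
  keep <- !is.na(label) & !x$external_conflict
  out <- x[keep, , drop = FALSE]
  out$truth_label <- label[keep]
  out
}

#' Split the truth set into the three analysis subsets
#'
#' Subset 1: variants present in both cohorts with case allele frequency at or
#' above `min_af` (boundary inclusive). Subset 2: present in both cohorts with
#' case AF below `min_af`. Subset 3: absent from controls. The per-subset
#' prior probability of pathogenicity is the fraction of positives.
#'
#' @param truth A truth-set tibble from [build_truth_set()].
#' @param min_af Minimum case allele frequency at which case-control
#'   significance is attainable (default 0.0005, from the minimum-AF
#'   simulation at cohort scale).
#' @return The tibble with an integer `subset` column; attribute `"priors"`
#'   holds a tibble of per-subset counts and priors. Subsets with zero
#'   positives or zero negatives are flagged in the `degenerate` column of
#'   that attribute, and downstream calibration refuses to run on them.
#' @export
split_truth_subsets <- function(truth, min_af = 0.0005) {
  stopifnot(min_af > 0, min_af < 1)
  if (!"truth_label" %in% names(truth)) {
    abort("input must come from build_truth_set()", class = "ps4_validation_error")
  }
  subset <- ifelse(truth$ac_control == 0L, 3L,
                   ifelse(truth$af_case >= min_af, 1L, 2L))
  truth$subset <- subset
  pri <- dplyr::summarise(
    dplyr::group_by(truth, subset = .data$subset),
    n_pos = sum(.data$truth_label == "positive"),
    n_neg = sum(.data$truth_label == "negative"),
    .groups = "drop"
  )
  pri$prior <- pri$n_pos / (pri$n_pos + pri$n_neg)
  pri$degenerate <- pri$n_pos == 0L | pri$n_neg == 0L
  if (any(pri$degenerate)) {
    warn(paste0("subset(s) ", paste(pri$subset[pri$degenerate], collapse = ", "),
                " have zero positives or negatives; calibration will refuse them"))
  }
  attr(truth, "priors") <- pri
  truth
}

#' Per-subset prior probability of pathogenicity
#'
#' @param truth A tibble from [split_truth_subsets()].
#' @param id Subset id (1, 2 or 3).
#' @return The empirical prior (positives over total) for that subset.
#' @export
subset_prior <- function(truth, id) {
  pri <- attr(truth, "priors")
  if (is.null(pri)) abort("input must come from split_truth_subsets()")
  row <- pri[pri$subset == id, , drop = FALSE]
  if (nrow(row) == 0) abort(paste0("no variants in subset ", id))
  if (row$degenerate) {
    abort(paste0("subset ", id, " has zero positives or zero negatives; ",
                 "prior undefined for calibration"), class = "ps4_degenerate_subset")
  }
  row$prior
}

#' Write a variant table to TSV
#'
#' @param x A variant tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
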