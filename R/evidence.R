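#' Parse ACMG/AMP evidence tags
#'
#' Splits a comma-separated tag string (e.g.
#' `"PVS1,PM2_Supporting,PM3_Strong,PP3"`) into one row per tag with the base
#' code, direction and effective strength. The code prefix sets the default
#' strength (PVS very strong, PS strong, PM moderate, PP supporting; BA
#' stand-alone, BS strong, BP supporting) and an explicit `_Strength` suffix
#' overrides it. One tag per base code is allowed.
#'
#' @param tags A comma-separated string, or character vector of single codes.
#' @return A tibble with columns `code`, `base`, `direction`, `strength`.
#' @export
parse_evidence_tags <- function(tags) {
  if (length(tags) == 1L && (is.na(tags) || tags == "")) {
    return(tibble::tibble(code = character(), base = character(),
                          direction = character(), strength = character()))
  }
  codes <- unlist(strsplit(tags, ",", fixed = TRUE))
  codes <- trimws(codes)
  codes <- codes[codes != ""]
  parts <- strsplit(codes, "_", fixed = TRUE)
  base <- vapply(parts, `[[`, character(1), 1L)
  mod <- vapply(parts, function(p) if (length(p) > 1L) tolower(p[[2L]]) else NA_character_,
                character(1))
  prefix <- toupper(substr(base, 1L, 2L))
  prefix[toupper(substr(base, 1L, 3L)) == "PVS"] <- "PVS"
  default <- c(PVS = "very_strong", PS = "strong", PM = "moderate",
               PP = "supporting", BA = "stand_alone", BS = "strong",
               BP = "supporting")
  if (any(!prefix %in% names(default))) {
    abort(paste0("unknown evidence code(s): ",
                 paste(unique(base[!prefix %in% names(default)]), collapse = ", ")),
          class = "ps4_validation_error")
  }
  strength <- unname(default[prefix])
  ok_mod <- c(verystrong = "very_strong", very_strong = "very_strong",
              strong = "strong", moderate = "moderate",
              supporting = "supporting", standalone = "stand_alone")
  has_mod <- !is.na(mod)
  if (any(has_mod & !mod %in% names(ok_mod))) {
    abort(paste0("unknown strength modifier in: ",
                 paste(codes[has_mod & !mod %in% names(ok_mod)], collapse = ", ")),
          class = "ps4_validation_error")
  }
  strength[has_mod] <- unname(ok_mod[mod[has_mod]])
  if (anyDuplicated(base)) {
    abort(paste0("duplicated base code(s): ",
                 paste(unique(base[duplicated(base)]), collapse = ", ")),
          class = "ps4_validation_error")
  }
  tibble::tibble(code = codes, base = base,
                 direction = ifelse(startsWith(prefix, "B"), "benign", "pathogenic"),
                 strength = strength)
}

#' Load the ACMG/AMP combining-rule table
#'
#' @param path Path to a combining-rule JSON file; defaults to the packaged
#'   standard 2015 table.
#' @return The rule list.
#' @export
acmg_rules_2015 <- function(path = NULL) {
  path <- path %||% system.file("extdata", "acmg_rules_2015.json",
                                package = "ps4calib", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

.count_strengths <- function(parsed) {
  path <- parsed[parsed$direction == "pathogenic", ]
  ben <- parsed[parsed$direction == "benign", ]
  list(
    vs = sum(path$strength == "very_strong"),
    s = sum(path$strength == "strong"),
    m = sum(path$strength == "moderate"),
    p = sum(path$strength == "supporting"),
    ba = sum(ben$strength == "stand_alone"),
    bs = sum(ben$strength == "strong"),
    # benign moderate tags (non-standard) are counted as supporting
    bp = sum(ben$strength %in% c("moderate", "supporting"))
  )
}

.match_rules <- function(counts, rules) {
  for (r in rules) {
    need <- r[setdiff(names(r), "rule")]
    if (all(vapply(names(need), function(k) counts[[k]] >= need[[k]], logical(1)))) {
      return(r$rule)
    }
  }
  NULL
}

#' Combine ACMG/AMP evidence into a five-class call
#'
#' Applies the configured combining table (default: the standard 2015 rules)
#' to the effective strength counts of the supplied tags. When both a
#' pathogenic and a benign combination qualify, the result is VUS with
#' `fired_rule = "conflict"`. VUS calls carry an ACGS temperature.
#'
#' @param tags A comma-separated tag string or a parsed tag tibble from
#'   [parse_evidence_tags()].
#' @param rules A combining-rule list from [acmg_rules_2015()].
#' @return A one-row tibble: `acmg_class`, `vus_temperature` (`NA` unless
#'   VUS), `fired_rule`.
#' @export
combine_acmg <- function(tags, rules = acmg_rules_2015()) {
  parsed <- if (is.data.frame(tags)) tags else parse_evidence_tags(tags)
  cnt <- .count_strengths(parsed)
  p_rule <- .match_rules(cnt, rules$pathogenic)
  lp_rule <- .match_rules(cnt, rules$likely_pathogenic)
  b_rule <- .match_rules(cnt, rules$benign)
  lb_rule <- .match_rules(cnt, rules$likely_benign)
  path_hit <- p_rule %||% lp_rule
  ben_hit <- b_rule %||% lb_rule
  if (!is.null(path_hit) && !is.null(ben_hit)) {
    cls <- "VUS"; fired <- "conflict"
  } else if (!is.null(p_rule)) {
    cls <- "P"; fired <- p_rule
  } else if (!is.null(lp_rule)) {
    cls <- "LP"; fired <- lp_rule
  } else if (!is.null(b_rule)) {
    cls <- "B"; fired <- b_rule
  } else if (!is.null(lb_rule)) {
    cls <- "LB"; fired <- lb_rule
  } else {
    cls <- "VUS"; fired <- "none"
  }
  tibble::tibble(
    acmg_class = cls,
    vus_temperature = if (cls == "VUS") vus_temperature(parsed) else NA_character_,
    fired_rule = fired
  )
}

#' ACGS VUS temperature from pathogenic evidence
#'
#' Grades a variant of uncertain significance by its pathogenic-direction
#' evidence pattern: hot (1 strong + 1 supporting, 2 moderate + 1 supporting,
#' or 1 moderate + 3 supporting), warm (1 strong, 2 moderate, 1 moderate + 2
#' supporting, or 4 supporting), tepid (1 moderate + 1 supporting or 3
#' supporting), cool (1 moderate or 2 supporting), cold (1 supporting),
#' ice cold (none). Patterns use at-least semantics, so exceeding a pattern
#' never yields a cooler level; very strong tags count as strong. Benign-
#' direction tags are ignored.
#'
#' @inheritParams combine_acmg
#' @return One of `"hot"`, `"warm"`, `"tepid"`, `"cool"`, `"cold"`,
#'   `"ice_cold"`.
#' @export
vus_temperature <- function(tags) {
  parsed <- if (is.data.frame(tags)) tags else parse_evidence_tags(tags)
  cnt <- .count_strengths(parsed)
  .acgs_temperature(cnt$vs + cnt$s, cnt$m, cnt$p)
}

#' Adjusted PS4 thresholds
#'
#' The calibrated PS4 rules: strong via OR > 6 with CI excluding 1; moderate
#' via OR > 3 with CI excluding 1, or case allele count >= 6 for variants
#' absent from controls; supporting via OR > 2.27 for variants with case AF
#' < 0.0005, or case allele count >= 3 when absent from controls. The
#' supporting OR rule deliberately carries no CI requirement (unlike the
#' strong/moderate OR rules); set `require_or_lb_supporting = TRUE` to add
#' one.
#'
#' @param or_strong,or_moderate,or_supporting OR cutoffs (strict).
#' @param supporting_af_max Case-AF ceiling for the supporting OR rule.
#' @param ac_moderate,ac_supporting Case allele-count cutoffs (inclusive) for
#'   control-absent variants.
#' @param require_or_lb_supporting Also require `or_lb > 1` for the
#'   supporting OR rule (default FALSE).
#' @return A `ps4_thresholds` list.
#' @export
ps4_thresholds <- function(or_strong = 6, or_moderate = 3, or_supporting = 2.27,
                           supporting_af_max = 0.0005,
                           ac_moderate = 6L, ac_supporting = 3L,
                           require_or_lb_supporting = FALSE) {
  structure(list(or_strong = or_strong, or_moderate = or_moderate,
                 or_supporting = or_supporting,
                 supporting_af_max = supporting_af_max,
                 ac_moderate = ac_moderate, ac_supporting = ac_supporting,
                 require_or_lb_supporting = require_or_lb_supporting),
            class = "ps4_thresholds")
}

#' Assign adjusted PS4 evidence to variants
#'
#' Applies the two PS4 pathways at the configured thresholds and returns the
#' highest applicable level per variant. Variants present in controls use the
#' odds-ratio pathway (columns `or`, `or_lb` from [variant_association()]
#' are required for them); variants absent from controls use the case
#' allele-count pathway.
#'
#' @param x A validated variant tibble, with association columns for any
#'   control-present variants.
#' @param thresholds A [ps4_thresholds()] list.
#' @return `x` with columns `ps4_level` (`"strong"`, `"moderate"`,
#'   `"supporting"` or `NA`), `ps4_pathway` (`"OR"`, `"AC"` or `NA`) and
#'   `ps4_tag` (e.g. `"PS4_Moderate"`; plain `"PS4"` for strong).
#' @export
assign_ps4 <- function(x, thresholds = ps4_thresholds()) {
  stopifnot(inherits(thresholds, "ps4_thresholds"))
  present <- x$ac_control > 0L
  if (any(present) && !all(c("or", "or_lb") %in% names(x))) {
    abort("control-present variants need or/or_lb columns; run variant_association()",
          class = "ps4_validation_error")
  }
  n <- nrow(x)
  or <- if ("or" %in% names(x)) x$or else rep(NA_real_, n)
  or_lb <- if ("or_lb" %in% names(x)) x$or_lb else rep(NA_real_, n)
  if (any(present & (is.na(or) | is.na(or_lb)))) {
    abort("missing odds ratio for control-present variant(s)",
          class = "ps4_validation_error")
  }
  level <- rep(NA_character_, n)
  pathway <- rep(NA_character_, n)

  # allele-count pathway (absent from controls), inclusive cutoffs
  ac_mod <- !present & x$ac_case >= thresholds$ac_moderate
  ac_sup <- !present & x$ac_case >= thresholds$ac_supporting
  level[ac_sup] <- "supporting"; pathway[ac_sup] <- "AC"
  level[ac_mod] <- "moderate"; pathway[ac_mod] <- "AC"

  # odds-ratio pathway (present in controls), strict OR cutoffs
  or_sup <- present & or > thresholds$or_supporting &
    x$af_case < thresholds$supporting_af_max
  if (thresholds$require_or_lb_supporting) or_sup <- or_sup & or_lb > 1
  or_mod <- present & or > thresholds$or_moderate & or_lb > 1
  or_str <- present & or > thresholds$or_strong & or_lb > 1
  level[or_sup] <- "supporting"
  level[or_mod] <- "moderate"
  level[or_str] <- "strong"
  pathway[or_sup | or_mod | or_str] <- "OR"

  x$ps4_level <- level
  x$ps4_pathway <- pathway
  x$ps4_tag <- dplyr::case_match(level,
                                 "strong" ~ "PS4",
                                 "moderate" ~ "PS4_Moderate",
                                 "supporting" ~ "PS4_Supporting",
                                 .default = NA_character_)
  x
}

#' Classify variants from their evidence tags
#'
#' Runs [combine_acmg()] over a variant table, optionally appending the
#' assigned PS4 tags first (so before/after comparisons share one code path).
#'
#' @param x A variant tibble with an `evidence_tags` column (and `ps4_tag`
#'   when `use_ps4 = TRUE`).
#' @param rules Combining rules, see [acmg_rules_2015()].
#' @param use_ps4 Append the `ps4_tag` column to each variant's tags before
#'   combining (default FALSE).
#' @return `x` with columns `acmg_class`, `vus_temperature`, `fired_rule`.
#' @export
classify_variants <- function(x, rules = acmg_rules_2015(), use_ps4 = FALSE) {
  tags <- x$evidence_tags
  if (use_ps4) {
    if (!"ps4_tag" %in% names(x)) abort("run assign_ps4() first", class = "ps4_validation_error")
    # the assigned PS4 replaces any pre-existing PS4 tag
    stripped <- vapply(strsplit(tags, ",", fixed = TRUE), function(tt) {
      paste(tt[!startsWith(trimws(tt), "PS4")], collapse = ",")
    }, character(1))
    tags <- ifelse(is.na(x$ps4_tag), stripped,
                   ifelse(stripped == "", x$ps4_tag,
                          paste(stripped, x$ps4_tag, sep = ",")))
  }
  res <- dplyr::bind_rows(purrr::map(tags, combine_acmg, rules = rules))
  x$acmg_class <- res$acmg_class
  x$vus_temperature <- res$vus_temperature
  x$fired_rule <- res$fired_rule
  x
}
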