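# Synthetic case-control cohorts with known ground truth. The reference cohort is
# controlled-access, so every pipeline stage is exercised on generated tables
# that emulate its stated shape: ~13,845 cases vs 6,570 controls, a rare-
# variant spectrum in which most variants have control AF < 0.0007 and about
# two thirds are absent from controls, and a mixture of truly enriched
# (pathogenic) and null (benign) variants.

.hl_genes <- c("GJB2", "SLC26A4", "MYO15A", "MYO7A", "CDH23", "OTOF",
               "PCDH15", "TMC1", "LOXHD1", "PTPRQ", "TMPRSS3", "OTOA",
               "USH2A", "ADGRV1", "TRIOBP", "COL11A2")

#' Configuration for the synthetic cohort generator
#'
#' Defaults state the emulated world: cohort sizes of the reference cohort (13,845
#' cases, 6,570 controls), a log-uniform control allele-frequency spectrum
#' over \[3e-7, 0.01\] (most mass below 0.0007, matching the observed
#' spectrum), about 19% truly pathogenic variants, pathogenic odds ratios
#' log-normal around 5, and benign odds ratios at 1.
#'
#' @param n_cases,n_controls Cohort sizes (individuals).
#' @param n_variants Number of variants to generate.
#' @param frac_pathogenic Fraction of truly enriched (pathogenic) variants.
#' @param control_af_bounds Log-uniform bounds for the latent population
#'   allele frequency.
#' @param or_pathogenic Log-normal parameters `c(meanlog, sdlog)` for
#'   pathogenic odds ratios (point mass when `sdlog = 0`).
#' @param or_benign Same for benign variants; default point mass at 1.
#' @param frac_blvus Fraction of benign-labelled variants curated as
#'   benign-leaning VUS rather than B/LB (exercises temperature handling).
#' @param frac_plvus Fraction of variants emitted as pathogenic-leaning VUS
#'   (excluded from the truth set).
#' @param frac_conflict Fraction of variants flagged with an external
#'   interpretation conflict.
#' @param seed Mandatory integer seed.
#' @return A `ps4_synth_config` list.
#' @export
synthetic_config <- function(n_cases = 13845, n_controls = 6570,
                             n_variants = 2000, frac_pathogenic = 0.19,
                             control_af_bounds = c(3e-7, 0.01),
                             or_pathogenic = c(meanlog = log(5), sdlog = 0.5),
                             or_benign = c(meanlog = 0, sdlog = 0),
                             frac_blvus = 0.5, frac_plvus = 0.0,
                             frac_conflict = 0.0, seed) {
  if (missing(seed)) abort("seed is mandatory", class = "ps4_config_error")
  stopifnot(n_cases > 0, n_controls > 0, n_variants > 0,
            frac_pathogenic > 0, frac_pathogenic < 1,
            all(control_af_bounds > 0), all(control_af_bounds <= 0.5),
            frac_blvus >= 0, frac_blvus <= 1,
            frac_plvus >= 0, frac_plvus <= 1,
            frac_conflict >= 0, frac_conflict <= 1)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_variants = n_variants, frac_pathogenic = frac_pathogenic,
                 control_af_bounds = control_af_bounds,
                 or_pathogenic = or_pathogenic, or_benign = or_benign,
                 frac_blvus = frac_blvus, frac_plvus = frac_plvus,
                 frac_conflict = frac_conflict, seed = as.integer(seed)),
            class = "ps4_synth_config")
}

# allele-level odds transform: case AF implied by control AF q and odds ratio
.case_af <- function(q, or) or * q / (1 - q + or * q)

.tags_for_temperature <- function(temp) {
  if (is.na(temp)) return("")
  switch(temp,
         hot = "PM3,PM2_Supporting,PP3,PP1",
         warm = "PM3,PM2_Supporting,PP3",
         tepid = "PM3,PM2_Supporting",
         cool = "PM2_Supporting,PP3",
         cold = "PM2_Supporting",
         ice_cold = "")
}

# Evidence tags consistent with the curated class, so the combining engine
# reproduces the curation in before/after comparisons.
.tags_for_class <- function(cls, temp) {
  switch(cls,
         P = "PVS1,PM3,PP3",
         LP = "PM3_Strong,PM1,PM2_Supporting,PP3",
         B = "BA1",
         LB = "BS1,BP4",
         VUS = .tags_for_temperature(temp))
}

#' Generate a synthetic case-control variant table
#'
#' Per variant: a latent population allele frequency is drawn log-uniformly,
#' a true odds ratio is drawn by label, the case allele frequency follows by
#' the allele-level odds transform `af_case = OR q / (1 - q + OR q)`, and the
#' observed allele counts are binomial draws at `2 n` alleles per cohort.
#' Variants never observed in a case are redrawn (the cohort table only rows
#' case-detected variants), falling back to a count of 1 after 20 attempts.
#' Pathogenic variants are curated P/LP; benign variants are a mix of B, LB
#' and benign-leaning VUS (with evidence tags matching their temperature).
#'
#' @param cfg A [synthetic_config()] object.
#' @return A validated variant tibble with the extra ground-truth columns
#'   `true_or` and `true_label`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "ps4_synth_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_variants
    an_case <- 2L * cfg$n_cases
    an_ctrl <- 2L * cfg$n_controls
    lab <- ifelse(runif(n) < cfg$frac_pathogenic, "pathogenic", "benign")
    b <- log(cfg$control_af_bounds)
    q <- exp(runif(n, b[1], b[2]))
    draw_or <- function(par, k) {
      if (par[["sdlog"]] == 0) rep(exp(par[["meanlog"]]), k)
      else rlnorm(k, par[["meanlog"]], par[["sdlog"]])
    }
    true_or <- numeric(n)
    true_or[lab == "pathogenic"] <- draw_or(cfg$or_pathogenic, sum(lab == "pathogenic"))
    true_or[lab == "benign"] <- draw_or(cfg$or_benign, sum(lab == "benign"))
    afc <- .case_af(q, true_or)
    if (any(afc > 1)) abort("case AF > 1 under these parameters", class = "ps4_config_error")
    ac_case <- rbinom(n, an_case, afc)
    for (i in seq_len(20)) {
      z <- ac_case == 0L
      if (!any(z)) break
      ac_case[z] <- rbinom(sum(z), an_case, afc[z])
    }
    ac_case[ac_case == 0L] <- 1L
    ac_control <- rbinom(n, an_ctrl, q)

    cls <- character(n)
    temp <- rep(NA_character_, n)
    is_path <- lab == "pathogenic"
    cls[is_path] <- sample(c("P", "LP"), sum(is_path), replace = TRUE)
    nben <- sum(!is_path)
    u <- runif(nben)
    cls[!is_path] <- ifelse(u < cfg$frac_blvus, "VUS",
                            sample(c("B", "LB"), nben, replace = TRUE))
    temp[!is_path & cls == "VUS"] <- sample(c("cool", "cold", "ice_cold"),
                                            sum(!is_path & cls == "VUS"),
                                            replace = TRUE, prob = c(0.1, 0.85, 0.05))
    if (cfg$frac_plvus > 0) {
      flip <- !is_path & runif(n) < cfg$frac_plvus
      cls[flip] <- "VUS"
      temp[flip] <- sample(c("hot", "warm", "tepid"), sum(flip),
                           replace = TRUE, prob = c(0.15, 0.15, 0.7))
    }
    tags <- vapply(seq_len(n), function(i) .tags_for_class(cls[i], temp[i]),
                   character(1))
    conflict <- runif(n) < cfg$frac_conflict

    out <- tibble::tibble(
      variant_id = sprintf("var_%05d", seq_len(n)),
      gene = sample(.hl_genes, n, replace = TRUE),
      consequence = sample(setdiff(.ps4_consequences, c("synonymous", "other")),
                           n, replace = TRUE),
      ac_case = ac_case, an_case = an_case,
      ac_control = ac_control, an_control = an_ctrl,
      curated_class = cls,
      evidence_tags = tags,
      external_conflict = conflict,
      vus_temperature = temp,
      true_or = true_or,
      true_label = lab
    )
    validate_variant_table(out)
  })
}

# Draw allele counts constrained to a truth-subset membership region.
# Rejection sampling with a deterministic clamp fallback keeps membership
# exact, which is the point of the emulation (see the methods vignette).
.draw_subset_counts <- function(k, subset, positive, an_case, an_ctrl, min_af) {
  min_ac_case <- as.integer(ceiling(min_af * an_case))
  if (subset == 3L) {
    # case allele counts geometric on {1, 2, ...}; tail rates chosen from the
    # reported AC = 3 sensitivity/specificity of the control-absent subset
    p <- if (positive) 1 - sqrt(0.178) else 1 - sqrt(0.043)
    ac_case <- stats::rgeom(k, p) + 1L
    return(list(ac_case = pmin(ac_case, 30L), ac_control = rep(0L, k)))
  }
  if (subset == 1L) {
    or <- if (positive) rlnorm(k, log(5), 0.5) else rlnorm(k, 0, 0.2)
    q <- exp(runif(k, log(1e-4), log(0.008)))
    ac_case <- rbinom(k, an_case, pmin(.case_af(q, or), 0.5))
    ac_control <- rbinom(k, an_ctrl, q)
    ac_case <- pmax(ac_case, min_ac_case)
    ac_control <- pmax(ac_control, 1L)
  } else {
    or <- if (positive) rlnorm(k, log(3), 0.5) else rlnorm(k, 0, 0.2)
    afc <- exp(runif(k, log(1 / an_case), log(min_af * 0.999)))
    q <- afc / (or - or * afc + afc)
    ac_case <- pmin(pmax(rbinom(k, an_case, afc), 1L), min_ac_case - 1L)
    ac_control <- pmax(rbinom(k, an_ctrl, pmin(q, 0.5)), 1L)
  }
  list(ac_case = ac_case, ac_control = ac_control)
}

#' Emulate the shape of the reference cohort
#'
#' Generates a ~9,050-variant table whose truth-subset split, class mix and
#' priors match the reference cohort's reported margins: subset sizes 598 / 1,997 / 4,951
#' with positives 80 / 186 / 1,411, plus 1,322 pathogenic-leaning VUS and 182
#' externally conflicted variants that the truth-set construction must
#' exclude. Intended for end-to-end smoke tests; see the methods vignette for
#' what it does and does not emulate.
#'
#' @param seed Integer seed.
#' @param scale Optional down-scaling factor in (0, 1\] applied to all
#'   stratum counts (useful for fast tests).
#' @param n_cases,n_controls Cohort sizes.
#' @param min_af Case-AF boundary between subsets 1 and 2.
#' @return A validated variant tibble with `true_label` ground truth.
#' @export
emulate_paper_shape <- function(seed, scale = 1, n_cases = 13845,
                                n_controls = 6570, min_af = 0.0005) {
  stopifnot(scale > 0, scale <= 1)
  an_case <- 2L * n_cases
  an_ctrl <- 2L * n_controls
  strata <- tibble::tribble(
    ~subset, ~positive, ~class_pool, ~n,
    1L, TRUE,  list(c("P", "LP")), 80L,
    1L, FALSE, list(c("VUS")), 189L,
    1L, FALSE, list(c("B", "LB")), 329L,
    2L, TRUE,  list(c("P", "LP")), 186L,
    2L, FALSE, list(c("VUS")), 1511L,
    2L, FALSE, list(c("B", "LB")), 300L,
    3L, TRUE,  list(c("P", "LP")), 1411L,
    3L, FALSE, list(c("VUS")), 3370L,
    3L, FALSE, list(c("B", "LB")), 170L
  )
  strata$n <- pmax(1L, as.integer(round(strata$n * scale)))
  n_plvus <- max(1L, as.integer(round(1322L * scale)))
  n_confl <- max(1L, as.integer(round(182L * scale)))

  withr::with_seed(seed, {
    rows <- purrr::pmap(strata, function(subset, positive, class_pool, n) {
      cnt <- .draw_subset_counts(n, subset, positive, an_case, an_ctrl, min_af)
      cls <- sample(class_pool[[1]], n, replace = TRUE)
      temp <- rep(NA_character_, n)
      temp[cls == "VUS"] <- sample(c("cool", "cold", "ice_cold"), sum(cls == "VUS"),
                                   replace = TRUE, prob = c(0.1, 0.85, 0.05))
      tibble::tibble(
        gene = sample(.hl_genes, n, replace = TRUE),
        consequence = sample(setdiff(.ps4_consequences, c("synonymous", "other")),
                             n, replace = TRUE),
        ac_case = cnt$ac_case, an_case = an_case,
        ac_control = cnt$ac_control, an_control = an_ctrl,
        curated_class = cls, vus_temperature = temp,
        external_conflict = FALSE,
        true_label = if (positive) "pathogenic" else "benign"
      )
    })
    # pathogenic-leaning VUS (excluded from the truth set) and conflicted rows
    extra_sub <- sample(1:3, n_plvus + n_confl, replace = TRUE,
                        prob = c(0.07, 0.22, 0.71))
    extra <- purrr::map(1:3, function(s) {
      k <- sum(extra_sub == s)
      if (k == 0) return(NULL)
      cnt <- .draw_subset_counts(k, s, FALSE, an_case, an_ctrl, min_af)
      tibble::tibble(
        gene = sample(.hl_genes, k, replace = TRUE),
        consequence = sample(setdiff(.ps4_consequences, c("synonymous", "other")),
                             k, replace = TRUE),
        ac_case = cnt$ac_case, an_case = an_case,
        ac_control = cnt$ac_control, an_control = an_ctrl,
        curated_class = "VUS",
        vus_temperature = sample(c("hot", "warm", "tepid"), k, replace = TRUE,
                                 prob = c(0.17, 0.13, 0.7)),
        external_conflict = FALSE,
        true_label = "benign"
      )
    })
    out <- dplyr::bind_rows(c(rows, extra))
    idx_confl <- sample(nrow(out), n_confl)
    out$external_conflict[idx_confl] <- TRUE
    out$variant_id <- sprintf("var_%05d", seq_len(nrow(out)))
    out$evidence_tags <- vapply(seq_len(nrow(out)), function(i)
      .tags_for_class(out$curated_class[i], out$vus_temperature[i]), character(1))
    out <- out[sample(nrow(out)), ]
    validate_variant_table(out)
  })
}
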