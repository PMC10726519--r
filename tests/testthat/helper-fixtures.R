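# Small in-code fixtures shared across test files.

# Minimal valid variant tibble; override any column via ...
make_variants <- function(n = 4, ...) {
  out <- tibble::tibble(
    variant_id = sprintf("v%02d", seq_len(n)),
    gene = rep("GJB2", n),
    consequence = rep("missense", n),
    ac_case = rep(2L, n),
    an_case = rep(27690L, n),
    ac_control = rep(1L, n),
    an_control = rep(13140L, n),
    curated_class = rep("VUS", n),
    evidence_tags = rep("", n),
    external_conflict = rep(FALSE, n)
  )
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  validate_variant_table(out)
}

# Write a variant tibble to a temp TSV and return the path
write_tsv_fixture <- function(x) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Brute-force two-sided Fisher p by direct enumeration over the support,
# computing table probabilities from first principles (independent of the
# package's noncentral hypergeometric code path).
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  p <- exp(logp)
  pobs <- p[xs == a]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# Independent bisection solver for the combined-odds constant C
oracle_solve_C <- function(prior, exponent = 0.75, target = 0.9) {
  f <- function(C) {
    lr <- C^exponent
    lr * prior / ((lr - 1) * prior + 1) - target
  }
  lo <- 1 + 1e-9; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# Truth tibble with explicit labels and odds ratios, for scan/local-lr tests
make_truth <- function(or, label, ac_control = 1L, ac_case = 5L) {
  n <- length(or)
  tibble::tibble(
    variant_id = sprintf("t%03d", seq_len(n)),
    gene = "GJB2", consequence = "missense",
    ac_case = rep_len(ac_case, n), an_case = 27690L,
    ac_control = rep_len(ac_control, n), an_control = 13140L,
    curated_class = ifelse(label == "positive", "P", "B"),
    evidence_tags = "", external_conflict = FALSE,
    af_case = rep_len(ac_case, n) / 27690,
    af_control = rep_len(ac_control, n) / 13140,
    truth_label = label,
    or = or, or_lb = pmax(or / 2, 1.01), or_ub = or * 2
  )
}
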