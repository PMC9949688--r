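# Cohort-level statistics: allele-frequency enrichment, mass-yield
# correlation, population coverage, and clinicopathological summary tables.

#' Allele-frequency enrichment against a reference population
#'
#' Builds a 2x2 allele-count table (each individual contributes two alleles
#' per locus) comparing the cohort with a reference population given by an
#' allele frequency and a number of typed individuals, and computes the odds
#' ratio with a 95% confidence interval and a p-value. Reference counts are
#' reconstructed as `round(ref_freq * 2 * ref_n_individuals)`. The default CI
#' is Woolf's log-OR interval `exp(log(OR) +/- 1.96 * sqrt(1/a+1/b+1/c+1/d))`;
#' `ci_method = "exact"` uses the conditional maximum-likelihood interval of
#' Fisher's exact test. When any cell is zero the Haldane-Anscombe 0.5
#' continuity correction is applied to the OR and Woolf CI and flagged. The
#' p-value is from the chi-square test with 1 df, replaced by Fisher's exact
#' test when any expected cell count is below 5; both are reported.
#'
#' @param cohort_alleles Character vector of all allele copies observed in the
#'   cohort at the locus of interest (2 per individual), or a typing table
#'   with columns `patient_id`/`allele`, in which case alleles at the query
#'   allele's locus are used.
#' @param allele The allele tested for enrichment.
#' @param ref_freq Reference allele frequency in `(0, 1)`.
#' @param ref_n_individuals Number of individuals in the reference cohort.
#' @param ci_method `"woolf"` (default) or `"exact"`.
#' @return List with `or`, `ci_low`, `ci_high`, `p`, `p_chisq`, `p_fisher`,
#'   `test_used`, `haldane_corrected`, `table` (a 2x2 matrix
#'   `[carrier, non-carrier] x [cohort, reference]`), `cohort_freq`,
#'   `n_carriers` and `ci_method`.
#' @export
allele_enrichment <- function(cohort_alleles, allele, ref_freq,
                              ref_n_individuals,
                              ci_method = c("woolf", "exact")) {
  ci_method <- match.arg(ci_method)
  stopifnot(ref_freq > 0, ref_freq < 1, ref_n_individuals > 0)
  allele <- normalize_hla(allele)
  if (is.data.frame(cohort_alleles)) {
    typing <- cohort_alleles
    typing$allele <- normalize_hla(typing$allele)
    locus <- parse_hla(allele)$locus
    keep <- parse_hla(typing$allele)$locus == locus
    n_carriers <- length(unique(typing$patient_id[typing$allele == allele]))
    cohort_alleles <- typing$allele[keep]
  } else {
    cohort_alleles <- normalize_hla(cohort_alleles)
    n_carriers <- NA_integer_
  }
  stopifnot(length(cohort_alleles) > 0)
  a <- sum(cohort_alleles == allele)
  b <- length(cohort_alleles) - a
  c_ <- round(ref_freq * 2 * ref_n_individuals)
  d <- 2 * ref_n_individuals - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2,
                dimnames = list(c("carrier", "non_carrier"),
                                c("cohort", "reference")))
  haldane <- any(tab == 0)
  tt <- if (haldane) tab + 0.5 else tab
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  se <- sqrt(sum(1 / tt))
  ci_woolf <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  fis <- stats::fisher.test(tab)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expected <- chi$expected
  test_used <- if (any(expected < 5)) "fisher" else "chisq"
  ci <- if (ci_method == "woolf") ci_woolf else unname(fis$conf.int)
  list(or = unname(or), ci_low = ci[1], ci_high = ci[2],
       p = if (test_used == "fisher") fis$p.value else chi$p.value,
       p_chisq = chi$p.value, p_fisher = fis$p.value, test_used = test_used,
       haldane_corrected = haldane, table = tab,
       cohort_freq = a / (a + b), n_carriers = n_carriers,
       ci_method = ci_method)
}

#' Tissue mass versus peptide yield correlation
#'
#' Pearson correlation between sample tissue mass and the number of HLA
#' peptides identified, with Fisher-z 95% confidence interval and two-sided
#' p-value.
#'
#' @param mass Numeric vector of tissue masses (mg), all positive.
#' @param yield Numeric vector of peptide yields per sample.
#' @return List with `r`, `ci` (length-2), `p` and `n`.
#' @export
mass_yield_correlation <- function(mass, yield) {
  stopifnot(length(mass) == length(yield), length(mass) >= 3,
            all(mass > 0))
  if (stats::sd(mass) == 0 || stats::sd(yield) == 0) {
    stop("zero variance in mass or yield")
  }
  ct <- stats::cor.test(mass, yield, method = "pearson")
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(mass))
}

#' Population coverage of an allele selection
#'
#' Probability that a random individual carries at least one of the selected
#' alleles, under Hardy-Weinberg equilibrium and independence between loci:
#' `1 - prod over loci of (1 - sum of covered allele frequencies)^2`.
#'
#' @param selected_alleles Character vector of covered alleles.
#' @param allele_freqs data.frame with columns `allele` and `frequency`
#'   (locus derived from the allele name), e.g. from [read_allele_freqs()].
#' @return Coverage as a fraction in `[0, 1]`.
#' @export
population_coverage <- function(selected_alleles, allele_freqs) {
  stopifnot(all(c("allele", "frequency") %in% names(allele_freqs)))
  af <- allele_freqs
  af$allele <- normalize_hla(af$allele)
  af$locus <- parse_hla(af$allele)$locus
  sums <- tapply(af$frequency, af$locus, sum)
  if (any(sums > 1 + 1e-9)) {
    stop("allele frequencies sum to more than 1 at locus/loci: ",
         paste(names(sums)[sums > 1 + 1e-9], collapse = ", "))
  }
  if (length(selected_alleles) == 0) return(0)
  selected_alleles <- unique(normalize_hla(selected_alleles))
  p_uncovered <- 1
  for (loc in unique(af$locus)) {
    f_cov <- sum(af$frequency[af$locus == loc &
                                af$allele %in% selected_alleles])
    p_uncovered <- p_uncovered * (1 - f_cov)^2
  }
  1 - p_uncovered
}

#' Clinicopathological cohort summary
#'
#' Per-stratum counts and percentages (HPV-negative, HPV-positive, total) for
#' each categorical metadata field, with percentages computed within stratum
#' and rounded to one decimal.
#'
#' @param metadata data.frame with one row per patient including an
#'   `hpv_status` column; every other non-numeric column is summarised.
#' @return data.frame with columns `field`, `level`, `n_hpv_negative`,
#'   `pct_hpv_negative`, `n_hpv_positive`, `pct_hpv_positive`, `n_total`,
#'   `pct_total`. Empty for an empty cohort.
#' @export
cohort_summary <- function(metadata) {
  empty <- data.frame(field = character(), level = character(),
                      n_hpv_negative = integer(), pct_hpv_negative = numeric(),
                      n_hpv_positive = integer(), pct_hpv_positive = numeric(),
                      n_total = integer(), pct_total = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(metadata) == 0) return(empty)
  stopifnot("hpv_status" %in% names(metadata))
  status <- as.character(metadata$hpv_status)
  n_neg <- sum(status == "negative")
  n_pos <- sum(status == "positive")
  n_tot <- nrow(metadata)
  fields <- setdiff(names(metadata),
                    c("hpv_status", "patient_id",
                      names(metadata)[vapply(metadata, is.numeric,
                                             logical(1))]))
  pct <- function(n, d) if (d == 0) NA_real_ else round(100 * n / d, 1)
  rows <- list(data.frame(
    field = "hpv_status", level = "positive",
    n_hpv_negative = 0L, pct_hpv_negative = pct(0, n_neg),
    n_hpv_positive = n_pos, pct_hpv_positive = pct(n_pos, n_pos),
    n_total = n_pos, pct_total = pct(n_pos, n_tot),
    stringsAsFactors = FALSE))
  for (f in fields) {
    vals <- as.character(metadata[[f]])
    for (lev in sort(unique(vals))) {
      rows[[length(rows) + 1]] <- data.frame(
        field = f, level = lev,
        n_hpv_negative = sum(vals == lev & status == "negative"),
        pct_hpv_negative = pct(sum(vals == lev & status == "negative"), n_neg),
        n_hpv_positive = sum(vals == lev & status == "positive"),
        pct_hpv_positive = pct(sum(vals == lev & status == "positive"), n_pos),
        n_total = sum(vals == lev), pct_total = pct(sum(vals == lev), n_tot),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
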