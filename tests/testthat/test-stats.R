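test_that("allele enrichment reproduces the known odds-ratio structure", {
  # 13 of 80 cohort alleles vs reference frequency 6.3% of 2 x 39689 alleles
  alleles <- c(rep("HLA-B*51:01", 13), rep("HLA-B*07:02", 67))
  res <- allele_enrichment(alleles, "B*51:01", ref_freq = 0.063,
                           ref_n_individuals = 39689)
  expect_equal(unname(res$table["carrier", "cohort"]), 13)
  expect_equal(unname(res$table["carrier", "reference"]),
               round(0.063 * 2 * 39689))
  expect_equal(res$or, 2.9, tolerance = 0.05)
  expect_lt(res$ci_low, res$or)
  expect_gt(res$ci_high, res$or)
  expect_lt(res$p, 0.01)
})

test_that("odds ratios are symmetric and antisymmetric as expected", {
  # a=b identical margins -> OR 1
  alleles <- c(rep("HLA-A*02:01", 5), rep("HLA-A*01:01", 5))
  res <- allele_enrichment(alleles, "A*02:01", ref_freq = 0.5,
                           ref_n_individuals = 5)
  expect_equal(res$or, 1.0, tolerance = 1e-12)
  # swapping enriched allele for the complement inverts the OR
  res_a <- allele_enrichment(c(rep("HLA-A*02:01", 30),
                               rep("HLA-A*01:01", 10)),
                             "A*02:01", 0.4, 1000)
  res_b <- allele_enrichment(c(rep("HLA-A*02:01", 10),
                               rep("HLA-A*01:01", 30)),
                             "A*02:01", 0.6, 1000)
  expect_equal(res_a$or, 1 / res_b$or, tolerance = 1e-9)
})

test_that("Woolf CI formula is applied and zero cells get Haldane", {
  alleles <- c(rep("HLA-B*51:01", 4), rep("HLA-B*07:02", 16))
  res <- allele_enrichment(alleles, "B*51:01", 0.1, 100)
  tt <- res$table
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  se <- sqrt(sum(1 / tt))
  expect_equal(res$ci_low, exp(log(or) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(res$ci_high, exp(log(or) + qnorm(0.975) * se),
               tolerance = 1e-12)
  zero <- allele_enrichment(rep("HLA-B*07:02", 20), "B*51:01", 0.1, 100)
  expect_true(zero$haldane_corrected)
  expect_true(is.finite(zero$or))
})

test_that("mass-yield correlation matches the covariance-formula oracle", {
  set.seed(31)
  mass <- exp(rnorm(10, 5, 0.4))
  yield <- 2 * mass + rnorm(10, 0, 100)
  res <- mass_yield_correlation(mass, yield)
  r_hand <- sum((mass - mean(mass)) * (yield - mean(yield))) /
    sqrt(sum((mass - mean(mass))^2) * sum((yield - mean(yield))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  # degenerate directions
  expect_equal(mass_yield_correlation(1:5, 2 * (1:5) + 3)$r, 1.0)
  expect_equal(mass_yield_correlation(1:5, -2 * (1:5) + 30)$r, -1.0)
  expect_error(mass_yield_correlation(rep(1, 5), 1:5), "variance")
})

test_that("population coverage equals exhaustive diploid enumeration", {
  af <- data.frame(allele = c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01",
                              "HLA-B*07:02", "HLA-B*08:01"),
                   frequency = c(0.2, 0.3, 0.5, 0.4, 0.6))
  sel <- c("HLA-A*02:01", "HLA-B*08:01")
  # enumerate all diploid genotypes over both loci and sum probabilities of
  # genotypes carrying at least one selected allele
  enumerate <- function(af, sel) {
    loci <- split(af, parse_hla(af$allele)$locus)
    geno_locus <- lapply(loci, function(sub) {
      g <- expand.grid(a1 = seq_len(nrow(sub)), a2 = seq_len(nrow(sub)))
      g$p <- sub$frequency[g$a1] * sub$frequency[g$a2]
      g$covered <- sub$allele[g$a1] %in% sel | sub$allele[g$a2] %in% sel
      g
    })
    # cross loci
    total <- 0
    g1 <- geno_locus[[1]]; g2 <- geno_locus[[2]]
    for (i in seq_len(nrow(g1))) {
      for (j in seq_len(nrow(g2))) {
        if (g1$covered[i] || g2$covered[j]) total <- total + g1$p[i] * g2$p[j]
      }
    }
    total
  }
  expect_equal(population_coverage(sel, af), enumerate(af, sel),
               tolerance = 1e-12)
  # forced endpoints
  expect_equal(population_coverage(character(), af), 0)
  af1 <- data.frame(allele = "HLA-A*02:01", frequency = 1.0)
  expect_equal(population_coverage("HLA-A*02:01", af1), 1.0)
  # monotone in the selected set
  expect_gte(population_coverage(c(sel, "HLA-A*01:01"), af),
             population_coverage(sel, af))
  # invalid frequency sums error
  af_bad <- data.frame(allele = c("HLA-A*01:01", "HLA-A*02:01"),
                       frequency = c(0.7, 0.6))
  expect_error(population_coverage("HLA-A*01:01", af_bad), "sum")
})

test_that("cohort summary reports per-stratum percentages to one decimal", {
  md <- data.frame(patient_id = sprintf("P%02d", 1:40),
                   hpv_status = rep(c("positive", "negative"), c(22, 18)),
                   sex = rep(c("male", "female", "male"), c(21, 7, 12)))
  s <- cohort_summary(md)
  hpv_row <- s[s$field == "hpv_status" & s$level == "positive", ]
  expect_equal(hpv_row$pct_total, 55.0)
  male <- s[s$field == "sex" & s$level == "male", ]
  expect_equal(male$n_total, 33)
  expect_equal(male$pct_total, 82.5)
  expect_equal(male$pct_hpv_positive, round(100 * 21 / 22, 1))
  expect_equal(nrow(cohort_summary(md[0, ])), 0)
})
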