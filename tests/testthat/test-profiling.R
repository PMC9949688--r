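test_that("TEP identification equals set-difference oracle on a toy cohort", {
  set.seed(21)
  peps <- random_seq(12, 9)
  benign_peps <- peps[1:4]
  ligs <- lapply(1:5, function(i) {
    toy_ligandome(sprintf("S%d", i), class_i = sample(peps, 6))
  })
  ben <- toy_benign(class_i = benign_peps)
  tep <- identify_tep(ligs, ben, "I")
  # brute-force oracle: union minus benign, with direct recount
  seen <- unique(unlist(lapply(ligs, function(l) l$class_i)))
  expect_setequal(tep$sequence, setdiff(seen, benign_peps))
  for (i in seq_len(nrow(tep))) {
    n <- sum(vapply(ligs, function(l) tep$sequence[i] %in% l$class_i,
                    logical(1)))
    expect_equal(tep$n_positive_samples[i], n)
    expect_equal(tep$prevalence_pct[i], 100 * n / 5)
  }
  expect_length(intersect(tep$sequence, benign_peps), 0)
})

test_that("degenerate benign references behave as forced", {
  set.seed(22)
  peps <- random_seq(6, 9)
  ligs <- list(toy_ligandome("S1", class_i = peps[1:4]),
               toy_ligandome("S2", class_i = peps[3:6]))
  expect_setequal(identify_tep(ligs, toy_benign(), "I")$sequence, peps)
  expect_equal(nrow(identify_tep(ligs, toy_benign(class_i = peps), "I")), 0)
})

test_that("class comparisons stay within HLA class and I/L collapse works", {
  ligs <- list(toy_ligandome("S1", class_i = "SIINFEKLV",
                             class_ii = "AAAAKAAAAKAAAA"))
  # benign contains the class I peptide only as class II: still a class I TEP
  ben <- toy_benign(class_ii = "SIINFEKLV")
  expect_equal(identify_tep(ligs, ben, "I")$sequence, "SIINFEKLV")
  # I/L collapse makes SLINFEKLV match benign SIINFEKLV
  ben2 <- toy_benign(class_i = "SIINFEKLV")
  ligs2 <- list(toy_ligandome("S1", class_i = "SLINFEKLV"))
  expect_equal(nrow(identify_tep(ligs2, ben2, "I")), 1)
  expect_equal(nrow(identify_tep(ligs2, ben2, "I", collapse_il = TRUE)), 0)
})

test_that("prevalence arithmetic and filtering", {
  teps <- data.frame(sequence = c("A", "B", "C"), hla_class = "I",
                     n_positive_samples = c(3L, 2L, 1L))
  teps$prevalence_pct <- 100 * teps$n_positive_samples / 40
  expect_equal(teps$prevalence_pct[1], 7.5)
  expect_equal(prevalence_filter(teps, 3)$sequence, "A")
  expect_equal(prevalence_filter(teps, 1), teps)
  teps2 <- teps[teps$n_positive_samples == 2, ]
  expect_equal(nrow(prevalence_filter(teps2, 3)), 0)
})

test_that("HPV stratification partitions the union peptide set", {
  set.seed(23)
  peps <- random_seq(15, 9)
  ligs <- list(toy_ligandome("P1", class_i = peps[1:6]),
               toy_ligandome("P2", class_i = peps[4:9]),
               toy_ligandome("P3", class_i = peps[8:15]))
  status <- c(P1 = "positive", P2 = "positive", P3 = "negative")
  parts <- stratify_by_hpv(ligs, status, "I")
  pos <- unique(c(peps[1:6], peps[4:9]))
  neg <- peps[8:15]
  expect_setequal(parts$exclusive_pos, setdiff(pos, neg))
  expect_setequal(parts$exclusive_neg, setdiff(neg, pos))
  expect_setequal(parts$shared, intersect(pos, neg))
  expect_equal(length(parts$exclusive_pos) + length(parts$exclusive_neg) +
                 length(parts$shared), length(unique(c(pos, neg))))
  # all-positive cohort
  all_pos <- stratify_by_hpv(ligs, c(P1 = "positive", P2 = "positive",
                                     P3 = "positive"), "I")
  expect_length(all_pos$exclusive_neg, 0)
  expect_length(all_pos$shared, 0)
  # missing call errors
  expect_error(stratify_by_hpv(ligs, status[1:2], "I"), "P3")
})

test_that("length distribution counts unique peptides and sums to one", {
  ligs <- list(toy_ligandome("S1", class_i = c("AAAAAAAA", "CCCCCCCCC")),
               toy_ligandome("S2", class_i = c("CCCCCCCCC", "DDDDDDDDD",
                                               "EEEEEEEEEE")))
  d <- length_distribution(ligs, "I")
  expect_equal(d, c("8" = 0.25, "9" = 0.5, "10" = 0.25))
  expect_equal(sum(d), 1, tolerance = 1e-9)
  three <- list(toy_ligandome("S1", class_i = random_seq(3, 9)))
  expect_equal(length_distribution(three, "I"), c("9" = 1.0))
})

test_that("accumulation curve equals the full-permutation oracle", {
  set.seed(24)
  sets <- lapply(1:5, function(i) sample(sprintf("PR%02d", 1:12), 6))
  names(sets) <- sprintf("S%d", 1:5)
  est <- saturation_estimate(sets)
  # exhaustive oracle over all 5! orderings
  perms <- gtools_perms <- NULL
  idx <- 1:5
  all_orders <- as.matrix(expand.grid(rep(list(idx), 5)))
  all_orders <- all_orders[apply(all_orders, 1, function(r) {
    length(unique(r)) == 5
  }), ]
  curves <- apply(all_orders, 1, function(ord) {
    seen <- character(0)
    vapply(ord, function(j) {
      seen <<- union(seen, sets[[j]])
      length(seen)
    }, numeric(1))
  })
  expect_equal(est$curve$mean_unique, unname(rowMeans(curves)),
               tolerance = 1e-12)
})

test_that("accumulation curve matches vegan's exact expectation", {
  skip_if_not_installed("vegan")
  set.seed(25)
  sets <- lapply(1:6, function(i) sample(sprintf("PR%02d", 1:30), 12))
  names(sets) <- sprintf("S%d", 1:6)
  est <- saturation_estimate(sets)
  universe <- sort(unique(unlist(sets)))
  comm <- t(vapply(sets, function(s) as.integer(universe %in% s),
                   integer(length(universe))))
  # specaccum's conditional-sd computation warns on NaN; the richness
  # expectation we compare against is unaffected
  sac <- suppressWarnings(vegan::specaccum(comm, method = "exact"))
  expect_equal(est$curve$mean_unique, as.numeric(sac$richness),
               tolerance = 1e-8)
})

test_that("saturation endpoints: identical samples vs disjoint samples", {
  same <- lapply(1:4, function(i) sprintf("PR%02d", 1:10))
  est <- saturation_estimate(same)
  expect_equal(est$pct_attained, 100)
  expect_true(all(diff(est$curve$mean_unique) < 1e-9))

  disjoint <- lapply(1:5, function(i) sprintf("PR%d_%02d", i, 1:10))
  est2 <- saturation_estimate(disjoint)
  expect_true(est2$est_max_proteins > est2$observed * 1.2)
  expect_true(est2$pct_attained < 90)
  # curve non-decreasing
  expect_true(all(diff(est2$curve$mean_unique) >= 0))
})
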