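pep9 <- function(ch) paste(rep(ch, 9), collapse = "")

test_that("QC gates are inclusive and use the best metric across samples", {
  recs <- data.frame(
    sequence = c("AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
    sample_id = c("S1", "S2", "S1", "S1"), hla_class = "I",
    assigned_allele = NA_character_,
    psm_count = c(1L, 2L, 1L, 2L), xcorr = c(1.2, 1.5, 3.0, 1.5),
    delta_cn = c(0.1, 0.2, 0.5, NA), q_value = 0.01,
    stringsAsFactors = FALSE)
  qc <- qc_filter(recs)
  expect_equal(qc$pass, "AAAAAAAAA")     # boundary values pass via best-of
  expect_setequal(qc$fail, c("CCCCCCCCC", "DDDDDDDDD"))  # PSM gate; missing
  empty <- qc_filter(recs[0, ])
  expect_length(empty$pass, 0)
  expect_length(empty$fail, 0)
})

test_that("incidence matrices respect the minimum-carrier filter", {
  typing <- data.frame(patient_id = rep(sprintf("P%d", 1:5), each = 2),
                       allele = rep(c("HLA-A*02:01", "HLA-B*07:02"), 5))
  peps <- c(pep9("A"), pep9("C"), pep9("D"))
  ligs <- list(
    P1 = toy_ligandome("P1", class_i = peps[c(1, 2)]),
    P2 = toy_ligandome("P2", class_i = peps[2]),
    P3 = toy_ligandome("P3", class_i = peps[3]),
    P4 = toy_ligandome("P4", class_i = character()),
    P5 = toy_ligandome("P5", class_i = character()))
  assignment <- stats::setNames(rep("HLA-A*02:01", 3), peps)
  inc <- build_incidence("A*02:01", ligs, typing, peps,
                         assignment = assignment)
  # peptide 1 and 3 are each in one carrier only -> excluded
  expect_equal(inc$peptides, peps[2])
  expect_equal(sum(inc$present), 2)
  expect_equal(inc$patients, sprintf("P%d", 1:5))
  expect_error(build_incidence("A*03:01", ligs, typing, peps), "carrier")
})

test_that("incidence uses per-ligandome allele assignments when present", {
  typing <- data.frame(patient_id = c("P1", "P2"),
                       allele = rep("HLA-A*02:01", 2))
  p <- pep9("A")
  mk <- function(id) {
    lig <- toy_ligandome(id, class_i = p)
    lig$assigned_allele <- stats::setNames("HLA-A*02:01", p)
    lig
  }
  inc <- build_incidence("A*02:01", list(P1 = mk("P1"), P2 = mk("P2")),
                         typing, p)
  expect_equal(inc$peptides, p)
})

test_that("trivial optimisation cases behave as forced", {
  # one peptide covering everyone
  inc <- make_incidence(matrix(TRUE, 1, 4))
  sel <- optimise_selection(inc)
  expect_equal(length(sel$selected), 1)
  expect_equal(sel$coverage_pct, 100)
  # duplicated rows: only one of two identical peptides enters
  inc2 <- make_incidence(matrix(TRUE, 2, 3))
  sel2 <- optimise_selection(inc2)
  expect_equal(length(sel2$selected), 1)
  expect_equal(sel2$selected, inc2$peptides[1])  # lexicographic tie-break
  # empty matrix
  inc0 <- make_incidence(matrix(FALSE, 0, 3))
  sel0 <- optimise_selection(inc0)
  expect_length(sel0$selected, 0)
  expect_equal(sel0$coverage_pct, 0)
})

test_that("exhaustive optimiser equals brute-force subset enumeration", {
  set.seed(41)
  for (trial in 1:25) {
    n <- sample(2:9, 1)
    P <- sample(2:8, 1)
    mat <- matrix(runif(n * P) < 0.4, n, P)
    while (any(rowSums(mat) == 0)) mat <- matrix(runif(n * P) < 0.4, n, P)
    inc <- make_incidence(mat)
    res <- optimise_selection(inc)
    oracle <- brute_force_selection(inc)
    expect_identical(res$selected, oracle$selected)
    expect_equal(res$pareto_front$size, oracle$front$size)
    expect_equal(res$pareto_front$n_covered, oracle$front$n_covered)
    # reported selection is non-dominated and coverage matches a recount
    expect_equal(length(res$covered_patients), oracle$cmax)
  }
})

test_that("stochastic search is seed-reproducible and never beats the optimum", {
  set.seed(42)
  mat <- matrix(runif(12 * 8) < 0.35, 12, 8)
  while (any(rowSums(mat) == 0)) mat <- matrix(runif(12 * 8) < 0.35, 12, 8)
  inc <- make_incidence(mat)
  exact <- optimise_selection(inc)                  # exhaustive
  for (s in c(1, 2, 3)) {
    sto <- optimise_selection(inc, iterations = 200, seed = s,
                              exhaustive_limit = 0)
    expect_identical(sto,
                     optimise_selection(inc, iterations = 200, seed = s,
                                        exhaustive_limit = 0))
    expect_gte(length(sto$selected), length(exact$selected))
    expect_equal(sto$coverage_pct, exact$coverage_pct)  # greedy attains cmax
  }
  expect_error(optimise_selection(inc, exhaustive_limit = 0), "seed")
})

test_that("coverage is monotone when peptides are added to a selection", {
  set.seed(43)
  mat <- matrix(runif(8 * 6) < 0.4, 8, 6)
  while (any(rowSums(mat) == 0)) mat <- matrix(runif(8 * 6) < 0.4, 8, 6)
  inc <- make_incidence(mat)
  cov_of <- function(idx) sum(colSums(inc$present[idx, , drop = FALSE]) > 0)
  for (k in 1:7) {
    idx <- sample(1:8, k)
    extra <- sample(setdiff(1:8, idx), 1)
    expect_gte(cov_of(c(idx, extra)), cov_of(idx))
  }
})

test_that("QC re-runs remove failing peptides and stop within three runs", {
  peps <- c(pep9("A"), pep9("B"), pep9("C"), pep9("D"))
  mat <- rbind(c(TRUE, TRUE, TRUE, TRUE),    # A: covers all, fails QC
               c(TRUE, TRUE, TRUE, TRUE),    # B: covers all, fails QC
               c(TRUE, TRUE, FALSE, FALSE),  # C: passes QC
               c(FALSE, FALSE, TRUE, TRUE))  # D: passes QC
  inc <- make_incidence(mat, peptides = peps)
  qc_pass <- peps[3:4]
  res <- optimise_with_qc(inc, qc_pass)
  expect_equal(res$n_runs, 3)
  expect_setequal(res$qc_removed, peps[1:2])
  expect_identical(res$selected, sort(peps[3:4]))
  expect_equal(res$coverage_pct, 100)
  expect_setequal(res$candidates, peps)  # all runs' selections recorded
  expect_length(intersect(res$selected, setdiff(peps, qc_pass)), 0)
  # all candidates pass -> one run, same as plain optimisation
  res_clean <- optimise_with_qc(inc, peps)
  expect_equal(res_clean$n_runs, 1)
  expect_identical(res_clean$selected, optimise_selection(inc)$selected)
  # best singleton fails -> second run picks from the remainder
  inc2 <- make_incidence(rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE)),
                         peptides = c(pep9("A"), pep9("C"), pep9("D")))
  res2 <- optimise_with_qc(inc2, c(pep9("C"), pep9("D")))
  expect_equal(res2$n_runs, 2)
  expect_identical(res2$selected, sort(c(pep9("C"), pep9("D"))))
})

test_that("selections never contain QC failures even when runs are exhausted", {
  # five QC-failing peptides each covering everyone: removals outlast the run
  # budget, so the reported selection is the QC-clean part of the final run
  peps <- c(pep9("A"), pep9("B"), pep9("C"), pep9("D"), pep9("E"))
  mat <- rbind(rep(TRUE, 4), rep(TRUE, 4), rep(TRUE, 4), rep(TRUE, 4),
               c(TRUE, TRUE, FALSE, FALSE))
  inc <- make_incidence(mat, peptides = peps)
  res <- optimise_with_qc(inc, qc_pass = peps[5])  # only E passes
  expect_equal(res$n_runs, 3)
  expect_length(intersect(res$selected, peps[1:4]), 0)
  expect_equal(res$coverage_pct,
               100 * sum(colSums(inc$present[match(res$selected,
                                                   inc$peptides), ,
                                             drop = FALSE]) > 0) / 4)
  # with enough extra runs the clean optimum is reachable and is found
  res5 <- optimise_with_qc(inc, qc_pass = peps[5], max_runs = 5)
  expect_equal(res5$n_runs, 5)
  expect_identical(res5$selected, peps[5])
  expect_equal(res5$coverage_pct, 50)
})

test_that("class II selection is cohort-wide with HPV breakdown", {
  set.seed(44)
  shared <- c(pep9("A"), pep9("C"), pep9("D"))
  ligs <- list(
    P1 = toy_ligandome("P1", class_ii = c(shared[1], random_seq(3, 15))),
    P2 = toy_ligandome("P2", class_ii = c(shared[1], random_seq(3, 15))),
    P3 = toy_ligandome("P3", class_ii = c(shared[1], shared[2])),
    P4 = toy_ligandome("P4", class_ii = shared[2]),
    P5 = toy_ligandome("P5", class_ii = c(shared[2], shared[3])),
    P6 = toy_ligandome("P6", class_ii = shared[3]))
  # shared[3] is only in 2 ligandomes -> not a candidate at min 3
  status <- c(P1 = "positive", P2 = "positive", P3 = "positive",
              P4 = "negative", P5 = "negative", P6 = "negative")
  sel <- select_class_ii(shared, ligs, qc_pass = shared, min_patients = 3,
                         hpv_status = status)
  expect_setequal(sel$selected, shared[1:2])
  expect_equal(sel$coverage_pct, 100 * 5 / 6)
  expect_equal(unname(sel$coverage_by_status["positive"]), 100)
  expect_equal(unname(sel$coverage_by_status["negative"]),
               100 * 2 / 3)
  # nothing survives QC -> empty selection with zero coverage
  sel0 <- select_class_ii(shared, ligs, qc_pass = character())
  expect_length(sel0$selected, 0)
  expect_equal(sel0$coverage_pct, 0)
})

test_that("patient composition is the union over carried allotypes", {
  pepsA <- c(pep9("A"), pep9("C"))
  pepsB <- pep9("D")
  wh <- list(
    structure(list(allotype = "HLA-A*02:01", selected = pepsA,
                   covered_patients = "P1", coverage_pct = 100,
                   n_carriers = 1), class = "warehouse_selection"),
    structure(list(allotype = "HLA-B*07:02", selected = pepsB,
                   covered_patients = "P1", coverage_pct = 100,
                   n_carriers = 1), class = "warehouse_selection"))
  typing <- data.frame(patient_id = c("P1", "P1", "P2"),
                       allele = c("HLA-A*02:01", "HLA-B*07:02",
                                  "HLA-C*07:01"))
  lig <- toy_ligandome("P1", class_i = c(pepsA[1], pepsB))
  comp <- compose_patient("P1", typing, wh, lig)
  expect_setequal(comp$selected_teps, c(pepsA, pepsB))
  expect_setequal(comp$presented_teps, c(pepsA[1], pepsB))
  expect_equal(comp$pct_of_selected, 100 * 2 / 3)
  expect_true(all(comp$presented_teps %in% comp$selected_teps))
  # patient carrying no warehouse allotype
  comp2 <- compose_patient("P2", typing, wh, toy_ligandome("P2"))
  expect_length(comp2$selected_teps, 0)
  expect_equal(comp2$pct_of_selected, 0)
  # patient presenting everything selected
  lig_all <- toy_ligandome("P1", class_i = c(pepsA, pepsB))
  expect_equal(compose_patient("P1", typing, wh, lig_all)$pct_of_selected,
               100)
})

test_that("coverage report recounts carrier coverage directly", {
  set.seed(45)
  sim <- small_sim()
  ligs <- annotate_sim(sim)
  tep <- identify_tep(ligs, sim$benign, "I")
  qc <- qc_filter(apply_identification_filters(sim$records))
  counts <- sort(table(unique(
    sim$typing[parse_hla(sim$typing$allele)$hla_class == "I", ])$allele),
    decreasing = TRUE)
  wh <- list()
  for (allo in names(counts)[1:4]) {
    inc <- build_incidence(allo, ligs, sim$typing, tep)
    if (length(inc$peptides) == 0) next
    wh[[allo]] <- optimise_with_qc(inc, qc$pass, seed = 1,
                                   iterations = 200)
  }
  rep_ <- coverage_report(wh, sim$typing, ligs)
  for (i in seq_len(nrow(rep_$by_allotype))) {
    allo <- rep_$by_allotype$allotype[i]
    carriers <- unique(sim$typing$patient_id[sim$typing$allele == allo])
    sel <- wh[[allo]]$selected
    covered <- sum(vapply(carriers, function(p) {
      any(sel %in% ligandome_peptides(ligs[[p]], "I"))
    }, logical(1)))
    expect_equal(rep_$by_allotype$n_covered[i], covered)
    expect_equal(rep_$by_allotype$coverage_pct[i],
                 100 * covered / length(carriers))
  }
  expect_true(all(rep_$by_patient$pct_of_selected >= 0 &
                    rep_$by_patient$pct_of_selected <= 100))
})
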