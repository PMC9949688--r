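# Peptide warehouse construction: spectral QC gates, per-allotype incidence
# matrices, multiobjective (selection size vs carrier coverage) optimisation
# with QC-driven re-runs, cohort-level class II selection, and per-patient
# semi-personalised compositions.

#' Spectral quality-control filter for warehouse candidates
#'
#' A peptide passes QC when, over all samples in which it was identified, its
#' maximum PSM count is at least `psm_min` (default 2), its best Xcorr at
#' least `xcorr_min` (default 1.5) and its best deltaCn at least
#' `delta_cn_min` (default 0.2); all boundaries inclusive. A peptide with any
#' required metric missing fails.
#'
#' @param records Peptide record data.frame.
#' @param psm_min,xcorr_min,delta_cn_min Inclusive QC gates.
#' @return List with character vectors `pass` and `fail` of unique sequences.
#' @export
qc_filter <- function(records, psm_min = 2, xcorr_min = 1.5,
                      delta_cn_min = 0.2) {
  if (nrow(records) == 0) return(list(pass = character(), fail = character()))
  agg <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  by_seq <- split(records[, c("psm_count", "xcorr", "delta_cn")],
                  records$sequence)
  ok <- vapply(by_seq, function(d) {
    psm <- agg(d$psm_count); xc <- agg(d$xcorr); dc <- agg(d$delta_cn)
    !is.na(psm) && !is.na(xc) && !is.na(dc) &&
      psm >= psm_min && xc >= xcorr_min && dc >= delta_cn_min
  }, logical(1))
  list(pass = sort(names(by_seq)[ok]), fail = sort(names(by_seq)[!ok]))
}

#' Build a per-allotype TEP incidence matrix
#'
#' Rows are tumour-exclusive peptides assigned to the allotype, restricted to
#' those present in at least `min_patients` carrier ligandomes (default 2);
#' columns are the patients carrying the allotype.
#'
#' @param allotype HLA class I allele.
#' @param ligandomes Named list of binder-annotated `ligandome` objects
#'   (names = patient ids).
#' @param typing Cohort typing table (`patient_id`, `allele`).
#' @param teps TEP table from [identify_tep()] or a character vector of TEP
#'   sequences.
#' @param assignment Optional named character vector peptide -> allele. When
#'   `NULL`, a peptide counts as belonging to the allotype if any carrier's
#'   ligandome assigned it that allele.
#' @param min_patients Minimum number of carrier ligandomes presenting the
#'   peptide.
#' @return Object of class `incidence_matrix`: `allotype`, `peptides`
#'   (lexicographically sorted), `patients`, and logical matrix `present`.
#' @export
build_incidence <- function(allotype, ligandomes, typing, teps,
                            assignment = NULL, min_patients = 2L) {
  stopifnot(min_patients >= 1)
  allotype <- normalize_hla(allotype)
  typing$allele <- normalize_hla(typing$allele)
  carriers <- sort(unique(typing$patient_id[typing$allele == allotype]))
  if (length(carriers) == 0) stop("no carriers of ", allotype, " in cohort")
  carriers <- carriers[carriers %in% names(ligandomes)]
  if (length(carriers) == 0) stop("no ligandome for any carrier of ", allotype)
  tep_seqs <- if (is.data.frame(teps)) teps$sequence else teps
  if (is.null(assignment)) {
    assigned <- unlist(lapply(ligandomes[carriers], function(l) {
      aa <- l$assigned_allele
      if (is.null(aa)) character() else names(aa)[!is.na(aa) & aa == allotype]
    }))
    pool <- intersect(tep_seqs, assigned)
  } else {
    pool <- tep_seqs[!is.na(assignment[tep_seqs]) &
                       assignment[tep_seqs] == allotype]
  }
  pool <- sort(unique(pool))
  present <- vapply(carriers, function(p) {
    pool %in% ligandome_peptides(ligandomes[[p]], "I")
  }, logical(length(pool)))
  present <- matrix(present, nrow = length(pool), ncol = length(carriers),
                    dimnames = list(pool, carriers))
  keep <- rowSums(present) >= min_patients
  structure(list(allotype = allotype, peptides = pool[keep],
                 patients = carriers,
                 present = present[keep, , drop = FALSE]),
            class = "incidence_matrix")
}

subset_incidence <- function(inc, keep_peptides) {
  keep <- inc$peptides %in% keep_peptides
  structure(list(allotype = inc$allotype, peptides = inc$peptides[keep],
                 patients = inc$patients,
                 present = inc$present[keep, , drop = FALSE]),
            class = "incidence_matrix")
}

# ---- internal: subset coverage machinery -----------------------------------

the <- new.env(parent = emptyenv())

popcount16_table <- function() {
  if (is.null(the$pc16)) {
    tab <- integer(65536)
    for (i in 1:65535) {
      tab[i + 1] <- tab[bitwShiftR(i, 1) + 1] + bitwAnd(i, 1L)
    }
    the$pc16 <- tab
  }
  the$pc16
}

popcount31 <- function(x) {
  tab <- popcount16_table()
  tab[bitwAnd(x, 65535L) + 1L] + tab[bitwShiftR(x, 16L) + 1L]
}

coverage_count <- function(present, sel_idx) {
  if (length(sel_idx) == 0) return(0L)
  sum(colSums(present[sel_idx, , drop = FALSE]) > 0)
}

# Pareto front (minimise size, maximise coverage) from best coverage per size.
front_from_best <- function(best_by_size, n_carriers) {
  sizes <- as.integer(names(best_by_size))
  ord <- order(sizes)
  sizes <- sizes[ord]
  best <- best_by_size[ord]
  keep <- logical(length(sizes))
  run_max <- -Inf
  for (i in seq_along(sizes)) {
    if (best[i] > run_max) {
      keep[i] <- TRUE
      run_max <- best[i]
    }
  }
  data.frame(size = sizes[keep], n_covered = as.integer(best[keep]),
             coverage_pct = 100 * best[keep] / n_carriers)
}

exhaustive_optimise <- function(inc) {
  n <- length(inc$peptides)
  P <- length(inc$patients)
  stopifnot(n >= 1, P <= 62)
  lo <- pmin(P, 31L)
  w1 <- integer(n); w2 <- integer(n)
  for (i in seq_len(n)) {
    bits <- which(inc$present[i, ])
    w1[i] <- sum(bitwShiftL(1L, bits[bits <= 31] - 1L))
    w2[i] <- sum(bitwShiftL(1L, bits[bits > 31] - 32L))
  }
  v1 <- 0L; v2 <- 0L; sz <- 0L
  for (i in seq_len(n)) {
    v1 <- c(v1, bitwOr(v1, w1[i]))
    v2 <- c(v2, bitwOr(v2, w2[i]))
    sz <- c(sz, sz + 1L)
  }
  cov <- popcount31(v1) + popcount31(v2)
  cmax <- cov[length(cov)]
  nonempty <- sz > 0
  best_by_size <- tapply(cov[nonempty], sz[nonempty], max)
  front <- front_from_best(best_by_size, P)
  kstar <- min(sz[nonempty][cov[nonempty] == cmax])
  opt_idx <- which(sz == kstar & cov == cmax) - 1L  # subset bit patterns
  decode <- function(s) which(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L) == 1L)
  subsets <- lapply(opt_idx, decode)
  if (length(subsets) > 1) {
    m <- do.call(rbind, subsets)  # each row sorted ascending
    subsets <- subsets[do.call(order, as.data.frame(m))[1]]
  }
  sel_idx <- subsets[[1]]
  list(selected = inc$peptides[sel_idx], front = front, cmax = cmax,
       method = "exhaustive")
}

greedy_cover <- function(present, pool_idx, cmax) {
  covered <- rep(FALSE, ncol(present))
  sel <- integer()
  chain_cov <- integer()
  repeat {
    gains <- vapply(pool_idx, function(i) {
      sum(present[i, ] & !covered)
    }, integer(1))
    if (length(pool_idx) == 0 || max(gains) == 0) break
    pick <- pool_idx[which.max(gains)]  # which.max: first (lex smallest) tie
    sel <- c(sel, pick)
    covered <- covered | present[pick, ]
    chain_cov <- c(chain_cov, sum(covered))
    pool_idx <- setdiff(pool_idx, pick)
    if (sum(covered) >= cmax) break
  }
  list(sel = sel, chain_cov = chain_cov)
}

prune_redundant <- function(present, sel, target_cov) {
  # drop peptides (largest index first) whose removal keeps coverage
  for (i in sort(sel, decreasing = TRUE)) {
    if (length(sel) > 1 &&
        coverage_count(present, setdiff(sel, i)) >= target_cov) {
      sel <- setdiff(sel, i)
    }
  }
  sel
}

stochastic_optimise <- function(inc, iterations, seed) {
  if (is.null(seed)) {
    stop("a seed is required for stochastic selection optimisation")
  }
  n <- length(inc$peptides)
  P <- length(inc$patients)
  present <- inc$present
  cmax <- coverage_count(present, seq_len(n))
  g <- greedy_cover(present, seq_len(n), cmax)
  best_by_size <- stats::setNames(as.numeric(g$chain_cov),
                                  seq_along(g$chain_cov))
  best_sel <- prune_redundant(present, g$sel, cmax)
  record <- function(size, covn) {
    key <- as.character(size)
    cur <- best_by_size[key]
    if (is.na(cur) || covn > cur) best_by_size[key] <<- covn
  }
  record(length(best_sel), cmax)
  with_seed(stream_seed(seed, "optimise"), {
    for (it in seq_len(iterations)) {
      if (it %% 2 == 0 && length(best_sel) > 1) {
        # try to shrink: drop one member, greedily repair, prune
        drop <- sample_vec(best_sel, 1)
        start <- setdiff(best_sel, drop)
        repair <- greedy_cover(present, setdiff(seq_len(n), start), cmax)
        covered0 <- coverage_count(present, start)
        cand <- start
        for (add in repair$sel) {
          if (coverage_count(present, cand) >= cmax) break
          cand <- c(cand, add)
        }
        if (coverage_count(present, cand) >= cmax) {
          cand <- prune_redundant(present, cand, cmax)
          if (length(cand) < length(best_sel) ||
              (length(cand) == length(best_sel) &&
               !identical(sort(cand), sort(best_sel)) &&
               paste(sort(cand), collapse = ",") <
               paste(sort(best_sel), collapse = ","))) {
            best_sel <- sort(cand)
          }
          record(length(cand), cmax)
        }
      } else {
        k <- sample.int(max(n - 1, 1), 1)
        idx <- sample_vec(seq_len(n), min(k, n))
        record(length(idx), coverage_count(present, idx))
      }
    }
  })
  list(selected = inc$peptides[sort(best_sel)],
       front = front_from_best(best_by_size, P), cmax = cmax,
       method = "stochastic")
}

#' Multiobjective warehouse selection for one incidence matrix
#'
#' Computes the Pareto front over selection size (minimised) and carrier
#' coverage (maximised), and returns as final selection the smallest peptide
#' set attaining the maximal attainable coverage, ties broken by the
#' lexicographically smallest peptide list. Instances with at most
#' `exhaustive_limit` candidate peptides are solved exactly by enumeration of
#' all subsets; larger instances use a seeded greedy-plus-local-search with
#' the given iteration budget.
#'
#' @param inc An `incidence_matrix` from [build_incidence()].
#' @param iterations Proposal budget of the stochastic search.
#' @param seed Integer seed (required on the stochastic path).
#' @param exhaustive_limit Maximum candidate count solved exactly.
#' @return Object of class `warehouse_selection` with fields `allotype`,
#'   `selected`, `covered_patients`, `coverage_pct`, `pareto_front`,
#'   `n_runs`, `qc_removed`, `candidates`, `n_carriers`, `method`.
#' @export
optimise_selection <- function(inc, iterations = 1e6, seed = NULL,
                               exhaustive_limit = 20L) {
  stopifnot(inherits(inc, "incidence_matrix"))
  n <- length(inc$peptides)
  P <- length(inc$patients)
  if (n == 0) {
    return(structure(list(allotype = inc$allotype, selected = character(),
                          covered_patients = character(), coverage_pct = 0,
                          pareto_front = data.frame(size = integer(),
                                                    n_covered = integer(),
                                                    coverage_pct = numeric()),
                          n_runs = 1L, qc_removed = character(),
                          candidates = character(), n_carriers = P,
                          method = "empty"),
                     class = "warehouse_selection"))
  }
  res <- if (n <= exhaustive_limit && P <= 62) {
    exhaustive_optimise(inc)
  } else {
    stochastic_optimise(inc, iterations = iterations, seed = seed)
  }
  sel_idx <- match(res$selected, inc$peptides)
  covered <- inc$patients[colSums(inc$present[sel_idx, , drop = FALSE]) > 0]
  structure(list(allotype = inc$allotype, selected = sort(res$selected),
                 covered_patients = covered,
                 coverage_pct = 100 * length(covered) / P,
                 pareto_front = res$front, n_runs = 1L,
                 qc_removed = character(), candidates = sort(res$selected),
                 n_carriers = P, method = res$method),
            class = "warehouse_selection")
}

#' @export
print.warehouse_selection <- function(x, ...) {
  cat("warehouse selection",
      if (!is.na(x$allotype)) x$allotype else "(cohort-wide)", "-",
      length(x$selected), "peptide(s), coverage",
      sprintf("%.1f%%", x$coverage_pct), "of", x$n_carriers,
      "carrier(s) in", x$n_runs, "run(s)\n")
  invisible(x)
}

#' Warehouse selection with post-hoc QC re-runs
#'
#' Runs [optimise_selection()]; if any selected peptide fails spectral QC it
#' is removed from the candidate pool and the optimisation re-runs, up to
#' `max_runs` (default 3) total runs. Peptides appearing in any run's
#' selection are recorded as warehouse candidates. The returned selection
#' never contains a QC-failing peptide: failing peptides still selected at
#' the final run are dropped and the coverage recomputed.
#'
#' @inheritParams optimise_selection
#' @param qc_pass Character vector of sequences passing [qc_filter()].
#' @param max_runs Maximum number of optimisation runs.
#' @return A `warehouse_selection` with `n_runs`, `qc_removed` and the
#'   accumulated `candidates` filled in.
#' @export
optimise_with_qc <- function(inc, qc_pass, max_runs = 3L, iterations = 1e6,
                             seed = NULL, exhaustive_limit = 20L) {
  pool <- inc
  removed <- character()
  candidates <- character()
  runs <- 0L
  repeat {
    runs <- runs + 1L
    sel <- optimise_selection(pool, iterations = iterations, seed = seed,
                              exhaustive_limit = exhaustive_limit)
    candidates <- union(candidates, sel$selected)
    fails <- setdiff(sel$selected, qc_pass)
    if (length(fails) == 0 || runs >= max_runs) break
    removed <- c(removed, fails)
    pool <- subset_incidence(pool, setdiff(pool$peptides, fails))
  }
  if (length(fails) > 0) {
    # ran out of re-runs: report the QC-clean part of the last selection
    removed <- c(removed, fails)
    clean <- setdiff(sel$selected, fails)
    idx <- match(clean, inc$peptides)
    covered <- inc$patients[colSums(inc$present[idx, , drop = FALSE]) > 0]
    sel$selected <- clean
    sel$covered_patients <- covered
    sel$coverage_pct <- 100 * length(covered) / length(inc$patients)
  }
  sel$n_runs <- runs
  sel$qc_removed <- unique(removed)
  sel$candidates <- sort(candidates)
  sel
}

#' Cohort-wide HLA class II TEP selection
#'
#' Class II selection is allotype-agnostic: candidates are class II TEP found
#' in at least `min_patients` ligandomes (default 3) that pass spectral QC,
#' and coverage is computed over the whole cohort (optionally broken down by
#' HPV status).
#'
#' @param teps_ii Class II TEP table or character vector of sequences.
#' @param ligandomes Named list of `ligandome` objects (names = patient ids).
#' @param qc_pass Sequences passing [qc_filter()].
#' @param min_patients Minimum number of ligandomes presenting a candidate.
#' @param hpv_status Optional named status vector for the per-status
#'   breakdown.
#' @inheritParams optimise_selection
#' @return A `warehouse_selection` (allotype `NA`) with an extra
#'   `coverage_by_status` element when `hpv_status` is given.
#' @export
select_class_ii <- function(teps_ii, ligandomes, qc_pass, min_patients = 3L,
                            hpv_status = NULL, iterations = 1e6, seed = NULL,
                            exhaustive_limit = 20L) {
  tep_seqs <- if (is.data.frame(teps_ii)) teps_ii$sequence else teps_ii
  patients <- sort(names(ligandomes))
  sets <- lapply(ligandomes[patients], ligandome_peptides, hla_class = "II")
  counts <- table(unlist(lapply(sets, unique)))
  eligible <- names(counts)[counts >= min_patients]
  pool <- sort(intersect(intersect(tep_seqs, eligible), qc_pass))
  present <- vapply(patients, function(p) pool %in% sets[[p]],
                    logical(length(pool)))
  inc <- structure(list(allotype = NA_character_, peptides = pool,
                        patients = patients,
                        present = matrix(present, nrow = length(pool),
                                         ncol = length(patients),
                                         dimnames = list(pool, patients))),
                   class = "incidence_matrix")
  sel <- optimise_selection(inc, iterations = iterations, seed = seed,
                            exhaustive_limit = exhaustive_limit)
  if (!is.null(hpv_status)) {
    by_status <- vapply(c(positive = "positive", negative = "negative"),
                        function(st) {
      grp <- patients[hpv_status[patients] == st]
      if (length(grp) == 0) return(NA_real_)
      100 * sum(grp %in% sel$covered_patients) / length(grp)
    }, numeric(1))
    sel$coverage_by_status <- by_status
  }
  sel
}

#' Semi-personalised patient composition
#'
#' The union of the warehouse selections for the class I allotypes the
#' patient carries, together with the subset actually presented in the
#' patient's own ligandome.
#'
#' @param patient_id Patient identifier.
#' @param typing Cohort typing table.
#' @param warehouse List of `warehouse_selection` objects (class I).
#' @param lig The patient's `ligandome` (may be `NULL`).
#' @return List with `patient_id`, `selected_teps`, `presented_teps` and
#'   `pct_of_selected` (0 when nothing is selected).
#' @export
compose_patient <- function(patient_id, typing, warehouse, lig = NULL) {
  carried <- normalize_hla(typing$allele[typing$patient_id == patient_id])
  allo <- vapply(warehouse, function(w) w$allotype, character(1))
  selected <- as.character(sort(unique(unlist(
    lapply(warehouse[allo %in% carried], function(w) w$selected)))))
  presented <- if (is.null(lig)) character() else {
    sort(intersect(selected, ligandome_peptides(lig, "I")))
  }
  pct <- if (length(selected) == 0) 0 else {
    100 * length(presented) / length(selected)
  }
  list(patient_id = patient_id, selected_teps = selected,
       presented_teps = presented, pct_of_selected = pct)
}

#' Warehouse coverage report
#'
#' Per-allotype absolute and relative carrier coverage, per-patient
#' semi-personalised composition sizes, and cohort medians.
#'
#' @param warehouse List of class I `warehouse_selection` objects.
#' @param typing Cohort typing table.
#' @param ligandomes Named list of `ligandome` objects.
#' @return List with data.frames `by_allotype` and `by_patient` and a
#'   `summary` list of cohort medians/ranges.
#' @export
coverage_report <- function(warehouse, typing, ligandomes) {
  by_allotype <- do.call(rbind, lapply(warehouse, function(w) {
    data.frame(allotype = w$allotype, n_carriers = w$n_carriers,
               n_selected = length(w$selected),
               n_covered = length(w$covered_patients),
               coverage_pct = w$coverage_pct, n_runs = w$n_runs,
               stringsAsFactors = FALSE)
  }))
  patients <- sort(unique(typing$patient_id))
  by_patient <- do.call(rbind, lapply(patients, function(p) {
    comp <- compose_patient(p, typing, warehouse, ligandomes[[p]])
    data.frame(patient_id = p, n_selected = length(comp$selected_teps),
               n_presented = length(comp$presented_teps),
               pct_of_selected = comp$pct_of_selected,
               stringsAsFactors = FALSE)
  }))
  summary <- list(
    median_selected = stats::median(by_patient$n_selected),
    range_selected = range(by_patient$n_selected),
    median_presented = stats::median(by_patient$n_presented),
    range_presented = range(by_patient$n_presented),
    median_pct_of_selected = stats::median(by_patient$pct_of_selected),
    range_pct_of_selected = range(by_patient$pct_of_selected),
    n_patients_uncovered = sum(by_patient$n_presented == 0))
  list(by_allotype = by_allotype, by_patient = by_patient, summary = summary)
}
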