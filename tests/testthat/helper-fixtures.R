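# Shared fixtures and independent oracles.

random_seq <- function(n, len = 9) {
  vapply(seq_len(n), function(i) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                 replace = TRUE), collapse = "")
  }, character(1))
}

make_incidence <- function(mat, allotype = "HLA-A*02:01",
                           peptides = NULL, patients = NULL) {
  n <- nrow(mat)
  if (is.null(peptides)) peptides <- sort(random_seq(n, 7))
  if (is.null(patients)) patients <- sprintf("P%02d", seq_len(ncol(mat)))
  ord <- order(peptides)
  rownames(mat) <- peptides
  structure(list(allotype = normalize_hla(allotype),
                 peptides = peptides[ord], patients = patients,
                 present = mat[ord, , drop = FALSE]),
            class = "incidence_matrix")
}

# brute-force multiobjective oracle: enumerate every non-empty subset
brute_force_selection <- function(inc) {
  mat <- inc$present
  n <- nrow(mat)
  cmax <- sum(colSums(mat) > 0)
  best <- rep(-1L, n)
  opt_lists <- list()
  kstar <- Inf
  for (s in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1))) > 0)
    cov <- sum(colSums(mat[idx, , drop = FALSE]) > 0)
    k <- length(idx)
    if (cov > best[k]) best[k] <- cov
    if (cov == cmax) {
      if (k < kstar) {
        kstar <- k
        opt_lists <- list(sort(inc$peptides[idx]))
      } else if (k == kstar) {
        opt_lists <- c(opt_lists, list(sort(inc$peptides[idx])))
      }
    }
  }
  keep <- logical(n)
  run_max <- -Inf
  for (i in seq_len(n)) {
    if (best[i] > run_max) {
      keep[i] <- TRUE
      run_max <- best[i]
    }
  }
  sel <- opt_lists[[do.call(order,
                            as.data.frame(do.call(rbind, opt_lists)))[1]]]
  list(front = data.frame(size = which(keep), n_covered = best[keep]),
       selected = sel, cmax = cmax)
}

toy_ligandome <- function(id, class_i = character(), class_ii = character(),
                          binders = class_i) {
  lig <- ligandome(id, class_i, class_ii)
  if (length(class_i) > 0) {
    lig$binder_flags <- stats::setNames(class_i %in% binders, class_i)
  }
  lig
}

toy_benign <- function(class_i = character(), class_ii = character()) {
  rows <- rbind(
    if (length(class_i)) data.frame(sequence = class_i, hla_class = "I",
                                    tissue = "tonsil", sample_id = "B1"),
    if (length(class_ii)) data.frame(sequence = class_ii, hla_class = "II",
                                     tissue = "lung", sample_id = "B2"))
  if (is.null(rows)) {
    rows <- data.frame(sequence = character(), hla_class = character(),
                       tissue = character(), sample_id = character())
  }
  benign_reference(rows)
}

small_sim <- function(seed = 11, n_patients = 12) {
  simulate_cohort(sim_config(
    n_patients = n_patients, mean_ligandome_size_i = 80,
    mean_ligandome_size_ii = 50, shared_pool_size_i = 60,
    shared_pool_size_ii = 40, benign_only_pool_size = 100,
    seed = seed))
}

annotate_sim <- function(sim) {
  recs <- apply_identification_filters(sim$records)
  ligs <- build_ligandomes(recs)
  lapply(ligs, function(l) {
    annotate_from_assignments(
      l, recs, sim$typing$allele[sim$typing$patient_id == l$sample_id])
  })
}
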