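# Comparative ligandome profiling: tumour-exclusive peptides, prevalence,
# HPV stratification, length distributions and source-protein saturation.

#' Identify tumour-exclusive peptides (TEP)
#'
#' A TEP is a peptide present in at least one tumour ligandome and absent from
#' the benign reference peptide set of the same HLA class. For class I, the
#' comparison is over binder-annotated HLA ligands when binder annotation is
#' available (`binders_only = TRUE`); for class II over all presented
#' peptides. Matching is exact string equality; set `collapse_il = TRUE` to
#' treat isoleucine and leucine as indistinguishable.
#'
#' @param ligandomes List of `ligandome` objects (the tumour cohort).
#' @param benign A `benign_reference`.
#' @param hla_class `"I"` or `"II"`.
#' @param binders_only For class I, restrict to annotated binders.
#' @param collapse_il Collapse I to L on both sides before comparing.
#' @return data.frame with columns `sequence`, `hla_class`,
#'   `n_positive_samples` and `prevalence_pct` (percentage of cohort samples
#'   presenting the peptide), sorted by decreasing prevalence then sequence.
#' @export
identify_tep <- function(ligandomes, benign, hla_class = c("I", "II"),
                         binders_only = TRUE, collapse_il = FALSE) {
  hla_class <- match.arg(hla_class)
  stopifnot(length(ligandomes) >= 1, inherits(benign, "benign_reference"))
  key <- il_key(collapse_il)
  benign_set <- unique(key(benign$peptides_by_class[[hla_class]]))
  per_sample <- lapply(ligandomes, ligandome_peptides, hla_class = hla_class,
                       binders_only = binders_only)
  counts <- table(unlist(lapply(per_sample, unique)))
  seqs <- names(counts)
  excl <- !(key(seqs) %in% benign_set)
  out <- data.frame(sequence = seqs[excl],
                    hla_class = rep(hla_class, sum(excl)),
                    n_positive_samples = as.integer(counts[excl]),
                    stringsAsFactors = FALSE)
  out$prevalence_pct <- 100 * out$n_positive_samples / length(ligandomes)
  out <- out[order(-out$n_positive_samples, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter TEP by cohort prevalence
#'
#' @param teps TEP table from [identify_tep()].
#' @param min_samples Minimum number of positive samples (default 3, i.e.
#'   a prevalence of 7.5% in a 40-patient cohort).
#' @return The subset of `teps` with `n_positive_samples >= min_samples`.
#' @export
prevalence_filter <- function(teps, min_samples = 3L) {
  stopifnot(min_samples >= 1)
  out <- teps[teps$n_positive_samples >= min_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify cohort peptides by HPV status
#'
#' Partitions the union of cohort peptides (of one HLA class) into peptides
#' seen only in HPV-positive samples, only in HPV-negative samples, and in
#' both.
#'
#' @param ligandomes List of `ligandome` objects.
#' @param hpv_status Named character vector sample/patient id ->
#'   `"positive"`/`"negative"` (see [hpv_status_map()]).
#' @param hla_class `"I"` or `"II"`.
#' @param binders_only For class I, restrict to annotated binders.
#' @return List with character-vector elements `exclusive_pos`,
#'   `exclusive_neg` and `shared`.
#' @export
stratify_by_hpv <- function(ligandomes, hpv_status, hla_class = c("I", "II"),
                            binders_only = TRUE) {
  hla_class <- match.arg(hla_class)
  ids <- vapply(ligandomes, function(l) l$sample_id, character(1))
  missing <- ids[!ids %in% names(hpv_status)]
  if (length(missing) > 0) {
    stop("no HPV call for sample(s): ", paste(missing, collapse = ", "))
  }
  sets <- lapply(ligandomes, ligandome_peptides, hla_class = hla_class,
                 binders_only = binders_only)
  pos <- unique(unlist(sets[hpv_status[ids] == "positive"]))
  neg <- unique(unlist(sets[hpv_status[ids] == "negative"]))
  list(exclusive_pos = sort(setdiff(pos, neg)),
       exclusive_neg = sort(setdiff(neg, pos)),
       shared = sort(intersect(pos, neg)))
}

#' Cohort peptide length distribution
#'
#' Fractions of each peptide length over the unique peptides of the cohort
#' (union across samples).
#'
#' @inheritParams stratify_by_hpv
#' @return Named numeric vector length -> fraction, summing to 1.
#' @export
length_distribution <- function(ligandomes, hla_class = c("I", "II"),
                                binders_only = TRUE) {
  hla_class <- match.arg(hla_class)
  peps <- unique(unlist(lapply(ligandomes, ligandome_peptides,
                               hla_class = hla_class,
                               binders_only = binders_only)))
  if (length(peps) == 0) stop("no peptides in cohort")
  tab <- table(nchar(peps))
  stats::setNames(as.numeric(tab) / length(peps), names(tab))
}

# mean accumulation curve over the given sample orderings
accumulation_from_orders <- function(sets, orders) {
  universe <- unique(unlist(sets))
  inc <- vapply(sets, function(s) universe %in% s,
                logical(length(universe)))
  inc <- matrix(inc, nrow = length(universe))
  curves <- vapply(orders, function(ord) {
    seen <- rep(FALSE, nrow(inc))
    vapply(ord, function(j) {
      seen <<- seen | inc[, j]
      sum(seen)
    }, numeric(1))
  }, numeric(length(sets)))
  rowMeans(matrix(curves, nrow = length(sets)))
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' Source-protein saturation of a cohort
#'
#' Computes the permutation-averaged accumulation curve of unique source
#' proteins against the number of samples, fits the saturating model
#' `S(n) = S_max * (1 - exp(-k * n))` by least squares, and reports the
#' fraction of the estimated maximum already attained,
#' `100 * observed unique proteins / S_max`. All sample orderings are
#' enumerated when there are at most 7 samples; otherwise `n_perm` random
#' orderings (seeded) are averaged.
#'
#' @param protein_sets Named list, one character vector of source-protein
#'   accessions per sample.
#' @param n_perm Number of random orderings when enumeration is infeasible.
#' @param seed Integer seed for the random orderings.
#' @return List with `curve` (data.frame `n_samples`, `mean_unique`),
#'   `est_max_proteins` (`NA` on fit failure, with a warning),
#'   `pct_attained`, `observed` and `fit_method`.
#' @export
saturation_estimate <- function(protein_sets, n_perm = 100L, seed = 1L) {
  n <- length(protein_sets)
  stopifnot(n >= 3)
  orders <- if (n <= 7) {
    all_permutations(n)
  } else {
    with_seed(stream_seed(seed, "saturation"),
              lapply(seq_len(n_perm), function(i) sample.int(n)))
  }
  curve_y <- accumulation_from_orders(protein_sets, orders)
  curve <- data.frame(n_samples = seq_len(n), mean_unique = curve_y)
  observed <- length(unique(unlist(protein_sets)))
  if (curve_y[n] - curve_y[1] < 1e-9) {
    # identical samples: saturated at the first sample
    return(list(curve = curve, est_max_proteins = observed,
                pct_attained = 100, observed = observed,
                fit_method = "flat"))
  }
  fit <- tryCatch({
    start <- list(smax = max(observed, 1) * 1.2, k = 0.5)
    f <- suppressWarnings(tryCatch(
      stats::nls(mean_unique ~ smax * (1 - exp(-k * n_samples)),
                 data = curve, start = start),
      error = function(e) minpack.lm::nlsLM(
        mean_unique ~ smax * (1 - exp(-k * n_samples)),
        data = curve, start = start,
        lower = c(smax = observed, k = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 500))))
    stats::coef(f)
  }, error = function(e) {
    warning("saturation model fit failed: ", conditionMessage(e))
    NULL
  })
  if (is.null(fit)) {
    return(list(curve = curve, est_max_proteins = NA_real_,
                pct_attained = NA_real_, observed = observed,
                fit_method = "failed"))
  }
  smax <- max(unname(fit["smax"]), observed)  # attained fraction capped at 100
  list(curve = curve, est_max_proteins = unname(fit["smax"]),
       pct_attained = 100 * observed / smax, observed = observed,
       fit_method = "exponential_ls")
}
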