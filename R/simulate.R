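# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: HLA genotypes drawn from allele frequencies
# under Hardy-Weinberg, per-sample ligandome sizes and length distributions,
# shared (allotype-attached) and private peptide pools with a controllable
# benign-overlap fraction, spectral QC metric distributions, HPV oncogene
# read counts, and a tissue-mass/peptide-yield correlation. Every planted
# fact is returned as ground truth so downstream stages can be checked
# exactly.

#' Default per-locus HLA allele frequencies
#'
#' A compact European-style frequency set over six loci, summing to 1 per
#' locus, used as the generator default. The HLA-B locus uses the enriched
#' B*51:01 frequency observed in the tumour cohort (16.2%).
#'
#' @return data.frame with columns `locus`, `allele`, `frequency`.
#' @export
default_allele_freqs <- function() {
  spec <- list(
    A = c("02:01" = 0.28, "01:01" = 0.17, "03:01" = 0.14, "24:02" = 0.11,
          "11:01" = 0.07, "26:01" = 0.05, "32:01" = 0.05, "25:01" = 0.05,
          "68:01" = 0.04, "23:01" = 0.04),
    B = c("51:01" = 0.162, "07:02" = 0.13, "08:01" = 0.12, "44:02" = 0.10,
          "18:01" = 0.08, "15:01" = 0.07, "40:01" = 0.06, "35:01" = 0.06,
          "44:03" = 0.05, "57:01" = 0.04, "27:05" = 0.04, "55:01" = 0.088),
    C = c("07:01" = 0.18, "04:01" = 0.15, "07:02" = 0.14, "03:04" = 0.08,
          "06:02" = 0.08, "05:01" = 0.08, "12:03" = 0.07, "02:02" = 0.06,
          "03:03" = 0.06, "01:02" = 0.05, "08:02" = 0.05),
    DRB1 = c("15:01" = 0.15, "07:01" = 0.13, "03:01" = 0.12, "01:01" = 0.10,
             "11:01" = 0.10, "13:01" = 0.08, "04:01" = 0.08, "08:01" = 0.06,
             "13:02" = 0.06, "14:01" = 0.05, "12:01" = 0.04, "16:01" = 0.03),
    DQB1 = c("03:01" = 0.20, "06:02" = 0.14, "02:01" = 0.14, "05:01" = 0.13,
             "03:02" = 0.10, "06:03" = 0.08, "04:02" = 0.06, "05:03" = 0.05,
             "03:03" = 0.05, "06:04" = 0.05),
    DPB1 = c("04:01" = 0.40, "02:01" = 0.20, "04:02" = 0.12, "03:01" = 0.10,
             "01:01" = 0.07, "06:01" = 0.05, "05:01" = 0.03, "13:01" = 0.03))
  do.call(rbind, lapply(names(spec), function(loc) {
    data.frame(locus = loc,
               allele = normalize_hla(paste0(loc, "*", names(spec[[loc]]))),
               frequency = unname(spec[[loc]]), stringsAsFactors = FALSE)
  }))
}

default_length_dist_ii <- function() {
  lens <- 8:25
  p <- stats::dnorm(lens, mean = 15, sd = 2.3)
  stats::setNames(p / sum(p), lens)
}

#' Simulation configuration
#'
#' Bundles and validates the generator parameters. Defaults reflect the study
#' conditions of a 40-patient oropharyngeal tumour cohort: 55% HPV-positive,
#' mean class I ligandome of 1338 peptides (70% 9-mers), mean class II
#' ligandome of 702 peptides with modal length 15 (17%), a tissue-mass/yield
#' Pearson correlation of 0.4645, and a benign-overlap fraction of 0.77 so
#' that roughly a quarter of cohort peptides are tumour-exclusive.
#'
#' @param n_patients Cohort size.
#' @param allele_freqs data.frame `locus`/`allele`/`frequency`; frequencies
#'   must sum to at most 1 per locus (renormalised for sampling when < 1).
#' @param mean_ligandome_size_i,mean_ligandome_size_ii Mean peptides per
#'   sample by HLA class.
#' @param length_dist_i,length_dist_ii Named probability vectors
#'   length -> probability, each summing to 1.
#' @param benign_overlap_frac Probability that a cohort peptide is also
#'   planted in the benign reference.
#' @param shared_pool_size_i,shared_pool_size_ii Sizes of the shared
#'   (multi-patient) peptide pools per class.
#' @param benign_only_pool_size Peptides present only in the benign
#'   reference.
#' @param shared_presentation_prob Probability that an eligible patient
#'   (an allotype carrier for class I) presents a given shared peptide.
#' @param hpv_positive_frac Fraction of HPV-positive patients (the positive
#'   count is `round(n_patients * hpv_positive_frac)`).
#' @param hpv_read_threshold Read threshold the planted positives must
#'   exceed.
#' @param mass_yield_r Target Pearson correlation between log tissue mass and
#'   log peptide yield.
#' @param sd_log_size Lognormal sigma of the per-sample ligandome sizes.
#' @param qc_pass_frac Fraction of unique peptides passing all three spectral
#'   QC gates.
#' @param seed Master seed; one named random stream is derived per generated
#'   table.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 40L,
                       allele_freqs = default_allele_freqs(),
                       mean_ligandome_size_i = 1338,
                       mean_ligandome_size_ii = 702,
                       length_dist_i = c("8" = 0.06, "9" = 0.70,
                                         "10" = 0.15, "11" = 0.09),
                       length_dist_ii = default_length_dist_ii(),
                       benign_overlap_frac = 0.77,
                       shared_pool_size_i = 400L,
                       shared_pool_size_ii = 300L,
                       benign_only_pool_size = 1000L,
                       shared_presentation_prob = 0.35,
                       hpv_positive_frac = 0.55,
                       hpv_read_threshold = 500L,
                       mass_yield_r = 0.4645,
                       sd_log_size = 0.45,
                       qc_pass_frac = 0.6,
                       seed = 1L) {
  stopifnot(n_patients >= 1,
            all(c("locus", "allele", "frequency") %in% names(allele_freqs)),
            benign_overlap_frac >= 0, benign_overlap_frac <= 1,
            shared_presentation_prob >= 0, shared_presentation_prob <= 1,
            hpv_positive_frac >= 0, hpv_positive_frac <= 1,
            abs(mass_yield_r) <= 1, qc_pass_frac >= 0, qc_pass_frac <= 1)
  sums <- tapply(allele_freqs$frequency, allele_freqs$locus, sum)
  if (any(sums > 1 + 1e-9)) {
    stop("allele frequencies exceed 1 at locus/loci: ",
         paste(names(sums)[sums > 1 + 1e-9], collapse = ", "))
  }
  for (d in list(length_dist_i, length_dist_ii)) {
    if (abs(sum(d) - 1) > 1e-9) stop("length distribution must sum to 1")
    if (is.null(names(d))) stop("length distribution must be named by length")
  }
  structure(list(n_patients = as.integer(n_patients),
                 allele_freqs = allele_freqs,
                 mean_ligandome_size_i = mean_ligandome_size_i,
                 mean_ligandome_size_ii = mean_ligandome_size_ii,
                 length_dist_i = length_dist_i,
                 length_dist_ii = length_dist_ii,
                 benign_overlap_frac = benign_overlap_frac,
                 shared_pool_size_i = as.integer(shared_pool_size_i),
                 shared_pool_size_ii = as.integer(shared_pool_size_ii),
                 benign_only_pool_size = as.integer(benign_only_pool_size),
                 shared_presentation_prob = shared_presentation_prob,
                 hpv_positive_frac = hpv_positive_frac,
                 hpv_read_threshold = as.integer(hpv_read_threshold),
                 mass_yield_r = mass_yield_r, sd_log_size = sd_log_size,
                 qc_pass_frac = qc_pass_frac, seed = as.integer(seed)),
            class = "sim_config")
}

# n unique random peptides with lengths from a named probability vector
random_peptides <- function(n, length_dist, exclude = character()) {
  lens <- as.integer(names(length_dist))
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    draw_len <- sample_vec(lens, ceiling(need * 1.2) + 10, replace = TRUE,
                           prob = length_dist)
    draws <- vapply(draw_len, function(L) {
      paste(sample_vec(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, setdiff(draws, exclude)))
  }
  out[seq_len(n)]
}

simulate_genotypes <- function(cfg) {
  with_seed(stream_seed(cfg$seed, "genotypes"), {
    af <- cfg$allele_freqs
    rows <- list()
    for (loc in unique(af$locus)) {
      sub <- af[af$locus == loc, ]
      # Hardy-Weinberg: two independent draws per patient
      draws <- sample_vec(sub$allele, 2 * cfg$n_patients, replace = TRUE,
                          prob = sub$frequency / sum(sub$frequency))
      rows[[loc]] <- data.frame(
        patient_id = rep(sprintf("OPSCC_%02d", seq_len(cfg$n_patients)),
                         each = 2),
        allele = draws, stringsAsFactors = FALSE)
    }
    typing <- do.call(rbind, rows)
    rownames(typing) <- NULL
    typing[order(typing$patient_id, typing$allele), ]
  })
}

simulate_hpv <- function(cfg, patients) {
  with_seed(stream_seed(cfg$seed, "hpv"), {
    n_pos <- round(cfg$n_patients * cfg$hpv_positive_frac)
    pos <- sample_vec(patients, n_pos)
    types <- c("HPV-16", "HPV-35", "HPV-58", "HPV-59")
    type_of <- stats::setNames(
      sample_vec(types, n_pos, replace = TRUE,
                 prob = c(19, 1, 1, 1) / 22), pos)
    thr <- cfg$hpv_read_threshold
    counts <- list()
    for (p in patients) {
      for (tp in types) {
        if (p %in% pos && tp == type_of[[p]]) {
          reads <- c(E1 = stats::rnbinom(1, mu = 300, size = 5),
                     E2 = stats::rnbinom(1, mu = 300, size = 5),
                     E4 = stats::rnbinom(1, mu = 200, size = 5),
                     E5 = stats::rnbinom(1, mu = 150, size = 5),
                     E6 = thr + stats::rnbinom(1, mu = 3000, size = 5),
                     E7 = thr + stats::rnbinom(1, mu = 2500, size = 5),
                     L1 = stats::rnbinom(1, mu = 100, size = 5),
                     L2 = stats::rnbinom(1, mu = 100, size = 5))
        } else {
          # background: ~8 reads per type in total, never near threshold
          reads <- pmin(stats::rpois(8, 1), 50L)
          names(reads) <- HPV_GENES
        }
        counts[[length(counts) + 1]] <- data.frame(
          patient_id = p, hpv_type = tp, gene = HPV_GENES,
          reads = as.integer(reads), stringsAsFactors = FALSE)
      }
    }
    list(counts = do.call(rbind, counts),
         status = stats::setNames(
           ifelse(patients %in% pos, "positive", "negative"), patients),
         hpv_type = type_of)
  })
}

simulate_mass_sizes <- function(cfg, patients) {
  with_seed(stream_seed(cfg$seed, "mass"), {
    n <- length(patients)
    z1 <- stats::rnorm(n)
    z2 <- cfg$mass_yield_r * z1 +
      sqrt(1 - cfg$mass_yield_r^2) * stats::rnorm(n)
    s <- cfg$sd_log_size
    mass <- exp(log(250) + 0.5 * z1)  # mg
    size_i <- pmax(30L, as.integer(round(
      exp(log(cfg$mean_ligandome_size_i) - s^2 / 2 + s * z2))))
    size_ii <- pmax(20L, as.integer(round(
      exp(log(cfg$mean_ligandome_size_ii) - s^2 / 2 + s * z2))))
    data.frame(patient_id = patients, tissue_mass_mg = mass,
               size_i = size_i, size_ii = size_ii, stringsAsFactors = FALSE)
  })
}

#' Simulate a synthetic cohort
#'
#' Generates, deterministically for a given seed, the four input tables of
#' the pipeline (typing, peptide records, benign reference, oncogene read
#' counts) together with per-patient metadata and the planted ground truth.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `typing`, `records`, `benign`
#'   (a `benign_reference`), `oncogene_counts`, `metadata` and `truth`.
#'   `truth` holds the planted facts: `membership` (sample x peptide table
#'   with pool, attached allotype, benign and QC flags), `tep_i`/`tep_ii`
#'   (planted tumour-exclusive sequences), `hpv_status`, `hpv_type` and
#'   `qc_pass`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  typing <- simulate_genotypes(cfg)
  patients <- sort(unique(typing$patient_id))
  hpv <- simulate_hpv(cfg, patients)
  sizes <- simulate_mass_sizes(cfg, patients)

  mem <- with_seed(stream_seed(cfg$seed, "peptides"), {
    class_i_typing <- typing[parse_hla(typing$allele)$hla_class == "I", ]
    carrier_count <- table(unique(class_i_typing)[, "allele"])
    allotypes <- names(carrier_count)
    # shared class I pool, each peptide attached to one allotype
    shared_i <- random_peptides(cfg$shared_pool_size_i, cfg$length_dist_i)
    attach <- sample_vec(allotypes, cfg$shared_pool_size_i, replace = TRUE,
                         prob = as.numeric(carrier_count))
    shared_ii <- random_peptides(cfg$shared_pool_size_ii, cfg$length_dist_ii,
                                 exclude = shared_i)
    rows <- list()
    used <- c(shared_i, shared_ii)
    for (p in patients) {
      own <- unique(class_i_typing$allele[class_i_typing$patient_id == p])
      # shared class I peptides of carried allotypes
      eligible <- which(attach %in% own)
      take <- eligible[stats::runif(length(eligible)) <
                         cfg$shared_presentation_prob]
      if (length(take) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = p, sequence = shared_i[take], hla_class = "I",
          allotype = attach[take], pool = "shared", stringsAsFactors = FALSE)
      }
      take2 <- which(stats::runif(cfg$shared_pool_size_ii) <
                       cfg$shared_presentation_prob)
      if (length(take2) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = p, sequence = shared_ii[take2], hla_class = "II",
          allotype = NA_character_, pool = "shared",
          stringsAsFactors = FALSE)
      }
      n_sh_i <- sum(length(take))
      n_sh_ii <- length(take2)
      sz <- sizes[sizes$patient_id == p, ]
      n_priv_i <- max(0L, sz$size_i - n_sh_i)
      n_priv_ii <- max(0L, sz$size_ii - n_sh_ii)
      priv_i <- random_peptides(n_priv_i, cfg$length_dist_i, exclude = used)
      used <- c(used, priv_i)
      priv_ii <- random_peptides(n_priv_ii, cfg$length_dist_ii,
                                 exclude = used)
      used <- c(used, priv_ii)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = p, sequence = priv_i, hla_class = "I",
        allotype = sample_vec(own, n_priv_i, replace = TRUE),
        pool = "private", stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = p, sequence = priv_ii, hla_class = "II",
        allotype = NA_character_, pool = "private", stringsAsFactors = FALSE)
    }
    mem <- do.call(rbind, rows)
    # benign planting at the unique-peptide level
    uni <- unique(mem$sequence)
    benign_flag <- stats::setNames(
      stats::runif(length(uni)) < cfg$benign_overlap_frac, uni)
    benign_only <- random_peptides(cfg$benign_only_pool_size,
                                   cfg$length_dist_i, exclude = used)
    list(membership = mem, benign_flag = benign_flag,
         benign_only = benign_only)
  })

  membership <- mem$membership
  membership$benign <- unname(mem$benign_flag[membership$sequence])

  qc <- with_seed(stream_seed(cfg$seed, "qc"), {
    uni <- unique(membership$sequence)
    pass <- stats::setNames(stats::runif(length(uni)) < cfg$qc_pass_frac, uni)
    fail_gate <- stats::setNames(
      sample_vec(c("psm", "xcorr", "delta_cn"), length(uni), replace = TRUE),
      uni)
    n <- nrow(membership)
    psm <- 2L + stats::rpois(n, 1)
    xcorr <- 1.5 + stats::rexp(n, 1 / 0.8)
    dcn <- 0.2 + 0.8 * stats::rbeta(n, 2, 5)
    p_pass <- pass[membership$sequence]
    gate <- fail_gate[membership$sequence]
    psm[!p_pass & gate == "psm"] <- 1L
    xcorr[!p_pass & gate == "xcorr"] <-
      stats::runif(sum(!p_pass & gate == "xcorr"), 0.5, 1.45)
    dcn[!p_pass & gate == "delta_cn"] <-
      stats::runif(sum(!p_pass & gate == "delta_cn"), 0, 0.15)
    list(pass = pass, psm = psm, xcorr = xcorr, dcn = dcn,
         q = stats::runif(n, 0, 0.05))
  })

  records <- data.frame(
    sequence = membership$sequence, sample_id = membership$patient_id,
    hla_class = membership$hla_class, assigned_allele = membership$allotype,
    psm_count = qc$psm, xcorr = round(qc$xcorr, 3),
    delta_cn = round(qc$dcn, 3), q_value = pmax(round(qc$q, 5), 1e-05),
    stringsAsFactors = FALSE)
  membership$qc_pass <- unname(qc$pass[membership$sequence])

  benign_tab <- with_seed(stream_seed(cfg$seed, "benign"), {
    tissues <- c("tonsil", "lung", "liver", "kidney", "colon", "skin",
                 "spleen", "blood", "bone_marrow", "thymus", "stomach",
                 "pancreas")
    planted <- membership[membership$benign, c("sequence", "hla_class")]
    planted <- unique(planted)
    extra <- data.frame(sequence = mem$benign_only,
                        hla_class = sample_vec(c("I", "II"),
                                               length(mem$benign_only),
                                               replace = TRUE),
                        stringsAsFactors = FALSE)
    tab <- rbind(planted, extra)
    tab$tissue <- sample_vec(tissues, nrow(tab), replace = TRUE)
    tab$sample_id <- sprintf("BEN_%03d", sample.int(60, nrow(tab),
                                                    replace = TRUE))
    tab
  })

  metadata <- with_seed(stream_seed(cfg$seed, "metadata"), {
    data.frame(
      patient_id = patients,
      hpv_status = unname(hpv$status[patients]),
      sex = sample_vec(c("male", "female"), length(patients), replace = TRUE,
                       prob = c(0.825, 0.175)),
      age = round(stats::rnorm(length(patients), 59.9, 9), 1),
      tissue_mass_mg = sizes$tissue_mass_mg[match(patients,
                                                  sizes$patient_id)],
      stringsAsFactors = FALSE)
  })

  benign_classwise <- split(benign_tab$sequence, benign_tab$hla_class)
  tep_i <- sort(setdiff(
    unique(membership$sequence[membership$hla_class == "I"]),
    benign_classwise[["I"]]))
  tep_ii <- sort(setdiff(
    unique(membership$sequence[membership$hla_class == "II"]),
    benign_classwise[["II"]]))

  list(typing = typing, records = records,
       benign = benign_reference(benign_tab),
       oncogene_counts = hpv$counts, metadata = metadata,
       truth = list(membership = membership, tep_i = tep_i, tep_ii = tep_ii,
                    hpv_status = hpv$status, hpv_type = hpv$hpv_type,
                    qc_pass = sort(names(qc$pass)[qc$pass]),
                    benign_only = mem$benign_only))
}

#' Write a simulated cohort to disk
#'
#' Writes the four pipeline input tables in the package's TSV formats.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_peptide_table(sim$records, file.path(dir, "peptides.tsv"))
  write_hla_typing(sim$typing, file.path(dir, "typing.tsv"))
  utils::write.table(sim$oncogene_counts,
                     file.path(dir, "oncogene_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ben <- sim$benign
  tab <- do.call(rbind, lapply(c("I", "II"), function(cl) {
    seqs <- ben$peptides_by_class[[cl]]
    if (length(seqs) == 0) return(NULL)
    data.frame(sequence = seqs, hla_class = cl,
               tissue = vapply(ben$tissue_index[seqs], `[`, character(1), 1),
               sample_id = "BEN_POOL", stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, file.path(dir, "benign_reference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
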