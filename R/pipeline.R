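# End-to-end pipeline orchestration: identification filters -> binder
# annotation -> HPV calls -> comparative profiling -> cohort statistics ->
# warehouse optimisation -> per-patient compositions, with a run manifest.

#' Annotate binders from upstream assignment columns
#'
#' When externally assigned alleles are already present in the peptide record
#' table (column `assigned_allele`), this uses them as binder calls instead
#' of the motif scorer: a class I peptide is flagged as a binder if any
#' record assigns it one of the patient's alleles.
#'
#' @param lig A `ligandome`.
#' @param records Peptide record data.frame for this sample.
#' @param patient_alleles The patient's class I alleles.
#' @return The annotated ligandome.
#' @export
annotate_from_assignments <- function(lig, records, patient_alleles) {
  patient_alleles <- unique(normalize_hla(patient_alleles))
  sub <- records[records$sample_id == lig$sample_id &
                   records$hla_class == "I" &
                   !is.na(records$assigned_allele), , drop = FALSE]
  sub <- sub[sub$assigned_allele %in% patient_alleles, , drop = FALSE]
  flags <- stats::setNames(lig$class_i %in% sub$sequence, lig$class_i)
  assigned <- stats::setNames(
    sub$assigned_allele[match(lig$class_i, sub$sequence)], lig$class_i)
  lig$binder_flags <- flags
  lig$assigned_allele <- assigned
  lig
}

#' Pipeline configuration
#'
#' Inputs may be in-memory objects (data.frames / `benign_reference`) or
#' paths to files in the package's TSV formats. Every threshold defaults to
#' the value used for the tumour-cohort analysis.
#'
#' @param peptides Peptide record table or TSV path.
#' @param typing Cohort typing table or TSV path.
#' @param benign `benign_reference` or TSV path.
#' @param oncogene_counts Oncogene read-count table or TSV path.
#' @param metadata Optional per-patient metadata (needs `patient_id`,
#'   `tissue_mass_mg` for the mass-yield correlation).
#' @param motifs Optional list of `motif_matrix` objects; when absent, binder
#'   annotation falls back to the `assigned_allele` column of the records.
#' @param q_max,len_min,len_max Identification filter thresholds.
#' @param psm_min,xcorr_min,delta_cn_min Spectral QC gates.
#' @param hpv_threshold HPV read-count threshold.
#' @param min_patients_i,min_patients_ii Minimum carrier/ligandome counts for
#'   warehouse candidacy by class.
#' @param top_per_isotype Number of most frequent allotypes per isotype
#'   (HLA-A, -B, -C) entered into warehouse optimisation.
#' @param iterations,max_runs,seed Optimiser settings (`seed` is mandatory).
#' @param out_dir Optional output directory for the report bundle.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(peptides, typing, benign, oncogene_counts,
                            metadata = NULL, motifs = NULL,
                            q_max = 0.05, len_min = 8L, len_max = 25L,
                            psm_min = 2, xcorr_min = 1.5, delta_cn_min = 0.2,
                            hpv_threshold = 500L,
                            min_patients_i = 2L, min_patients_ii = 3L,
                            top_per_isotype = 5L,
                            iterations = 1e6, max_runs = 3L, seed,
                            out_dir = NULL) {
  stopifnot(!missing(seed), q_max >= 0, len_min >= 1, hpv_threshold > 0,
            min_patients_i >= 1, min_patients_ii >= 1, max_runs >= 1)
  structure(list(peptides = peptides, typing = typing, benign = benign,
                 oncogene_counts = oncogene_counts, metadata = metadata,
                 motifs = motifs, q_max = q_max, len_min = len_min,
                 len_max = len_max, psm_min = psm_min,
                 xcorr_min = xcorr_min, delta_cn_min = delta_cn_min,
                 hpv_threshold = as.integer(hpv_threshold),
                 min_patients_i = as.integer(min_patients_i),
                 min_patients_ii = as.integer(min_patients_ii),
                 top_per_isotype = as.integer(top_per_isotype),
                 iterations = iterations, max_runs = as.integer(max_runs),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds input paths and (optionally) any threshold accepted by
#' [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full analysis pipeline
#'
#' Executes identification filtering, binder annotation, HPV calling,
#' comparative TEP profiling, cohort statistics, warehouse optimisation and
#' per-patient composition, collecting per-stage record counters into a run
#' manifest. The run is deterministic for a given seed. On a stage error the
#' manifest marks the failure point, results computed so far are kept, and
#' `status` is 1.
#'
#' @param config A `pipeline_config`.
#' @return List with `status` (0 on success), `manifest` and `results`.
#'   When `config$out_dir` is set, the report bundle (TSV/JSON) is written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed,
                   thresholds = config[c("q_max", "len_min", "len_max",
                                         "psm_min", "xcorr_min",
                                         "delta_cn_min", "hpv_threshold",
                                         "min_patients_i", "min_patients_ii",
                                         "iterations", "max_runs")],
                   assumptions = c(
                     "binder rule: OR over motif calls at 2-field resolution",
                     "HPV sum rule applied per HPV type",
                     "saturation model: S_max*(1-exp(-k*n))"),
                   stages = list())
  results <- list()
  status <- 0L
  stage <- function(name, fun) {
    if (status != 0L) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      status <<- 1L
    } else {
      manifest$stages[[name]] <<- c(list(status = "completed"), res$counters)
      results[[name]] <<- res$value
    }
    invisible(NULL)
  }

  typing <- resolve_input(config$typing, read_hla_typing)
  benign <- resolve_input(config$benign, read_benign_reference)

  stage("filter", function() {
    raw <- resolve_input(config$peptides, read_peptide_table)
    kept <- apply_identification_filters(raw, config$q_max, config$len_min,
                                         config$len_max)
    list(value = kept, counters = list(records_in = nrow(raw),
                                       records_out = nrow(kept)))
  })

  stage("binder_annotation", function() {
    records <- results$filter
    ligs <- build_ligandomes(records)
    ligs <- lapply(ligs, function(l) {
      alleles <- typing$allele[typing$patient_id == l$sample_id]
      if (!is.null(config$motifs)) {
        annotate_binders(l, alleles, config$motifs)
      } else {
        annotate_from_assignments(l, records, alleles)
      }
    })
    purity <- vapply(ligs, ligandome_purity, numeric(1))
    list(value = list(ligandomes = ligs, purity = purity),
         counters = list(n_samples = length(ligs),
                         mean_purity = mean(purity, na.rm = TRUE)))
  })

  stage("hpv", function() {
    counts <- resolve_input(config$oncogene_counts, read_oncogene_counts)
    calls <- call_hpv_status(counts, config$hpv_threshold)
    list(value = calls,
         counters = list(n_positive = sum(calls$status == "positive"),
                         n_negative = sum(calls$status == "negative")))
  })

  stage("profiling", function() {
    ligs <- results$binder_annotation$ligandomes
    status_map <- hpv_status_map(results$hpv)
    tep_i <- identify_tep(ligs, benign, "I")
    tep_ii <- identify_tep(ligs, benign, "II")
    prof <- list(
      tep_i = tep_i, tep_ii = tep_ii,
      tep_i_prevalent = prevalence_filter(tep_i, config$min_patients_ii),
      tep_ii_prevalent = prevalence_filter(tep_ii, config$min_patients_ii),
      strata_i = stratify_by_hpv(ligs, status_map, "I"),
      strata_ii = stratify_by_hpv(ligs, status_map, "II"),
      length_dist_i = length_distribution(ligs, "I"),
      length_dist_ii = length_distribution(ligs, "II"))
    list(value = prof,
         counters = list(n_tep_i = nrow(tep_i), n_tep_ii = nrow(tep_ii)))
  })

  stage("stats", function() {
    ligs <- results$binder_annotation$ligandomes
    out <- list(hpv_summary = NULL, mass_yield = NULL)
    if (!is.null(config$metadata)) {
      md <- config$metadata
      md$hpv_status <- hpv_status_map(results$hpv)[md$patient_id]
      out$cohort_summary <- cohort_summary(md)
      if ("tissue_mass_mg" %in% names(md)) {
        yields <- vapply(ligs, function(l) length(l$class_i), numeric(1))
        common <- intersect(md$patient_id, names(yields))
        out$mass_yield <- mass_yield_correlation(
          md$tissue_mass_mg[match(common, md$patient_id)], yields[common])
      }
    }
    class_i <- typing[parse_hla(typing$allele)$hla_class == "I", ]
    out$allotype_counts <- sort(table(unique(class_i)$allele),
                                decreasing = TRUE)
    list(value = out, counters = list(
      n_class_i_allotypes = length(out$allotype_counts)))
  })

  stage("warehouse", function() {
    ligs <- results$binder_annotation$ligandomes
    records <- results$filter
    qc <- qc_filter(records, config$psm_min, config$xcorr_min,
                    config$delta_cn_min)
    counts <- results$stats$allotype_counts
    loci <- parse_hla(names(counts))$locus
    top <- unlist(lapply(c("A", "B", "C"), function(iso) {
      utils::head(names(counts)[loci == iso], config$top_per_isotype)
    }))
    selections <- list()
    skipped <- character()
    for (allo in top) {
      inc <- build_incidence(allo, ligs, typing,
                             results$profiling$tep_i,
                             min_patients = config$min_patients_i)
      max_cov <- coverage_count(inc$present, seq_along(inc$peptides))
      if (length(inc$peptides) == 0 || max_cov <= 1) {
        skipped <- c(skipped, allo)  # negligible attainable coverage
        next
      }
      selections[[allo]] <- optimise_with_qc(
        inc, qc$pass, max_runs = config$max_runs,
        iterations = config$iterations, seed = config$seed)
    }
    class_ii <- select_class_ii(
      results$profiling$tep_ii_prevalent, ligs, qc$pass,
      min_patients = config$min_patients_ii,
      hpv_status = hpv_status_map(results$hpv),
      iterations = config$iterations, seed = config$seed)
    list(value = list(class_i = selections, class_ii = class_ii,
                      skipped_allotypes = skipped, qc = qc),
         counters = list(n_allotypes_selected = length(selections),
                         n_allotypes_skipped = length(skipped),
                         n_class_ii_selected = length(class_ii$selected)))
  })

  stage("compositions", function() {
    ligs <- results$binder_annotation$ligandomes
    rep <- coverage_report(results$warehouse$class_i, typing, ligs)
    list(value = rep,
         counters = list(
           median_pct_of_selected = rep$summary$median_pct_of_selected))
  })

  manifest$n_stages_completed <- sum(vapply(manifest$stages, function(s) {
    identical(s$status, "completed")
  }, logical(1)))

  if (!is.null(config$out_dir)) {
    write_report_bundle(results, manifest, config$out_dir)
  }
  list(status = status, manifest = manifest, results = results)
}

write_report_bundle <- function(results, manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(results$profiling)) {
    tep <- rbind(results$profiling$tep_i, results$profiling$tep_ii)
    utils::write.table(tep, file.path(out_dir, "tep.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(results$hpv)) {
    utils::write.table(results$hpv, file.path(out_dir, "hpv_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(results$warehouse)) {
    wh <- lapply(results$warehouse$class_i, function(w) {
      w[c("allotype", "selected", "coverage_pct", "pareto_front", "n_runs",
          "qc_removed")]
    })
    jsonlite::write_json(wh, file.path(out_dir, "warehouse.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  if (!is.null(results$compositions)) {
    utils::write.table(results$compositions$by_patient,
                       file.path(out_dir, "patient_compositions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
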