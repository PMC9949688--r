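# HPV status calling from oncogene RNA-seq read counts.

HPV_GENES <- c("E1", "E2", "E4", "E5", "E6", "E7", "L1", "L2")

#' Call HPV status from oncogene read counts
#'
#' A patient is HPV-positive when, for any single HPV type, the read count of
#' E6 or of E7 reaches `threshold` (default 500), or the summed reads over the
#' eight genes E1, E2, E4, E5, E6, E7, L1, L2 of that type reach `threshold`.
#' All comparisons are inclusive. For positive patients the called type is the
#' HPV type with the highest total read count over the eight genes; ties are
#' broken by the higher E6+E7 count, then lexicographically by type name.
#' The sum rule is evaluated per HPV type, never across types.
#'
#' @param counts data.frame with columns `patient_id`, `hpv_type`, `gene`,
#'   `reads` (as from [read_oncogene_counts()]); may hold several patients.
#' @param threshold Read-count threshold (inclusive).
#' @return data.frame with one row per patient: `patient_id`, `status`
#'   (`"positive"`/`"negative"`), `hpv_type` (`NA` when negative) and
#'   `total_oncogene_reads` (reads of the called type, or all types when
#'   negative).
#' @export
call_hpv_status <- function(counts, threshold = 500L) {
  stopifnot(all(c("patient_id", "hpv_type", "gene", "reads") %in%
                  names(counts)))
  bad <- setdiff(unique(counts$gene), HPV_GENES)
  if (length(bad) > 0) stop("unknown HPV gene(s): ", paste(bad, collapse = ", "))
  stopifnot(all(counts$reads >= 0))
  one <- function(sub) {
    types <- sort(unique(sub$hpv_type))
    per_type <- do.call(rbind, lapply(types, function(tp) {
      g <- sub[sub$hpv_type == tp, , drop = FALSE]
      reads_of <- function(gene) sum(g$reads[g$gene == gene])
      total <- sum(g$reads)
      data.frame(hpv_type = tp, e6 = reads_of("E6"), e7 = reads_of("E7"),
                 total = total,
                 positive = reads_of("E6") >= threshold |
                   reads_of("E7") >= threshold | total >= threshold,
                 stringsAsFactors = FALSE)
    }))
    if (any(per_type$positive)) {
      cand <- per_type[per_type$positive, , drop = FALSE]
      ord <- order(-cand$total, -(cand$e6 + cand$e7), cand$hpv_type)
      best <- cand[ord[1], ]
      data.frame(patient_id = sub$patient_id[1], status = "positive",
                 hpv_type = best$hpv_type,
                 total_oncogene_reads = best$total, stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = sub$patient_id[1], status = "negative",
                 hpv_type = NA_character_,
                 total_oncogene_reads = sum(per_type$total),
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(split(counts, counts$patient_id), one))
  rownames(out) <- NULL
  out
}

#' Named HPV status vector from HPV calls
#'
#' @param calls Output of [call_hpv_status()], or a data.frame with
#'   `patient_id` and `status`.
#' @return Named character vector patient_id -> `"positive"`/`"negative"`.
#' @export
hpv_status_map <- function(calls) {
  stats::setNames(as.character(calls$status), calls$patient_id)
}
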