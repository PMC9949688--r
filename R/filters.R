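# Identification-level filtering of peptide records.

#' Apply identification filters
#'
#' Keeps records at the identification confidence and length window used for
#' accepting HLA-presented peptides: FDR-calibrated `q_value <= q_max`
#' (default 0.05) and peptide length within `[len_min, len_max]` (default
#' 8-25 amino acids). Both boundaries are inclusive. The operation preserves
#' input order and is idempotent.
#'
#' @param records Peptide record data.frame.
#' @param q_max Maximum q-value (inclusive).
#' @param len_min,len_max Inclusive peptide length bounds.
#' @return The filtered data.frame.
#' @export
apply_identification_filters <- function(records, q_max = 0.05,
                                         len_min = 8L, len_max = 25L) {
  stopifnot(q_max >= 0, len_min >= 1, len_max >= len_min)
  len <- nchar(records$sequence)
  keep <- !is.na(records$q_value) & records$q_value <= q_max &
    len >= len_min & len <= len_max
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
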