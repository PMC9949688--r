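# Query the cohort peptidome against supplied protein sequences
# (e.g. the HPV proteome or patient-specific mutated sequences).

#' Query the peptidome against protein sequences
#'
#' Exact substring search of every unique cohort peptide against every
#' supplied protein; all occurrences are reported with 0-based start and
#' exclusive end offsets. An empty result is a valid outcome. Matching is
#' exact; set `collapse_il = TRUE` to treat I and L as indistinguishable.
#'
#' @param ligandomes List of `ligandome` objects.
#' @param proteins Named character vector of protein sequences (e.g. from
#'   [read_protein_fasta()]).
#' @param hla_class `"I"`, `"II"` or `"both"` (default).
#' @param binders_only For class I, restrict to annotated binders.
#' @param collapse_il Collapse I to L on both sides before matching (reported
#'   offsets refer to the collapsed coordinates, sequences to the originals).
#' @return data.frame with columns `peptide`, `protein_id`, `start`, `end`,
#'   `n_samples` and `sample_ids` (comma-separated), ordered by peptide,
#'   protein and offset.
#' @export
query_peptidome <- function(ligandomes, proteins,
                            hla_class = c("both", "I", "II"),
                            binders_only = TRUE, collapse_il = FALSE) {
  hla_class <- match.arg(hla_class)
  stopifnot(length(proteins) > 0, is.character(proteins))
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    stop("proteins must be named")
  }
  classes <- if (hla_class == "both") c("I", "II") else hla_class
  pep_samples <- list()
  for (lig in ligandomes) {
    for (cl in classes) {
      for (p in ligandome_peptides(lig, cl, binders_only = binders_only)) {
        pep_samples[[p]] <- c(pep_samples[[p]], lig$sample_id)
      }
    }
  }
  peptides <- sort(names(pep_samples))
  key <- il_key(collapse_il)
  prot_seq <- key(toupper(proteins))
  hits <- list()
  for (pep in peptides) {
    for (pid in sort(names(proteins))) {
      # lookahead so that overlapping occurrences are all reported
      m <- gregexpr(paste0("(?=", key(pep), ")"), prot_seq[[pid]],
                    perl = TRUE)[[1]]
      if (m[1] == -1) next
      for (s in as.integer(m)) {
        hits[[length(hits) + 1]] <- data.frame(
          peptide = pep, protein_id = pid, start = s - 1L,
          end = s - 1L + nchar(pep),
          n_samples = length(unique(pep_samples[[pep]])),
          sample_ids = paste(sort(unique(pep_samples[[pep]])),
                             collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(peptide = character(), protein_id = character(),
                      start = integer(), end = integer(),
                      n_samples = integer(), sample_ids = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$peptide, out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
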