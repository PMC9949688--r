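# Readers and writers for the tabular inputs and outputs, plus the core
# domain containers (peptide record table, ligandome, benign reference).

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_valid_peptide <- function(x) {
  grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), x)
}

PEPTIDE_COLUMNS <- c("sequence", "sample_id", "hla_class", "assigned_allele",
                     "psm_count", "xcorr", "delta_cn", "q_value")

#' Collapse isoleucine to leucine
#'
#' Mass spectrometry cannot distinguish I from L. Sequence comparisons in this
#' package are exact by default; this helper implements the optional I->L
#' collapse for exclusivity comparisons.
#'
#' @param x Character vector of peptide sequences.
#' @return `x` with every `I` replaced by `L`.
#' @export
collapse_il <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Read a peptide identification table
#'
#' Reads a TSV of per-sample peptide identifications with spectral quality
#' metrics. Rows whose sequence contains characters outside the 20-letter
#' amino-acid alphabet are dropped with a warning giving their count.
#'
#' @param path Path to a tab-separated file with a header.
#' @param col_map Optional named character vector mapping the canonical column
#'   names (`sequence`, `sample_id`, `hla_class`, `assigned_allele`,
#'   `psm_count`, `xcorr`, `delta_cn`, `q_value`) to the names used in the
#'   file.
#' @return A data.frame of peptide records; sequences are uppercased and
#'   assigned alleles normalised to 2-field nomenclature.
#' @export
read_peptide_table <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  mandatory <- c("sequence", "sample_id", "hla_class", "q_value")
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0) {
    stop("peptide table ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  for (opt in setdiff(PEPTIDE_COLUMNS, names(df))) df[[opt]] <- NA
  df <- df[, PEPTIDE_COLUMNS, drop = FALSE]
  df$sequence <- toupper(as.character(df$sequence))
  bad <- !is_valid_peptide(df$sequence)
  if (any(bad)) {
    warning(sum(bad), " row(s) with invalid residues dropped from ", path)
    df <- df[!bad, , drop = FALSE]
  }
  df$hla_class <- toupper(as.character(df$hla_class))
  stopifnot(all(df$hla_class %in% c("I", "II")))
  df$assigned_allele <- normalize_hla(as.character(df$assigned_allele))
  df$psm_count <- as.integer(df$psm_count)
  df$xcorr <- as.numeric(df$xcorr)
  df$delta_cn <- as.numeric(df$delta_cn)
  df$q_value <- as.numeric(df$q_value)
  rownames(df) <- NULL
  df
}

#' Write a peptide identification table
#'
#' @param records Peptide record data.frame.
#' @param path Output TSV path.
#' @export
write_peptide_table <- function(records, path) {
  utils::write.table(records[, PEPTIDE_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort HLA typing table
#'
#' Long-format TSV with columns `patient_id` and `allele` (one row per allele
#' copy; at most two per locus per patient).
#'
#' @param path Input TSV path.
#' @return data.frame with columns `patient_id`, `allele` (normalised),
#'   `locus` and `hla_class`.
#' @export
read_hla_typing <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "allele"), names(df))
  if (length(missing) > 0) {
    stop("typing table missing column(s): ", paste(missing, collapse = ", "))
  }
  parsed <- parse_hla(df$allele)
  out <- data.frame(patient_id = as.character(df$patient_id),
                    allele = parsed$allele, locus = parsed$locus,
                    hla_class = parsed$hla_class, stringsAsFactors = FALSE)
  n_per_locus <- stats::aggregate(allele ~ patient_id + locus, out, length)
  if (any(n_per_locus$allele > 2)) {
    stop("more than two alleles at one locus for patient(s): ",
         paste(unique(n_per_locus$patient_id[n_per_locus$allele > 2]),
               collapse = ", "))
  }
  out
}

#' Write a cohort HLA typing table
#' @param typing data.frame with `patient_id` and `allele`.
#' @param path Output TSV path.
#' @export
write_hla_typing <- function(typing, path) {
  utils::write.table(typing[, c("patient_id", "allele")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a benign reference ligandome
#'
#' @param table data.frame with columns `sequence`, `hla_class`, `tissue`,
#'   `sample_id`.
#' @return An object of class `benign_reference` holding per-class peptide
#'   sets, a sequence -> tissue index, and per-class sample counts.
#' @export
benign_reference <- function(table) {
  stopifnot(all(c("sequence", "hla_class", "tissue", "sample_id") %in%
                  names(table)))
  table$sequence <- toupper(as.character(table$sequence))
  stopifnot(all(is_valid_peptide(table$sequence)))
  table$hla_class <- toupper(as.character(table$hla_class))
  stopifnot(all(table$hla_class %in% c("I", "II")))
  by_class <- lapply(c(I = "I", II = "II"), function(cl) {
    unique(table$sequence[table$hla_class == cl])
  })
  tissue_index <- lapply(split(table$tissue, table$sequence),
                         function(x) sort(unique(x)))
  n_samples <- vapply(c(I = "I", II = "II"), function(cl) {
    length(unique(table$sample_id[table$hla_class == cl]))
  }, integer(1))
  structure(list(peptides_by_class = by_class, tissue_index = tissue_index,
                 n_samples = n_samples),
            class = "benign_reference")
}

#' Read a benign reference table
#' @param path TSV with columns `sequence`, `hla_class`, `tissue`, `sample_id`.
#' @return A `benign_reference` object.
#' @export
read_benign_reference <- function(path) {
  benign_reference(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read an HPV oncogene read-count table
#'
#' @param path TSV with columns `patient_id`, `hpv_type`, `gene`, `reads`.
#' @return data.frame restricted to the eight oncogene/capsid genes
#'   E1, E2, E4, E5, E6, E7, L1, L2; all counts non-negative.
#' @export
read_oncogene_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "hpv_type", "gene", "reads"), names(df))
  if (length(missing) > 0) {
    stop("oncogene count table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df$gene <- toupper(df$gene)
  bad <- setdiff(unique(df$gene), HPV_GENES)
  if (length(bad) > 0) {
    stop("unknown HPV gene(s): ", paste(bad, collapse = ", "))
  }
  df$reads <- as.integer(df$reads)
  stopifnot(all(df$reads >= 0))
  df
}

#' Read a reference allele-frequency table
#'
#' Accepts an allelefrequencies.net-style export.
#'
#' @param path TSV with columns `allele`, `frequency`, and optionally
#'   `population` and `n_individuals`.
#' @return data.frame with normalised alleles, their locus, and frequencies.
#' @export
read_allele_freqs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("allele", "frequency"), names(df))
  if (length(missing) > 0) {
    stop("allele frequency table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  parsed <- parse_hla(df$allele)
  df$allele <- parsed$allele
  df$locus <- parsed$locus
  stopifnot(all(df$frequency >= 0 & df$frequency <= 1))
  df
}

#' Read protein sequences from FASTA
#'
#' @param path Path to an amino-acid FASTA file.
#' @return Named character vector of uppercase protein sequences.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no sequences in FASTA file ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

# ---- ligandomes -------------------------------------------------------------

#' Construct a per-sample ligandome
#'
#' A ligandome is the set of peptides presented by one sample, kept separately
#' for HLA class I and class II. Class I peptides may carry binder flags and
#' per-peptide allotype assignments once [annotate_binders()] has run.
#'
#' @param sample_id Sample identifier.
#' @param class_i,class_ii Character vectors of peptide sequences.
#' @param binder_flags Optional named logical vector over `class_i`.
#' @param assigned_allele Optional named character vector over `class_i`.
#' @return An object of class `ligandome`.
#' @export
ligandome <- function(sample_id, class_i = character(), class_ii = character(),
                      binder_flags = NULL, assigned_allele = NULL) {
  class_i <- unique(toupper(class_i))
  class_ii <- unique(toupper(class_ii))
  if (!is.null(binder_flags)) {
    stopifnot(all(names(binder_flags) %in% class_i))
  }
  structure(list(sample_id = as.character(sample_id),
                 class_i = class_i, class_ii = class_ii,
                 binder_flags = binder_flags,
                 assigned_allele = assigned_allele),
            class = "ligandome")
}

#' @export
print.ligandome <- function(x, ...) {
  cat("ligandome", x$sample_id, "-", length(x$class_i), "class I /",
      length(x$class_ii), "class II peptides")
  if (!is.null(x$binder_flags)) {
    cat(sprintf(", purity %.1f%%", 100 * ligandome_purity(x)))
  }
  cat("\n")
  invisible(x)
}

#' Build per-sample ligandomes from a peptide record table
#'
#' @param records Peptide record data.frame (after identification filtering).
#' @return Named list of `ligandome` objects, one per sample.
#' @export
build_ligandomes <- function(records) {
  samples <- sort(unique(records$sample_id))
  out <- lapply(samples, function(s) {
    sub <- records[records$sample_id == s, , drop = FALSE]
    ligandome(s,
              class_i = sub$sequence[sub$hla_class == "I"],
              class_ii = sub$sequence[sub$hla_class == "II"])
  })
  names(out) <- samples
  out
}

#' Class I or class II peptide set of a ligandome
#'
#' For class I, `binders_only = TRUE` restricts to peptides flagged as HLA
#' binders (HLA ligands); if no binder annotation is present all class I
#' peptides are returned.
#'
#' @param lig A `ligandome`.
#' @param hla_class `"I"` or `"II"`.
#' @param binders_only Restrict class I to annotated binders (default `TRUE`).
#' @return Character vector of peptide sequences.
#' @export
ligandome_peptides <- function(lig, hla_class = c("I", "II"),
                               binders_only = TRUE) {
  hla_class <- match.arg(hla_class)
  if (hla_class == "II") return(lig$class_ii)
  if (binders_only && !is.null(lig$binder_flags)) {
    return(names(lig$binder_flags)[lig$binder_flags])
  }
  lig$class_i
}
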