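# HLA class I binder annotation with position-specific scoring motifs.
#
# The package scores peptides with additive position-specific weight matrices
# (one per allele and length) with a per-allele threshold. Externally produced
# binder calls (from dedicated predictors) can be imported instead via
# read_binder_calls().

#' Construct a position-specific scoring motif
#'
#' @param allele Allele name (normalised internally).
#' @param weights Numeric matrix, `length` rows (positions) by 20 columns
#'   (residues, named with the amino-acid alphabet).
#' @param threshold Score at or above which a peptide is called a binder.
#' @return Object of class `motif_matrix`.
#' @export
motif_matrix <- function(allele, weights, threshold) {
  stopifnot(is.matrix(weights), ncol(weights) == 20,
            is.finite(threshold))
  if (is.null(colnames(weights)) ||
      !setequal(colnames(weights), AA_ALPHABET)) {
    stop("motif weights must have the 20 amino acids as column names")
  }
  weights <- weights[, AA_ALPHABET, drop = FALSE]
  structure(list(allele = normalize_hla(allele), length = nrow(weights),
                 weights = weights, threshold = threshold),
            class = "motif_matrix")
}

#' Score a peptide against a motif
#'
#' Additive position-specific score: the sum over positions of the weight of
#' the residue observed at that position.
#'
#' @param peptide Peptide sequence; its length must equal the motif length.
#' @param motif A `motif_matrix`.
#' @return Numeric score.
#' @export
score_peptide <- function(peptide, motif) {
  stopifnot(inherits(motif, "motif_matrix"))
  res <- strsplit(toupper(peptide), "")[[1]]
  if (length(res) != motif$length) {
    stop("peptide length ", length(res), " does not match motif length ",
         motif$length)
  }
  sum(motif$weights[cbind(seq_along(res), match(res, AA_ALPHABET))])
}

score_peptides <- function(peptides, motif) {
  # vectorised scorer over same-length peptides
  n <- length(peptides)
  if (n == 0) return(numeric(0))
  L <- motif$length
  mat <- matrix(match(unlist(strsplit(peptides, "")), AA_ALPHABET),
                nrow = L)
  idx <- cbind(rep(seq_len(L), n), as.vector(mat))
  colSums(matrix(motif$weights[idx], nrow = L))
}

#' Annotate class I binders in a ligandome
#'
#' Flags each class I peptide as a binder when it reaches the threshold of any
#' motif of any allele the patient carries, over motifs matching the peptide
#' length. Binders are assigned the allele whose motif gives the highest
#' margin above its threshold. Peptides with no same-length motif are
#' non-binders.
#'
#' @param lig A `ligandome`.
#' @param patient_alleles Character vector of the patient's (class I) alleles.
#' @param motifs List of `motif_matrix` objects.
#' @return The ligandome with `binder_flags` and `assigned_allele` filled in.
#' @export
annotate_binders <- function(lig, patient_alleles, motifs) {
  patient_alleles <- unique(normalize_hla(patient_alleles))
  patient_alleles <- patient_alleles[
    parse_hla(patient_alleles)$hla_class == "I"]
  motif_alleles <- vapply(motifs, function(m) m$allele, character(1))
  usable <- motifs[motif_alleles %in% patient_alleles]
  if (length(usable) == 0) {
    stop("no motifs available for any patient allele; missing: ",
         paste(setdiff(patient_alleles, motif_alleles), collapse = ", "))
  }
  peptides <- lig$class_i
  flags <- stats::setNames(rep(FALSE, length(peptides)), peptides)
  assigned <- stats::setNames(rep(NA_character_, length(peptides)), peptides)
  margin <- stats::setNames(rep(-Inf, length(peptides)), peptides)
  lens <- nchar(peptides)
  for (m in usable) {
    sel <- which(lens == m$length)
    if (length(sel) == 0) next
    sc <- score_peptides(peptides[sel], m)
    pass <- sc >= m$threshold
    hit <- sel[pass]
    flags[hit] <- TRUE
    better <- (sc[pass] - m$threshold) > margin[hit]
    assigned[hit][better] <- m$allele
    margin[hit][better] <- (sc[pass] - m$threshold)[better]
  }
  lig$binder_flags <- flags
  lig$assigned_allele <- assigned
  lig
}

#' Ligandome purity
#'
#' The proportion of class I-presented peptides annotated as binders to the
#' donor's HLA allotypes.
#'
#' @param lig A binder-annotated `ligandome`.
#' @return Fraction in `[0, 1]` (`NA` when no class I peptides).
#' @export
ligandome_purity <- function(lig) {
  if (is.null(lig$binder_flags)) stop("ligandome has no binder annotation")
  if (length(lig$class_i) == 0) return(NA_real_)
  sum(lig$binder_flags) / length(lig$class_i)
}

#' Read motif matrices from TSV
#'
#' Long-format weights table `[allele, length, position, residue, weight]`
#' and a threshold table `[allele, threshold]`.
#'
#' @param weights_path,thresholds_path Paths to the two TSV files.
#' @return List of `motif_matrix` objects.
#' @export
read_motifs <- function(weights_path, thresholds_path) {
  w <- utils::read.delim(weights_path, stringsAsFactors = FALSE)
  th <- utils::read.delim(thresholds_path, stringsAsFactors = FALSE)
  stopifnot(all(c("allele", "length", "position", "residue", "weight") %in%
                  names(w)),
            all(c("allele", "threshold") %in% names(th)))
  w$allele <- normalize_hla(w$allele)
  th$allele <- normalize_hla(th$allele)
  keys <- unique(w[, c("allele", "length")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- w[w$allele == keys$allele[i] & w$length == keys$length[i], ]
    mat <- matrix(0, nrow = keys$length[i], ncol = 20,
                  dimnames = list(NULL, AA_ALPHABET))
    mat[cbind(sub$position, match(sub$residue, AA_ALPHABET))] <- sub$weight
    motif_matrix(keys$allele[i], mat,
                 th$threshold[match(keys$allele[i], th$allele)])
  })
}

#' Import externally produced binder calls
#'
#' Drop-in path for real predictor output, bypassing the motif scorer.
#'
#' @param path TSV with columns `sequence`, `allele`, `is_binder`.
#' @param lig A `ligandome` to annotate.
#' @return The ligandome with `binder_flags`/`assigned_allele` set from the
#'   imported calls (peptides absent from the file are non-binders).
#' @export
apply_binder_calls <- function(lig, path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sequence", "allele", "is_binder") %in% names(df)))
  df$sequence <- toupper(df$sequence)
  df <- df[as.logical(df$is_binder) & df$sequence %in% lig$class_i, ]
  flags <- stats::setNames(lig$class_i %in% df$sequence, lig$class_i)
  assigned <- stats::setNames(
    normalize_hla(df$allele[match(lig$class_i, df$sequence)]), lig$class_i)
  lig$binder_flags <- flags
  lig$assigned_allele <- assigned
  lig
}

#' Generate a synthetic anchor-style motif
#'
#' Builds a simple class I-like motif with two strong anchor positions
#' (position 2 and the C-terminus) and weak preferences elsewhere. Used by the
#' synthetic-data tooling and examples; not a trained predictor.
#'
#' @param allele Allele name.
#' @param length Peptide length the motif applies to.
#' @param seed Integer seed making the motif reproducible.
#' @return A `motif_matrix` whose threshold accepts peptides carrying both
#'   anchor residues.
#' @export
synthetic_motif <- function(allele, length = 9L, seed = 1L) {
  with_seed(seed, {
    w <- matrix(stats::runif(length * 20, 0, 0.5), nrow = length,
                dimnames = list(NULL, AA_ALPHABET))
    for (p in c(2L, length)) {
      res <- sample_vec(AA_ALPHABET, 1)
      w[p, ] <- 0
      w[p, res] <- 10
    }
    motif_matrix(allele, w, threshold = 20)
  })
}

#' Sample peptides conforming to a motif
#'
#' Draws peptides that score at or above the motif threshold (anchor residues
#' fixed, other positions random); used to plant binders in synthetic data.
#'
#' @param motif A `motif_matrix`.
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @return Character vector of `n` peptides of the motif's length.
#' @export
sample_peptides_from_motif <- function(motif, n, seed = 1L) {
  anchor_res <- apply(motif$weights, 1, function(row) {
    AA_ALPHABET[which.max(row)]
  })
  strong <- apply(motif$weights, 1, max) >= 5
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      res <- sample_vec(AA_ALPHABET, motif$length, replace = TRUE)
      res[strong] <- anchor_res[strong]
      paste(res, collapse = "")
    }, character(1))
  })
}
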