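# HLA nomenclature: parsing, normalisation and rendering of 2-field allele names.

HLA_CLASS_I_LOCI  <- c("A", "B", "C")
HLA_CLASS_II_LOCI <- c("DRB1", "DRB3", "DRB4", "DRB5", "DQB1", "DPB1")
HLA_LOCI <- c(HLA_CLASS_I_LOCI, HLA_CLASS_II_LOCI)

#' HLA class of a locus
#'
#' @param locus Character vector of locus names (e.g. `"A"`, `"DRB1"`).
#' @return `"I"` or `"II"` per element.
#' @export
hla_class_of <- function(locus) {
  bad <- setdiff(unique(locus), HLA_LOCI)
  if (length(bad) > 0) {
    stop("unknown HLA locus: ", paste(bad, collapse = ", "))
  }
  ifelse(locus %in% HLA_CLASS_II_LOCI, "II", "I")
}

#' Parse HLA allele names
#'
#' Parses allele names in standard nomenclature (e.g. `"HLA-A*02:01"`) into
#' locus, allele group (field 1) and specific protein (field 2). Parsing is
#' case-insensitive, the `"HLA-"` prefix is optional, and names given at
#' higher than 2-field resolution (e.g. `"B*51:01:02"`) are truncated to
#' 2 fields, the resolution at which all matching in this package is done.
#'
#' @param text Character vector of allele names.
#' @return A data.frame with columns `locus`, `field1`, `field2`, `hla_class`
#'   and `allele` (the normalised `"HLA-A*02:01"` rendering).
#' @examples
#' parse_hla(c("HLA-A*02:01", "hla-b*51:01:02", "DPB1*04:01"))
#' @export
parse_hla <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 0) {
    return(data.frame(locus = character(), field1 = integer(),
                      field2 = integer(), hla_class = character(),
                      allele = character(), stringsAsFactors = FALSE))
  }
  txt <- toupper(trimws(text))
  txt <- sub("^HLA-", "", txt)
  # locus*group:protein[:synonymous[:noncoding]][expression suffix]
  rx <- "^([A-Z][A-Z0-9]*)\\*([0-9]+):([0-9]+)(:[0-9]+)*[A-Z]?$"
  ok <- grepl(rx, txt)
  if (!all(ok)) {
    stop("malformed HLA allele name(s): ",
         paste(sQuote(text[!ok]), collapse = ", "))
  }
  locus <- sub(rx, "\\1", txt)
  bad <- setdiff(unique(locus), HLA_LOCI)
  if (length(bad) > 0) {
    stop("unknown HLA locus in allele name(s): ", paste(bad, collapse = ", "))
  }
  field1 <- as.integer(sub(rx, "\\2", txt))
  field2 <- as.integer(sub(rx, "\\3", txt))
  data.frame(locus = locus, field1 = field1, field2 = field2,
             hla_class = hla_class_of(locus),
             allele = sprintf("HLA-%s*%02d:%02d", locus, field1, field2),
             stringsAsFactors = FALSE)
}

#' Render HLA alleles in standard 2-field nomenclature
#'
#' @param locus Locus names, or the data.frame returned by [parse_hla()].
#' @param field1,field2 Integer allele-group and protein fields (ignored when
#'   `locus` is a data.frame).
#' @return Character vector of `"HLA-A*02:01"`-style names.
#' @export
format_hla <- function(locus, field1 = NULL, field2 = NULL) {
  if (is.data.frame(locus)) {
    field1 <- locus$field1
    field2 <- locus$field2
    locus <- locus$locus
  }
  sprintf("HLA-%s*%02d:%02d", locus, as.integer(field1), as.integer(field2))
}

#' Normalise HLA allele names to the canonical 2-field form
#'
#' @param text Character vector of allele names in any accepted spelling.
#' @return Character vector of normalised `"HLA-A*02:01"` names.
#' @export
normalize_hla <- function(text) {
  out <- rep(NA_character_, length(text))
  has <- !is.na(text) & nzchar(trimws(text))
  if (any(has)) out[has] <- parse_hla(text[has])$allele
  out
}
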