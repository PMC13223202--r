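#' Amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in the order used by
#' PAML-style rate-matrix files (A R N D C Q E G H I L K M F P S T W Y V).
#' All rate matrices, frequency vectors, and posterior matrices in this
#' package index states in this order.
#'
#' @format A character vector of length 20.
#' @export
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## legal residue characters in sequence input; '-' gap, 'X' unknown
.aa_legal <- c(AA_CODES, "-", "X")

#' Encode residue characters as state indices
#'
#' Maps one-letter codes to integer states 1..20 in [AA_CODES] order.
#' Gaps ('-') and unknowns ('X') encode as NA and are treated as missing
#' data by every likelihood computation.
#'
#' @param chars character vector of single residue letters.
#' @return integer vector with NA for gap/unknown.
#' @keywords internal
aa_encode <- function(chars) {
  idx <- match(toupper(chars), AA_CODES)
  idx
}

## validate a residue string; returns the offending position or 0L
.first_illegal <- function(residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% .aa_legal))
  if (length(bad)) bad[1] else 0L
}

.check_residues <- function(residues, id) {
  for (i in seq_along(residues)) {
    p <- .first_illegal(residues[i])
    if (p > 0L) {
      ch <- substr(residues[i], p, p)
      stop(sprintf("illegal residue character '%s' at position %d in sequence '%s'",
                   ch, p, id[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
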