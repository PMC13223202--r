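#' Construct a protein alignment
#'
#' An `aa_alignment` stores equal-length gapped protein sequences as a
#' character matrix (one row per sequence, one column per alignment
#' column). Sequence ids must be unique, residues are uppercased, and the
#' legal characters are the 20 one-letter amino-acid codes plus '-' (gap)
#' and 'X' (unknown; treated as missing data downstream).
#'
#' @param seqs named character vector of aligned sequences (names are ids),
#'   or a character matrix of single residues with rownames.
#' @param drop_gap_only_columns drop columns that are gaps in every
#'   sequence (default TRUE); the stored alignment never contains such
#'   columns.
#' @return an object of class `aa_alignment`: a list with elements `ids`
#'   (character) and `mat` (character matrix, rows = sequences).
#' @export
aa_alignment <- function(seqs, drop_gap_only_columns = TRUE) {
  if (is.matrix(seqs)) {
    mat <- seqs
    ids <- rownames(mat)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named", call. = FALSE)
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("aligned sequences must have identical length", call. = FALSE)
    .check_residues(seqs, ids)
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- ids
  }
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (length(ids) < 2L)
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  if (drop_gap_only_columns && ncol(mat) > 0L) {
    allgap <- colSums(mat != "-") == 0L
    if (any(allgap)) mat <- mat[, !allgap, drop = FALSE]
  }
  if (ncol(mat) < 1L) stop("alignment has no columns", call. = FALSE)
  colnames(mat) <- NULL
  structure(list(ids = ids, mat = mat), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d sequences x %d columns\n",
              n_seq(x), n_col(x)))
  show <- utils::head(x$ids, 6)
  for (id in show) {
    s <- paste(x$mat[id, seq_len(min(50, n_col(x)))], collapse = "")
    cat(sprintf("  %-12s %s%s\n", id, s, if (n_col(x) > 50) "..." else ""))
  }
  if (n_seq(x) > 6) cat(sprintf("  ... and %d more\n", n_seq(x) - 6))
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param aln an `aa_alignment`.
#' @return integer count.
#' @export
n_seq <- function(aln) length(aln$ids)

#' @rdname n_seq
#' @export
n_col <- function(aln) ncol(aln$mat)

#' Extract aligned sequences as strings
#' @param x an `aa_alignment`.
#' @param ... unused.
#' @return named character vector of gapped sequence strings.
#' @export
as.character.aa_alignment <- function(x, ...) {
  out <- apply(x$mat, 1, paste, collapse = "")
  names(out) <- x$ids
  out
}

#' Alignment-column / residue-number maps
#'
#' For one sequence of an alignment, builds the bidirectional map between
#' 1-based alignment columns and 1-based ungapped residue indices. Gap
#' columns have no residue index. This bookkeeping underlies statements
#' that translate a position in one protein into the numbering of another
#' (for instance an ancestral-residue position into human-enzyme
#' numbering).
#'
#' @param aln an `aa_alignment`.
#' @param id sequence id.
#' @return list with `col_to_res` (integer vector over columns, NA at
#'   gaps) and `res_to_col` (integer vector over residues).
#' @export
residue_number_map <- function(aln, id) {
  if (!(id %in% aln$ids)) stop("unknown sequence id: ", id, call. = FALSE)
  row <- aln$mat[id, ]
  nongap <- row != "-"
  col_to_res <- rep(NA_integer_, length(row))
  col_to_res[nongap] <- seq_len(sum(nongap))
  res_to_col <- which(nongap)
  list(col_to_res = col_to_res, res_to_col = res_to_col)
}

#' Translate a residue position to its alignment column
#' @param aln an `aa_alignment`.
#' @param id sequence id.
#' @param pos 1-based ungapped residue position(s) in that sequence.
#' @return 1-based alignment column(s).
#' @export
residue_to_column <- function(aln, id, pos) {
  m <- residue_number_map(aln, id)
  if (any(pos < 1L | pos > length(m$res_to_col)))
    stop("residue position out of range for ", id, call. = FALSE)
  m$res_to_col[pos]
}

#' Translate an alignment column to a residue position
#' @param aln an `aa_alignment`.
#' @param id sequence id.
#' @param col 1-based alignment column(s).
#' @return 1-based residue position(s); NA where the sequence is gapped.
#' @export
column_to_residue <- function(aln, id, col) {
  m <- residue_number_map(aln, id)
  if (any(col < 1L | col > length(m$col_to_res)))
    stop("column out of range", call. = FALSE)
  m$col_to_res[col]
}

## integer-encoded alignment: nseq x ncol matrix of states 1..20, NA missing
encode_alignment <- function(aln) {
  enc <- matrix(aa_encode(aln$mat), nrow = n_seq(aln))
  rownames(enc) <- aln$ids
  enc
}
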