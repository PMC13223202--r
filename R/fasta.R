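#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; ids are the
#' first whitespace-delimited token of each header, residues are
#' uppercased and validated against the amino-acid alphabet (plus '-'
#' and 'X').
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  .check_residues(seqs, ids)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector (or an `aa_alignment`).
#' @param path output path.
#' @param width residues per line (default 60).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (inherits(seqs, "aa_alignment")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  con <- file(path, open = "wb")  # LF line endings on every platform
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
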