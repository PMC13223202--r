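#' Read a PHYLIP interleaved protein alignment
#'
#' Reads the "relaxed-strict" interleaved dialect written by common
#' aligners (and by [write_phylip_interleaved()]): a header line with the
#' number of taxa and columns, a first block whose lines start with a
#' name in a 10-character field followed by sequence text, and further
#' blocks (separated by blank lines) of sequence text only, in the same
#' taxon order. Whitespace inside sequence text is ignored.
#'
#' @param path path to the PHYLIP file.
#' @return an [aa_alignment].
#' @export
read_phylip_interleaved <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty PHYLIP file: ", path, call. = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr))
    stop("PHYLIP header must hold two integers (ntaxa ncol)", call. = FALSE)
  ntax <- hdr[1]; ncols <- hdr[2]
  body <- lines[-1]
  body <- body[cumsum(nzchar(trimws(body))) > 0]   # skip leading blanks
  nonblank <- which(nzchar(trimws(body)))
  if (length(nonblank) < ntax)
    stop(sprintf("PHYLIP header declares %d taxa but only %d sequence lines found",
                 ntax, length(nonblank)), call. = FALSE)

  ## first block: names in the leading 10-char field
  first <- body[nonblank[seq_len(ntax)]]
  ids <- character(ntax); seqs <- character(ntax)
  for (i in seq_len(ntax)) {
    ln <- first[i]
    nm <- trimws(substr(ln, 1, 10))
    rest <- substr(ln, 11, nchar(ln))
    if (!nzchar(nm)) {
      ## tolerate names longer than 10 chars separated by whitespace
      parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      nm <- parts[1]; rest <- paste(parts[-1], collapse = "")
    }
    ids[i] <- nm
    seqs[i] <- gsub("[[:space:]]", "", rest)
  }
  if (anyDuplicated(ids))
    stop("duplicate taxon names after 10-character field parsing: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  ## remaining blocks: sequence text only, taxa in the same order
  extra <- nonblank[-seq_len(ntax)]
  if (length(extra) %% ntax != 0L)
    stop("interleaved block size does not match the declared taxon count", call. = FALSE)
  k <- 0L
  for (j in extra) {
    i <- (k %% ntax) + 1L
    seqs[i] <- paste0(seqs[i], gsub("[[:space:]]", "", body[j]))
    k <- k + 1L
  }
  lens <- nchar(seqs)
  if (any(lens != ncols))
    stop(sprintf("sequence lengths (%s) do not match the declared %d columns",
                 paste(unique(lens), collapse = ","), ncols), call. = FALSE)
  names(seqs) <- ids
  aa_alignment(seqs, drop_gap_only_columns = FALSE)
}

#' Write a PHYLIP interleaved protein alignment
#'
#' Emits the dialect read by [read_phylip_interleaved()]: names
#' left-justified in a 10-character field, sequence text in blocks of 60
#' columns, a blank line between blocks, LF line endings.
#'
#' @param aln an [aa_alignment].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_phylip_interleaved <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  short <- substr(aln$ids, 1, 10)
  if (anyDuplicated(short))
    stop("taxon names collide after truncation to 10 characters: ",
         paste(unique(short[duplicated(short)]), collapse = ", "), call. = FALSE)
  seqs <- as.character(aln)
  nc <- n_col(aln)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", n_seq(aln), nc), con)
  starts <- seq(1, nc, by = 60)
  for (b in seq_along(starts)) {
    from <- starts[b]; to <- min(from + 59, nc)
    chunk <- substring(seqs, from, to)
    if (b == 1L) {
      writeLines(sprintf("%-10s%s", short, chunk), con)
    } else {
      writeLines(chunk, con)
    }
    if (b < length(starts)) writeLines("", con)
  }
  invisible(path)
}
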