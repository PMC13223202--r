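#' Percent identity between two aligned sequences
#'
#' `100 * identical co-non-gap pairs / co-non-gap columns`. Columns
#' where either sequence is gapped are excluded from the denominator;
#' 'X' never counts as identical (even against another 'X').
#'
#' @param seqA,seqB aligned residue strings of equal length.
#' @return percent identity in [0, 100].
#' @export
percent_identity <- function(seqA, seqB) {
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)", call. = FALSE)
  ok <- a != "-" & b != "-"
  if (!any(ok)) stop("no co-non-gap columns", call. = FALSE)
  100 * sum(a[ok] == b[ok] & a[ok] != "X") / sum(ok)
}

#' Pairwise percent-identity matrix
#'
#' All-pairs [percent_identity()] over an alignment; the diagonal is
#' exactly 100.
#'
#' @param aln an [aa_alignment].
#' @return object of class `identity_matrix` (a symmetric numeric
#'   matrix with the alignment ids as dimnames).
#' @export
identity_matrix <- function(aln) {
  n <- n_seq(aln)
  seqs <- as.character(aln)
  M <- matrix(100, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    M[i, j] <- M[j, i] <- percent_identity(seqs[i], seqs[j])
  structure(M, class = c("identity_matrix", "matrix"))
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("Percent identity matrix\n")
  print(round(unclass(x), 1))
  invisible(x)
}

#' Per-column conservation profile
#'
#' For each alignment column: residue frequencies over non-gap
#' characters, the consensus residue and its fraction, and the
#' information content in bits, `IC = log2(20) - H` where `H` is the
#' Shannon entropy of the frequency vector (no small-sample correction).
#' This is the matrix behind a sequence logo. All-gap columns get IC 0
#' and consensus '-'.
#'
#' @param aln an [aa_alignment].
#' @return object of class `conservation_profile`: list with `freq`
#'   (ncol x 20 matrix), `consensus`, `fraction`, `ic_bits`.
#' @export
conservation_profile <- function(aln) {
  enc <- encode_alignment(aln)
  nc <- n_col(aln)
  freq <- matrix(0, nc, 20, dimnames = list(NULL, AA_CODES))
  consensus <- character(nc); fraction <- numeric(nc); ic <- numeric(nc)
  for (s in seq_len(nc)) {
    cnt <- tabulate(enc[, s][!is.na(enc[, s])], nbins = 20)
    tot <- sum(cnt)
    if (tot == 0) {
      consensus[s] <- "-"
      next
    }
    f <- cnt / tot
    freq[s, ] <- f
    top <- which(f >= max(f) - 1e-12)
    consensus[s] <- sort(AA_CODES[top])[1]
    fraction[s] <- max(f)
    pos <- f > 0
    ic[s] <- max(0, log2(20) + sum(f[pos] * log2(f[pos])))
  }
  structure(list(freq = freq, consensus = consensus, fraction = fraction,
                 ic_bits = ic),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("conservation_profile: %d columns, mean IC %.3f bits\n",
              length(x$ic_bits), mean(x$ic_bits)))
  invisible(x)
}

#' Clade-specific conservation of one reference position
#'
#' Percentage of clade sequences whose residue at the alignment column
#' of a reference residue equals that reference residue — the style of
#' statement "position H291 is 86% conserved among KT3Ks". By default
#' only clade sequences that are non-gap at the column enter the
#' denominator; `count_gaps_as_mismatch` switches to counting them as
#' mismatches.
#'
#' @param aln an [aa_alignment].
#' @param clade_ids ids of the clade members.
#' @param reference_id id of the reference sequence.
#' @param reference_position 1-based ungapped residue position in the
#'   reference sequence.
#' @param count_gaps_as_mismatch see above (default FALSE).
#' @return list with `percent`, `percent_rounded` (half-up to integer),
#'   `column`, `residue`, `n_matching`, `n_counted`.
#' @export
clade_conservation <- function(aln, clade_ids, reference_id, reference_position,
                               count_gaps_as_mismatch = FALSE) {
  stopifnot(all(clade_ids %in% aln$ids))
  col <- residue_to_column(aln, reference_id, reference_position)
  ref <- aln$mat[reference_id, col]
  if (ref == "-")
    stop("reference position is gapped in the reference sequence", call. = FALSE)
  obs <- aln$mat[clade_ids, col]
  if (count_gaps_as_mismatch) {
    n_counted <- length(obs)
  } else {
    obs <- obs[obs != "-"]
    n_counted <- length(obs)
  }
  if (n_counted == 0) stop("no clade sequence covers the column", call. = FALSE)
  n_match <- sum(obs == ref)
  pct <- 100 * n_match / n_counted
  list(percent = pct, percent_rounded = floor(pct + 0.5), column = col,
       residue = ref, n_matching = n_match, n_counted = n_counted)
}

#' Divergent positions between two aligned sequences
#'
#' Lists every column where two sequences both have residues and those
#' residues differ — e.g. the 12 positions separating a pre- and
#' post-duplication ancestor — with each sequence's own residue
#' numbering and, optionally, the numbering of a third reference
#' sequence (e.g. the human orthologue), enabling statements such as
#' "ancestral position 253 corresponds to human 244".
#'
#' @param aln an [aa_alignment].
#' @param idA,idB sequence ids to compare.
#' @param reference_id optional third id supplying a translated
#'   numbering column.
#' @return object of class `divergence_report`: data frame with
#'   `column`, `residueA`, `residueB`, `posA`, `posB`, and `posRef`/
#'   `residueRef` when a reference is given. Zero rows when identical.
#' @export
divergent_positions <- function(aln, idA, idB, reference_id = NULL) {
  for (id in c(idA, idB, reference_id))
    if (!(id %in% aln$ids)) stop("unknown sequence id: ", id, call. = FALSE)
  a <- aln$mat[idA, ]; b <- aln$mat[idB, ]
  sel <- which(a != "-" & b != "-" & a != b)
  mA <- residue_number_map(aln, idA)$col_to_res
  mB <- residue_number_map(aln, idB)$col_to_res
  out <- data.frame(column = sel, residueA = a[sel], residueB = b[sel],
                    posA = mA[sel], posB = mB[sel], stringsAsFactors = FALSE)
  if (!is.null(reference_id)) {
    mR <- residue_number_map(aln, reference_id)$col_to_res
    out$residueRef <- aln$mat[reference_id, sel]
    out$posRef <- mR[sel]
  }
  rownames(out) <- NULL
  class(out) <- c("divergence_report", "data.frame")
  out
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("divergence_report: %d differing co-non-gap positions\n", nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Write conservation outputs as TSV
#'
#' @param x an `identity_matrix`, `conservation_profile`, or
#'   `divergence_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_conservation_tsv <- function(x, path) {
  if (inherits(x, "identity_matrix")) {
    df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  } else if (inherits(x, "conservation_profile")) {
    df <- data.frame(column = seq_along(x$ic_bits), x$freq,
                     consensus = x$consensus, fraction = x$fraction,
                     IC_bits = x$ic_bits, check.names = FALSE)
  } else if (inherits(x, "divergence_report")) {
    df <- as.data.frame(x)
  } else stop("unsupported object", call. = FALSE)
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
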