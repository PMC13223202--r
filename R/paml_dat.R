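#' Read a PAML-style exchangeability file
#'
#' PAML-style `.dat` files carry an empirical reversible amino-acid model
#' as the 190 lower-triangular exchangeabilities (rows 2..20 of the
#' symmetric matrix, amino acids in A R N D C Q E G H I L K M F P S T W Y
#' V order) followed by 20 equilibrium frequencies. Any further content
#' (comments, references) is ignored.
#'
#' @param path path to the `.dat` file.
#' @return list with `S` (20x20 symmetric exchangeability matrix, zero
#'   diagonal, dimnames = [AA_CODES]) and `pi` (frequencies, renormalised
#'   to sum exactly 1; the file's values must sum to 1 within 1e-4).
#' @export
read_exchangeability_dat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  vals <- suppressWarnings(as.numeric(toks))
  ## keep the leading run of numeric tokens (trailing prose is common)
  if (anyNA(vals)) {
    stopn <- which(is.na(vals))[1] - 1L
    vals <- vals[seq_len(stopn)]
  }
  if (length(vals) < 210)
    stop(sprintf("expected 190 exchangeabilities + 20 frequencies, found %d numbers",
                 length(vals)), call. = FALSE)
  vals <- vals[seq_len(210)]
  ex <- vals[1:190]; fr <- vals[191:210]
  if (any(ex < 0)) stop("negative exchangeability entry", call. = FALSE)
  if (any(fr < 0)) stop("negative frequency entry", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-4)
    stop(sprintf("frequencies sum to %.6f, outside 1 +/- 1e-4", sum(fr)),
         call. = FALSE)
  S <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- S[j, i] <- ex[k]
    k <- k + 1L
  }
  pi <- fr / sum(fr)
  names(pi) <- AA_CODES
  list(S = S, pi = pi)
}

#' Write a PAML-style exchangeability file
#'
#' Inverse of [read_exchangeability_dat()]; useful for exporting built-in
#' matrices or simulation models for other tools.
#'
#' @param S symmetric 20x20 exchangeability matrix.
#' @param pi equilibrium frequencies (length 20).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_exchangeability_dat <- function(S, pi, path) {
  stopifnot(is.matrix(S), all(dim(S) == 20), length(pi) == 20)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in 2:20)
    writeLines(paste(formatC(S[i, 1:(i - 1)], format = "g", digits = 10),
                     collapse = " "), con)
  writeLines("", con)
  writeLines(paste(formatC(pi, format = "g", digits = 10), collapse = " "), con)
  invisible(path)
}

#' Built-in empirical amino-acid exchangeabilities
#'
#' Returns the exchangeability matrix and equilibrium frequencies of a
#' named empirical model, taken from the model library shipped with
#' \pkg{phangorn} and reordered to [AA_CODES] order. Additional matrices
#' (for instance Q.plant) can be supplied as PAML-style files via
#' [read_exchangeability_dat()].
#'
#' @param name one of "LG", "WAG", "JTT", "Dayhoff".
#' @return list with `S` and `pi` as in [read_exchangeability_dat()].
#' @export
aa_exchangeabilities <- function(name = c("LG", "WAG", "JTT", "Dayhoff")) {
  name <- match.arg(name)
  obj <- get(paste0(".", name), envir = asNamespace("phangorn"))
  ord <- toupper(names(obj$bf))
  if (is.null(ord) || !setequal(ord, AA_CODES))
    stop("unexpected amino-acid ordering in model library", call. = FALSE)
  perm <- match(AA_CODES, ord)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- obj$Q
  S <- S + t(S)
  S <- S[perm, perm]
  dimnames(S) <- list(AA_CODES, AA_CODES)
  pi <- as.numeric(obj$bf)[perm]
  pi <- pi / sum(pi)
  names(pi) <- AA_CODES
  list(S = S, pi = pi)
}
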