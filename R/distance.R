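#' Maximum-likelihood pairwise distance
#'
#' Estimates the evolutionary distance between two aligned sequences by
#' maximising the pairwise likelihood
#' `sum_sites ln sum_c w_c pi_a P_ab(t r_c)` over t in [1e-6, 10]
#' (bounded Brent search). Sites where either residue is a gap or 'X'
#' are skipped. The site-pair count matrix is symmetrised so the
#' distance is exactly symmetric in its arguments.
#'
#' @param seqA,seqB aligned residue strings of equal length.
#' @param model an [aa_model].
#' @return the ML distance (substitutions/site).
#' @export
ml_pairwise_distance <- function(seqA, seqB, model) {
  a <- aa_encode(strsplit(toupper(seqA), "")[[1]])
  b <- aa_encode(strsplit(toupper(seqB), "")[[1]])
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no comparable (co-non-gap) sites", call. = FALSE)
  N <- matrix(0, 20, 20)
  tab <- table(factor(a[ok], levels = 1:20), factor(b[ok], levels = 1:20))
  N[] <- as.numeric(tab)
  N <- (N + t(N)) / 2                     # exact symmetry in (seqA, seqB)
  Q <- build_rate_matrix(model$S, model$pi)
  eig <- .q_eigen(Q, model$pi)
  cats <- rate_categories(model)
  nz <- N > 0
  f <- function(t) {
    M <- matrix(0, 20, 20)
    for (c in seq_along(cats$rates)) {
      r <- cats$rates[c]
      P <- if (t * r == 0) diag(20) else {
        Pc <- eig$V %*% (exp(eig$lambda * (t * r)) * eig$Vi)
        Pc[Pc < 0] <- 0
        Pc
      }
      M <- M + cats$weights[c] * (model$pi * P)
    }
    if (any(M[nz] <= 0)) return(-Inf)
    sum(N[nz] * log(M[nz]))
  }
  opt <- stats::optimize(f, c(1e-6, 10), maximum = TRUE, tol = 1e-8)
  ## the boundary can beat the interior optimum for identical sequences
  if (f(1e-6) >= opt$objective) return(1e-6)
  opt$maximum
}

#' ML distance matrix for an alignment
#'
#' All pairwise [ml_pairwise_distance()] values; entries are capped at
#' 10 substitutions/site.
#'
#' @param aln an [aa_alignment].
#' @param model an [aa_model].
#' @return symmetric numeric matrix with the alignment ids as dimnames.
#' @export
ml_distance_matrix <- function(aln, model) {
  n <- n_seq(aln)
  if (n < 3) stop("need at least 3 sequences for a distance matrix", call. = FALSE)
  seqs <- as.character(aln)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- min(ml_pairwise_distance(seqs[i], seqs[j], model), 10)
    D[i, j] <- D[j, i] <- d
  }
  D
}
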