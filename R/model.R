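#' Specify a reversible amino-acid substitution model
#'
#' Combines an exchangeability matrix and equilibrium frequencies with
#' among-site rate-variation parameters: a discrete-gamma shape `alpha`
#' (`+G`, NA for none), an invariant-site proportion `p_inv` (`+I`), and
#' the gamma category count `k`.
#'
#' @param matrix name of a built-in matrix (see [aa_exchangeabilities()])
#'   or a list with elements `S` and `pi` (e.g. from
#'   [read_exchangeability_dat()]).
#' @param alpha gamma shape (> 0), or NA for no rate heterogeneity.
#' @param p_inv invariant-site proportion in [0, 1).
#' @param k number of gamma categories (default 4; ignored when `alpha`
#'   is NA).
#' @param pi optional replacement frequencies (e.g. observed alignment
#'   frequencies for a `+F` variant); must be positive and sum to 1.
#' @param name label used in printouts and model-selection tables.
#' @return object of class `aa_model`: list with `S`, `pi`, `alpha`,
#'   `p_inv`, `k`, `name`, `freq_mode`.
#' @export
aa_model <- function(matrix = "LG", alpha = NA, p_inv = 0, k = 4,
                     pi = NULL, name = NULL) {
  if (is.character(matrix)) {
    base <- aa_exchangeabilities(matrix)
    if (is.null(name)) name <- matrix
  } else {
    base <- matrix
    if (is.null(name)) name <- "custom"
  }
  stopifnot(is.matrix(base$S), all(dim(base$S) == 20), length(base$pi) == 20)
  if (max(abs(base$S - t(base$S))) > 1e-12)
    stop("exchangeability matrix must be symmetric", call. = FALSE)
  freq_mode <- "model"
  if (!is.null(pi)) {
    stopifnot(length(pi) == 20)
    if (any(pi <= 0)) stop("frequencies must be positive", call. = FALSE)
    base$pi <- pi / sum(pi)
    freq_mode <- "observed"
  }
  if (any(base$pi <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (!is.na(alpha) && alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)", call. = FALSE)
  structure(list(S = base$S,
                 pi = stats::setNames(as.numeric(base$pi) / sum(base$pi), AA_CODES),
                 alpha = alpha, p_inv = p_inv, k = as.integer(k),
                 name = name, freq_mode = freq_mode),
            class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  tag <- x$name
  if (!is.na(x$alpha)) tag <- paste0(tag, "+G", x$k)
  if (x$p_inv > 0) tag <- paste0(tag, "+I")
  if (x$freq_mode == "observed") tag <- paste0(tag, "+F")
  cat(sprintf("aa_model: %s", tag))
  if (!is.na(x$alpha)) cat(sprintf(", alpha = %.4g", x$alpha))
  if (x$p_inv > 0) cat(sprintf(", p_inv = %.4g", x$p_inv))
  cat("\n")
  invisible(x)
}

#' Build the normalised rate matrix Q
#'
#' Constructs the general time-reversible rate matrix from
#' exchangeabilities and frequencies: `q_ij = S_ij * pi_j` off the
#' diagonal, diagonal set so rows sum to zero, then the whole matrix is
#' rescaled so the mean substitution rate `-sum_i pi_i q_ii` equals 1
#' (branch lengths are expected substitutions per site). Detailed
#' balance `pi_i q_ij = pi_j q_ji` holds by construction.
#'
#' @param S symmetric exchangeability matrix with zero (ignored) diagonal.
#' @param pi positive equilibrium frequencies summing to 1.
#' @return 20x20 rate matrix Q.
#' @export
build_rate_matrix <- function(S, pi) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), length(pi) == nrow(S))
  if (any(pi <= 0)) stop("pi must be strictly positive", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-12) stop("S must be symmetric", call. = FALSE)
  n <- nrow(S)
  Q <- S * rep(pi, each = n)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (all exchangeabilities zero?)", call. = FALSE)
  Q <- Q / mu
  dimnames(Q) <- dimnames(S)
  Q
}

## symmetrized eigendecomposition of Q; P(t) = V %*% diag(exp(lambda t)) %*% Vi
## B = D^{1/2} Q D^{-1/2} is symmetric for a reversible Q (D = diag(pi))
.q_eigen <- function(Q, pi) {
  rpi <- sqrt(pi)
  B <- Q * (rpi %o% (1 / rpi))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(lambda = e$values,
       V = e$vectors / rpi,          # row-scaled: diag(1/rpi) %*% U
       Vi = t(e$vectors * rpi))      # t(diag(rpi) %*% U)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed through the symmetrised eigendecomposition of the reversible
#' rate matrix (similarity transform with diag(sqrt(pi))), which keeps
#' the computation exact and stable. Tiny negative entries arising from
#' round-off are clamped to 0 and rows renormalised to sum to 1.
#'
#' @param Q rate matrix from [build_rate_matrix()].
#' @param pi equilibrium frequencies used to build `Q`.
#' @param t branch length (>= 0), expected substitutions per site.
#' @param eig optional cached result of the internal eigendecomposition.
#' @return stochastic matrix P(t).
#' @export
transition_matrix <- function(Q, pi, t, eig = NULL) {
  if (t < 0) stop("branch length must be >= 0", call. = FALSE)
  if (is.null(eig)) eig <- .q_eigen(Q, pi)
  P <- eig$V %*% (exp(eig$lambda * t) * eig$Vi)
  if (any(!is.finite(P))) stop("non-finite transition probabilities", call. = FALSE)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Discrete-gamma rate categories
#'
#' Discretises gamma(alpha, rate = alpha) rate variation into `k`
#' equal-probability categories, each represented by the mean of the
#' distribution within its inter-quantile slab (the category-mean
#' convention). The rates are renormalised so the mixture mean is
#' exactly 1.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return object of class `rate_categories`: list with `rates` and
#'   `weights`.
#' @export
discrete_gamma_rates <- function(alpha, k = 4) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k == 1L) {
    return(structure(list(rates = 1, weights = 1), class = "rate_categories"))
  }
  ## mean of gamma(a, rate=a) over quantile slab [q_{i-1}, q_i]:
  ## k * (pgamma(q_i, a+1, a) - pgamma(q_{i-1}, a+1, a))  (mean-value identity)
  qb <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  pb <- stats::pgamma(qb, shape = alpha + 1, rate = alpha)
  rates <- k * diff(pb)
  rates <- rates / sum(rates / k)    # mixture mean exactly 1
  structure(list(rates = rates, weights = rep(1 / k, k)),
            class = "rate_categories")
}

#' Add an invariant-site category
#'
#' Mixes a rate-0 category of weight `p_inv` into an existing set of rate
#' categories; the remaining weights are scaled by `1 - p_inv` and the
#' rates divided by `1 - p_inv`, so the overall mean rate stays 1.
#'
#' @param p_inv invariant proportion in [0, 1).
#' @param cats a `rate_categories` object.
#' @return a `rate_categories` object (first category is the invariant
#'   one when `p_inv > 0`).
#' @export
apply_invariant <- function(p_inv, cats) {
  stopifnot(inherits(cats, "rate_categories"))
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)", call. = FALSE)
  if (p_inv == 0) return(cats)
  structure(list(rates = c(0, cats$rates / (1 - p_inv)),
                 weights = c(p_inv, cats$weights * (1 - p_inv))),
            class = "rate_categories")
}

## rate categories implied by an aa_model
rate_categories <- function(model) {
  cats <- if (is.na(model$alpha)) {
    structure(list(rates = 1, weights = 1), class = "rate_categories")
  } else {
    discrete_gamma_rates(model$alpha, model$k)
  }
  apply_invariant(model$p_inv, cats)
}

#' Akaike Information Criterion
#'
#' @param lnL log-likelihood (nats).
#' @param nparams number of free parameters (>= 1).
#' @return `2 * nparams - 2 * lnL`.
#' @export
aic <- function(lnL, nparams) {
  if (!is.finite(lnL)) stop("lnL must be finite", call. = FALSE)
  if (nparams < 1) stop("nparams must be >= 1", call. = FALSE)
  2 * nparams - 2 * lnL
}

#' Observed amino-acid frequencies of an alignment
#'
#' Relative frequencies of the 20 amino acids over all non-gap, non-'X'
#' characters (no pseudocount); used for `+F` model variants.
#'
#' @param aln an [aa_alignment].
#' @return numeric vector of length 20 (names = [AA_CODES]).
#' @export
observed_frequencies <- function(aln) {
  enc <- encode_alignment(aln)
  cnt <- tabulate(enc[!is.na(enc)], nbins = 20)
  if (sum(cnt) == 0) stop("alignment has no amino-acid characters", call. = FALSE)
  out <- cnt / sum(cnt)
  names(out) <- AA_CODES
  out
}
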