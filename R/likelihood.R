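## Likelihood kernel: Felsenstein pruning over site patterns with per-node
## scaling, a discrete-rate mixture (+G/+I), and the inside-outside pass
## shared by branch-length optimization and marginal ancestral
## reconstruction. Everything downstream (treeinfer, ancestor, model
## selection) goes through .lik_prep / .inside_pass / .outside_pass.


## fast column maxima of a numeric matrix (max.col is C-level)
.colmax <- function(M) {
  i <- max.col(t(M), ties.method = "first")
  M[cbind(i, seq_len(ncol(M)))]
}

## compress alignment columns into unique site patterns
.compress_patterns <- function(enc) {
  key <- apply(enc, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- enc[, first, drop = FALSE]
  idx <- match(key, key[first])
  w <- tabulate(idx, nbins = sum(first))
  list(pat = pat, w = w, index = idx)
}

## shared preprocessing for one (tree, alignment, model) triple
.lik_prep <- function(tree, aln, model) {
  .check_blens(tree)
  .check_labels(tree, aln)
  tr <- stats::reorder(tree, "postorder")
  enc <- encode_alignment(aln)[tr$tip.label, , drop = FALSE]
  cp <- .compress_patterns(enc)
  Q <- build_rate_matrix(model$S, model$pi)
  cats <- rate_categories(model)
  list(tree = tr, ntip = length(tr$tip.label), nnode = tr$Nnode,
       root = length(tr$tip.label) + 1L,
       edge = tr$edge, blen = tr$edge.length,
       pat = cp$pat, w = cp$w, index = cp$index, npat = length(cp$w),
       pi = model$pi, eig = .q_eigen(Q, model$pi),
       rates = cats$rates, weights = cats$weights, model = model)
}

## transition matrix for category rate r at branch length t (identity at 0)
.pmat <- function(prep, t, r) {
  if (t * r == 0) return(diag(20))
  P <- prep$eig$V %*% (exp(prep$eig$lambda * (t * r)) * prep$eig$Vi)
  P[P < 0] <- 0
  P
}

## contribution of a tip with pattern states s through branch matrix P
.tip_contrib <- function(P, s) {
  na <- is.na(s)
  if (any(na)) s[na] <- 1L
  M <- P[, s, drop = FALSE]
  if (any(na)) M[, na] <- 1
  M
}

## inside (post-order) pass; returns per category the partials at every
## internal node with cumulative per-pattern log scaling factors
.inside_pass <- function(prep, blen = prep$blen) {
  ntip <- prep$ntip; nn <- ntip + prep$nnode
  k <- length(prep$rates)
  ins <- vector("list", k); logsc <- vector("list", k)
  for (c in seq_len(k)) {
    part <- vector("list", nn)
    lsc <- matrix(0, nrow = nn, ncol = prep$npat)
    Pe <- lapply(seq_len(nrow(prep$edge)), function(e)
      .pmat(prep, blen[e], prep$rates[c]))
    for (v in unique(prep$edge[, 1])) {       # postorder: children first
      kids <- which(prep$edge[, 1] == v)
      M <- matrix(1, 20, prep$npat)
      sc <- numeric(prep$npat)
      for (e in kids) {
        ch <- prep$edge[e, 2]
        if (ch <= ntip) {
          M <- M * .tip_contrib(Pe[[e]], prep$pat[ch, ])
        } else {
          M <- M * (Pe[[e]] %*% part[[ch]])
          sc <- sc + lsc[ch, ]
        }
      }
      mx <- .colmax(M)
      mx[mx <= 0] <- 1                         # impossible pattern: keep zeros
      M <- M / rep(mx, each = 20)
      part[[v]] <- M
      lsc[v, ] <- sc + log(mx)
    }
    ins[[c]] <- part; logsc[[c]] <- lsc
  }
  list(part = ins, logsc = logsc)
}

## per-pattern log-likelihood for one category from the root partial
.cat_site_loglik <- function(prep, inside, c) {
  rootp <- inside$part[[c]][[prep$root]]
  sl <- colSums(prep$pi * rootp)
  out <- rep(-Inf, prep$npat)
  pos <- sl > 0
  out[pos] <- log(sl[pos]) + inside$logsc[[c]][prep$root, pos]
  out
}

## mixture per-pattern log-likelihood (logsumexp over categories)
.site_loglik <- function(prep, inside = .inside_pass(prep)) {
  k <- length(prep$rates)
  L <- vapply(seq_len(k), function(c)
    log(prep$weights[c]) + .cat_site_loglik(prep, inside, c),
    numeric(prep$npat))
  L <- matrix(L, nrow = prep$npat)
  mx <- L[, 1]
  for (c in seq_len(ncol(L))[-1]) mx <- pmax(mx, L[, c])
  res <- mx + log(rowSums(exp(L - mx)))
  res[!is.finite(mx)] <- -Inf
  res
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of an alignment on a tree under a
#' reversible amino-acid model with a discrete rate mixture. Gaps and
#' 'X' characters are missing data (all-ones tip vectors); per-node
#' scaling guards against underflow; site patterns are compressed before
#' the pruning pass.
#'
#' @param tree "phylo" object with branch lengths; tips must match the
#'   alignment ids.
#' @param alignment an [aa_alignment].
#' @param model an [aa_model].
#' @param per_site also return the per-column log-likelihood vector.
#' @return object of class `likelihood_result`: list with `lnL`,
#'   `nparams` (branch lengths + shape/p_inv/+F frequencies), and
#'   optionally `per_site_lnL`.
#' @export
log_likelihood <- function(tree, alignment, model, per_site = FALSE) {
  prep <- .lik_prep(tree, alignment, model)
  sll <- .site_loglik(prep)
  lnL <- sum(prep$w * sll)
  np <- nrow(prep$edge) + (!is.na(model$alpha)) + (model$p_inv > 0) +
    if (model$freq_mode == "observed") 19L else 0L
  out <- list(lnL = lnL, nparams = np)
  if (per_site) out$per_site_lnL <- sll[prep$index]
  structure(out, class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("log-likelihood: %.6f  (free parameters: %d)\n", x$lnL, x$nparams))
  invisible(x)
}

## outside (pre-order) pass. For each internal node v and category c:
## out[[c]][[v]] (20 x npat) with log-scalers outsc[c][v,], such that
## inside*outside*exp(scalers) is the joint mass of data and state at v.
## Also returns, for every edge e = (u,v), the "rest of tree" profile
## G[[c]][[e]] at u excluding v's subtree (with log-scaler gsc), used for
## single-edge likelihood curves.
.outside_pass <- function(prep, inside, blen = prep$blen) {
  ntip <- prep$ntip; nn <- ntip + prep$nnode
  k <- length(prep$rates)
  out <- vector("list", k); outsc <- vector("list", k)
  G <- vector("list", k); gsc <- vector("list", k)
  parent_edge <- integer(nn)
  parent_edge[prep$edge[, 2]] <- seq_len(nrow(prep$edge))
  preorder_edges <- rev(seq_len(nrow(prep$edge)))   # postorder reversed
  for (c in seq_len(k)) {
    Pe <- lapply(seq_len(nrow(prep$edge)), function(e)
      .pmat(prep, blen[e], prep$rates[c]))
    ## child contributions C_e = P_e %*% inside(child) (scaled), log-scaler
    Ce <- vector("list", nrow(prep$edge))
    csc <- numeric(nrow(prep$edge))
    for (e in seq_len(nrow(prep$edge))) {
      ch <- prep$edge[e, 2]
      if (ch <= ntip) {
        Ce[[e]] <- .tip_contrib(Pe[[e]], prep$pat[ch, ])
        csc[e] <- 0
      } else {
        Ce[[e]] <- Pe[[e]] %*% inside$part[[c]][[ch]]
      }
    }
    cscv <- lapply(seq_len(nrow(prep$edge)), function(e) {
      ch <- prep$edge[e, 2]
      if (ch <= ntip) numeric(prep$npat) else inside$logsc[[c]][ch, ]
    })
    o <- vector("list", nn); osc <- matrix(0, nn, prep$npat)
    o[[prep$root]] <- matrix(prep$pi, 20, prep$npat)
    g <- vector("list", nrow(prep$edge)); gs <- matrix(0, nrow(prep$edge), prep$npat)
    for (e in preorder_edges) {
      u <- prep$edge[e, 1]; v <- prep$edge[e, 2]
      sibs <- setdiff(which(prep$edge[, 1] == u), e)
      M <- o[[u]]
      sc <- osc[u, ]
      for (s in sibs) {
        M <- M * Ce[[s]]
        sc <- sc + cscv[[s]]
      }
      mx <- .colmax(M); mx[mx <= 0] <- 1
      M <- M / rep(mx, each = 20); sc <- sc + log(mx)
      g[[e]] <- M; gs[e, ] <- sc
      if (v > ntip) {
        o[[v]] <- crossprod(Pe[[e]], M)
        osc[v, ] <- sc
      }
    }
    out[[c]] <- o; outsc[[c]] <- osc; G[[c]] <- g; gsc[[c]] <- gs
  }
  list(out = out, outsc = outsc, G = G, gsc = gsc)
}

## log-likelihood as a function of a single edge length t, using cached
## edge profiles (inside of the child side, rest-of-tree profile G)
.edge_loglik <- function(prep, inside, outside, e, t) {
  ch <- prep$edge[e, 2]
  k <- length(prep$rates)
  L <- matrix(-Inf, prep$npat, k)
  for (c in seq_len(k)) {
    P <- .pmat(prep, t, prep$rates[c])
    F1 <- if (ch <= prep$ntip) NULL else inside$part[[c]][[ch]]
    if (is.null(F1)) {
      M <- .tip_contrib(P, prep$pat[ch, ])
      sl <- colSums(M * outside$G[[c]][[e]])
      sc <- outside$gsc[[c]][e, ]
    } else {
      sl <- colSums(F1 * crossprod(P, outside$G[[c]][[e]]))
      sc <- outside$gsc[[c]][e, ] + inside$logsc[[c]][ch, ]
    }
    pos <- sl > 0
    L[pos, c] <- log(prep$weights[c]) + log(sl[pos]) + sc[pos]
  }
  mx <- L[, 1]
  for (c in seq_len(ncol(L))[-1]) mx <- pmax(mx, L[, c])
  sll <- mx + log(rowSums(exp(L - mx)))
  sll[!is.finite(mx)] <- -Inf
  sum(prep$w * sll)
}
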