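#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou–Nei neighbour joining via [ape::nj()], with negative
#' branch lengths clamped to 0. Used as the start tree for the ML
#' search; on additive distances it reconstructs the generating topology
#' and branch lengths exactly.
#'
#' @param D symmetric distance matrix with labels as dimnames.
#' @return an unrooted "phylo" tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D))
  if (nrow(D) < 3) stop("need at least 3 labels", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric", call. = FALSE)
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## canonical bipartition keys for the internal edges of an unrooted tree:
## the smaller tip-label side (the side containing the alphabetically
## first label on ties), sorted and joined with "|"
.bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge)))
    below[[tr$edge[e, 1]]] <- c(below[[tr$edge[e, 1]]], below[[tr$edge[e, 2]]])
  all_tips <- sort(tree$tip.label)
  keys <- character(0); edges <- integer(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip) next
    side <- sort(below[[ch]])
    other <- setdiff(all_tips, side)
    if (length(side) < 2 || length(other) < 2) next
    if (length(side) > length(other) ||
        (length(side) == length(other) && !(all_tips[1] %in% side)))
      side <- other
    keys <- c(keys, paste(side, collapse = "|"))
    edges <- c(edges, e)
  }
  list(keys = keys, edges = edges, tree = tr)
}

#' Optimise branch lengths on a fixed topology
#'
#' Round-robin single-branch optimisation: each branch in turn is
#' optimised by bounded Brent search (bounds [1e-8, 10], tolerance 1e-8)
#' of the exact single-edge likelihood curve obtained from cached
#' inside/outside partials; sweeps repeat until the log-likelihood gain
#' falls below `tol` or `max_sweeps` is reached. The log-likelihood is
#' non-decreasing across sweeps.
#'
#' @param tree "phylo" with branch lengths (start values).
#' @param alignment an [aa_alignment].
#' @param model an [aa_model].
#' @param max_sweeps maximum rounds over all branches (default 50).
#' @param tol stop when a full sweep improves lnL by less than this
#'   (default 1e-6).
#' @return list with `tree` (optimised lengths, postorder) and
#'   `result` (a `likelihood_result`).
#' @export
optimize_branch_lengths <- function(tree, alignment, model,
                                    max_sweeps = 50, tol = 1e-6) {
  prep <- .lik_prep(tree, alignment, model)
  blen <- prep$blen
  lnL <- sum(prep$w * .site_loglik(prep, .inside_pass(prep, blen)))
  for (sweep in seq_len(max_sweeps)) {
    lnL_prev <- lnL
    for (e in seq_len(nrow(prep$edge))) {
      ins <- .inside_pass(prep, blen)
      outs <- .outside_pass(prep, ins, blen)
      opt <- stats::optimize(function(t) .edge_loglik(prep, ins, outs, e, t),
                             c(1e-8, 10), maximum = TRUE, tol = 1e-8)
      if (opt$objective >= lnL) {
        blen[e] <- opt$maximum
        lnL <- opt$objective
      }
    }
    if (lnL - lnL_prev < tol) break
  }
  tr <- prep$tree
  tr$edge.length <- blen
  np <- nrow(prep$edge) + (!is.na(model$alpha)) + (model$p_inv > 0) +
    if (model$freq_mode == "observed") 19L else 0L
  list(tree = tr,
       result = structure(list(lnL = lnL, nparams = np), class = "likelihood_result"))
}

#' Nearest-neighbour-interchange search
#'
#' Hill-climbing topology search: every NNI neighbour of the current
#' (binary, unrooted) tree is evaluated with full branch-length
#' re-optimisation; the single best improving move is accepted and the
#' search repeats until no move improves the log-likelihood by more than
#' `tol`. Neighbour enumeration is deterministic, so the search is
#' reproducible.
#'
#' @param tree binary tree with branch lengths.
#' @param alignment an [aa_alignment].
#' @param model an [aa_model].
#' @param max_iter maximum accepted moves (default 20).
#' @param tol minimum lnL improvement to accept a move (default 1e-6).
#' @param sweeps branch-length sweeps when scoring each candidate
#'   (default 3; the accepted tree is re-optimised fully).
#' @return list with `tree`, `result` (a `likelihood_result`), and
#'   `n_moves` (accepted NNI moves).
#' @export
nni_search <- function(tree, alignment, model, max_iter = 20, tol = 1e-6,
                       sweeps = 3) {
  if (!ape::is.binary(ape::unroot(tree)))
    stop("NNI search needs a binary tree", call. = FALSE)
  cur <- optimize_branch_lengths(tree, alignment, model)
  n_moves <- 0L
  for (it in seq_len(max_iter)) {
    nbrs <- phangorn::nni(cur$tree)
    best <- NULL; best_lnL <- cur$result$lnL + tol
    for (i in seq_along(nbrs)) {
      nb <- nbrs[[i]]       # [[ restores shared tip labels of a multiPhylo
      ## carry over current lengths where edges persist; init new edges at 0.1
      nb$edge.length[!is.finite(nb$edge.length) | nb$edge.length < 0] <- 0.1
      cand <- optimize_branch_lengths(nb, alignment, model, max_sweeps = sweeps)
      if (cand$result$lnL > best_lnL) {
        best <- cand; best_lnL <- cand$result$lnL
      }
    }
    if (is.null(best)) break
    cur <- optimize_branch_lengths(best$tree, alignment, model)
    n_moves <- n_moves + 1L
  }
  list(tree = cur$tree, result = cur$result, n_moves = n_moves)
}

#' Nonparametric bootstrap support
#'
#' Resamples alignment columns with replacement, re-infers a tree for
#' each replicate (ML distances + neighbour joining, with optional NNI
#' refinement), and reports for each internal edge of the input tree the
#' fraction of replicates containing the same bipartition. All
#' resampling indices are drawn up front from `seed`, so a given seed is
#' bit-reproducible regardless of replicate count batching.
#'
#' Replicates reuse the model's point estimates (shape, invariant
#' fraction) from the full data rather than re-estimating them.
#'
#' @param alignment an [aa_alignment].
#' @param model an [aa_model].
#' @param tree the reference tree whose internal edges receive support.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param nni also refine each replicate tree by NNI (default FALSE;
#'   replicate branch lengths are then optimised too, which cannot
#'   change bipartition counts on their own and is otherwise skipped).
#' @return object of class `bootstrap_result`: list with `support`
#'   (named fraction per bipartition key), `tree` (input tree with
#'   `$support` on internal nodes), `n_replicates`, `seed`.
#' @export
bootstrap_support <- function(alignment, model, tree, n_replicates = 500,
                              seed = 1, nni = FALSE) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  nc <- n_col(alignment)
  idx <- matrix(sample.int(nc, nc * n_replicates, replace = TRUE),
                nrow = n_replicates)
  ref <- .bipartitions(tree)
  counts <- setNames(numeric(length(ref$keys)), ref$keys)
  for (r in seq_len(n_replicates)) {
    sub <- aa_alignment(alignment$mat[, idx[r, ], drop = FALSE],
                        drop_gap_only_columns = FALSE)
    D <- ml_distance_matrix(sub, model)
    btr <- neighbor_joining(D)
    if (nni) btr <- nni_search(btr, sub, model)$tree
    keys <- .bipartitions(btr)$keys
    hit <- ref$keys %in% keys
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / n_replicates
  ## annotate the input tree: support value on the child node of each edge
  tr <- ref$tree
  sup_nodes <- rep(NA_real_, tr$Nnode)
  for (i in seq_along(ref$edges)) {
    ch <- tr$edge[ref$edges[i], 2]
    sup_nodes[ch - length(tr$tip.label)] <- support[i]
  }
  tr$support <- sup_nodes
  structure(list(support = support, tree = tr,
                 n_replicates = n_replicates, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d replicates (seed %d)\n",
              x$n_replicates, x$seed))
  for (i in seq_along(x$support))
    cat(sprintf("  %-50s %.3f\n", names(x$support)[i], x$support[i]))
  invisible(x)
}
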