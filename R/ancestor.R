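#' PAML-style node labels
#'
#' Assigns the deterministic integer ids used by PAML to address
#' ancestors: tips are numbered 1..n in their order of appearance in the
#' tree's Newick serialisation, internal nodes n+1..2n-1 in preorder
#' from the stored root. The labelling is stable across re-parses of the
#' same Newick text.
#'
#' @param tree a "phylo" object.
#' @return object of class `node_labeling`: list with `paml` (integer
#'   vector indexed by the tree's internal node numbers), `ape`
#'   (inverse map, indexed by PAML id), and `table` (data frame: id,
#'   type, label, child ids, tip set).
#' @export
label_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "cladewise")
  root <- ntip + 1L
  ## appearance order in Newick text = cladewise traversal order
  tip_seq <- tr$edge[tr$edge[, 2] <= ntip, 2]
  int_seq <- c(root, tr$edge[tr$edge[, 2] > ntip, 2])
  paml <- integer(ntip + tree$Nnode)
  paml[tip_seq] <- seq_len(ntip)
  paml[int_seq] <- ntip + seq_along(int_seq)
  ape_of <- order(paml)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- .tips_below(tree)
  tab <- data.frame(
    id = paml,
    type = ifelse(seq_along(paml) <= ntip, "tip", "internal"),
    label = c(tree$tip.label, rep("", tree$Nnode)),
    children = vapply(seq_along(paml), function(v) {
      ch <- kids[[as.character(v)]]
      if (is.null(ch)) "" else paste(sort(paml[ch]), collapse = ",")
    }, ""),
    tips = vapply(seq_along(paml), function(v)
      paste(sort(below[[v]]), collapse = ","), ""),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$id), ]
  rownames(tab) <- NULL
  structure(list(paml = paml, ape = ape_of, table = tab), class = "node_labeling")
}

#' @export
print.node_labeling <- function(x, ...) {
  print(x$table)
  invisible(x)
}

## tip labels below each node
.tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge)))
    below[[tr$edge[e, 1]]] <- c(below[[tr$edge[e, 1]]], below[[tr$edge[e, 2]]])
  below
}

#' Find an ancestor node by its descendant tips
#'
#' Integer node ids depend on taxon ordering and rooting, so ancestors
#' are more robustly addressed as the most recent common ancestor of a
#' set of tips; this returns that node's PAML-style id.
#'
#' @param tree a "phylo" object.
#' @param tips character vector of (at least two) tip labels.
#' @return the PAML-style id of the MRCA.
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(length(tips) >= 2, all(tips %in% tree$tip.label))
  v <- ape::getMRCA(tree, tips)
  label_nodes(tree)$paml[v]
}

#' Marginal ancestral posteriors at every internal node
#'
#' Empirical-Bayes marginal reconstruction: for each internal node and
#' alignment column, the posterior distribution over the 20 amino acids
#' given all tip data, computed by the inside-outside decomposition at
#' that node and mixed over rate categories by each category's posterior
#' mass for the site. The result is invariant to where the (reversible)
#' tree is rooted.
#'
#' @param tree "phylo" with branch lengths.
#' @param alignment an [aa_alignment].
#' @param model an [aa_model].
#' @return named list (by PAML node id, as "node<N>") of
#'   `ancestral_posterior` objects: each has `node` (PAML id),
#'   `probs` (ncol x 20 matrix), `map` (MAP residue per column, ties
#'   broken alphabetically), `max_pp` (max posterior per column).
#' @export
marginal_posteriors <- function(tree, alignment, model) {
  prep <- .lik_prep(tree, alignment, model)
  ins <- .inside_pass(prep)
  outs <- .outside_pass(prep, ins)
  lab <- label_nodes(prep$tree)
  k <- length(prep$rates)
  internal <- prep$ntip + seq_len(prep$nnode)
  res <- list()
  for (v in internal) {
    ## log joint mass of (state at v, data) per category, then softmax
    J <- array(-Inf, dim = c(20, prep$npat, k))
    for (c in seq_len(k)) {
      M <- ins$part[[c]][[v]] * outs$out[[c]][[v]]
      sc <- ins$logsc[[c]][v, ] + outs$outsc[[c]][v, ]
      pos <- M > 0
      lM <- matrix(-Inf, 20, prep$npat)
      lM[pos] <- log(M[pos])
      J[, , c] <- lM + rep(sc, each = 20) + log(prep$weights[c])
    }
    mx <- apply(J, 2, max)
    post <- matrix(0, 20, prep$npat)
    for (c in seq_len(k)) post <- post + exp(J[, , c] - rep(mx, each = 20))
    post <- post / rep(colSums(post), each = 20)
    probs <- t(post[, prep$index, drop = FALSE])
    colnames(probs) <- AA_CODES
    map <- apply(probs, 1, function(p) {
      cand <- AA_CODES[p >= max(p) - 1e-12]
      sort(cand)[1]
    })
    res[[paste0("node", lab$paml[v])]] <- structure(
      list(node = lab$paml[v], probs = probs, map = map,
           max_pp = apply(probs, 1, max)),
      class = "ancestral_posterior")
  }
  res[order(vapply(res, `[[`, 1L, "node"))]
}

#' @export
print.ancestral_posterior <- function(x, ...) {
  cat(sprintf("ancestral_posterior: node %d, %d columns, mean max-PP %.4f\n",
              x$node, length(x$map), mean(x$max_pp)))
  invisible(x)
}

#' Ancestral gap states by Fitch parsimony
#'
#' The likelihood treats gaps as missing data, so indel history is
#' reconstructed separately: each column's presence/absence pattern
#' (non-gap = present) is run through Fitch small parsimony, with ties
#' at the root resolved to presence and the downward pass preferring the
#' parent's state. Deterministic by construction.
#'
#' @param tree "phylo" object.
#' @param alignment an [aa_alignment].
#' @return logical matrix (internal nodes x columns, rownames
#'   "node<PAML id>"); TRUE where the ancestral residue is present.
#' @export
reconstruct_gap_states <- function(tree, alignment) {
  .check_labels(tree, alignment)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  lab <- label_nodes(tr)
  nc <- n_col(alignment)
  present <- alignment$mat[tr$tip.label, , drop = FALSE] != "-"
  ## state sets coded 1 = {absent}, 2 = {present}, 3 = {absent, present}
  sets <- matrix(0L, ntip + tr$Nnode, nc)
  sets[seq_len(ntip), ] <- ifelse(present, 2L, 1L)
  for (v in unique(tr$edge[, 1])) {
    kids <- tr$edge[tr$edge[, 1] == v, 2]
    inter <- rep(3L, nc); uni <- rep(0L, nc)
    for (ch in kids) {
      inter <- bitwAnd(inter, sets[ch, ])
      uni <- bitwOr(uni, sets[ch, ])
    }
    sets[v, ] <- ifelse(inter > 0L, inter, uni)
  }
  root <- ntip + 1L
  state <- matrix(FALSE, tr$Nnode, nc)
  rn <- paste0("node", lab$paml[ntip + seq_len(tr$Nnode)])
  rownames(state) <- rn
  ## root: presence on ties (set 3)
  state[root - ntip, ] <- sets[root, ] >= 2L
  for (e in rev(seq_len(nrow(tr$edge)))) {     # preorder
    ch <- tr$edge[e, 2]
    if (ch <= ntip) next
    par_state <- state[tr$edge[e, 1] - ntip, ]
    s <- sets[ch, ]
    state[ch - ntip, ] <- ifelse(s == 3L, par_state, s == 2L)
  }
  state
}

#' MAP ancestral sequence with posterior summary
#'
#' Combines a node's marginal posteriors with its reconstructed gap
#' states: the MAP residue at each present column ('-' where absent),
#' and the mean posterior probability (meanPP), i.e. the mean over
#' present columns of the maximum posterior.
#'
#' @param posteriors result of [marginal_posteriors()].
#' @param gap_states result of [reconstruct_gap_states()].
#' @param node PAML-style node id.
#' @return list with `id` ("node<N>"), `sequence` (gapped string), and
#'   `mean_pp`.
#' @export
extract_map_sequence <- function(posteriors, gap_states, node) {
  key <- paste0("node", node)
  if (!key %in% names(posteriors) || !key %in% rownames(gap_states))
    stop("unknown node id: ", node, call. = FALSE)
  p <- posteriors[[key]]
  pres <- gap_states[key, ]
  chars <- ifelse(pres, p$map, "-")
  list(id = key,
       sequence = paste(chars, collapse = ""),
       mean_pp = mean(p$max_pp[pres]))
}

#' Full marginal ancestral sequence reconstruction
#'
#' Runs [marginal_posteriors()] and [reconstruct_gap_states()] and
#' extracts the MAP sequence and meanPP for every internal node. This is
#' what `predict()` on a [phylo_ml] fit returns.
#'
#' @param tree "phylo" with branch lengths.
#' @param alignment an [aa_alignment].
#' @param model an [aa_model].
#' @return object of class `ancestral_reconstruction`: list with
#'   `labeling`, `posteriors`, `gap_states`, `sequences` (named
#'   character vector, ids "node<N>"), `mean_pp` (named numeric),
#'   `log_likelihood`.
#' @export
ancestral_reconstruction <- function(tree, alignment, model) {
  post <- marginal_posteriors(tree, alignment, model)
  gaps <- reconstruct_gap_states(tree, alignment)
  nodes <- vapply(post, `[[`, 1L, "node")
  maps <- lapply(nodes, function(v) extract_map_sequence(post, gaps, v))
  seqs <- vapply(maps, `[[`, "", "sequence")
  names(seqs) <- vapply(maps, `[[`, "", "id")
  mpp <- vapply(maps, `[[`, 0, "mean_pp")
  names(mpp) <- names(seqs)
  structure(list(labeling = label_nodes(tree), posteriors = post,
                 gap_states = gaps, sequences = seqs, mean_pp = mpp,
                 log_likelihood = log_likelihood(tree, alignment, model)$lnL),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("ancestral_reconstruction: %d internal nodes, lnL %.4f\n",
              length(x$sequences), x$log_likelihood))
  for (id in names(x$sequences))
    cat(sprintf("  %-8s meanPP %.4f\n", id, x$mean_pp[id]))
  invisible(x)
}

#' Write reconstruction outputs
#'
#' `write_ancestors_fasta()` writes one record per internal node
#' (ids "node<N>"); `write_posteriors_tsv()` writes the per-column
#' posteriors (node, column, 20 probabilities, MAP, maxPP; columns
#' 1-based); `write_node_table()` writes the node labelling table.
#'
#' @param asr an `ancestral_reconstruction`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ancestors_fasta <- function(asr, path) {
  write_fasta(asr$sequences, path)
}

#' @rdname write_ancestors_fasta
#' @export
write_posteriors_tsv <- function(asr, path) {
  rows <- lapply(asr$posteriors, function(p) {
    df <- as.data.frame(p$probs)
    data.frame(node = p$node, column = seq_along(p$map), df,
               MAP = p$map, maxPP = p$max_pp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(format(out, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ancestors_fasta
#' @export
write_node_table <- function(asr, path) {
  utils::write.table(asr$labeling$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
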