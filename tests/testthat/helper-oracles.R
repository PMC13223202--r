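## Independent oracles used across the suite. These deliberately avoid the
## package's own pruning / eigendecomposition / graph-search code paths:
## transition probabilities come from Matrix::expm, likelihoods from
## explicit enumeration over ancestral state assignments, path queries
## from exhaustive simple-path enumeration.

## random reversible model: symmetric exchangeabilities, dirichlet-ish pi
random_model <- function(seed, alpha = NA, p_inv = 0, k = 4) {
  set.seed(seed)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- stats::runif(190, 0.05, 2)
  S <- S + t(S)
  pi <- stats::rgamma(20, shape = 5)
  pi <- pi / sum(pi)
  aa_model(list(S = S, pi = pi), alpha = alpha, p_inv = p_inv, k = k,
           name = paste0("rand", seed))
}

## transition matrix by matrix exponential (independent of .q_eigen)
expm_pmat <- function(model, t, rate = 1) {
  Q <- build_rate_matrix(model$S, model$pi)
  as.matrix(Matrix::expm(Matrix::Matrix(Q * t * rate)))
}

## brute-force site likelihood: enumerate all ancestral state assignments
## over the internal nodes; edges to gap/X tips are dropped (their state
## sum telescopes to 1). Returns the per-site likelihood for one rate.
brute_site_lik_onerate <- function(tree, states_by_tip, model, rate) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  internals <- (ntip + 1):(ntip + tr$Nnode)
  Pe <- lapply(seq_len(nrow(tr$edge)), function(e)
    expm_pmat(model, tr$edge.length[e], rate))
  tip_state <- states_by_tip[tr$tip.label]
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  for (g in seq_len(nrow(grid))) {
    assign_state <- function(v) {
      if (v <= ntip) tip_state[[v]] else grid[g, match(v, internals)]
    }
    p <- unname(model$pi[grid[g, 1]])    # internals[1] is the root (ntip+1)
    for (e in seq_len(nrow(tr$edge))) {
      sv <- assign_state(tr$edge[e, 2])
      if (is.na(sv)) next                # missing tip: contributes 1
      p <- p * Pe[[e]][assign_state(tr$edge[e, 1]), sv]
    }
    total <- total + p
  }
  total
}

## brute-force mixture log-likelihood of a whole alignment
brute_log_lik <- function(tree, aln, model) {
  cats <- protasr:::rate_categories(model)
  enc <- protasr:::encode_alignment(aln)
  total <- 0
  for (s in seq_len(n_col(aln))) {
    st <- enc[, s]
    names(st) <- aln$ids
    L <- 0
    for (c in seq_along(cats$rates))
      L <- L + cats$weights[c] *
        brute_site_lik_onerate(tree, as.list(st), model, cats$rates[c])
    total <- total + log(L)
  }
  total
}

## brute-force marginal posterior at one internal node (PAML id) for one
## site: P(state | data) by enumeration, mixing rate categories by their
## posterior mass
brute_posterior <- function(tree, aln, model, paml_id, site) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  lab <- label_nodes(tr)
  v <- which(lab$paml == paml_id)
  internals <- (ntip + 1):(ntip + tr$Nnode)
  cats <- protasr:::rate_categories(model)
  enc <- protasr:::encode_alignment(aln)
  st <- enc[, site]; names(st) <- aln$ids
  tip_state <- as.list(st)[tr$tip.label]
  joint <- numeric(20)
  for (c in seq_along(cats$rates)) {
    Pe <- lapply(seq_len(nrow(tr$edge)), function(e)
      expm_pmat(model, tr$edge.length[e], cats$rates[c]))
    grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(u) {
        if (u <= ntip) tip_state[[u]] else grid[g, match(u, internals)]
      }
      p <- unname(model$pi[grid[g, 1]])
      for (e in seq_len(nrow(tr$edge))) {
        sv <- assign_state(tr$edge[e, 2])
        if (is.na(sv)) next
        p <- p * Pe[[e]][assign_state(tr$edge[e, 1]), sv]
      }
      a <- grid[g, match(v, internals)]
      joint[a] <- joint[a] + cats$weights[c] * p
    }
  }
  joint / sum(joint)
}

## mean of gamma(alpha, rate = alpha) within each inter-quantile slab, by
## direct numeric integration (independent of the pgamma identity)
gamma_category_means_integrate <- function(alpha, k) {
  qb <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  vapply(seq_len(k), function(i) {
    upper <- if (i == k) Inf else qb[i + 1]
    num <- stats::integrate(function(x) x * stats::dgamma(x, alpha, rate = alpha),
                            qb[i], upper, rel.tol = 1e-10)$value
    num * k
  }, 0)
}

## exhaustive simple-path enumeration on a residue_network-like edge list
all_simple_paths_brute <- function(edges, from, to) {
  adj <- list()
  adde <- function(a, b) adj[[a]] <<- c(adj[[a]], b)
  for (r in seq_len(nrow(edges))) {
    adde(edges$res_i[r], edges$res_j[r])
    adde(edges$res_j[r], edges$res_i[r])
  }
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (nb in adj[[last]]) if (!(nb %in% path)) walk(c(path, nb))
  }
  if (!is.null(adj[[from]])) walk(from)
  out
}

## best path by the package's stated metric, from the brute-force set:
## min hops, then max cumulative strength, then lexicographic
brute_best_path <- function(network, from, to) {
  paths <- all_simple_paths_brute(network$edges, from, to)
  if (!length(paths)) return(NULL)
  hops <- vapply(paths, length, 0L)
  paths <- paths[hops == min(hops)]
  st <- vapply(paths, function(p) protasr:::.path_strength(network, p), 0)
  paths <- paths[st >= max(st) - 1e-12]
  keys <- vapply(paths, function(p) paste(formatC(p, width = 10), collapse = ","), "")
  paths[[order(keys)[1]]]
}

## build a residue_network by hand from an edge data frame (res_i, res_j,
## strength), for graph-query tests that need no structure
make_network <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$res_i, edges$res_j)))
  nd <- data.frame(reskey = as.character(nodes),
                   resno = suppressWarnings(as.integer(nodes)),
                   resname = "ALA", n_atoms = 4L, stringsAsFactors = FALSE)
  edges$res_i <- as.character(edges$res_i)
  edges$res_j <- as.character(edges$res_j)
  if (is.null(edges$n_pairs)) edges$n_pairs <- 1L
  g <- igraph::graph_from_data_frame(edges[, c("res_i", "res_j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nd$reskey))
  if (nrow(edges)) igraph::E(g)$strength <- edges$strength
  structure(list(nodes = nd, edges = edges, graph = g,
                 atom_cutoff = 3, i_min = 0),
            class = "residue_network")
}

## random connected-ish sparse network on n nodes
random_network <- function(n, seed) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < min(1, 2.2 / n)
  ## guarantee a spanning path so most queries are connected
  spine <- cbind(1:(n - 1), 2:n)
  sel <- unique(rbind(pairs[keep, , drop = FALSE], spine))
  make_network(data.frame(res_i = sel[, 1], res_j = sel[, 2],
                          strength = round(stats::runif(nrow(sel), 1, 50), 3)))
}

## tiny helper: alignment from bare strings
make_aln <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("s", seq_along(seqs))
  aa_alignment(seqs, drop_gap_only_columns = FALSE)
}

## topology equality (unrooted Robinson-Foulds distance of zero)
expect_same_topology <- function(t1, t2) {
  testthat::expect_equal(
    as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0)
}

## rooting-independent identity of internal vertices: the sorted blocks of
## the tip partition induced by removing the vertex (children subtrees +
## complement). Degree-2 roots get a 2-block signature that matches no
## vertex of another rooting, so they are excluded from comparisons.
node_signatures <- function(tree) {
  ntip <- length(tree$tip.label)
  below <- protasr:::.tips_below(tree)
  all_tips <- sort(tree$tip.label)
  ids <- label_nodes(tree)$paml
  sig <- character(tree$Nnode)
  for (v in (ntip + 1):(ntip + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    blocks <- lapply(kids, function(ch) sort(below[[ch]]))
    comp <- setdiff(all_tips, sort(below[[v]]))
    if (length(comp)) blocks <- c(blocks, list(comp))
    keys <- sort(vapply(blocks, paste, "", collapse = ","))
    sig[v - ntip] <- paste(keys, collapse = " | ")
  }
  names(sig) <- paste0("node", ids[(ntip + 1):(ntip + tree$Nnode)])
  sig
}

## compare marginal posteriors of two rootings of the same tree; returns
## the maximum absolute difference over all matchable internal vertices
max_posterior_reroot_diff <- function(post_a, sig_a, post_b, sig_b) {
  shared <- intersect(sig_a, sig_b)
  stopifnot(length(shared) >= 1)
  mx <- 0
  for (s in shared) {
    a <- post_a[[names(sig_a)[sig_a == s]]]
    b <- post_b[[names(sig_b)[sig_b == s]]]
    mx <- max(mx, max(abs(a$probs - b$probs)))
  }
  mx
}
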