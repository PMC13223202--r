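## Structure-based contact and network analyses: ligand-binding residues,
## residue-residue contacts at a distance cutoff, protein structure
## networks (PSN), and constrained shortest communication paths.

## squared distances between two coordinate matrices (n x 3, m x 3)
.dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
}

## resolve residue selectors (numeric resno or character reskey) to the
## reskeys present in an atom table
.resolve_residues <- function(atoms, sel, what = "residue selector") {
  keys <- unique(atoms$reskey)
  out <- if (is.numeric(sel)) as.character(sel) else as.character(sel)
  miss <- setdiff(out, keys)
  if (length(miss))
    stop(what, " does not resolve: ", paste(miss, collapse = ", "), call. = FALSE)
  out
}

#' Ligand-contacting residues
#'
#' Protein residues with any heavy atom within `cutoff` of any heavy
#' atom of the named ligand group — the analysis that identifies the
#' substrate-binding pocket (e.g. the nine DMF-contacting residues of
#' a fructosamine kinase). Backbone atoms are included, so purely
#' backbone-mediated contacts (a glycine, say) are reported too.
#'
#' @param structure an `aa_structure` from [read_pdb()].
#' @param ligand_name HETATM residue name (e.g. "DMF", "ATP").
#' @param cutoff heavy-atom distance cutoff in Å (default 4.0).
#' @param chain protein chain to scan (default: first protein chain).
#' @return object of class `contact_set`: data frame with `chain`,
#'   `resno`, `insert`, `reskey`, `resname`, `min_dist`, sorted by
#'   residue number.
#' @export
ligand_contacts <- function(structure, ligand_name, cutoff = 4.0, chain = NULL) {
  stopifnot(cutoff > 0)
  lig <- structure$atoms[structure$atoms$het &
                           structure$atoms$resid == ligand_name, , drop = FALSE]
  if (nrow(lig) == 0)
    stop("ligand '", ligand_name, "' absent from structure", call. = FALSE)
  prot <- .protein_residues(structure, chain)
  L <- as.matrix(lig[, c("x", "y", "z")])
  rows <- list()
  for (key in unique(prot$reskey)) {
    sub <- prot[prot$reskey == key, , drop = FALSE]
    d <- sqrt(max(0, min(.dist2(as.matrix(sub[, c("x", "y", "z")]), L))))
    if (d <= cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = sub$chain[1], resno = sub$resno[1], insert = sub$insert[1],
        reskey = key, resname = sub$resid[1], min_dist = d,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), insert = character(),
               reskey = character(), resname = character(),
               min_dist = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ligand") <- ligand_name
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_set", "data.frame")
  out
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set: %d residues within %.2f Å of %s\n",
              nrow(x), attr(x, "cutoff"), attr(x, "ligand")))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Residue-residue contact pairs
#'
#' All pairs (a in `setA`, b in `setB`, a != b) whose minimum heavy-atom
#' distance is at most `cutoff` (default 6.0 Å), with the minimum
#' distance per pair.
#'
#' @param structure an `aa_structure`.
#' @param setA,setB residue selectors: numeric residue numbers or
#'   character residue keys (number + insertion code).
#' @param cutoff distance cutoff in Å (default 6.0).
#' @param chain protein chain (default: first protein chain).
#' @return data frame with `resA`, `resB`, `min_dist`.
#' @export
residue_contact_pairs <- function(structure, setA, setB, cutoff = 6.0,
                                  chain = NULL) {
  stopifnot(cutoff > 0)
  prot <- .protein_residues(structure, chain)
  A <- .resolve_residues(prot, setA, "setA")
  B <- .resolve_residues(prot, setB, "setB")
  coords <- lapply(split(seq_len(nrow(prot)), prot$reskey), function(i)
    as.matrix(prot[i, c("x", "y", "z")]))
  rows <- list()
  for (a in A) for (b in B) {
    if (a == b) next
    d <- sqrt(max(0, min(.dist2(coords[[a]], coords[[b]]))))
    if (d <= cutoff)
      rows[[length(rows) + 1L]] <- data.frame(resA = a, resB = b, min_dist = d,
                                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resA = character(), resB = character(), min_dist = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a protein structure network
#'
#' Residues are nodes; an edge joins residues i and j when side-chain
#' heavy atoms (plus C-alpha for glycine) approach within `atom_cutoff`.
#' The interaction strength is `I_ij = 100 * n_ij / sqrt(N_i * N_j)`,
#' where `n_ij` counts atom pairs within the cutoff and `N_i` is the
#' residue's node atom count (an override table of per-residue-name
#' normalisation factors can be supplied). Edges are kept when
#' `I_ij > i_min`; sequence neighbours (|i - j| <= 1 within the chain)
#' are excluded.
#'
#' @param structure an `aa_structure`.
#' @param atom_cutoff atom-pair distance cutoff in Å (default 3.0).
#' @param i_min minimum interaction strength for an edge (default 0).
#' @param chain protein chain (default: first protein chain).
#' @param norm optional named numeric vector of normalisation atom
#'   counts per residue name (e.g. `c(GLY = 1, ALA = 2, ...)`),
#'   overriding the structure-derived counts.
#' @return object of class `residue_network`: list with `nodes` (data
#'   frame: reskey, resno, resname, n_atoms), `edges` (data frame:
#'   res_i, res_j, n_pairs, strength), `graph` (an \pkg{igraph} graph
#'   with `strength` edge attribute), `atom_cutoff`, `i_min`.
#' @export
build_psn <- function(structure, atom_cutoff = 3.0, i_min = 0, chain = NULL,
                      norm = NULL) {
  stopifnot(atom_cutoff > 0, i_min >= 0)
  prot <- .protein_residues(structure, chain)
  backbone <- c("N", "CA", "C", "O", "OXT")
  side <- prot[!(prot$elety %in% backbone) |
                 (prot$resid == "GLY" & prot$elety == "CA"), , drop = FALSE]
  keys <- unique(prot$reskey)
  info <- prot[!duplicated(prot$reskey), c("reskey", "resno", "resid")]
  side <- side[side$reskey %in% keys, , drop = FALSE]
  counts <- table(side$reskey)
  nodes <- data.frame(reskey = info$reskey, resno = info$resno,
                      resname = info$resid,
                      n_atoms = as.integer(counts[info$reskey]),
                      stringsAsFactors = FALSE)
  nodes$n_atoms[is.na(nodes$n_atoms)] <- 0L
  Nnorm <- nodes$n_atoms
  if (!is.null(norm)) {
    hit <- nodes$resname %in% names(norm)
    Nnorm[hit] <- as.numeric(norm[nodes$resname[hit]])
  }
  names(Nnorm) <- nodes$reskey
  coords <- lapply(split(seq_len(nrow(side)), side$reskey), function(i)
    as.matrix(side[i, c("x", "y", "z")]))
  rows <- list()
  nk <- nodes$reskey
  for (ii in seq_len(nrow(nodes) - 1)) for (jj in (ii + 1):nrow(nodes)) {
    if (abs(nodes$resno[ii] - nodes$resno[jj]) <= 1) next
    ci <- coords[[nk[ii]]]; cj <- coords[[nk[jj]]]
    if (is.null(ci) || is.null(cj)) next
    npair <- sum(.dist2(ci, cj) <= atom_cutoff^2 + 1e-9)
    if (npair == 0) next
    I <- 100 * npair / sqrt(Nnorm[nk[ii]] * Nnorm[nk[jj]])
    if (I > i_min)
      rows[[length(rows) + 1L]] <- data.frame(
        res_i = nk[ii], res_j = nk[jj], n_pairs = npair, strength = as.numeric(I),
        stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(res_i = character(), res_j = character(),
               n_pairs = integer(), strength = numeric(), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("res_i", "res_j")], directed = FALSE,
    vertices = data.frame(name = nodes$reskey))
  if (nrow(edges)) igraph::E(g)$strength <- edges$strength
  structure(list(nodes = nodes, edges = edges, graph = g,
                 atom_cutoff = atom_cutoff, i_min = i_min),
            class = "residue_network")
}

#' @export
print.residue_network <- function(x, ...) {
  cat(sprintf("residue_network: %d nodes, %d edges (cutoff %.2f Å, Imin %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$atom_cutoff, x$i_min))
  invisible(x)
}

## rank key for deterministic path ordering: hop count, then -strength,
## then lexicographic residue-number sequence
.path_strength <- function(network, path) {
  if (length(path) < 2) return(0)
  s <- 0
  for (i in seq_len(length(path) - 1)) {
    hit <- (network$edges$res_i == path[i] & network$edges$res_j == path[i + 1]) |
      (network$edges$res_j == path[i] & network$edges$res_i == path[i + 1])
    s <- s + network$edges$strength[hit][1]
  }
  s
}

.path_lex_key <- function(path)
  paste(formatC(path, width = 10, flag = " "), collapse = ",")

## all minimum-hop paths between two vertices (list of reskey vectors)
.shortest_paths_between <- function(network, from, to) {
  if (from == to) return(list(from))
  res <- suppressWarnings(
    igraph::all_shortest_paths(network$graph, from = from, to = to))
  lapply(res$vpaths, function(p) igraph::V(network$graph)$name[as.integer(p)])
}

## pick the best path from a candidate list: max strength, then lexicographic
.best_path <- function(network, paths) {
  if (!length(paths)) return(NULL)
  st <- vapply(paths, function(p) .path_strength(network, p), 0)
  keep <- which(st >= max(st) - 1e-12)
  paths <- paths[keep]
  paths[[order(vapply(paths, .path_lex_key, ""))[1]]]
}

#' Shortest communication pathways
#'
#' Finds, for every source-target pair, the shortest communication path
#' in a residue network (minimum hop count, ties broken by maximum
#' cumulative interaction strength, remaining ties lexicographically by
#' residue key). When `via` residues are given, the search is
#' constrained: for each via residue, the shortest source-to-via and
#' via-to-target legs are concatenated; concatenations that revisit a
#' node are discarded. Disconnected pairs are reported with a warning
#' and contribute no path.
#'
#' @param network a `residue_network`.
#' @param sources,targets residue selectors (residue numbers or keys).
#' @param via optional constraint residues the path must pass through.
#' @return object of class `path_set`: list with `paths` (list of
#'   residue-key vectors), `strengths`, `sources`, `targets`, `via`.
#' @export
communication_paths <- function(network, sources, targets, via = NULL) {
  stopifnot(length(sources) >= 1, length(targets) >= 1)
  nodes <- network$nodes
  srcs <- .resolve_residues(nodes, sources, "sources")
  tgts <- .resolve_residues(nodes, targets, "targets")
  vias <- if (is.null(via)) NULL else {
    v <- as.character(via)
    absent <- setdiff(v, nodes$reskey)
    if (length(absent)) {
      warning("via residues absent from network: ",
              paste(absent, collapse = ", "))
      v <- setdiff(v, absent)
    }
    v
  }
  if (!is.null(via) && !length(vias))
    return(structure(list(paths = list(), strengths = numeric(),
                          sources = srcs, targets = tgts, via = character()),
                     class = "path_set"))
  paths <- list()
  for (s in srcs) for (t in tgts) {
    if (s == t) next
    if (is.null(vias)) {
      best <- .best_path(network, .shortest_paths_between(network, s, t))
      if (is.null(best)) {
        warning("no path between ", s, " and ", t)
      } else paths[[length(paths) + 1L]] <- best
    } else {
      for (v in vias) {
        legs1 <- if (s == v) list(v) else .shortest_paths_between(network, s, v)
        legs2 <- if (v == t) list(v) else .shortest_paths_between(network, v, t)
        if (!length(legs1) || !length(legs2)) {
          warning("no path ", s, " -> ", v, " -> ", t)
          next
        }
        cands <- list()
        for (l1 in legs1) for (l2 in legs2) {
          p <- c(l1, l2[-1])
          if (!anyDuplicated(p)) cands[[length(cands) + 1L]] <- p
        }
        if (!length(cands)) next
        hops <- vapply(cands, length, 0L)
        best <- .best_path(network, cands[hops == min(hops)])
        if (!is.null(best)) paths[[length(paths) + 1L]] <- best
      }
    }
  }
  ## de-duplicate, deterministic lexicographic order
  if (length(paths)) {
    keys <- vapply(paths, .path_lex_key, "")
    paths <- paths[!duplicated(keys)]
    paths <- paths[order(vapply(paths, .path_lex_key, ""))]
  }
  structure(list(paths = paths,
                 strengths = vapply(paths, function(p) .path_strength(network, p), 0),
                 sources = srcs, targets = tgts,
                 via = if (is.null(vias)) character() else vias),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("path_set: %d paths", length(x$paths)))
  if (length(x$via)) cat(" (via ", paste(x$via, collapse = ", "), ")", sep = "")
  cat("\n")
  for (i in seq_along(x$paths))
    cat(sprintf("  %s   [strength %.2f]\n",
                paste(x$paths[[i]], collapse = " - "), x$strengths[i]))
  invisible(x)
}

#' Targets reached by a path set
#'
#' The de-duplicated, sorted subset of `targets` appearing anywhere in
#' the paths — e.g. "the pathway network reaches five of the nine
#' substrate-binding residues".
#'
#' @param pathset a `path_set`.
#' @param targets residue keys (or numbers) to test.
#' @return sorted character vector of reached targets.
#' @export
reached_targets <- function(pathset, targets) {
  targets <- as.character(targets)
  hit <- targets[targets %in% unique(unlist(pathset$paths))]
  sort(hit)
}

#' Write structure-analysis outputs as TSV
#'
#' @param x a `contact_set`, `residue_network`, or `path_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structnet_tsv <- function(x, path) {
  if (inherits(x, "contact_set")) {
    df <- as.data.frame(x)
  } else if (inherits(x, "residue_network")) {
    df <- x$edges
  } else if (inherits(x, "path_set")) {
    df <- data.frame(
      path = vapply(x$paths, paste, "", collapse = "-"),
      hops = vapply(x$paths, function(p) length(p) - 1L, 0L),
      strength = x$strengths, stringsAsFactors = FALSE)
  } else stop("unsupported object", call. = FALSE)
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
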