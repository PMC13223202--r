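#' Simulate protein evolution along a tree
#'
#' Evolves an alignment along a tree under a reversible amino-acid model
#' with discrete rate categories, recording the true states at every
#' internal node. Draw order is fixed (per-site rate categories, then
#' the root states from the equilibrium frequencies, then each branch in
#' preorder), so a given seed replays bit-identically. No indel process
#' is simulated: the likelihood machinery treats gaps as missing data,
#' so gaps add no tested behaviour and can be masked in afterwards.
#'
#' @param tree "phylo" with branch lengths.
#' @param model an [aa_model].
#' @param ncol number of columns to simulate (>= 1).
#' @param seed integer RNG seed.
#' @return object of class `sim_alignment`: list with `alignment` (tip
#'   [aa_alignment]), `ancestors` (named character vector, ids
#'   "node<PAML id>"), `categories` (per-site rate category index),
#'   `rates` (category rates), `tree`, `model`, `seed`.
#' @export
simulate_alignment <- function(tree, model, ncol, seed = 1) {
  .check_blens(tree)
  stopifnot(ncol >= 1)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  lab <- label_nodes(tr)
  cats <- rate_categories(model)
  Q <- build_rate_matrix(model$S, model$pi)
  eig <- .q_eigen(Q, model$pi)
  set.seed(seed)
  cat_idx <- sample.int(length(cats$rates), ncol, replace = TRUE,
                        prob = cats$weights)
  site_rate <- cats$rates[cat_idx]
  states <- matrix(0L, ntip + tr$Nnode, ncol)
  root <- ntip + 1L
  states[root, ] <- sample.int(20, ncol, replace = TRUE, prob = model$pi)
  for (e in rev(seq_len(nrow(tr$edge)))) {        # preorder over branches
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
    Pc <- lapply(sort(unique(site_rate)), function(r) {
      P <- if (t * r == 0) diag(20) else {
        M <- eig$V %*% (exp(eig$lambda * (t * r)) * eig$Vi)
        M[M < 0] <- 0
        M / rowSums(M)
      }
      P
    })
    names(Pc) <- as.character(sort(unique(site_rate)))
    for (s in seq_len(ncol)) {
      P <- Pc[[as.character(site_rate[s])]]
      states[ch, s] <- sample.int(20, 1, prob = P[states[par, s], ])
    }
  }
  to_str <- function(v) paste(AA_CODES[v], collapse = "")
  tips <- vapply(seq_len(ntip), function(i) to_str(states[i, ]), "")
  names(tips) <- tr$tip.label
  anc <- vapply(root:(ntip + tr$Nnode), function(v) to_str(states[v, ]), "")
  names(anc) <- paste0("node", lab$paml[root:(ntip + tr$Nnode)])
  anc <- anc[order(as.integer(sub("node", "", names(anc))))]
  structure(list(alignment = aa_alignment(tips, drop_gap_only_columns = FALSE),
                 ancestors = anc, categories = cat_idx, rates = cats$rates,
                 tree = tr, model = model, seed = seed),
            class = "sim_alignment")
}

#' @export
print.sim_alignment <- function(x, ...) {
  cat(sprintf("sim_alignment: %d tips x %d columns (seed %d), %d recorded ancestors\n",
              n_seq(x$alignment), n_col(x$alignment), x$seed, length(x$ancestors)))
  invisible(x)
}

#' Random binary tree
#'
#' Uniform random unrooted binary topology (via [ape::rtopology()])
#' with tips labelled T1..Tn and branch lengths drawn uniformly from
#' `branch_range`.
#'
#' @param ntips number of tips (>= 3).
#' @param branch_range length-2 numeric range for branch lengths.
#' @param seed integer RNG seed.
#' @return an unrooted "phylo" tree.
#' @export
random_tree <- function(ntips, branch_range = c(0.05, 0.5), seed = 1) {
  stopifnot(ntips >= 3, length(branch_range) == 2)
  if (branch_range[2] < branch_range[1] || branch_range[1] < 0)
    stop("degenerate branch length range", call. = FALSE)
  set.seed(seed)
  tr <- ape::rtopology(ntips, rooted = FALSE,
                       tip.label = paste0("T", seq_len(ntips)))
  tr$edge.length <- stats::runif(nrow(tr$edge), branch_range[1], branch_range[2])
  tr
}

#' Synthetic structure with planted contacts
#'
#' Builds a toy single-chain protein structure (optionally with a
#' ligand group) in which specified residue pairs achieve specified
#' minimum heavy-atom distances to within 0.01 Å, while all unrelated
#' residue pairs are far apart (residue centres sit on a coarse grid
#' with `spacing` Å pitch). Each constraint is realised by a dedicated
#' atom pair on the segment between the two residue centres, so
#' constraints on disjoint atom pairs never interact; duplicate
#' constraints for one pair must agree.
#'
#' @param residues data frame with columns `resno` (residue numbers) and
#'   `atoms` (heavy-atom count per residue, >= 2), and optionally
#'   `resname` (default ALA).
#' @param contacts optional data frame with columns `i`, `j` (residue
#'   numbers) and `dist` (required minimum heavy-atom distance, Å).
#' @param ligand optional list with `name` (residue name, e.g. "DMF"),
#'   `atoms` (count), and `dists` (named numeric: required min distance
#'   from the ligand to each named residue; residues not named are far).
#' @param spacing grid pitch for residue centres (default 100 Å).
#' @param path optional output path for the PDB text.
#' @return the structure re-read through [read_pdb()]; when `path` is
#'   NULL a temporary file is used.
#' @export
synthetic_structure <- function(residues, contacts = NULL, ligand = NULL,
                                spacing = 100, path = NULL) {
  stopifnot(is.data.frame(residues), all(c("resno", "atoms") %in% names(residues)))
  if (any(residues$atoms < 2)) stop("each residue needs >= 2 heavy atoms", call. = FALSE)
  if (is.null(residues$resname)) residues$resname <- "ALA"
  if (!is.null(contacts)) {
    stopifnot(all(c("i", "j", "dist") %in% names(contacts)))
    if (any(contacts$dist <= 0)) stop("infeasible spec: non-positive distance", call. = FALSE)
    key <- paste(pmin(contacts$i, contacts$j), pmax(contacts$i, contacts$j))
    if (anyDuplicated(key)) {
      agg <- tapply(contacts$dist, key, function(d) diff(range(d)))
      if (any(agg > 1e-9))
        stop("infeasible spec: conflicting distances for one residue pair", call. = FALSE)
    }
    if (any(contacts$dist >= spacing / 4))
      stop("infeasible spec: required distance too large for the grid spacing",
           call. = FALSE)
  }
  n <- nrow(residues)
  ngrp <- n + !is.null(ligand)
  ## residue centres on a coarse 3D grid
  g <- ceiling(ngrp^(1 / 3))
  centres <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g), z = seq_len(g)))[
    seq_len(ngrp), , drop = FALSE] * spacing
  rownames(centres) <- NULL

  atoms <- list()
  emit <- function(grp, resname, resno, het, coords) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      resname = resname, resno = resno, het = het,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE)
  }
  ## base cluster: atoms within 0.4 Å of the centre
  cluster <- function(centre, natoms) {
    off <- matrix(0, natoms, 3)
    if (natoms > 1)
      off[2:natoms, 1] <- seq_len(natoms - 1) * 0.4 / natoms
    sweep(off, 2, centre, `+`)
  }
  grp_centre <- function(grp_idx) centres[grp_idx, ]
  idx_of <- function(resno) match(resno, residues$resno)

  placed <- lapply(seq_len(n), function(i)
    cluster(grp_centre(i), residues$atoms[i]))
  lig_coords <- if (!is.null(ligand)) cluster(grp_centre(n + 1L), ligand$atoms) else NULL

  ## realise each constraint with a dedicated atom pair on the i->j segment
  place_pair <- function(ci, cj, d) {
    u <- cj - ci
    u <- u / sqrt(sum(u^2))
    a1 <- ci + u * 5
    a2 <- a1 + u * d
    rbind(a1, a2)
  }
  if (!is.null(contacts)) {
    for (r in seq_len(nrow(contacts))) {
      i <- idx_of(contacts$i[r]); j <- idx_of(contacts$j[r])
      if (is.na(i) || is.na(j)) stop("contact names unknown residue", call. = FALSE)
      pp <- place_pair(grp_centre(i), grp_centre(j), contacts$dist[r])
      placed[[i]] <- rbind(placed[[i]], pp[1, , drop = FALSE])
      placed[[j]] <- rbind(placed[[j]], pp[2, , drop = FALSE])
    }
  }
  if (!is.null(ligand) && length(ligand$dists)) {
    for (nm in names(ligand$dists)) {
      i <- idx_of(as.numeric(nm))
      if (is.na(i)) stop("ligand distance names unknown residue", call. = FALSE)
      pp <- place_pair(grp_centre(n + 1L), grp_centre(i), ligand$dists[[nm]])
      lig_coords <- rbind(lig_coords, pp[1, , drop = FALSE])
      placed[[i]] <- rbind(placed[[i]], pp[2, , drop = FALSE])
    }
  }
  for (i in seq_len(n))
    emit(i, residues$resname[i], residues$resno[i], FALSE, placed[[i]])
  if (!is.null(ligand))
    emit(n + 1L, ligand$name, max(residues$resno) + 1L, TRUE, lig_coords)

  if (is.null(path)) path <- tempfile(fileext = ".pdb")
  .write_pdb_text(do.call(rbind, atoms), path)
  read_pdb(path)
}

## minimal fixed-column PDB writer for synthetic structures (chain A,
## carbon atoms named C1..Cn per residue)
.write_pdb_text <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  serial <- 0L
  for (key in unique(paste(df$resno, df$het))) {
    sub <- df[paste(df$resno, df$het) == key, , drop = FALSE]
    for (a in seq_len(nrow(sub))) {
      serial <- serial + 1L
      rec <- if (sub$het[a]) "HETATM" else "ATOM"
      writeLines(sprintf(
        "%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial, paste0("C", a), sub$resname[a], sub$resno[a],
        sub$x[a], sub$y[a], sub$z[a], 1, 0, "C"), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
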