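#' Read a protein structure from a PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper applies the
#' filtering policy shared by all structure analyses: waters (HOH) and
#' hydrogens are dropped, alternate locations other than blank or 'A' are
#' excluded, and HETATM groups are retained as ligand groups keyed by
#' residue name (e.g. DMF, ATP). Author residue numbering is preserved;
#' insertion codes are concatenated onto the residue number to form an
#' unambiguous residue key (e.g. "52A").
#'
#' @param path path to a fixed-column PDB file.
#' @return an object of class `aa_structure`: list with `atoms` (data
#'   frame: chain, resno, insert, reskey, resid, elety, elesy, x, y, z,
#'   het) and `ligands` (character vector of HETATM residue names).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  ## element symbol: trust the element column, fall back to atom-name letter
  elesy <- trimws(at$elesy)
  miss <- !nzchar(elesy) | is.na(elesy)
  if (any(miss)) elesy[miss] <- substr(gsub("[0-9]", "", trimws(at$elety[miss])), 1, 1)
  keep <- toupper(elesy) != "H" &
    at$resid != "HOH" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]
  if (nrow(at) == 0) stop("no atoms left after water/hydrogen filtering", call. = FALSE)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("non-finite coordinates in ", path, call. = FALSE)
  ins <- at$insert
  ins[is.na(ins)] <- ""
  chain <- at$chain
  chain[is.na(chain)] <- ""
  atoms <- data.frame(
    chain = chain,
    resno = at$resno,
    insert = ins,
    reskey = paste0(at$resno, ins),
    resid = at$resid,
    elety = trimws(at$elety),
    elesy = toupper(elesy),
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms,
                 ligands = sort(unique(atoms$resid[atoms$het]))),
            class = "aa_structure")
}

#' @export
print.aa_structure <- function(x, ...) {
  a <- x$atoms
  prot <- a[!a$het, ]
  cat(sprintf("aa_structure: %d atoms, %d protein residues, chains: %s\n",
              nrow(a), nrow(unique(prot[, c("chain", "reskey")])),
              paste(sort(unique(a$chain)), collapse = " ")))
  if (length(x$ligands))
    cat("  ligand groups:", paste(x$ligands, collapse = ", "), "\n")
  invisible(x)
}

## protein residues of one chain, in author numbering order
.protein_residues <- function(structure, chain = NULL) {
  a <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  if (is.null(chain)) chain <- sort(unique(a$chain))[1]
  a <- a[a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no protein atoms in chain '", chain, "'", call. = FALSE)
  a
}
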