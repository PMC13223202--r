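#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] adding the contract checks the
#' rest of the pipeline relies on: unique tip labels, finite non-negative
#' branch lengths, and numeric internal-node labels interpreted as
#' support values. Trees are stored in `ape`'s rooted "phylo" form; all
#' likelihood computations are invariant to the (arbitrary) root
#' placement under a reversible model.
#'
#' @param text Newick string, or a path to a file holding one.
#' @return an [ape::read.tree()] "phylo" object; numeric node labels are
#'   copied to `tree$support` (vector over internal nodes).
#' @export
read_newick <- function(text) {
  tr <- if (file.exists(text) && !grepl("\\(", text)) ape::read.tree(file = text)
        else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick text", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(tr$edge.length)) {
    if (any(!is.finite(tr$edge.length)))
      stop("non-finite branch length", call. = FALSE)
    if (any(tr$edge.length < 0))
      stop("negative branch length", call. = FALSE)
  }
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    if (any(!is.na(sup))) tr$support <- sup
  }
  tr
}

#' Write a tree as Newick text
#'
#' @param tree a "phylo" object; if `tree$support` is present it is
#'   written as internal node labels.
#' @param path optional output path; when NULL the Newick string is
#'   returned.
#' @param digits significant digits for branch lengths (default 10).
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  if (!is.null(tree$support)) {
    lab <- tree$support
    lab[is.na(lab)] <- ""
    tree$node.label <- as.character(lab)
  }
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(txt)
}

## stop unless every branch length is present
.check_blens <- function(tree) {
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("tree has missing branch lengths; likelihood operations need them",
         call. = FALSE)
  invisible(TRUE)
}

## stop unless tree tips match alignment ids exactly (as sets)
.check_labels <- function(tree, aln) {
  if (!setequal(tree$tip.label, aln$ids))
    stop("tree tip labels and alignment ids do not match", call. = FALSE)
  invisible(TRUE)
}
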