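#' Fit a maximum-likelihood phylogeny to a protein alignment
#'
#' The central fitting function of the package. Starting from a
#' neighbour-joining tree on ML pairwise distances (or a user-supplied
#' tree), it optimises branch lengths by exact single-edge Brent sweeps,
#' optionally re-estimates the gamma shape and invariant-site proportion,
#' optionally refines the topology by NNI hill climbing, and optionally
#' attaches nonparametric bootstrap supports.
#'
#' @param alignment an [aa_alignment].
#' @param model an [aa_model]; its `alpha`/`p_inv` values are start
#'   values when `optimize_shape`/`optimize_pinv` are TRUE.
#' @param tree optional start tree ("phylo", tips = alignment ids); when
#'   NULL a neighbour-joining tree on ML distances is built.
#' @param optimize_shape re-estimate the gamma shape by bounded search in
#'   [0.02, 100] (default: TRUE when the model has `+G`).
#' @param optimize_pinv re-estimate the invariant proportion in
#'   [0, 0.99] (default: TRUE when the model has `+I`).
#' @param nni refine the topology by [nni_search()] (default TRUE).
#' @param bootstrap number of bootstrap replicates (0 = none).
#' @param seed RNG seed used for the bootstrap.
#' @return object of class `phylo_ml`: list with `tree` (optimised, with
#'   `$support` when bootstrapped), `model` (with fitted rate
#'   parameters), `logLik`, `nparams`, `alignment`, `bootstrap`,
#'   `n_nni_moves`, `call`.
#' @seealso [predict.phylo_ml()] for ancestral reconstruction,
#'   [simulate.phylo_ml()] for parametric simulation, [select_model()]
#'   for choosing the substitution model.
#' @export
phylo_ml <- function(alignment, model = aa_model("LG", alpha = 1),
                     tree = NULL,
                     optimize_shape = !is.na(model$alpha),
                     optimize_pinv = model$p_inv > 0,
                     nni = TRUE, bootstrap = 0, seed = 1) {
  stopifnot(inherits(alignment, "aa_alignment"), inherits(model, "aa_model"))
  if (is.null(tree)) {
    D <- ml_distance_matrix(alignment, model)
    tree <- neighbor_joining(D)
  }
  .check_labels(tree, alignment)
  .check_blens(tree)
  fit <- optimize_branch_lengths(tree, alignment, model)
  if (optimize_shape || optimize_pinv) {
    for (round in 1:2) {
      model <- .optimize_rate_params(fit$tree, alignment, model,
                                     optimize_shape, optimize_pinv)
      fit <- optimize_branch_lengths(fit$tree, alignment, model)
    }
  }
  n_moves <- 0L
  if (nni && length(alignment$ids) > 3) {
    res <- nni_search(fit$tree, alignment, model)
    fit <- list(tree = res$tree, result = res$result)
    n_moves <- res$n_moves
  }
  boot <- NULL
  if (bootstrap > 0) {
    boot <- bootstrap_support(alignment, model, fit$tree,
                              n_replicates = bootstrap, seed = seed)
    fit$tree$support <- boot$tree$support
  }
  structure(list(tree = fit$tree, model = model,
                 logLik = fit$result$lnL, nparams = fit$result$nparams,
                 alignment = alignment, bootstrap = boot,
                 n_nni_moves = n_moves, call = match.call()),
            class = "phylo_ml")
}

## bounded search for gamma shape and/or invariant proportion on a fixed tree
.optimize_rate_params <- function(tree, aln, model, shape, pinv) {
  obj <- function(alpha, p_inv) {
    m <- model
    m$alpha <- alpha; m$p_inv <- p_inv
    log_likelihood(tree, aln, m)$lnL
  }
  if (shape && pinv) {
    start <- c(if (is.na(model$alpha)) 1 else model$alpha, model$p_inv)
    op <- stats::optim(start, function(p) -obj(p[1], p[2]),
                       method = "L-BFGS-B",
                       lower = c(0.02, 0), upper = c(100, 0.99),
                       control = list(factr = 1e7))
    model$alpha <- op$par[1]; model$p_inv <- op$par[2]
  } else if (shape) {
    op <- stats::optimize(function(a) obj(a, model$p_inv),
                          c(0.02, 100), maximum = TRUE, tol = 1e-6)
    model$alpha <- op$maximum
  } else if (pinv) {
    op <- stats::optimize(function(p) obj(model$alpha, p),
                          c(0, 0.99), maximum = TRUE, tol = 1e-6)
    model$p_inv <- op$maximum
  }
  model
}

#' @export
print.phylo_ml <- function(x, ...) {
  cat("Maximum-likelihood phylogeny\n")
  cat(sprintf("  %d tips, %d columns, model ", length(x$tree$tip.label),
              n_col(x$alignment)))
  print(x$model)
  cat(sprintf("  log-likelihood: %.4f  (%d free parameters, AIC %.2f)\n",
              x$logLik, x$nparams, aic(x$logLik, x$nparams)))
  if (!is.null(x$bootstrap))
    cat(sprintf("  bootstrap: %d replicates\n", x$bootstrap$n_replicates))
  invisible(x)
}

#' @export
summary.phylo_ml <- function(object, ...) {
  print(object)
  cat("\nBranch lengths:\n")
  print(summary(object$tree$edge.length))
  if (!is.null(object$bootstrap)) {
    cat("\nBipartition support:\n")
    print(round(object$bootstrap$support, 3))
  }
  invisible(object)
}

#' @export
logLik.phylo_ml <- function(object, ...) {
  structure(object$logLik, df = object$nparams, class = "logLik")
}

#' @export
coef.phylo_ml <- function(object, ...) {
  out <- c(alpha = object$model$alpha, p_inv = object$model$p_inv)
  bl <- object$tree$edge.length
  names(bl) <- paste0("edge", seq_along(bl))
  c(out[!is.na(out)], bl)
}

#' @export
plot.phylo_ml <- function(x, show_support = !is.null(x$tree$support), ...) {
  ape::plot.phylo(x$tree, ...)
  if (show_support && !is.null(x$tree$support)) {
    lab <- ifelse(is.na(x$tree$support), "", sprintf("%.2f", x$tree$support))
    ape::nodelabels(lab, frame = "none", adj = c(1.1, -0.3), cex = 0.7)
  }
  invisible(x)
}

#' Simulate alignments from a fitted phylogeny
#'
#' Parametric simulation: evolves `nsim` alignments of the fitted
#' alignment's width along the fitted tree under the fitted model (see
#' [simulate_alignment()]).
#'
#' @param object a `phylo_ml` fit.
#' @param nsim number of simulated alignments.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of `sim_alignment` objects.
#' @export
simulate.phylo_ml <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_alignment(object$tree, object$model, n_col(object$alignment),
                       seed = seed + i - 1L))
}

#' Ancestral reconstruction from a fitted phylogeny
#'
#' `predict()` on a `phylo_ml` object performs empirical-Bayes marginal
#' ancestral sequence reconstruction at every internal node (see
#' [ancestral_reconstruction()]).
#'
#' @param object a `phylo_ml` fit.
#' @param ... passed on to [ancestral_reconstruction()].
#' @return an `ancestral_reconstruction` object.
#' @export
predict.phylo_ml <- function(object, ...) {
  ancestral_reconstruction(object$tree, object$alignment, object$model, ...)
}

#' Substitution-model selection by AIC
#'
#' Fits every candidate exchangeability matrix under the requested rate
#' options (none, `+G`, `+I`, `+G+I`, each optionally with observed
#' `+F` frequencies) on a fixed topology, optimising branch lengths and
#' the rate parameters for each combination, and ranks the fits by AIC.
#' Free parameters are counted as the branch lengths (2n-3) plus 1 per
#' `+G`, 1 per `+I`, and 19 per `+F`.
#'
#' @param alignment an [aa_alignment].
#' @param tree optional fixed topology; when NULL a neighbour-joining
#'   start tree is built under the first candidate.
#' @param candidates character vector of built-in matrix names and/or
#'   named lists with `S` and `pi` (e.g. a matrix loaded from a
#'   PAML-style file).
#' @param gamma,inv,freq include `+G`, `+I`, `+F` variants (defaults:
#'   gamma TRUE, inv TRUE, freq FALSE).
#' @param k gamma category count (default 4).
#' @return object of class `model_selection`: list with `best_model`
#'   (an [aa_model] with fitted parameters), `best_tree`, and `table`
#'   (data frame: matrix, options, lnL, nparams, AIC, dAIC; sorted by
#'   AIC ascending).
#' @export
select_model <- function(alignment, tree = NULL, candidates = c("LG", "WAG", "JTT"),
                         gamma = TRUE, inv = TRUE, freq = FALSE, k = 4) {
  if (length(candidates) == 0) stop("empty candidate list", call. = FALSE)
  cand_names <- if (is.null(names(candidates))) {
    vapply(seq_along(candidates), function(i)
      if (is.character(candidates[[i]])) candidates[[i]] else paste0("custom", i), "")
  } else names(candidates)
  if (is.null(tree)) {
    m0 <- aa_model(candidates[[1]], name = cand_names[1])
    tree <- neighbor_joining(ml_distance_matrix(alignment, m0))
  }
  .check_labels(tree, alignment)
  opts <- list(c(g = FALSE, i = FALSE))
  if (gamma) opts <- c(opts, list(c(g = TRUE, i = FALSE)))
  if (inv) opts <- c(opts, list(c(g = FALSE, i = TRUE)))
  if (gamma && inv) opts <- c(opts, list(c(g = TRUE, i = TRUE)))
  fmodes <- if (freq) c(FALSE, TRUE) else FALSE
  obs_pi <- if (freq) observed_frequencies(alignment) else NULL

  rows <- list(); fits <- list()
  for (ci in seq_along(candidates)) {
    for (op in opts) for (fm in fmodes) {
      m <- aa_model(candidates[[ci]],
                    alpha = if (op["g"]) 1 else NA,
                    p_inv = if (op["i"]) 0.1 else 0, k = k,
                    pi = if (fm) obs_pi else NULL,
                    name = cand_names[ci])
      fit <- optimize_branch_lengths(tree, alignment, m, max_sweeps = 10)
      if (op["g"] || op["i"]) {
        for (round in 1:2) {
          m <- .optimize_rate_params(fit$tree, alignment, m, op["g"], op["i"])
          fit <- optimize_branch_lengths(fit$tree, alignment, m, max_sweeps = 10)
        }
      }
      tag <- paste0(if (op["g"]) "+G" else "", if (op["i"]) "+I" else "",
                    if (fm) "+F" else "")
      np <- nrow(fit$tree$edge) + sum(op) + if (fm) 19L else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        matrix = cand_names[ci], options = tag, lnL = fit$result$lnL,
        nparams = np, AIC = aic(fit$result$lnL, np), stringsAsFactors = FALSE)
      fits[[length(fits) + 1L]] <- list(model = m, tree = fit$tree)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$AIC)
  tab <- tab[ord, , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  best <- fits[[ord[1]]]
  structure(list(best_model = best$model, best_tree = best$tree, table = tab),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Substitution-model selection (AIC)\n")
  print(x$table, digits = 8)
  cat("best: ")
  print(x$best_model)
  invisible(x)
}

#' Write a model-selection table as TSV
#' @param x a `model_selection` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model_selection <- function(x, path) {
  utils::write.table(format(x$table, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
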