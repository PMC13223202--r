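#' Read a pipeline run configuration
#'
#' Plain key-value text, one `key = value` per line ('#' comments and
#' blank lines ignored). Recognised keys:
#' \describe{
#'   \item{alignment}{path to the input alignment (.phy/.phylip read as
#'     PHYLIP interleaved, anything else as FASTA); required.}
#'   \item{tree}{optional Newick file with a fixed topology.}
#'   \item{structure}{optional PDB file; `ligand` names the HETATM
#'     group(s) for contact analysis (comma-separated).}
#'   \item{candidates}{substitution matrices to rank (default
#'     LG,WAG,JTT); `gamma`, `inv`, `freq` (true/false) toggle +G/+I/+F
#'     variants; `k` sets the gamma category count (default 4).}
#'   \item{nni}{true/false topology refinement (default true).}
#'   \item{bootstrap}{replicate count (default 500; 0 disables).}
#'   \item{seed}{RNG seed (default 1).}
#'   \item{ancestor.<name>}{comma-separated tip list; the named ancestor
#'     is the MRCA of those tips. `ancestor.<name> = node:<id>`
#'     addresses a PAML-style node id directly.}
#'   \item{clade.<name>}{comma-separated tip ids defining a clade.}
#'   \item{conserve}{`<reference id>,<residue position>`: report each
#'     clade's conservation at that reference position.}
#'   \item{diverge}{`<idA>,<idB>`: divergent-position report;
#'     `numbering_reference` adds a third sequence's numbering.}
#'   \item{ligand_cutoff, contact_cutoff, psn_cutoff, i_min}{structure
#'     analysis parameters (defaults 4.0, 6.0, 3.0, 0).}
#'   \item{psn_sources, psn_targets, psn_via}{residue numbers for the
#'     communication-path stage.}
#' }
#'
#' @param path config file path.
#' @return object of class `run_config` (a named list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop("unparseable config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 2))
  vals <- trimws(vapply(kv, `[`, "", 3))
  raw <- stats::setNames(as.list(vals), keys)

  get1 <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  as_bool <- function(x) tolower(x) %in% c("true", "yes", "1")
  split1 <- function(x) trimws(strsplit(x, ",")[[1]])

  cfg <- list(
    alignment = get1("alignment", NULL),
    tree = get1("tree", NULL),
    structure = get1("structure", NULL),
    ligand = if (!is.null(raw$ligand)) split1(raw$ligand) else character(),
    candidates = split1(get1("candidates", "LG,WAG,JTT")),
    gamma = as_bool(get1("gamma", "true")),
    inv = as_bool(get1("inv", "true")),
    freq = as_bool(get1("freq", "false")),
    k = as.integer(get1("k", "4")),
    nni = as_bool(get1("nni", "true")),
    bootstrap = as.integer(get1("bootstrap", "500")),
    seed = as.integer(get1("seed", "1")),
    conserve = if (!is.null(raw$conserve)) split1(raw$conserve) else NULL,
    diverge = if (!is.null(raw$diverge)) split1(raw$diverge) else NULL,
    numbering_reference = get1("numbering_reference", NULL),
    ligand_cutoff = as.numeric(get1("ligand_cutoff", "4.0")),
    contact_cutoff = as.numeric(get1("contact_cutoff", "6.0")),
    psn_cutoff = as.numeric(get1("psn_cutoff", "3.0")),
    i_min = as.numeric(get1("i_min", "0")),
    psn_sources = if (!is.null(raw$psn_sources)) split1(raw$psn_sources) else NULL,
    psn_targets = if (!is.null(raw$psn_targets)) split1(raw$psn_targets) else NULL,
    psn_via = if (!is.null(raw$psn_via)) split1(raw$psn_via) else NULL,
    ancestors = raw[grep("^ancestor\\.", names(raw))],
    clades = lapply(raw[grep("^clade\\.", names(raw))], split1),
    raw = raw
  )
  if (is.null(cfg$alignment)) stop("config must set 'alignment'", call. = FALSE)
  for (p in c(cfg$alignment, cfg$tree, cfg$structure))
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  if (cfg$bootstrap < 0) stop("bootstrap must be >= 0", call. = FALSE)
  for (key in c("ligand_cutoff", "contact_cutoff", "psn_cutoff"))
    if (cfg[[key]] <= 0) stop(key, " must be > 0", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full reconstruction workflow
#'
#' Orchestrates the end-to-end analysis from one [read_run_config()]
#' config: substitution-model selection by AIC, ML tree inference with
#' optional NNI refinement and bootstrap, marginal ancestral
#' reconstruction with PAML-style node labels, identity/conservation/
#' divergence statistics, and (when a structure is supplied)
#' ligand-contact, contact-pair, PSN, and communication-path analyses.
#' Stages without inputs are skipped with a logged notice; a stage error
#' aborts the run with a log entry naming the stage. Results are
#' deterministic given the seed.
#'
#' @param config a `run_config` (or a path to one).
#' @param outdir report directory (created if needed).
#' @return invisibly, `outdir`. Writes model_selection.tsv, tree.nwk,
#'   ancestors.fasta, posteriors.tsv, node_table.tsv, identity.tsv,
#'   conservation.tsv, divergence.tsv, contacts.tsv, psn_edges.tsv,
#'   psn_paths.tsv, and run.log.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      logmsg("stage %s: ERROR: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  logmsg("run_pipeline (protasr %s), seed %d",
         as.character(utils::packageVersion("protasr")), config$seed)
  for (key in names(config$raw)) logmsg("config: %s = %s", key, config$raw[[key]])

  aln <- stage("read_alignment", {
    if (grepl("\\.(phy|phylip)$", config$alignment, ignore.case = TRUE))
      read_phylip_interleaved(config$alignment)
    else aa_alignment(read_fasta(config$alignment))
  })
  tree0 <- if (!is.null(config$tree)) stage("read_tree", read_newick(config$tree)) else NULL

  sel <- stage("model_selection", {
    s <- select_model(aln, tree = tree0, candidates = config$candidates,
                      gamma = config$gamma, inv = config$inv,
                      freq = config$freq, k = config$k)
    write_model_selection(s, file.path(outdir, "model_selection.tsv"))
    logmsg("best model: %s%s", s$table$matrix[1], s$table$options[1])
    s
  })

  fit <- stage("tree_inference", {
    f <- phylo_ml(aln, model = sel$best_model, tree = sel$best_tree,
                  optimize_shape = FALSE, optimize_pinv = FALSE,
                  nni = config$nni, bootstrap = config$bootstrap,
                  seed = config$seed)
    write_newick(f$tree, file.path(outdir, "tree.nwk"))
    logmsg("lnL %.4f, %d NNI moves", f$logLik, f$n_nni_moves)
    f
  })

  asr <- stage("ancestral_reconstruction", {
    a <- predict(fit)
    write_ancestors_fasta(a, file.path(outdir, "ancestors.fasta"))
    write_posteriors_tsv(a, file.path(outdir, "posteriors.tsv"))
    write_node_table(a, file.path(outdir, "node_table.tsv"))
    a
  })
  for (nm in names(config$ancestors)) {
    q <- config$ancestors[[nm]]
    id <- if (startsWith(q, "node:")) as.integer(sub("node:", "", q))
          else mrca_node(fit$tree, trimws(strsplit(q, ",")[[1]]))
    logmsg("ancestor %s -> node %d (meanPP %.4f)",
           sub("^ancestor\\.", "", nm), id, asr$mean_pp[paste0("node", id)])
  }

  stage("identity", {
    write_conservation_tsv(identity_matrix(aln), file.path(outdir, "identity.tsv"))
  })
  stage("conservation", {
    write_conservation_tsv(conservation_profile(aln),
                           file.path(outdir, "conservation.tsv"))
    if (!is.null(config$conserve) && length(config$clades)) {
      ref <- config$conserve[1]; pos <- as.integer(config$conserve[2])
      for (nm in names(config$clades)) {
        cc <- clade_conservation(aln, config$clades[[nm]], ref, pos)
        logmsg("conservation of %s%d in %s: %.1f%% (%d/%d)", cc$residue, pos,
               sub("^clade\\.", "", nm), cc$percent, cc$n_matching, cc$n_counted)
      }
    }
  })
  if (!is.null(config$diverge)) {
    stage("divergence", {
      rep <- divergent_positions(aln, config$diverge[1], config$diverge[2],
                                 reference_id = config$numbering_reference)
      write_conservation_tsv(rep, file.path(outdir, "divergence.tsv"))
      logmsg("divergent positions: %d", nrow(rep))
    })
  } else logmsg("stage divergence: skipped (no 'diverge' ids)")

  if (!is.null(config$structure)) {
    struct <- stage("read_structure", read_pdb(config$structure))
    stage("contacts", {
      rows <- lapply(config$ligand, function(lg)
        ligand_contacts(struct, lg, cutoff = config$ligand_cutoff))
      if (length(rows)) {
        all <- do.call(rbind, lapply(seq_along(rows), function(i)
          cbind(ligand = config$ligand[i], as.data.frame(rows[[i]]))))
        utils::write.table(format(all, digits = 10, trim = TRUE),
                           file.path(outdir, "contacts.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      } else logmsg("stage contacts: no ligand configured")
    })
    psn <- stage("psn", {
      net <- build_psn(struct, atom_cutoff = config$psn_cutoff,
                       i_min = config$i_min)
      write_structnet_tsv(net, file.path(outdir, "psn_edges.tsv"))
      net
    })
    if (!is.null(config$psn_sources) && !is.null(config$psn_targets)) {
      stage("psn_paths", {
        ps <- communication_paths(psn, config$psn_sources, config$psn_targets,
                                  via = config$psn_via)
        write_structnet_tsv(ps, file.path(outdir, "psn_paths.tsv"))
        logmsg("paths: %d, reached targets: %s", length(ps$paths),
               paste(reached_targets(ps, config$psn_targets), collapse = ","))
      })
    } else logmsg("stage psn_paths: skipped (no sources/targets)")
  } else logmsg("structure stages skipped (no structure input)")

  logmsg("run complete")
  invisible(outdir)
}
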