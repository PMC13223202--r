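Package: protasr
Title: Maximum-Likelihood Phylogenetics, Ancestral Protein Reconstruction,
    and Protein Structure Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the evolution of protein families such as the
    fructosamine-3-kinase (FN3K) family: reversible amino-acid substitution
    models with discrete-gamma rate heterogeneity and invariant sites,
    Felsenstein-pruning likelihood, AIC-based substitution-model selection,
    maximum-likelihood tree inference (ML distances, neighbour joining,
    branch-length optimisation, NNI search, nonparametric bootstrap),
    empirical-Bayes marginal ancestral sequence reconstruction with
    PAML-style node labels, family conservation and percent-identity
    statistics, structure-based ligand-contact and residue-network analyses
    with constrained shortest-path queries, and a seeded sequence/structure
    simulator for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    igraph,
    bio3d,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
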