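---
title: "Models and methods behind protasr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protasr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`protasr` implements the computational machinery used to study how
protein families such as the fructosamine-3-kinases diverged in
substrate specificity: maximum-likelihood phylogenetics, marginal
ancestral sequence reconstruction, family conservation statistics, and
structure-based interaction networks. This vignette is the package's
account of the underlying models, the tunable parameters, and the
design and numerical choices made where the method itself leaves room.

## The substitution model

Evolution at each alignment column is a reversible continuous-time
Markov chain on the 20 amino acids. An `aa_model` combines:

* an **exchangeability matrix** `S` (symmetric, unit-free relative
  rates) and **equilibrium frequencies** `π`. The rate matrix is
  `q_ij = S_ij π_j` for `i ≠ j`, diagonal set so rows sum to zero, then
  globally rescaled so `−Σ_i π_i q_ii = 1`. Branch lengths are thereby
  expected substitutions per site. Detailed balance
  `π_i q_ij = π_j q_ji` holds by construction, which is what makes the
  likelihood invariant to root placement.
* a **discrete-gamma** shape `α > 0` with `k` equal-probability rate
  categories (default `k = 4`). Category rates are the means of the
  gamma(α, rate = α) distribution between consecutive quantiles,
  computed through the incomplete-gamma identity and renormalised so
  the mixture mean is exactly 1. The category-mean convention (rather
  than the median) was chosen because it keeps the mixture mean at 1
  without ad-hoc rescaling; a quadrature oracle in the test suite
  confirms the means to 1e-6.
* an **invariant fraction** `p_inv ∈ [0, 1)`, added as a rate-0
  category of weight `p_inv` with the remaining rates divided by
  `1 − p_inv`, so the overall mean rate stays 1.
* optionally, **observed frequencies** (`+F`): the alignment's non-gap
  amino-acid frequencies with no pseudocount, replacing the matrix's
  `π` (19 extra free parameters).

LG, WAG, JTT, and Dayhoff exchangeabilities are taken from the model
library shipped with `phangorn` and reordered into the PAML amino-acid
order used throughout the package. Other matrices — Q.plant in
particular, which is not distributed with any package available here —
are loaded from PAML-style `.dat` files via
`read_exchangeability_dat()`, so the default model-selection candidate
set is {LG, WAG, JTT} plus whatever the user supplies.

Transition probabilities `P(t) = exp(Qt)` are computed through the
symmetrised eigendecomposition `diag(√π) Q diag(1/√π)`; entries are
clamped at 0 and rows renormalised to absorb round-off. A note on
stationarity: the slowest eigenmode of empirical matrices decays slowly
(for LG, deviations from `π` are still ~1e-2 at `t = 10`), so the
stationarity property is asserted at `t = 100` in the tests.

## Likelihood

`log_likelihood()` is Felsenstein pruning: post-order partial
likelihood vectors over **compressed site patterns**, with per-node
scaling factors to prevent underflow, and a log-sum-exp mixture over
rate categories. Gaps and `'X'` are missing data (all-ones tip
vectors); a column that is gap in every sequence therefore contributes
exactly zero to the log-likelihood. The kernel is validated two
independent ways: against brute-force enumeration over all ancestral
state assignments (with `Matrix::expm` transition matrices) on small
instances, and against `phangorn::pml` on larger ones.

The same machinery provides an **inside–outside pass**: for every edge,
the conditional likelihood of the subtree below it and the "rest of
tree" profile above it. This yields the exact likelihood as a function
of a single branch length at the cost of one matrix product, which is
what branch-length optimisation and marginal reconstruction both
consume.

## Tree inference

* **Start tree.** Neighbour joining (`ape::nj`, negative branch
  lengths clamped to 0) on maximum-likelihood pairwise distances, each
  distance a bounded Brent search of the two-sequence likelihood on
  `t ∈ [1e-6, 10]` (tolerance 1e-8; the site-pair count matrix is
  symmetrised so the distance is exactly symmetric). NJ approximates
  the BioNJ start trees used by mainstream ML programs; on additive
  distances it is exact, which the tests assert.
* **Branch lengths.** Round-robin single-edge Brent optimisation
  (bounds `[1e-8, 10]`, per-edge tolerance 1e-8) on the cached
  inside–outside profiles, sweeping until a full sweep gains less than
  1e-6 log-units (at most 50 sweeps). Each single-edge step maximises
  the exact likelihood in that coordinate, so lnL is non-decreasing.
* **Topology.** NNI hill climbing: all nearest-neighbour interchanges
  of the current tree are scored with branch-length re-optimisation
  (three sweeps per candidate — an economy that leaves the ranking of
  candidates intact in practice — followed by full re-optimisation of
  the accepted tree); the best improving move is taken and the search
  repeats to a local optimum. Enumeration order is deterministic, so
  runs are reproducible. SPR/TBR are out of scope.
* **Bootstrap.** Column resampling with all replicate index draws taken
  up front from the seed (bit-reproducible); each replicate re-runs the
  ML-distance + NJ pipeline, optionally with NNI. Replicates reuse the
  full-data estimates of `α`/`p_inv` rather than re-estimating them —
  the standard speed/variance trade-off. Branch-length re-optimisation
  is performed within replicates only when NNI is on: bipartition
  counts depend solely on topology, so re-fitting lengths without a
  topology search cannot change any support value. Supports are keyed
  by canonical bipartition (smaller side, sorted labels).
* **Model selection.** For each candidate matrix × rate-option
  combination (none, `+G`, `+I`, `+G+I`, each optionally `+F`),
  branch lengths and rate parameters are optimised on a fixed topology
  (alternating twice between the two), and models are ranked by
  `AIC = 2k − 2 lnL` with `k` counted as `2n − 3` branch lengths plus 1
  per `+G`, 1 per `+I`, 19 per `+F`. Rate-parameter bounds are
  `α ∈ [0.02, 100]`, `p_inv ∈ [0, 0.99]`. Whether model or observed
  frequencies win is recorded in the ranking table rather than assumed.

## Ancestral reconstruction

Marginal (empirical-Bayes) reconstruction: at each internal node `v`
and site, the posterior over states is
`p_v(a) ∝ inside_v(a) · outside_v(a)`, summed over rate categories
weighted by each category's posterior mass for that site, and
normalised. Marginal rather than joint reconstruction is used because
the product of interest — per-site most-probable characters with their
posterior probabilities — is the marginal one. Under reversibility the
posteriors are invariant to root placement, which the tests assert at
1e-9 by matching internal vertices across rootings through their
tip-partition signatures.

The likelihood treats gaps as missing data, so indel history is
reconstructed separately by Fitch small parsimony on the binary
presence/absence character, with two deterministic conventions: ties at
the root resolve to *presence*, and the downward pass prefers the
parent's state. The MAP sequence takes the most probable residue at
each present column (probability ties broken alphabetically by
one-letter code) and `'-'` elsewhere; **meanPP** averages the maximum
posterior over present columns only. On simulated data meanPP tracks
realised accuracy to within a few percent, which is exactly the sense
in which it is a confidence summary.

Node addressing follows the PAML convention: tips `1..n` in Newick
appearance order, internal nodes from `n+1` in preorder from the stored
root. Because trees are stored unrooted (arbitrary trifurcating root),
a tree with `n` tips has `2n − 2` nodes rather than `2n − 1`; the same
convention mainstream ASR tools use for unrooted trees. Integer ids are
ordering-fragile, so `mrca_node()` supports addressing ancestors by the
tip set they subtend, and the pipeline accepts both forms.

## Conservation statistics

Percent identity divides identical co-non-gap pairs by co-non-gap
columns (`'X'` never counts as identical). This is the most common
denominator convention; published identity figures for specific pairs
may use another, so agreement is expected only approximately.
Column-wise conservation reports non-gap residue frequencies, the
consensus and its fraction, and information content
`IC = log2(20) − H` in bits with no small-sample correction (the
logo-matrix contract; drawing is presentation, not analysis).
`clade_conservation()` reports the percentage of clade members matching
a reference residue, with gapped members excluded from the denominator
by default (a flag counts them as mismatches); display rounding is
half-up to integers, full precision goes to the TSV.
`divergent_positions()` lists co-non-gap differing columns with each
sequence's own residue numbering and, optionally, a third sequence's
numbering frame — the machinery behind statements that map an ancestral
position onto the human orthologue's numbering.

## Structure networks

Structures are parsed from fixed-column PDB files with a fixed policy:
waters and hydrogens dropped, alternate locations other than blank/'A'
excluded, HETATM groups kept as ligand groups keyed by residue name,
author numbering preserved with insertion codes concatenated into the
residue key. Analyses default to the first protein chain, as the
studies this supports analyse monomers; mmCIF is out of scope.

* **Ligand contacts** (default cutoff 4.0 Å, heavy atoms, backbone
  included): residues with any atom within the cutoff of any ligand
  atom, with minimum distances. The 4 Å default is the standard contact
  criterion; it is a parameter, not a baked-in answer.
* **Contact pairs** (default 6.0 Å): all pairs between two residue
  selections with their minimum heavy-atom distances.
* **PSN** (default 3.0 Å atom cutoff): nodes are residues with
  side-chain heavy atoms (plus C-alpha for glycine); edge strength is
  `I_ij = 100 · n_ij / √(N_i N_j)` with `n_ij` the number of atom pairs
  within the cutoff. `N_i` defaults to the residue's own node atom
  count — a self-contained choice in place of externally tabulated
  per-type normalisation factors, which can be supplied as an override
  table when matching a specific webPSN configuration matters. Edges
  require `I_ij > i_min`; sequence neighbours (|Δresno| ≤ 1) are
  excluded.
* **Communication paths**: shortest means minimum hop count, ties
  broken by maximum cumulative strength, remaining ties
  lexicographically — the simplest defensible reading of "shortest
  communication pathway" given that recurrence-based metrics vary
  between tools. Constrained searches concatenate the best
  source→via and via→target legs and discard non-simple results;
  disconnected queries warn and return an empty path set. All path
  queries are validated against exhaustive simple-path enumeration on
  networks of up to 12 nodes.

## The synthetic-data generator

`simulate_alignment()` draws, in a fixed order (per-site rate
categories, root states from `π`, then each branch in preorder), the
full ancestral process along a tree and records every internal
sequence, so reconstruction accuracy can be measured exactly. It
emulates site-independent substitution with among-site rate variation —
the model class the inference assumes. It deliberately does **not**
emulate indels (gaps are missing data throughout, so a gap process
would add no tested behaviour; gaps can be masked in post hoc),
heterotachy, site-interdependence, or alignment error. Passing the
recovery tests therefore demonstrates correctness of the inference
machinery under its own model, not robustness to real-data violations
of it. `synthetic_structure()` places residue clusters on a coarse
grid (100 Å pitch) and realises each required contact with a dedicated
atom pair to within 0.01 Å, so contact and path analyses have planted
ground truth; conflicting or non-positive distance requirements are
rejected as infeasible.

## Validation scale and reproducibility

The shipped tests and the acceptance script validate at desk scale,
chosen so the full suite runs in a few minutes on one core while
leaving no statistical ambiguity: brute-force oracles on trees of up
to 4 tips × 6 sites (enumeration is exponential in internal nodes);
recovery on 8 taxa × 2000 columns under LG+G (α = 1, all branches 0.1),
where NNI from an NJ start recovers the generating topology and MAP
ancestors match truth at ≥ 85% identity with meanPP ≈ 0.97; AIC model
selection on 50 replicates of 6 taxa × 1000 columns (LG versus WAG);
100 random networks for path queries; 50,000-site two-taxon simulations
against closed-form identity fractions. Every stochastic step is
seeded, bootstrap substreams are drawn up front, and ties everywhere
break by canonical (alphabetical or lexicographic) order, so identical
seeds give identical results.

## Known limitations

* NNI-only topology search can stop in local optima that SPR would
  escape; fine for the well-resolved desk-scale regimes tested, not a
  replacement for a full ML program on hard datasets.
* The likelihood model ignores indel evolution; ancestral gap placement
  is parsimony-based and independent of the substitution model.
* Family-scale claims (tens of thousands of homologues) are exercised
  in kind on fixtures; reproducing a specific study's numbers requires
  that study's deposited alignment, tree, and structures as inputs.
* Branch lengths are capped at 10 substitutions/site and distances
  saturate there; sequences more divergent than that carry essentially
  no signal for these methods anyway.
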