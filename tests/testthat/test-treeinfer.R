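test_that("ML pairwise distances are symmetric, near zero for identical pairs", {
  m <- aa_model("LG")
  s1 <- "MKVLWAALLVTFLAGCQA"
  expect_lte(ml_pairwise_distance(s1, s1, m), 1e-4)
  s2 <- "MKVLWAALLVTALAGCQA"
  expect_identical(ml_pairwise_distance(s1, s2, m),
                   ml_pairwise_distance(s2, s1, m))
  expect_error(ml_pairwise_distance("M-", "--", m), "no comparable")
})

test_that("ML distance is consistent on simulated pairs", {
  Su <- matrix(1, 20, 20); diag(Su) <- 0
  m <- aa_model(list(S = Su, pi = rep(1 / 20, 20)), name = "uniform")
  tr <- read_newick("(A:0.25,B:0.25);")
  sim <- simulate_alignment(tr, m, 5000, seed = 17)
  seqs <- as.character(sim$alignment)
  d <- ml_pairwise_distance(seqs["A"], seqs["B"], m)
  expect_lt(abs(d - 0.5), 0.05)
})

test_that("NJ reproduces the additive 4-taxon worked example exactly", {
  lab <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(lab, lab))
  D["A", "B"] <- 3; D["C", "D"] <- 7; D["A", "C"] <- 5
  D["A", "D"] <- 6; D["B", "C"] <- 6; D["B", "D"] <- 7
  D <- D + t(D)
  tr <- neighbor_joining(D)
  ## topology AB|CD
  expect_identical(sort(ape::extract.clade(ape::root(tr, "C"), ape::getMRCA(
    ape::root(tr, "C"), c("A", "B")))$tip.label), c("A", "B"))
  tip_edge <- function(t, lab) t$edge.length[t$edge[, 2] == match(lab, t$tip.label)]
  expect_equal(tip_edge(tr, "A"), 1)
  expect_equal(tip_edge(tr, "B"), 2)
  expect_equal(tip_edge(tr, "C"), 3)
  expect_equal(tip_edge(tr, "D"), 4)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)

  ## permuting the label order leaves the topology unchanged
  perm <- c("D", "B", "A", "C")
  tr2 <- neighbor_joining(D[perm, perm])
  expect_same_topology(tr, tr2)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2,
                                       dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3")
})

test_that("NJ reconstructs random additive trees exactly", {
  for (seed in 1:50) {
    tr <- random_tree(sample(4:10, 1), c(0.1, 1), seed = seed + 200)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D[tr$tip.label, tr$tip.label])
    expect_same_topology(ape::unroot(tr), ape::unroot(nj))
  }
})

test_that("branch-length optimisation is monotone and recovers true lengths", {
  tr <- read_newick("((A:0.15,B:0.25):0.2,(C:0.1,D:0.3):0.2);")
  m <- aa_model("LG")
  sim <- simulate_alignment(tr, m, 2000, seed = 29)
  start <- tr
  start$edge.length <- rep(0.08, nrow(tr$edge))
  lnL0 <- log_likelihood(start, sim$alignment, m)$lnL
  fit <- optimize_branch_lengths(start, sim$alignment, m)
  expect_gte(fit$result$lnL, lnL0)

  ## recovered lengths within 20% of truth (edges matched by tip below)
  true_by_child <- function(t) {
    lab <- c(t$tip.label, rep(NA, t$Nnode))
    setNames(t$edge.length, lab[t$edge[, 2]])
  }
  tv <- true_by_child(tr); fv <- true_by_child(fit$tree)
  for (tip in c("A", "B", "C", "D"))
    expect_lt(abs(fv[tip] - tv[tip]) / tv[tip], 0.2)

  ## a second pass from the optimum moves lnL by < 1e-6
  fit2 <- optimize_branch_lengths(fit$tree, sim$alignment, m, max_sweeps = 1)
  expect_lt(abs(fit2$result$lnL - fit$result$lnL), 1e-6)
})

test_that("likelihood agrees with an independent implementation and rerooting", {
  set.seed(37)
  tr <- random_tree(6, c(0.05, 0.4), seed = 41)
  m <- aa_model("WAG", alpha = 0.8, k = 4)
  sim <- simulate_alignment(tr, m, 120, seed = 43)
  mine <- log_likelihood(tr, sim$alignment, m)$lnL
  ## independent kernel: phangorn's pml on the same data
  pd <- phangorn::phyDat(sim$alignment$mat, type = "AA")
  ref <- phangorn::pml(tr, pd, model = "WAG", k = 4, shape = 0.8)$logLik
  expect_equal(mine, ref, tolerance = 1e-9)
  ## root invariance
  for (og in c("T2", "T5")) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(log_likelihood(rerooted, sim$alignment, m)$lnL, mine,
                 tolerance = 1e-8)
  }
})

test_that("NNI search fixes a wrong topology and is idle at the optimum", {
  tr <- read_newick("((A:0.1,B:0.1):0.3,(C:0.1,D:0.1):0.3);")
  m <- aa_model("LG")
  sim <- simulate_alignment(tr, m, 1000, seed = 53)
  ## start from the wrong NNI neighbour AC|BD
  wrong <- read_newick("((A:0.1,C:0.1):0.1,(B:0.1,D:0.1):0.1);")
  res <- nni_search(wrong, sim$alignment, m)
  expect_same_topology(ape::unroot(res$tree), ape::unroot(tr))
  expect_gte(res$result$lnL, log_likelihood(wrong, sim$alignment, m)$lnL)
  ## restarting at the found optimum accepts no move
  res2 <- nni_search(res$tree, sim$alignment, m)
  expect_equal(res2$n_moves, 0L)
})

test_that("bootstrap support is reproducible, bounded, and covers all edges", {
  tr <- read_newick("((A:0.1,B:0.1):0.4,(C:0.1,D:0.1):0.4);")
  m <- aa_model("LG")
  sim <- simulate_alignment(tr, m, 300, seed = 59)
  b1 <- bootstrap_support(sim$alignment, m, tr, n_replicates = 5, seed = 71)
  b2 <- bootstrap_support(sim$alignment, m, tr, n_replicates = 5, seed = 71)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 1))
  ## every internal bipartition of a 4-taxon tree gets exactly one value
  expect_equal(length(b1$support), 1)
  expect_false(anyNA(b1$support))
})
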