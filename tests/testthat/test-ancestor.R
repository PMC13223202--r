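test_that("pruning equals brute-force enumeration on small instances", {
  newicks <- c("(A:0.2,B:0.35);",
               "((A:0.1,B:0.4):0.2,C:0.3);",
               "((A:0.12,B:0.3):0.21,(C:0.4,D:0.05):0.1);")
  set.seed(61)
  for (nw in newicks) {
    tr <- read_newick(nw)
    m <- random_model(sample(1e4, 1), alpha = 1.2, k = 2)
    sim <- simulate_alignment(tr, m, 6, seed = sample(1e4, 1))
    mine <- log_likelihood(tr, sim$alignment, m)$lnL
    oracle <- brute_log_lik(tr, sim$alignment, m)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("gap and unknown characters behave as missing data", {
  tr <- read_newick("((A:0.1,B:0.2):0.1,(C:0.15,D:0.25):0.1);")
  m <- aa_model("LG")
  base <- make_aln(A = "MKV", B = "MKV", C = "MRV", D = "MRV")
  with_gapcol <- make_aln(A = "MKV-", B = "MKV-", C = "MRV-", D = "MRV-")
  ## an all-gap column contributes exactly 0
  expect_equal(log_likelihood(tr, with_gapcol, m)$lnL,
               log_likelihood(tr, base, m)$lnL, tolerance = 1e-12)
  ## X is missing too: brute force agrees on a partly-missing column
  partial <- make_aln(A = "MXV", B = "MKV", C = "M-V", D = "MRV")
  expect_equal(log_likelihood(tr, partial, m)$lnL,
               brute_log_lik(tr, partial, m), tolerance = 1e-10)
})

test_that("marginal posteriors equal brute-force conditionals and sum to 1", {
  tr <- read_newick("((A:0.12,B:0.3):0.21,(C:0.4,D:0.05):0.1);")
  set.seed(67)
  m <- random_model(404, alpha = 0.9, k = 2)
  sim <- simulate_alignment(tr, m, 3, seed = 73)
  post <- marginal_posteriors(tr, sim$alignment, m)
  for (p in post) {
    expect_equal(unname(rowSums(p$probs)), rep(1, 3), tolerance = 1e-9)
    for (s in 1:3) {
      oracle <- brute_posterior(tr, sim$alignment, m, p$node, s)
      expect_equal(unname(p$probs[s, ]), unname(oracle), tolerance = 1e-9)
    }
  }
})

test_that("posteriors follow evident signal: zero-length copies and consensus", {
  ## internal node tied to tip by a zero-length branch copies its residue
  tr <- read_newick("((A:0.0,B:1.0):0.5,(C:1.0,D:1.0):0.5);")
  m <- aa_model("LG")
  aln <- make_aln(A = "W", B = "A", C = "A", D = "A")
  post <- marginal_posteriors(tr, aln, m)
  lab <- label_nodes(tr)
  anc_ab <- post[[paste0("node", mrca_node(tr, c("A", "B")))]]
  expect_gte(anc_ab$probs[1, "W"], 0.999)

  ## 3-taxon star, all tips agree: MAP is the shared residue, above its prior
  star <- read_newick("(A:0.3,B:0.3,C:0.3);")
  aln3 <- make_aln(A = "A", B = "A", C = "A")
  p3 <- marginal_posteriors(star, aln3, m)[[1]]
  expect_identical(p3$map, "A")
  expect_gt(p3$probs[1, "A"], m$pi["A"])
})

test_that("posteriors are invariant to rerooting", {
  tr <- random_tree(8, c(0.05, 0.3), seed = 79)
  m <- aa_model("LG", alpha = 1, k = 4)
  sim <- simulate_alignment(tr, m, 40, seed = 83)
  ref <- marginal_posteriors(tr, sim$alignment, m)
  ref_sig <- node_signatures(tr)
  rerooted <- ape::root(ape::unroot(tr), outgroup = "T4", resolve.root = TRUE)
  alt <- marginal_posteriors(rerooted, sim$alignment, m)
  alt_sig <- node_signatures(rerooted)
  expect_gte(length(intersect(ref_sig, alt_sig)), 5)
  expect_lt(max_posterior_reroot_diff(ref, ref_sig, alt, alt_sig), 1e-9)
})

test_that("Fitch gap reconstruction follows presence parsimony with root ties present", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  aln <- make_aln(A = "-A-K", B = "-A-K", C = "KAK-", D = "KAK-")
  g <- reconstruct_gap_states(tr, aln)
  ## column 1: gap in A,B; present in C,D; root tie resolved to presence
  root_row <- g[paste0("node", length(tr$tip.label) + 1), ]
  expect_true(root_row[1])
  ## an all-present column is present everywhere
  expect_true(all(g[, 2]))
  aln2 <- make_aln(A = "-", B = "-", C = "K", D = "K")
  g2 <- reconstruct_gap_states(tr, aln2)
  expect_true(g2[1, 1])   # root tie -> present
  aln3 <- make_aln(A = "-", B = "-", C = "-", D = "-")
  g3 <- reconstruct_gap_states(tr, aln3)
  expect_false(any(g3[, 1]))
})

test_that("MAP extraction applies gap masks, tie-breaks, and meanPP rules", {
  tr <- read_newick("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  m <- aa_model("LG")
  aln <- make_aln(A = "MK-", B = "MK-", C = "MR-", D = "MR-")
  post <- marginal_posteriors(tr, aln, m)
  gaps <- reconstruct_gap_states(tr, aln)
  root_id <- length(tr$tip.label) + 1
  ms <- extract_map_sequence(post, gaps, label_nodes(tr)$paml[root_id])
  expect_equal(nchar(ms$sequence), 3)
  expect_identical(substr(ms$sequence, 3, 3), "-")
  expect_identical(substr(ms$sequence, 1, 1), "M")
  ## meanPP averages max posterior over present columns only
  key <- ms$id
  expect_equal(ms$mean_pp, mean(post[[key]]$max_pp[1:2]))
  expect_error(extract_map_sequence(post, gaps, 999), "unknown node")

  ## hand-built posteriors: uniform -> meanPP 0.05; 0.6/0.4 -> MAP by max
  fake <- post
  fake[[key]]$probs[] <- 1 / 20
  fake[[key]]$max_pp <- apply(fake[[key]]$probs, 1, max)
  fake[[key]]$map <- apply(fake[[key]]$probs, 1, function(p)
    sort(protasr::AA_CODES[p >= max(p) - 1e-12])[1])
  ms2 <- extract_map_sequence(fake, gaps, post[[key]]$node)
  expect_equal(ms2$mean_pp, 0.05)
  expect_identical(substr(ms2$sequence, 1, 1), "A")   # alphabetical tie-break
})

test_that("PAML-style labels: ladder-tree example, stability, MRCA addressing", {
  nw <- "((((A:1,B:1):1,C:1):1,D:1):1,E:1);"
  tr <- read_newick(nw)
  lab <- label_nodes(tr)
  expect_identical(lab$table$label[1:5], c("A", "B", "C", "D", "E"))
  expect_identical(lab$table$id[1:5], 1:5)
  internals <- lab$table[lab$table$type == "internal", ]
  expect_identical(internals$id, 6:9)
  ## root is node 6; the AB cherry is the deepest, node 9
  expect_identical(internals$tips[internals$id == 6], "A,B,C,D,E")
  expect_identical(internals$tips[internals$id == 9], "A,B")
  ## stable across re-parses of the same text
  lab2 <- label_nodes(read_newick(nw))
  expect_identical(lab$table, lab2$table)
  expect_equal(mrca_node(tr, c("A", "B")), 9)
  expect_equal(mrca_node(tr, c("A", "C")), 8)
  expect_equal(mrca_node(tr, c("A", "E")), 6)
})

test_that("reconstruction recovers simulated ancestors with calibrated confidence", {
  tr <- random_tree(8, c(0.1, 0.1), seed = 89)
  m <- aa_model("LG", alpha = 1, k = 4)
  sim <- simulate_alignment(tr, m, 400, seed = 97)
  asr <- ancestral_reconstruction(tr, sim$alignment, m)
  accs <- c(); pps <- c()
  for (id in names(asr$sequences)) {
    truth <- strsplit(sim$ancestors[[id]], "")[[1]]
    est <- strsplit(asr$sequences[[id]], "")[[1]]
    accs <- c(accs, mean(truth == est))
    pps <- c(pps, asr$mean_pp[[id]])
  }
  expect_gte(mean(accs), 0.85)
  ## meanPP tracks realised accuracy
  expect_lt(abs(mean(pps) - mean(accs)), 0.05)
})
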