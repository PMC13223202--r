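test_that("ligand contacts respect the cutoff and are monotone in it", {
  s <- synthetic_structure(
    residues = data.frame(resno = c(10, 20, 30), atoms = c(4, 4, 4)),
    ligand = list(name = "DMF", atoms = 3,
                  dists = list(`10` = 3.9, `20` = 4.1)))
  cs <- ligand_contacts(s, "DMF", cutoff = 4.0)
  expect_identical(cs$resno, 10L)
  expect_equal(cs$min_dist, 3.9, tolerance = 0.01)
  wider <- ligand_contacts(s, "DMF", cutoff = 4.5)
  expect_true(all(cs$reskey %in% wider$reskey))
  expect_setequal(wider$resno, c(10L, 20L))
  expect_error(ligand_contacts(s, "ATP", 4), "absent")
})

test_that("residue contact pairs report minimum distances within cutoff", {
  s <- synthetic_structure(
    residues = data.frame(resno = 1:4, atoms = rep(3, 4)),
    contacts = data.frame(i = c(1, 2), j = c(3, 4), dist = c(5.9, 6.1)))
  hit <- residue_contact_pairs(s, 1, 3, cutoff = 6)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$min_dist, 5.9, tolerance = 0.01)
  expect_equal(nrow(residue_contact_pairs(s, 2, 4, cutoff = 6)), 0)
  ## whole chain against itself: symmetric pair list
  all_pairs <- residue_contact_pairs(s, 1:4, 1:4, cutoff = 6)
  key <- paste(pmin(all_pairs$resA, all_pairs$resB),
               pmax(all_pairs$resA, all_pairs$resB))
  expect_true(all(table(key) == 2))
  expect_error(residue_contact_pairs(s, 99, 1, 6), "resolve")
})

test_that("PSN strengths follow I = 100 n / sqrt(Ni Nj) with conventions", {
  ## hand-placed structure: residues 1 and 3, 4 side-chain atoms each,
  ## exactly 2 atom pairs within 3 A
  f <- withr::local_tempfile(fileext = ".pdb")
  at <- function(serial, name, res, resno, x, y = 0, el = "C")
    sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "ATOM", serial, name, res, resno, x, y, 0, 1, 0, el)
  writeLines(c(
    at(1, "CB", "ALA", 1, 0.0), at(2, "CG", "ALA", 1, 1.0),
    at(3, "CD", "ALA", 1, -20.0), at(4, "CE", "ALA", 1, -21.0),
    at(5, "CB", "ALA", 3, 1.0, 2.9), at(6, "CG", "ALA", 3, 0.0, 2.9),
    at(7, "CD", "ALA", 3, 30.0), at(8, "CE", "ALA", 3, 31.0),
    "END"), f)
  s <- read_pdb(f)
  net <- build_psn(s, atom_cutoff = 3, i_min = 0)
  ## within 3 A: (1,0)-(1,2.9) and (0,0)-(0,2.9); the diagonals are 3.07
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$n_pairs, 2)
  expect_equal(net$edges$strength, 50)
  ## i_min above the maximum strength: empty edge set
  expect_equal(nrow(build_psn(s, atom_cutoff = 3, i_min = 60)$edges), 0)
  ## normalisation override changes the denominator
  net2 <- build_psn(s, atom_cutoff = 3, norm = c(ALA = 25))
  expect_equal(net2$edges$strength, 100 * 2 / 25)
})

test_that("glycine nodes keep only the C-alpha; sequence neighbours excluded", {
  f <- withr::local_tempfile(fileext = ".pdb")
  at <- function(serial, name, res, resno, x, el = "C")
    sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "ATOM", serial, name, res, resno, x, 0, 0, 1, 0, el)
  writeLines(c(
    at(1, "N", "GLY", 1, 0, "N"), at(2, "CA", "GLY", 1, 0.5),
    at(3, "C", "GLY", 1, 1.0), at(4, "O", "GLY", 1, 1.2, "O"),
    at(5, "CA", "ALA", 2, 1.5), at(6, "CB", "ALA", 2, 2.0),
    "END"), f)
  net <- build_psn(read_pdb(f), atom_cutoff = 3)
  expect_equal(net$nodes$n_atoms[net$nodes$resname == "GLY"], 1L)
  ## residues 1 and 2 are sequence neighbours: no edge despite proximity
  expect_equal(nrow(net$edges), 0)
})

test_that("communication paths match exhaustive enumeration on random networks", {
  for (seed in 1:30) {
    net <- random_network(sample(5:12, 1), seed + 300)
    nodes <- net$nodes$reskey
    src <- nodes[1]; tgt <- nodes[length(nodes)]
    mine <- communication_paths(net, src, tgt)
    oracle <- brute_best_path(net, src, tgt)
    if (is.null(oracle)) {
      expect_equal(length(mine$paths), 0)
    } else {
      expect_equal(length(mine$paths), 1)
      expect_identical(mine$paths[[1]], oracle)
    }
  }
})

test_that("via-constrained paths visit the constraint and stay simple", {
  ## line 1-2-3-4-5 with shortcut 1-5; via 3 forces the long way
  net <- make_network(data.frame(
    res_i = c(1, 2, 3, 4, 1), res_j = c(2, 3, 4, 5, 5),
    strength = c(10, 10, 10, 10, 99)))
  free <- communication_paths(net, 1, 5)
  expect_identical(free$paths[[1]], c("1", "5"))
  via <- communication_paths(net, 1, 5, via = 3)
  expect_identical(via$paths[[1]], as.character(1:5))
  expect_false(anyDuplicated(via$paths[[1]]) > 0)
  ## absent via node: empty set with a warning
  expect_warning(empty <- communication_paths(net, 1, 5, via = 77), "absent")
  expect_equal(length(empty$paths), 0)
  ## disconnected target: warning, empty
  net2 <- make_network(data.frame(res_i = c(1, 3), res_j = c(2, 4),
                                  strength = c(1, 1)))
  expect_warning(none <- communication_paths(net2, 1, 4), "no path")
  expect_equal(length(none$paths), 0)
})

test_that("reached targets are the de-duplicated union over paths", {
  net <- make_network(data.frame(
    res_i = c(1, 1, 2, 3), res_j = c(2, 3, 4, 5), strength = c(5, 5, 5, 5)))
  ps <- communication_paths(net, 1, c(4, 5))
  expect_identical(reached_targets(ps, c(4, 5)), c("4", "5"))
  expect_identical(reached_targets(ps, c(4, 5, 9)), c("4", "5"))
  empty <- structure(list(paths = list(), strengths = numeric(),
                          sources = "1", targets = "9", via = character()),
                     class = "path_set")
  expect_identical(reached_targets(empty, c(4, 5)), character(0))
  ## brute-force union identity
  expect_identical(reached_targets(ps, 1:9),
                   sort(intersect(as.character(1:9), unique(unlist(ps$paths)))))
})
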