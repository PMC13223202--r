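test_that("FASTA reading normalises case, takes first header token, validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a some description", "mkv", ">b", "MK-X"), f)
  seqs <- read_fasta(f)
  expect_identical(seqs, c(a = "MKV", b = "MK-X"))

  writeLines(c(">a", "MKV", ">a", "MKL"), f)
  expect_error(read_fasta(f), "duplicate ids")

  writeLines(c(">a", "MKO"), f)          # 'O' is not a legal residue
  expect_error(read_fasta(f), "illegal residue.*position 3")

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA round-trips random sequence sets exactly", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c(protasr::AA_CODES, "-", "X"), sample(5:120, 1),
                   replace = TRUE), collapse = ""), "")
    names(seqs) <- paste0("seq", seq_len(n), "_", rep)
    f <- tempfile(fileext = ".fa")
    write_fasta(seqs, f)
    expect_identical(read_fasta(f), seqs)
    unlink(f)
  }
})

test_that("PHYLIP interleaved honours the 10-char/60-column dialect", {
  f <- withr::local_tempfile(fileext = ".phy")
  writeLines(c(" 2 4", "A         MK-V", "B         MKAV"), f)
  aln <- read_phylip_interleaved(f)
  expect_equal(n_col(aln), 4)
  expect_identical(as.character(aln), c(A = "MK-V", B = "MKAV"))

  writeLines(c(" 3 4", "A         MK-V", "B         MKAV"), f)
  expect_error(read_phylip_interleaved(f), "3 taxa")

  ## name collision after truncation to the 10-character field
  set.seed(7)
  seqs <- c(x = "MKV", y = "MKL")
  names(seqs) <- c("abcdefghij_1", "abcdefghij_2")
  expect_error(write_phylip_interleaved(aa_alignment(seqs), f), "collide")
})

test_that("PHYLIP round-trips a multi-block alignment identically", {
  set.seed(11)
  seqs <- vapply(1:5, function(i)
    paste(sample(c(protasr::AA_CODES, "-"), 130, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("taxon", 1:5)
  aln <- aa_alignment(seqs, drop_gap_only_columns = FALSE)
  f <- withr::local_tempfile(fileext = ".phy")
  write_phylip_interleaved(aln, f)
  back <- read_phylip_interleaved(f)
  expect_identical(as.character(back), as.character(aln))
  ## blocks of 60: a 130-column alignment spans 3 blocks
  expect_gte(sum(!nzchar(readLines(f))), 2)
})

test_that("Newick wrapper enforces tree contracts", {
  tr <- read_newick("((A:1,B:2):1,C:3);")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)

  expect_error(read_newick("((A:1,B:2):1,A:3);"), "duplicate tip")
  expect_error(read_newick("((A:1,B:-2):1,C:3);"), "negative branch")

  ## lengths absent: parse succeeds, likelihood operations refuse
  tr2 <- read_newick("(A,B);")
  aln <- make_aln(A = "MK", B = "MK")
  expect_error(log_likelihood(tr2, aln, aa_model("LG")), "branch length")

  ## numeric internal labels become support values
  tr3 <- read_newick("((A:1,B:2)95:1,C:3);")
  expect_true(95 %in% tr3$support)
})

test_that("Newick round-trips topology and lengths on random trees", {
  for (seed in 1:20) {
    tr <- random_tree(sample(4:42, 1), c(0.01, 2), seed = seed)
    back <- read_newick(write_newick(tr))
    expect_same_topology(back, tr)
    expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  }
})

test_that("PAML .dat parsing validates counts and recovers LG exactly", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.5 0.5"), f)
  expect_error(read_exchangeability_dat(f), "expected 190")

  ## all-equal exchangeabilities + uniform frequencies
  lg <- aa_exchangeabilities("LG")
  Su <- matrix(1, 20, 20); diag(Su) <- 0
  write_exchangeability_dat(Su, rep(0.05, 20), f)
  u <- read_exchangeability_dat(f)
  expect_true(all(u$S[lower.tri(u$S)] == 1))
  expect_equal(unname(u$pi), rep(1 / 20, 20))

  ## LG written and re-read matches the library matrix; pi sums to 1
  write_exchangeability_dat(lg$S, lg$pi, f)
  back <- read_exchangeability_dat(f)
  expect_equal(back$S, lg$S, tolerance = 1e-8)
  expect_equal(sum(back$pi), 1, tolerance = 1e-14)
  expect_identical(back$S, t(back$S))
})

test_that("PDB reader drops waters/hydrogens/altloc B and keys ligands", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      12.000  10.000  10.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1      12.500  10.000  10.000  1.00  0.00           H",
    "ATOM      4  CA AGLY A   2      15.000  10.000  10.000  1.00  0.00           C",
    "ATOM      5  CA BGLY A   2      15.200  10.000  10.000  1.00  0.00           C",
    "ATOM      6  CA  SER A   2A     18.000  10.000  10.000  1.00  0.00           C",
    "HETATM    7  O   HOH A 101      30.000  10.000  10.000  1.00  0.00           O",
    "HETATM    8  C1  DMF A 201      40.000  10.000  10.000  1.00  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 5)                  # H, HOH, altloc B removed
  expect_identical(s$ligands, "DMF")
  expect_true("2A" %in% s$atoms$reskey)           # insertion code in the key
  expect_equal(sum(s$atoms$het), 1)
})

test_that("residue-number maps round-trip on non-gap columns", {
  set.seed(23)
  for (rep in 1:30) {
    chars <- sample(c(protasr::AA_CODES, "-"), 40, replace = TRUE,
                    prob = c(rep(1, 20), 8))
    chars[1] <- "M"                                # at least one residue
    aln <- make_aln(a = paste(chars, collapse = ""),
                    b = paste(rev(chars), collapse = ""))
    m <- residue_number_map(aln, "a")
    nongap <- which(!is.na(m$col_to_res))
    expect_identical(m$res_to_col[m$col_to_res[nongap]], nongap)
    expect_true(all(diff(m$res_to_col) > 0))
  }
})
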