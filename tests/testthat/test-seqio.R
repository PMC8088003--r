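test_that("FASTA parsing validates and normalizes", {
  msa <- read_fasta(tmpfile_with(c(">A", "ACGT", ">B", "ACGA"), ".fasta"))
  expect_s3_class(msa, "nr_msa")
  expect_equal(msa$labels, c("A", "B"))
  expect_equal(ncol(msa$seq), 4L)

  lower <- read_fasta(tmpfile_with(c(">A", "acgt", ">B", "acga"), ".fasta"))
  expect_equal(paste(lower$seq[1, ], collapse = ""), "ACGT")

  expect_error(read_fasta(tmpfile_with(c(">A", "ACG", ">B", "ACGT"), ".fasta")),
               "not aligned")
  expect_error(read_fasta(tmpfile_with(c(">A", "ACGT", ">A", "ACGA"), ".fasta")),
               "duplicate")
  expect_error(read_fasta(tmpfile_with(c(">A", "ACQT", ">B", "ACGA"), ".fasta")),
               "unknown sequence characters")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("PHYLIP parsing handles strict and relaxed dialects", {
  msa <- read_phylip(tmpfile_with(c(" 2 4", "A ACGT", "B ACGA"), ".phy"))
  expect_equal(msa$labels, c("A", "B"))
  expect_equal(ncol(msa$seq), 4L)

  # strict dialect: 10-character name field, no separator before sequence
  strict <- read_phylip(tmpfile_with(
    c("2 4", "taxon_a   ACGT", "taxon_b   ACGA"), ".phy"))
  expect_equal(strict$labels, c("taxon_a", "taxon_b"))

  # multi-line sequences
  multi <- read_phylip(tmpfile_with(
    c("2 8", "A ACGT", "ACGT", "B ACGA", "ACGA"), ".phy"))
  expect_equal(ncol(multi$seq), 8L)

  expect_error(read_phylip(tmpfile_with(c(" 3 4", "A ACGT", "B ACGA"), ".phy")),
               "fewer records")
  expect_error(read_phylip(tmpfile_with(c(" 2 5", "A ACGT", "B ACGA"), ".phy")),
               "disagrees")
})

test_that("FASTA and PHYLIP inputs give identical alignments", {
  f <- read_fasta(tmpfile_with(c(">A", "ACGTN-RY", ">B", "ACGAACGT"), ".fasta"))
  p <- read_phylip(tmpfile_with(c("2 8", "A ACGTN-RY", "B ACGAACGT"), ".phy"))
  expect_identical(f$seq, p$seq)
  expect_identical(read_msa(tmpfile_with(c(">A", "ACGT", ">B", "ACGA")))$seq,
                   read_msa(tmpfile_with(c("2 4", "A ACGT", "B ACGA")))$seq)
})

test_that("pattern compression merges identical columns deterministically", {
  m <- msa_from(c("A", "B"), c("AAAA", "AAAA"))
  pm <- compress_patterns(m)
  expect_equal(ncol(pm$patterns), 1L)
  expect_equal(pm$weights, 4L)

  m2 <- msa_from(c("A", "B"), c("ACGT", "AAAA"))
  pm2 <- compress_patterns(m2)
  expect_equal(ncol(pm2$patterns), 4L)
  expect_equal(pm2$weights, rep(1L, 4))

  # first-occurrence order
  m3 <- msa_from(c("A", "B"), c("AGAG", "CTCT"))
  pm3 <- compress_patterns(m3)
  expect_equal(pm3$patterns[1, ], c("A", "G"))
})

test_that("pattern weights always sum to the alignment length", {
  for (seed in 1:5) {
    fx <- sim_fixture(5, 73, seed)
    pm <- compress_patterns(fx$msa)
    expect_equal(sum(pm$weights), 73L)
    expect_false(anyDuplicated(apply(pm$patterns, 2, paste, collapse = "")) > 0)
  }
})

test_that("likelihood on compressed patterns equals raw-alignment likelihood", {
  fx <- sim_fixture(4, 60, 42)
  rooted <- fx$rooted
  ll_raw <- log_likelihood(rooted, fx$model, fx$msa)
  ll_pat <- log_likelihood(rooted, fx$model, compress_patterns(fx$msa))
  expect_equal(ll_pat, ll_raw, tolerance = 1e-12)
})

test_that("ambiguity codes act as partial unknowns in the likelihood", {
  # N / gap tips carry no information: LL with an all-N taxon equals the
  # LL marginalized over that taxon's states, i.e. finite and well-defined
  tree <- parse_newick("((A:0.1,B:0.2):0.1,C:0.3,D:0.2);")
  m <- msa_from(c("A", "B", "C", "D"), c("ACGT", "ACGT", "NN-N", "ACGA"))
  ll <- log_likelihood(place_root(tree, 1, 0.5), default_params(), m)
  expect_true(is.finite(ll))
  # R = A or G: likelihood must lie between the A-only and the sum of both
  mR <- msa_from(c("A", "B", "C", "D"), c("A", "A", "A", "R"))
  mA <- msa_from(c("A", "B", "C", "D"), c("A", "A", "A", "A"))
  mG <- msa_from(c("A", "B", "C", "D"), c("A", "A", "A", "G"))
  p <- default_params()
  r <- place_root(tree, 1, 0.5)
  expect_equal(exp(log_likelihood(r, p, mR)),
               exp(log_likelihood(r, p, mA)) + exp(log_likelihood(r, p, mG)),
               tolerance = 1e-12)
})
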