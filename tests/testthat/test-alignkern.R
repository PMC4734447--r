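test_that("global alignment handles identity, gaps, and symmetry", {
  al <- globalAlign("ACGT", "ACGT")
  expect_equal(identityPercent(al), 100)
  expect_equal(al@alnLen, 4L)

  al <- globalAlign("ACGT", "AGT")
  expect_equal(al@alnLen, 4L)
  expect_equal(al@nIdentical, 3L)

  set.seed(11)
  for (i in 1:5) {
    a <- rndSeq(60); b <- rndSeq(55)
    expect_equal(identityPercent(globalAlign(a, b)),
                 identityPercent(globalAlign(b, a)))
  }
})

test_that("nucleotide local alignment is exact on self and strands", {
  set.seed(12)
  s <- rndSeq(300)
  al <- localAlignNt(s, s)
  expect_equal(identityPercent(al), 100)
  expect_equal(c(al@queryStart, al@queryEnd), c(0L, 300L))
  expect_equal(c(al@subjectStart, al@subjectEnd), c(0L, 300L))
  expect_equal(al@strand, "+")

  rc <- GenomicTaxonomy:::cpp_revcomp(s)
  al <- localAlignNt(rc, s)
  expect_equal(identityPercent(al), 100)
  expect_equal(al@strand, "-")

  # too short for a seed
  expect_null(localAlignNt("ACGT", "ACGT", k = 11))
})

test_that("seed-and-extend matches exhaustive DP on small instances", {
  set.seed(13)
  n_checked <- 0
  for (i in 1:60) {
    la <- sample(50:400, 1); lb <- sample(50:400, 1)
    a <- rndSeq(la)
    b <- if (i %% 2) mutateSeq(substr(a, 1, min(la, lb)), 0.08)
         else rndSeq(lb)
    oracle <- bioLocalAlign(a, b)
    al <- localAlignNt(a, b)
    if (is.null(al)) next        # no seed: nothing to compare
    n_checked <- n_checked + 1
    # small subjects are fully covered, so the result is exact SW
    expect_equal(al@score, Biostrings::score(oracle))
  }
  expect_gte(n_checked, 25)
})

test_that("planted 5% substitutions recover near-oracle identity", {
  set.seed(14)
  for (i in 1:5) {
    a <- rndSeq(300)
    b <- mutateSeq(a, 0.05)
    al <- localAlignNt(a, b)
    oracle <- bioLocalAlign(a, b)
    oid <- 100 * Biostrings::nmatch(oracle) /
      (Biostrings::nmatch(oracle) + Biostrings::nmismatch(oracle))
    expect_lte(abs(identityPercent(al) - oid), 2)
  }
})

test_that("protein SW equals the exhaustive DP oracle", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
           "P","S","T","W","Y","V")
  set.seed(15)
  for (i in 1:20) {
    p1 <- paste(sample(aas, sample(40:200, 1), TRUE), collapse = "")
    p2 <- paste(sample(aas, sample(40:200, 1), TRUE), collapse = "")
    al <- localAlignAa(p1, p2)
    oracle <- Biostrings::pairwiseAlignment(
      p1, p2, type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = 11, gapExtension = 1)
    if (is.null(al)) {
      expect_lte(Biostrings::score(oracle), 0)
    } else {
      expect_equal(al@score, Biostrings::score(oracle))
    }
  }
})

test_that("Karlin-Altschul statistics behave as published constants imply", {
  set.seed(16)
  p <- paste(sample(c("M","K","V","L","D","E"), 100, TRUE), collapse = "")
  al <- localAlignAa(p, p, dbSize = 1e6)
  expect_equal(identityPercent(al), 100)
  expect_lt(al@evalue, 1e-20)
  # bitscore monotone in raw score, evalue decreasing in bitscore
  sch <- scoringScheme("aa")
  scores <- c(20, 50, 100, 200)
  bits <- GenomicTaxonomy:::.bitscore(scores, sch)
  expect_true(all(diff(bits) > 0))
  evs <- GenomicTaxonomy:::.evalue(bits, 100, 1e6)
  expect_true(all(diff(evs) < 0))
})

test_that("score is invariant under joint reverse complement", {
  set.seed(17)
  for (i in 1:5) {
    a <- rndSeq(200); b <- mutateSeq(a, 0.1)
    al1 <- localAlignNt(a, b)
    al2 <- localAlignNt(GenomicTaxonomy:::cpp_revcomp(a),
                        GenomicTaxonomy:::cpp_revcomp(b))
    expect_equal(al1@score, al2@score)
  }
})

test_that("scoring scheme validates its invariants", {
  expect_error(scoringScheme("nt", gapOpen = 1, gapExtend = 5), "gapOpen")
  expect_error(scoringScheme("nt", lambda = -1), "Karlin")
  s <- scoringScheme("nt")
  expect_equal(c(s@lambda, s@K), c(1.28, 0.46))
  s <- scoringScheme("aa")
  expect_equal(c(s@lambda, s@K), c(0.267, 0.041))
})
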