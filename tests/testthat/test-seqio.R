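test_that("readFasta parses headers, wraps lines, and validates", {
  tf <- writeTempFasta(c(">g1", "ACGT"))
  x <- readFasta(tf, "nt")
  expect_equal(as.character(x), c(g1 = "ACGT"))

  tf <- writeTempFasta(c(">a x", "AC", "GT", ">b", "NN"))
  x <- readFasta(tf, "nt")
  expect_equal(as.character(x), c(a = "ACGT", b = "NN"))

  tf <- writeTempFasta(c(">a", "ACGT", ">a", "ACGT"))
  expect_error(readFasta(tf, "nt"), "duplicate.*'a'")

  tf <- writeTempFasta(character(0))
  expect_error(readFasta(tf, "nt"), "no records")

  tf <- writeTempFasta(c(">a", "ACGJ"))
  expect_error(readFasta(tf, "nt"), "illegal character 'J' at position 4")

  tf <- writeTempFasta(c(">p", "MKV*"))
  expect_silent(readFasta(tf, "aa"))
  tf <- writeTempFasta(c(">p", "MKVU"))
  expect_error(readFasta(tf, "aa"), "illegal character")

  tf <- writeTempFasta(c(">lc", "acgtn"))
  expect_equal(as.character(readFasta(tf, "nt")), c(lc = "ACGTN"))
})

test_that("FASTA round trip preserves sequences byte-identically", {
  set.seed(4)
  seqs <- setNames(vapply(c(10, 61, 200), rndSeq, character(1)),
                   c("s1", "s2", "s3"))
  tf <- tempfile(fileext = ".fna")
  writeFasta(seqs, tf)
  expect_equal(as.character(readFasta(tf, "nt")), seqs)
})

test_that("genomeStats computes GC over unambiguous bases", {
  expect_equal(genomeStats(genome("g", c(c = "GGCC")))$gc_percent, 100)
  for (n in c(1, 3, 7))
    expect_equal(genomeStats(genome("g", c(c = strrep("ACGT", n))))$gc_percent,
                 50)
  g <- genome("g", c(c = "GGCCNNNN"))
  st <- genomeStats(g)
  expect_equal(st$gc_percent, 100)
  expect_equal(st$length_bp, 8L)
  expect_error(genomeStats(genome("g", c(c = "NNNN"))),
               "no unambiguous bases")
  # revcomp invariance
  set.seed(5)
  s <- rndSeq(1000, gc = 0.61)
  g1 <- genome("a", c(c = s))
  g2 <- genome("b", c(c = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))))
  expect_equal(genomeStats(g1)$gc_percent, genomeStats(g2)$gc_percent)
  # n_cds reported only with a proteome
  p <- proteome("a", c(p1 = "MK", p2 = "ML"))
  expect_equal(genomeStats(g1, p)$n_cds, 2L)
})

test_that("fragmentGenome tiles contigs and applies the remainder rule", {
  g <- genome("g", c(c1 = strrep("ACGT", 510)))        # 2040 bp
  fr <- fragmentGenome(g, 1020)
  expect_equal(length(fr), 2L)
  expect_equal(S4Vectors::mcols(fr)$start, c(0L, 1020L))
  expect_equal(S4Vectors::mcols(fr)$end, c(1020L, 2040L))

  g <- genome("g", c(c1 = strrep("ACGT", 625)))        # 2500 bp
  fr <- fragmentGenome(g, 1020)                        # 460 < 510 dropped
  expect_equal(length(fr), 2L)
  expect_equal(max(S4Vectors::mcols(fr)$end), 2040L)

  g <- genome("g", c(c1 = substr(strrep("ACGT", 400), 1, 1550)))
  fr <- fragmentGenome(g, 1020)                        # 530 >= 510 kept
  expect_equal(length(fr), 2L)
  expect_equal(Biostrings::width(fr), c(1020L, 530L))

  # disjoint, ordered, total <= genome length; never spans contigs
  set.seed(6)
  g <- genome("g", c(c1 = rndSeq(2750), c2 = rndSeq(900)))
  fr <- fragmentGenome(g, 1020)
  mc <- S4Vectors::mcols(fr)
  expect_true(sum(Biostrings::width(fr)) <= 3650)
  for (ct in unique(mc$contig_id)) {
    i <- mc$contig_id == ct
    expect_true(all(diff(mc$start[i]) > 0))
    expect_true(all(mc$start[i][-1] >= mc$end[i][-sum(i)]))
  }
  expect_error(fragmentGenome(g, 50), "fragLen")
})

test_that("proteome constructor enforces CDS/protein consistency", {
  expect_silent(proteome("g", c(a = "MK"), c(a = "ATGAAATAA")))
  expect_silent(proteome("g", c(a = "MK"), c(a = "ATGAAA")))
  expect_error(proteome("g", c(a = "MR"), c(a = "ATGAAATAA")),
               "does not translate")
  expect_error(proteome("g", c(a = "MK"), c(a = "ATGAAAT")),
               "divisible by 3")
})
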