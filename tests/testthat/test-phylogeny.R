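test_that("progressive MSA handles base cases and the ungap invariant", {
  seqs <- c(a = "MKVLIT", b = "MKVLIT", c = "MKVLIT")
  m <- progressiveMsa(seqs, scoringScheme("aa"))
  expect_equal(unname(alignedSeqs(m)), rep("MKVLIT", 3))

  # two sequences reduce to plain global alignment
  al <- globalAlign("ACGT", "AGT", scoringScheme("nt"),
                    queryId = "a", subjectId = "b")
  m2 <- progressiveMsa(c(a = "ACGT", b = "AGT"), scoringScheme("nt"))
  expect_equal(unname(alignedSeqs(m2)),
               c(al@alignedQuery, al@alignedSubject))

  set.seed(91)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
           "P","S","T","W","Y","V")
  for (i in 1:20) {
    base <- paste(sample(aas, 60, TRUE), collapse = "")
    seqs <- c(a = mutateAa(base, 0.1), b = mutateAa(base, 0.1),
              c = mutateAa(base, 0.1))
    m <- progressiveMsa(seqs, scoringScheme("aa"))
    expect_equal(gsub("-", "", alignedSeqs(m)), seqs)
    # label order of the output matches the input
    expect_equal(names(alignedSeqs(m)), names(seqs))
  }
})

test_that("back-translation maps columns to codons", {
  m <- msa(c(x = "M-K", y = "MGK"), "aa")
  bt <- backtranslate(m, c(x = "ATGAAA", y = "ATGGGTAAGTAA"))
  expect_equal(alignedSeqs(bt), c(x = "ATG---AAA", y = "ATGGGTAAG"))
  # gap-free alignment: concatenated codons, ungap reproduces the CDS
  m2 <- msa(c(x = "MK", y = "ML"), "aa")
  bt2 <- backtranslate(m2, c(x = "ATGAAATAA", y = "ATGCTG"))
  expect_equal(gsub("-", "", alignedSeqs(bt2)[["x"]]), "ATGAAA")
  expect_equal(nchar(alignedSeqs(bt2)[[1]]), 6L)
  expect_error(backtranslate(m2, c(x = "ATGAAAGGGTAA", y = "ATGCTG")),
               "length mismatch for 'x'")
  expect_error(backtranslate(m2, c(x = "ATGATTTAA", y = "ATGCTG")),
               "residue 2")
})

test_that("concatenation preserves labels, widths, and gene maps", {
  m1 <- msa(c(a = "AAA", b = "AAC"), "nt")
  m2 <- msa(c(a = "GGGG", b = "G-GG"), "nt")
  cc <- concatenateMsa(list(x = m1, y = m2))
  expect_equal(nchar(alignedSeqs(cc)[[1]]), 7L)
  expect_equal(cc@genes$end - cc@genes$start, c(3L, 4L))
  single <- concatenateMsa(list(only = m1))
  expect_equal(alignedSeqs(single), alignedSeqs(m1))
  m3 <- msa(c(a = "AA", z = "AA"), "nt")
  expect_error(concatenateMsa(list(m1, m3)), "label mismatch")
  # permuting gene order changes columns but not the distance matrix
  set.seed(92)
  blocks <- lapply(1:4, function(i) {
    s <- rndSeq(120)
    msa(c(a = s, b = mutateSeq(s, 0.1), c = mutateSeq(s, 0.15)), "nt")
  })
  names(blocks) <- paste0("g", 1:4)
  d1 <- tajimaNei(concatenateMsa(blocks))
  d2 <- tajimaNei(concatenateMsa(blocks[c(3, 1, 4, 2)]))
  expect_equal(d1, d2[rownames(d1), colnames(d1)])
})

test_that("Tajima-Nei matches the closed form and its properties", {
  expect_equal(tajimaNei(msa(c(a = "ACGTACGT", b = "ACGTACGT"), "nt"))["a", "b"],
               0)
  # two-row toy: 100 columns, 10 mismatches, near-uniform composition;
  # expected value computed independently from the published formula
  set.seed(93)
  a <- strsplit(strrep("ACGT", 25), "")[[1]]
  b <- a
  pos <- seq(1, 100, by = 10)
  for (i in pos) b[i] <- c(A = "C", C = "G", G = "T", T = "A")[a[i]]
  m <- msa(c(x = paste(a, collapse = ""), y = paste(b, collapse = "")), "nt")
  D <- tajimaNei(m)
  # independent scalar computation
  L <- 100; p <- 10 / 100
  cnt <- table(factor(c(a, b), c("A", "C", "G", "T")))
  gg <- as.numeric(cnt) / (2 * L)
  key <- ifelse(a[pos] < b[pos], paste0(a[pos], b[pos]),
                paste0(b[pos], a[pos]))
  x <- as.numeric(table(factor(key, c("AC","AG","AT","CG","CT","GT")))) / L
  gprod <- c(gg[1]*gg[2], gg[1]*gg[3], gg[1]*gg[4], gg[2]*gg[3],
             gg[2]*gg[4], gg[3]*gg[4])
  h <- sum(x^2 / (2 * gprod))
  bb <- 0.5 * (1 - sum(gg^2) + p^2 / h)
  expect_equal(D["x", "y"], -bb * log(1 - p / bb), tolerance = 1e-9)
  # correction inflates relative to the p-distance
  expect_gte(D["x", "y"], p)
  # column permutation invariance
  perm <- sample(100)
  m2 <- msa(c(x = paste(a[perm], collapse = ""),
              y = paste(b[perm], collapse = "")), "nt")
  expect_equal(tajimaNei(m2)["x", "y"], D["x", "y"])
  # saturation reports NA with a warning
  sat <- msa(c(x = strrep("A", 40), y = strrep("C", 40)), "nt")
  expect_warning(Ds <- tajimaNei(sat), "saturated")
  expect_true(is.na(Ds["x", "y"]))
})

test_that("neighbor-joining recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  dm <- ape::cophenetic.phylo(tr)
  nj1 <- njTree(dm)
  expect_equal(suppressMessages(phangorn::RF.dist(nj1, ape::unroot(tr))), 0)
  expect_equal(max(abs(ape::cophenetic.phylo(nj1)[rownames(dm), colnames(dm)]
                       - dm)), 0, tolerance = 1e-8)
  # three taxa: unique star with closed-form lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- njTree(d3)
  cp <- ape::cophenetic.phylo(t3)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(cp, d3, tolerance = 1e-8)
  # property: random additive trees, 5-10 taxa
  set.seed(94)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    dm <- ape::cophenetic.phylo(tr)
    nj2 <- njTree(dm)
    expect_equal(suppressMessages(phangorn::RF.dist(nj2, ape::unroot(tr))), 0)
    expect_equal(max(abs(ape::cophenetic.phylo(nj2)[rownames(dm),
                                                    colnames(dm)] - dm)),
                 0, tolerance = 1e-8)
  }
  # label permutation yields an isomorphic tree
  dmp <- dm[rev(rownames(dm)), rev(colnames(dm))]
  expect_equal(suppressMessages(phangorn::RF.dist(njTree(dmp), nj2)), 0)
  expect_error(njTree(dm[1:2, 1:2]), ">= 3")
  dmBad <- dm; dmBad[1, 2] <- dmBad[2, 1] <- Inf
  expect_error(njTree(dmBad), "non-finite")
})

test_that("bootstrap supports are seeded, bounded, and sensible", {
  set.seed(95)
  base <- rndSeq(600)
  clade1 <- lapply(1:3, function(i) mutateSeq(base, 0.02))
  base2 <- mutateSeq(base, 0.15)
  clade2 <- lapply(1:3, function(i) mutateSeq(base2, 0.02))
  rows <- c(setNames(clade1, paste0("a", 1:3)),
            setNames(clade2, paste0("b", 1:3)))
  m <- msa(unlist(rows), "nt")
  bt1 <- bootstrapTree(m, nReps = 1, seed = 7)
  sup <- as.numeric(bt1$node.label[bt1$node.label != ""])
  expect_true(all(sup %in% c(0, 100)))
  bt2 <- bootstrapTree(m, nReps = 25, seed = 8)
  bt3 <- bootstrapTree(m, nReps = 25, seed = 8)
  expect_equal(bt2$node.label, bt3$node.label)
  expect_equal(ape::write.tree(bt2), ape::write.tree(bt3))
  # the deep a/b split should be strongly supported
  sp <- GenomicTaxonomy:::.splitKeys(bt2)
  deep <- which(sp$keys == paste(sort(paste0("b", 1:3)), collapse = "|"))
  sup2 <- as.numeric(bt2$node.label[bt2$node.label != ""])
  expect_gte(max(sup2), 95)
})

test_that("Newick output round-trips topology and supports", {
  set.seed(96)
  tr <- ape::rtree(6)
  tf <- tempfile(fileext = ".nwk")
  writeNewick(tr, tf)
  tr2 <- ape::read.tree(tf)
  expect_equal(suppressMessages(phangorn::RF.dist(tr, tr2)), 0)
  expect_equal(tr2$edge.length,
               as.numeric(sprintf("%.6g", tr$edge.length)),
               tolerance = 1e-5)
})
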