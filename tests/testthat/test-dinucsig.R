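test_that("profiles match the brute-force counter", {
  g <- genome("g", c(c1 = strrep("ACGT", 150)))
  p <- dinucProfile(g)
  expect_equal(rhoValues(p), bruteDinucRho(strrep("ACGT", 150)),
               tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(200:800, 1)
    seqs <- vapply(seq_len(sample(1:3, 1)), function(j)
      rndSeq(n, gc = runif(1, 0.3, 0.7)), character(1))
    names(seqs) <- paste0("c", seq_along(seqs))
    p <- dinucProfile(genome("g", seqs))
    expect_equal(rhoValues(p), bruteDinucRho(unname(seqs)),
                 tolerance = 1e-12)
  }
})

test_that("profiles are strand- and duplication-invariant", {
  set.seed(32)
  s <- rndSeq(2000, gc = 0.6)
  g <- genome("g", c(c = s))
  grc <- genome("g", c(c = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))))
  expect_equal(rhoValues(dinucProfile(g)), rhoValues(dinucProfile(grc)))
  gdup <- genome("g", c(c1 = s, c2 = s))
  expect_equal(rhoValues(dinucProfile(g)), rhoValues(dinucProfile(gdup)))
})

test_that("rho is undefined when a base is absent", {
  # counting is strand-symmetrized, so only a complementary pair of
  # bases can be jointly absent
  expect_error(dinucProfile(genome("g", c(c = "AATTAATTAA"))),
               "rho undefined")
})

test_that("delta is a scaled L1 metric on profiles", {
  set.seed(33)
  ps <- lapply(1:3, function(i)
    dinucProfile(genome(paste0("g", i),
                        c(c = rndSeq(3000, gc = 0.3 + 0.15 * i)))))
  expect_equal(deltaDistance(ps[[1]], ps[[1]]), 0)
  d12 <- deltaDistance(ps[[1]], ps[[2]])
  expect_equal(d12, deltaDistance(ps[[2]], ps[[1]]))
  d13 <- deltaDistance(ps[[1]], ps[[3]])
  d23 <- deltaDistance(ps[[2]], ps[[3]])
  expect_lte(d13, d12 + d23 + 1e-12)
  expect_equal(deltaDistance(ps[[1]], ps[[2]], times1000 = TRUE),
               1000 * d12)
})

test_that("compositionally distinct simulated genomes exceed the 0.01 cutoff", {
  cfgA <- simConfig(seed = 34, ancestorLength = 60000L, gcTarget = 0.40,
                    nGenes = 20L,
                    geneLengthCodons = c(min = 80L, mode = 150L,
                                         max = 250L), p = 0)
  cfgB <- simConfig(seed = 35, ancestorLength = 60000L, gcTarget = 0.65,
                    nGenes = 20L,
                    geneLengthCodons = c(min = 80L, mode = 150L,
                                         max = 250L), p = 0)
  gA <- makeAncestor(cfgA)$genome
  gB <- makeAncestor(cfgB)$genome
  d <- deltaDistance(dinucProfile(gA), dinucProfile(gB))
  expect_gt(d, 0.01)
  # signature stability: two halves of one genome are closer than
  # genomes of different composition
  sA <- as.character(contigs(gA)[[1]])
  h1 <- dinucProfile(genome("h1", c(c = substr(sA, 1, 30000))))
  h2 <- dinucProfile(genome("h2", c(c = substr(sA, 30001, 60000))))
  expect_lt(deltaDistance(h1, h2), d)
})
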