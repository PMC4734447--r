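test_that("the generator is deterministic and hits its GC target", {
  cfg <- simConfig(seed = 111, ancestorLength = 60000L, nGenes = 20L,
                   geneLengthCodons = c(min = 80L, mode = 150L,
                                        max = 250L), gcTarget = 0.5,
                   p = 0.05)
  a1 <- makeAncestor(cfg)
  a2 <- makeAncestor(cfg)
  expect_equal(as.character(contigs(a1$genome)),
               as.character(contigs(a2$genome)))
  expect_lte(abs(genomeStats(a1$genome)$gc_percent - 50), 1)
  # planted CDS translate to the emitted proteome
  expect_equal(unname(GenomicTaxonomy:::.translateBatch(
    as.character(cdsSeqs(a1$proteome)))),
    unname(as.character(proteins(a1$proteome))))
  # genes are in-frame, non-overlapping, ATG...stop
  g <- a1$genes
  expect_true(all((g$end - g$start) %% 3 == 0))
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  cds <- as.character(cdsSeqs(a1$proteome))
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  expect_true(all(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA")))
  expect_error(makeAncestor(simConfig(1, ancestorLength = 10000L,
                                      nGenes = 50L)),
               "infeasible packing")
})

test_that("flat divergence realizes p and keeps ortholog pairing", {
  ev <- simPair(0.05)
  expect_lte(abs(ev$truth$identity["g1", "g2"] - 0.95), 0.005)
  expect_equal(sort(ev$truth$ortholog_pairs),
               sort(names(proteins(ev$proteomes$g1))))
  expect_equal(sort(ev$truth$ortholog_pairs),
               sort(names(proteins(ev$proteomes$g2))))
})

test_that("zero-length branches copy the ancestor exactly", {
  cfg <- simConfig(seed = 112, ancestorLength = 30000L, nGenes = 10L,
                   geneLengthCodons = c(min = 80L, mode = 120L,
                                        max = 180L),
                   tree = "(x:0,y:0.1);")
  anc <- makeAncestor(cfg)
  ev <- evolveGenomes(anc, cfg)
  expect_equal(as.character(contigs(ev$genomes$x)[[1]]),
               as.character(contigs(anc$genome)[[1]]))
  expect_equal(unname(ev$truth$branch_substitutions["x"]), 0)
})

test_that("realized substitutions concentrate around branch lengths", {
  lens <- c(0.02, 0.1, 0.3)
  cfg <- simConfig(seed = 113, ancestorLength = 60000L, nGenes = 15L,
                   geneLengthCodons = c(min = 80L, mode = 150L,
                                        max = 250L),
                   tree = sprintf("(a:%g,b:%g,c:%g);", lens[1], lens[2],
                                  lens[3]))
  anc <- makeAncestor(cfg)
  ev <- evolveGenomes(anc, cfg)
  L <- 60000
  for (i in seq_along(lens)) {
    t <- lens[i]
    # per-branch events follow the multiple-hit-corrected change rate
    pChange <- 3 / 4 * (1 - exp(-4 * t / 3))
    n <- unname(ev$truth$branch_substitutions[c("a", "b", "c")[i]])
    sd <- sqrt(L * pChange * (1 - pChange))
    expect_lte(abs(n - L * pChange), 3 * sd + 1)
  }
})

test_that("pairwise identity matches the Jukes-Cantor expectation", {
  cfg <- simConfig(seed = 114, ancestorLength = 100000L, nGenes = 20L,
                   geneLengthCodons = c(min = 80L, mode = 150L,
                                        max = 250L),
                   tree = "(A:0.025,B:0.025);")
  ev <- evolveGenomes(makeAncestor(cfg), cfg)
  expected <- 100 * (0.25 + 0.75 * exp(-4 * 0.05 / 3))
  expect_lte(abs(100 * ev$truth$identity["A", "B"] - expected), 0.5)
})

test_that("indels respect protected gene boundaries", {
  cfg <- simConfig(seed = 115, ancestorLength = 30000L, nGenes = 8L,
                   geneLengthCodons = c(min = 80L, mode = 120L,
                                        max = 180L),
                   p = 0.02, indelRate = 2e-4)
  anc <- makeAncestor(cfg)
  ev <- evolveGenomes(anc, cfg)
  g2 <- ev$genes$g2
  # genome length changed by indels but every gene still starts ATG
  cds <- as.character(cdsSeqs(ev$proteomes$g2))
  expect_true(all(substr(cds, 1, 3) == "ATG" |
                  grepl("\\*", as.character(proteins(ev$proteomes$g2)))))
  expect_true(all(g2$end > g2$start))
})

test_that("fixture suites are reproducible on disk and match their truth", {
  d1 <- tempfile("fx1"); d2 <- tempfile("fx2")
  fx1 <- fixtureSuite("two_species", d1, seed = 116)
  fx2 <- fixtureSuite("two_species", d2, seed = 116)
  for (f in c("g1.fna", "g2.fna", "g3.fna", "g1.faa", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$scenario, "two_species")
  expect_equal(sort(unlist(truth$genome_ids)), c("g1", "g2", "g3"))
  # the requested topology round-trips through the truth file
  tr <- ape::read.tree(text = truth$tree)
  expect_equal(sort(tr$tip.label), c("g1", "g2", "g3"))
  # the two_clades truth tree matches the requested 8-taxon topology
  d3 <- tempfile("fx3")
  fx3 <- fixtureSuite("two_clades", d3, seed = 117)
  truth3 <- jsonlite::read_json(file.path(d3, "truth.json"))
  tr3 <- ape::read.tree(text = truth3$tree)
  expect_equal(suppressMessages(phangorn::RF.dist(
    tr3, ape::read.tree(text = fx3$config$tree))), 0)
  expect_equal(length(fx3$evolved$genomes), 8L)
})
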