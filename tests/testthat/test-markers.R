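# small genome with a marker planted at a known spot
plantMarker <- function(ref, strand = "+", flank = 3000, seed = 51) {
  set.seed(seed)
  left <- rndSeq(flank); right <- rndSeq(flank)
  ins <- if (strand == "+") ref else GenomicTaxonomy:::cpp_revcomp(ref)
  genome("g", c(chr = paste0(left, ins, right)))
}

test_that("an exact planted copy is extracted verbatim", {
  set.seed(52)
  ref <- rndSeq(800)
  g <- plantMarker(ref, "+")
  h <- extractMarker(g, ref, "rrsA")
  expect_equal(h@seq, ref)
  expect_equal(h@identity, 100)
  expect_equal(h@strand, "+")
  expect_equal(c(h@start, h@end), c(3000L, 3800L))
})

test_that("minus-strand copies are reported in reference orientation", {
  set.seed(53)
  ref <- rndSeq(800)
  g <- plantMarker(ref, "-")
  h <- extractMarker(g, ref, "rrsA")
  expect_equal(h@seq, ref)
  expect_equal(h@strand, "-")
})

test_that("a 3%-diverged copy is found with matching identity", {
  set.seed(54)
  ref <- rndSeq(1000)
  g <- plantMarker(mutateSeq(ref, 0.03), "+")
  h <- extractMarker(g, ref, "gyrB")
  expect_lte(abs(h@identity - 97), 1)
  # idempotence: re-extracting from the extraction returns it unchanged
  h2 <- extractMarker(genome("x", c(c = h@seq)), ref, "gyrB")
  expect_equal(h2@seq, h@seq)
})

test_that("absent markers return NULL under the coverage floor", {
  set.seed(55)
  ref <- rndSeq(900)
  g <- genome("g", c(c = rndSeq(5000)))
  expect_null(extractMarker(g, ref, "recA"))
})

test_that("marker identity matrices have the expected structure", {
  set.seed(56)
  ref <- rndSeq(700)
  hits <- list(
    a = extractMarker(plantMarker(ref, "+", seed = 61), ref, "pyrH"),
    b = extractMarker(plantMarker(ref, "-", seed = 62), ref, "pyrH"),
    c = extractMarker(plantMarker(mutateSeq(ref, 0.02), "+", seed = 63),
                      ref, "pyrH"))
  m <- markerIdentityMatrix(hits)
  expect_equal(diag(m), c(a = 100, b = 100, c = 100))
  expect_equal(m["a", "b"], 100)       # identical extractions
  expect_lte(abs(m["a", "c"] - 98), 1)
  expect_equal(m, t(m))
  expect_error(markerIdentityMatrix(list(a = hits$a, b = NULL)),
               ">= 2 genomes")
})

test_that("MLSA concatenates the five markers with sane distances", {
  fx <- fixtureSuite("marker_set", tempfile("mk"), seed = 57)
  refs <- as.list(fx$config$markerSet)
  res <- mlsa(fx$evolved$genomes, refs)
  D <- res$distance
  expect_equal(diag(D), setNames(rep(0, nrow(D)), rownames(D)))
  expect_equal(D, t(D))
  # concatenation length is the sum of the marker alignment widths
  widths <- vapply(res$perMarkerIdentity, function(x) !is.null(x),
                   logical(1))
  expect_equal(nchar(alignedSeqs(res$concatenated)[[1]]),
               sum(res$concatenated@genes$end -
                   res$concatenated@genes$start))
  # sister pairs are closer than cross-clade pairs
  expect_lt(D["g1", "g2"], D["g1", "g3"])
  expect_lt(D["g3", "g4"], D["g1", "g4"])
})

test_that("two genomes with identical markers have MLSA distance 0", {
  set.seed(58)
  refs <- list(rrsA = rndSeq(600), gyrB = rndSeq(500), pyrH = rndSeq(400))
  mkGenome <- function(id, seed) {
    set.seed(seed)
    genome(id, c(chr = paste0(rndSeq(1000), refs$rrsA, rndSeq(500),
                              refs$gyrB, rndSeq(500), refs$pyrH,
                              rndSeq(1000))))
  }
  res <- mlsa(list(mkGenome("a", 71), mkGenome("b", 72)), refs,
              minMarkers = 3)
  expect_equal(res$distance["a", "b"], 0)
})
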