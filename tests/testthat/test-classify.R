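test_that("cutoff verdicts follow the 95/95/70/0.01 rules", {
  cl <- callPair(ani = 100, aai = 100, ddh = 100, delta = 0)
  expect_true(all(cl@verdicts[c("ani", "aai", "ddh", "delta")] ==
                  "same-species"))
  expect_equal(cl@consensus, "same-species")

  cl <- callPair(ani = 96.2, ddh = 74, delta = 0.004)
  expect_equal(cl@consensus, "same-species")
  expect_equal(unname(cl@verdicts["aai"]), "no-signal")

  cl <- callPair(ani = 80, aai = 75, ddh = 20, delta = 0.03)
  expect_true(all(cl@verdicts[c("ani", "aai", "ddh", "delta")] ==
                  "different-species"))
  expect_equal(cl@consensus, "different-species")

  # boundary values are inclusive on the same-species side
  cl <- callPair(ani = 95, aai = 95, ddh = 70, delta = 0.01)
  expect_equal(cl@consensus, "same-species")
  expect_error(callPair(), "no metric")
})

test_that("verdicts are monotone in each metric", {
  set.seed(101)
  for (i in 1:50) {
    v <- list(ani = runif(1, 90, 100), aai = runif(1, 90, 100),
              ddh = runif(1, 50, 100), delta = runif(1, 0, 0.02))
    base <- callPair(v$ani, v$aai, v$ddh, v$delta)@consensus
    up <- callPair(min(v$ani + runif(1, 0, 10), 100),
                   min(v$aai + runif(1, 0, 10), 100),
                   min(v$ddh + runif(1, 0, 20), 100),
                   max(v$delta - runif(1, 0, 0.02), 0))@consensus
    # improving every metric can never flip same -> different
    expect_false(base == "same-species" && up != "same-species")
  }
})

test_that("the two-species fixture yields exactly one conspecific pair", {
  fx <- fixtureSuite("two_species", tempfile("ts2"), seed = 102)
  od <- tempfile("report")
  out <- classifyGenomes(fx$evolved$genomes, fx$evolved$proteomes,
                         outDir = od)
  expect_equal(nrow(out$callsTable), 3L)   # n(n-1)/2 pairs
  expect_equal(sum(out$callsTable$consensus == "same-species"), 1L)
  same <- out$callsTable[out$callsTable$consensus == "same-species", ]
  expect_equal(sort(c(same$genome_a, same$genome_b)), c("g1", "g2"))
  # report files exist and the JSON parses with matching values
  expect_true(file.exists(file.path(od, "ani.tsv")))
  expect_true(file.exists(file.path(od, "calls.tsv")))
  rep <- jsonlite::read_json(file.path(od, "report.json"))
  expect_equal(length(rep$calls), 3L)
  aniJson <- rep$matrices$ani$values[[1]][[2]]
  expect_equal(aniJson, out$matrices$ani["g1", "g2"], tolerance = 1e-12)
})

test_that("identical genomes classify as one conspecific pair", {
  set.seed(103)
  s <- rndSeq(20000)
  out <- classifyGenomes(list(genome("a", c(c = s)), genome("b", c(c = s))),
                         metrics = c("ani", "ddh", "dinuc"))
  expect_equal(nrow(out$callsTable), 1L)
  expect_equal(out$callsTable$consensus, "same-species")
  expect_equal(out$callsTable$ani, 100)
})
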