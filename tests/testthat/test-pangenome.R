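# hand-built weighted graph helper
edgeGraph <- function(nodes, edges, weights) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(as.matrix(edges)), weight = weights)
  g
}

test_that("two disjoint cliques come out as two clusters", {
  nodes <- c(paste0("a|g", 1:4), paste0("b|h", 1:4))
  e <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)))
  g <- edgeGraph(nodes, e, rep(50, nrow(e)))
  hg <- mclCluster(g)
  tab <- groupTable(hg)
  expect_equal(length(unique(tab$group)), 2L)
  expect_equal(as.integer(table(tab$group)), c(4L, 4L))
})

test_that("MCL agrees with an independent dense reference on small graphs", {
  set.seed(81)
  for (rep in 1:8) {
    n <- sample(6:30, 1)
    nodes <- sprintf("g%02d|x", seq_len(n))
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    nedge <- sample(n:(2 * n), 1)
    for (k in seq_len(nedge)) {
      ij <- sample(n, 2)
      W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- runif(1, 5, 120)
    }
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    hg <- mclCluster(g, inflation = 1.25)
    ours <- split(groupTable(hg)$gene, groupTable(hg)$group)
    ours <- unname(lapply(ours, sort))
    ours <- ours[order(vapply(ours, `[`, character(1), 1))]
    oracle <- denseMclOracle(W, inflation = 1.25)
    expect_equal(ours, oracle)
  }
})

test_that("raising inflation never merges separated clusters", {
  # barbell: two cliques joined by one weak edge
  nodes <- sprintf("g|%02d", 1:8)
  e <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(4, 5))
  w <- c(rep(100, 12), 6)
  g <- edgeGraph(nodes, e, w)
  nClusters <- vapply(c(1.25, 2, 4), function(inf)
    length(unique(groupTable(mclCluster(g, inflation = inf))$group)),
    numeric(1))
  expect_true(all(diff(nClusters) >= 0))
})

test_that("the similarity graph is order-independent with paralog edges", {
  ev <- simPair(0.05, len = 15000L, nGenes = 6L)
  ps <- list(ev$proteomes$g1, ev$proteomes$g2)
  g1 <- buildSimilarityGraph(ps)
  g2 <- buildSimilarityGraph(rev(ps))
  el1 <- igraph::as_data_frame(g1); el2 <- igraph::as_data_frame(g2)
  o1 <- el1[order(el1$from, el1$to), ]; o2 <- el2[order(el2$from, el2$to), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  # ortholog edges present for every gene
  expect_gte(igraph::ecount(g1), 6)
})

test_that("unrelated random proteins produce no edges", {
  set.seed(82)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
           "P","S","T","W","Y","V")
  mk <- function(id) {
    prots <- vapply(1:5, function(i)
      paste(sample(aas, 120, TRUE), collapse = ""), character(1))
    names(prots) <- paste0("p", 1:5)
    proteome(id, prots)
  }
  g <- buildSimilarityGraph(list(mk("a"), mk("b")))
  expect_equal(igraph::ecount(g), 0)
  # and clustering still partitions every gene as singletons
  hg <- mclCluster(g)
  expect_equal(nrow(groupTable(hg)), 10L)
  expect_equal(length(unique(groupTable(hg)$group)), 10L)
})

test_that("planted ortholog families are clustered perfectly", {
  fx <- fixtureSuite("ortholog_families", tempfile("of2"), seed = 83)
  # subset to 15 families to keep the unit test light
  keep <- sprintf("gene%04d", 1:15)
  ps <- lapply(fx$evolved$proteomes, function(p)
    new("Proteome", genomeId = genomeId(p),
        proteins = proteins(p)[keep], cds = cdsSeqs(p)[keep]))
  g <- buildSimilarityGraph(ps)
  hg <- mclCluster(g, inflation = 1.25)
  s <- pangenomeSummary(hg)
  expect_equal(s$n_groups, 15L)
  expect_equal(s$n_single_copy_core, 15L)
  expect_equal(s$n_orphans, 0L)
  scc <- singleCopyCore(hg)
  expect_equal(nrow(scc), 45L)
})

test_that("pangenome summary counts satisfy their invariants", {
  tab <- data.frame(
    gene = c("a|1", "a|2", "a|3", "a|4", "b|1", "b|2", "b|5"),
    genome = c("a", "a", "a", "a", "b", "b", "b"),
    group = c("G1", "G1", "G2", "G3", "G1", "G2", "G4"),
    stringsAsFactors = FALSE)
  hg <- new("HomologGroups", table = tab, genomeIds = c("a", "b"),
            inflation = 1.25)
  s <- pangenomeSummary(hg)
  expect_equal(s$n_groups, 4L)
  expect_equal(s$n_core, 2L)                 # G1, G2
  expect_equal(s$n_single_copy_core, 1L)     # G2
  expect_equal(s$n_exclusive_genes +
               sum(!is.na(s$groups$exclusive_to)) * 0, 2L)  # a|4, b|5
  expect_equal(s$n_orphans + s$n_exclusive_with_paralog,
               s$n_exclusive_genes)
  # one genome only: every group is core
  s1 <- pangenomeSummary(hg, genomeIds = "a")
  expect_equal(s1$n_core, length(unique(tab$group[tab$genome == "a"])))
  # removing a genome can only keep or increase core count
  expect_gte(s1$n_core, s$n_core)
})
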