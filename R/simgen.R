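#' @include seqio.R
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Study conditions for the genome-evolution simulator. The defaults
#' emulate small cyanobacteria-like chromosomes: a 200 kb ancestor at
#' 55\% GC carrying 100 protein-coding genes of 100-300 codons.
#' Divergence is specified either as a Newick \code{tree} with branch
#' lengths in expected substitutions/site (Jukes-Cantor, multiple
#' hits accounted for) or as a flat pairwise divergence \code{p}, in
#' which case each site of the second genome is substituted with
#' probability exactly \code{p} (realized difference proportion ~ p).
#' Background (intergenic) sequence comes from a strand-symmetric
#' first-order Markov chain with GC-dependent CpG and fixed TpA
#' depletion, so genomes of different GC carry distinct dinucleotide
#' signatures, as real genomes do; genes use GC-biased codon
#' sampling.
#'
#' @param seed integer RNG seed; all outputs are deterministic given
#'   the seed.
#' @param ancestorLength ancestor chromosome length in bp.
#' @param gcTarget target GC fraction in (0.25, 0.75).
#' @param nGenes number of planted protein-coding genes.
#' @param geneLengthCodons c(min, mode, max) gene length in codons
#'   (including start and stop).
#' @param tree Newick string or \code{phylo} with branch lengths in
#'   substitutions/site, or \code{NULL}.
#' @param p flat pairwise divergence in [0, 0.5], used when
#'   \code{tree} is \code{NULL}.
#' @param indelRate per-site indel probability per unit branch length
#'   (default 0).
#' @param indelMean mean indel length (geometric; default 3).
#' @param markerSet optional named character vector of marker
#'   sequences to plant alongside the genes.
#' @return Config list for \code{\link{makeAncestor}} /
#'   \code{\link{evolveGenomes}}.
#' @export
simConfig <- function(seed = 1L, ancestorLength = 200000L,
                      gcTarget = 0.55, nGenes = 100L,
                      geneLengthCodons = c(min = 100L, mode = 200L,
                                           max = 300L),
                      tree = NULL, p = NULL, indelRate = 0,
                      indelMean = 3, markerSet = NULL) {
  stopifnot(gcTarget > 0.25, gcTarget < 0.75,
            indelRate >= 0, indelRate <= 0.5)
  if (!is.null(p) && (p < 0 || p > 0.5))
    stop("flat divergence p must be in [0, 0.5]")
  list(seed = as.integer(seed), ancestorLength = as.integer(ancestorLength),
       gcTarget = gcTarget, nGenes = as.integer(nGenes),
       geneLengthCodons = geneLengthCodons, tree = tree, p = p,
       indelRate = indelRate, indelMean = indelMean,
       markerSet = markerSet)
}

# strand-symmetric background transition matrix with stationary GC
# matched to the target: P(x->y) propto pi_y * w_xy, with CpG
# depletion scaled by GC and a fixed TpA depletion
.backgroundModel <- function(gcTarget) {
  w <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  w["C", "G"] <- max(1.6 - 1.5 * gcTarget, 0.2)
  w["G", "C"] <- w["C", "G"]
  w["T", "A"] <- 0.85
  w["A", "T"] <- 0.85
  stationaryGc <- function(gc) {
    pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    P <- sweep(w, 2, pi, "*")
    P <- P / rowSums(P)
    ev <- eigen(t(P))
    s <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
    s <- s / sum(s)
    s[2] + s[3]
  }
  g <- uniroot(function(gc) stationaryGc(gc) - gcTarget,
               c(0.05, 0.95), tol = 1e-8)$root
  pi <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
  P <- sweep(w, 2, pi, "*")
  P <- P / rowSums(P)
  ev <- eigen(t(P))
  s <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
  list(P = P, init = s / sum(s))
}

# the 61 sense codons with GC-biased sampling weights solved so the
# expected codon GC fraction equals the target
.codonModel <- function(gcTarget) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, .STOP_CODONS)
  gcCount <- vapply(strsplit(sense, ""), function(x)
    sum(x %in% c("G", "C")), numeric(1))
  f <- function(b) {
    wt <- b^gcCount
    sum(wt * gcCount) / sum(wt) / 3 - gcTarget
  }
  b <- uniroot(f, c(0.05, 20), tol = 1e-8)$root
  list(codons = sense, weights = b^gcCount / sum(b^gcCount))
}

.sampleGene <- function(nCodons, cm) {
  internal <- sample(cm$codons, nCodons - 2L, replace = TRUE,
                     prob = cm$weights)
  paste0("ATG", paste(internal, collapse = ""),
         sample(.STOP_CODONS, 1L))
}

# triangular-ish discrete length sampler over [min, max] peaked at mode
.sampleLengths <- function(n, spec) {
  lo <- spec[["min"]]; md <- spec[["mode"]]; hi <- spec[["max"]]
  vals <- lo:hi
  wt <- ifelse(vals <= md,
               (vals - lo + 1) / (md - lo + 1),
               (hi - vals + 1) / (hi - md + 1))
  sample(vals, n, replace = TRUE, prob = wt)
}

#' Build a random ancestor genome with planted genes
#'
#' Generates background sequence from the configured Markov model and
#' plants \code{nGenes} protein-coding genes (ATG start, sense codons
#' with GC-biased usage, one stop) on alternating strands at uniform
#' spacing, plus any configured marker sequences. Deterministic given
#' \code{cfg$seed}.
#'
#' @param cfg config from \code{\link{simConfig}}.
#' @return List with \code{genome} (\code{\linkS4class{Genome}}),
#'   \code{proteome} (\code{\linkS4class{Proteome}} with CDS),
#'   \code{genes} (coordinate table, 0-based half-open),
#'   \code{markers} (coordinate table or NULL).
#' @export
makeAncestor <- function(cfg) {
  set.seed(cfg$seed)
  cm <- .codonModel(cfg$gcTarget)
  bg <- .backgroundModel(cfg$gcTarget)
  lens <- .sampleLengths(cfg$nGenes, cfg$geneLengthCodons)
  if (cfg$nGenes * 3 * cfg$geneLengthCodons[["max"]] >
      cfg$ancestorLength / 2)
    stop("infeasible packing: genes would exceed half the ancestor")
  geneSeqs <- vapply(lens, .sampleGene, character(1), cm = cm)
  featSeqs <- geneSeqs
  featIds <- sprintf("gene%04d", seq_len(cfg$nGenes))
  featKind <- rep("gene", cfg$nGenes)
  if (!is.null(cfg$markerSet)) {
    featSeqs <- c(featSeqs, toupper(cfg$markerSet))
    featIds <- c(featIds, names(cfg$markerSet))
    featKind <- c(featKind, rep("marker", length(cfg$markerSet)))
  }
  nFeat <- length(featSeqs)
  featLen <- nchar(featSeqs)
  if (sum(featLen) >= cfg$ancestorLength)
    stop("infeasible packing: features exceed the ancestor length")
  gapTotal <- cfg$ancestorLength - sum(featLen)
  gaps <- diff(floor(seq(0, gapTotal, length.out = nFeat + 2)))
  starts <- cumsum(c(0, featLen[-nFeat])) + cumsum(gaps[-(nFeat + 1)])
  strands <- rep(c("+", "-"), length.out = nFeat)
  chr <- strsplit(cpp_markov_seq(bg$P, bg$init, cfg$ancestorLength),
                  "")[[1]]
  for (i in seq_len(nFeat)) {
    sq <- if (strands[i] == "+") featSeqs[i] else cpp_revcomp(featSeqs[i])
    chr[(starts[i] + 1):(starts[i] + featLen[i])] <-
      strsplit(sq, "")[[1]]
  }
  feats <- data.frame(id = featIds, kind = featKind, contig = "chr",
                      start = as.integer(starts),
                      end = as.integer(starts + featLen),
                      strand = strands, stringsAsFactors = FALSE)
  genes <- feats[feats$kind == "gene", ]
  prots <- .translateBatch(geneSeqs)
  names(prots) <- genes$id
  cds <- stats::setNames(geneSeqs, genes$id)
  list(genome = genome("anc", stats::setNames(paste(chr, collapse = ""),
                                              "chr")),
       proteome = proteome("anc", prots, cds),
       genes = genes,
       markers = if (any(feats$kind == "marker"))
         feats[feats$kind == "marker", ] else NULL)
}

# Jukes-Cantor substitution of a base vector along branch length t;
# returns list(seq, nSub)
.jcBranch <- function(v, t) {
  if (t <= 0) return(list(seq = v, nSub = 0L))
  psame <- 0.25 + 0.75 * exp(-4 * t / 3)
  hit <- which(runif(length(v)) > psame)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(v[hit], bases)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  list(seq = v, nSub = length(hit))
}

# direct substitution with per-site probability p (single hit)
.flatBranch <- function(v, p) {
  hit <- which(runif(length(v)) < p)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(v[hit], bases)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  list(seq = v, nSub = length(hit))
}

# apply indel events to (seq, origIdx), protecting +-30 bp around
# feature boundaries; insertions sampled from the background model
.applyIndels <- function(v, origIdx, nEvents, protected, meanLen, bg) {
  L <- length(v)
  if (nEvents <= 0 || L < 10) return(list(seq = v, origIdx = origIdx))
  for (e in seq_len(nEvents)) {
    len <- rgeom(1, 1 / meanLen) + 1L
    pos <- sample.int(length(v) - len, 1L)
    span <- pos:(pos + len)
    anc <- origIdx[span]
    if (any(!is.na(anc) & protected[pmax(anc, 1L)])) next
    if (runif(1) < 0.5) {   # deletion
      keep <- setdiff(seq_along(v), pos:(pos + len - 1L))
      v <- v[keep]; origIdx <- origIdx[keep]
    } else {                # insertion
      ins <- strsplit(cpp_markov_seq(bg$P, bg$init, len), "")[[1]]
      v <- append(v, ins, after = pos)
      origIdx <- append(origIdx, rep(NA_integer_, len), after = pos)
    }
  }
  list(seq = v, origIdx = origIdx)
}

#' Evolve an ancestor genome along a tree or to a flat divergence
#'
#' Tree mode applies Jukes-Cantor substitutions per branch (branch
#' length = expected substitutions/site, multiple hits accounted
#' for); flat mode (\code{cfg$p}) emits \code{g1} (identical copy)
#' and \code{g2} with each site substituted with probability
#' \code{p}. Indels (if configured) avoid a protected 30 bp window
#' around every gene/marker boundary so coordinates and ortholog
#' pairing stay well defined. Genes are re-extracted and re-translated
#' after evolution; genes acquiring internal stops are kept and
#' flagged. The truth log records per-branch substitution counts and
#' the realized pairwise identity of every genome pair over the
#' site-homology map.
#'
#' @param ancestor result of \code{\link{makeAncestor}}.
#' @param cfg config from \code{\link{simConfig}} (supplies tree/p,
#'   indel settings and the seed).
#' @return List with \code{genomes} (named list of
#'   \code{\linkS4class{Genome}}), \code{proteomes} (named list),
#'   \code{genes} (per-genome coordinate tables), \code{truth}: list
#'   with \code{identity} (pairwise realized identity matrix),
#'   \code{branch_substitutions}, \code{ortholog_pairs},
#'   \code{flagged_genes}, and marker coordinates.
#' @export
evolveGenomes <- function(ancestor, cfg) {
  set.seed(cfg$seed + 1L)
  chr <- strsplit(as.character(contigs(ancestor$genome)[["chr"]]),
                  "")[[1]]
  L <- length(chr)
  feats <- rbind(ancestor$genes,
                 if (!is.null(ancestor$markers)) ancestor$markers)
  protected <- rep(FALSE, L)
  for (b in c(feats$start, feats$end)) {
    lo <- max(1L, b - 29L); hi <- min(L, b + 30L)
    protected[lo:hi] <- TRUE
  }
  bg <- .backgroundModel(cfg$gcTarget)
  tips <- list()
  branchSubs <- numeric(0)
  if (!is.null(cfg$tree)) {
    tree <- if (is.character(cfg$tree)) ape::read.tree(text = cfg$tree)
            else cfg$tree
    if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
    ntip <- length(tree$tip.label)
    walk <- function(node, v, origIdx) {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      lens <- tree$edge.length[tree$edge[, 1] == node]
      for (ki in seq_along(kids)) {
        sub <- .jcBranch(v, lens[ki])
        nm <- if (kids[ki] <= ntip) tree$tip.label[kids[ki]]
              else paste0("node", kids[ki])
        branchSubs[nm] <<- sub$nSub
        st <- list(seq = sub$seq, origIdx = origIdx)
        if (cfg$indelRate > 0) {
          nEv <- rpois(1, cfg$indelRate * lens[ki] * length(v))
          st <- .applyIndels(st$seq, st$origIdx, nEv, protected,
                             cfg$indelMean, bg)
        }
        if (kids[ki] <= ntip) tips[[nm]] <<- st
        else walk(kids[ki], st$seq, st$origIdx)
      }
    }
    walk(length(tree$tip.label) + 1L, chr, seq_len(L))
  } else {
    if (is.null(cfg$p)) stop("config needs a tree or a flat divergence p")
    tips[["g1"]] <- list(seq = chr, origIdx = seq_len(L))
    sub <- .flatBranch(chr, cfg$p)
    branchSubs["g2"] <- sub$nSub
    st <- list(seq = sub$seq, origIdx = seq_len(L))
    if (cfg$indelRate > 0) {
      nEv <- rpois(1, cfg$indelRate * L)
      st <- .applyIndels(st$seq, st$origIdx, nEv, protected,
                         cfg$indelMean, bg)
    }
    tips[["g2"]] <- st
  }
  ids <- names(tips)
  # site-homology base table: ancestor position -> base per tip
  baseAt <- lapply(tips, function(st) {
    b <- rep(NA_character_, L)
    keep <- !is.na(st$origIdx)
    b[st$origIdx[keep]] <- st$seq[keep]
    b
  })
  idMat <- matrix(1, length(ids), length(ids),
                  dimnames = list(ids, ids))
  if (length(ids) >= 2)
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      both <- !is.na(baseAt[[i]]) & !is.na(baseAt[[j]])
      idMat[i, j] <- idMat[j, i] <-
        mean(baseAt[[i]][both] == baseAt[[j]][both])
    }
  genomes <- list(); proteomes <- list(); geneTabs <- list()
  flagged <- character(0)
  for (id in ids) {
    st <- tips[[id]]
    seqStr <- paste(st$seq, collapse = "")
    genomes[[id]] <- genome(id, stats::setNames(seqStr, "chr"))
    anc2cur <- rep(NA_integer_, L)
    keep <- !is.na(st$origIdx)
    anc2cur[st$origIdx[keep]] <- which(keep)
    g <- ancestor$genes
    newStart <- anc2cur[g$start + 1L] - 1L
    newEnd <- anc2cur[g$end]
    cds <- substring(seqStr, newStart + 1L, newEnd)
    minus <- g$strand == "-"
    cds[minus] <- vapply(cds[minus], cpp_revcomp, character(1),
                         USE.NAMES = FALSE)
    extra <- nchar(cds) %% 3L
    cds <- substr(cds, 1L, nchar(cds) - extra)
    prots <- .translateBatch(cds)
    hasStop <- grepl("\\*", prots)
    flagged <- c(flagged, paste0(id, "|", g$id[hasStop]))
    names(cds) <- names(prots) <- g$id
    proteomes[[id]] <- new("Proteome", genomeId = id,
                           proteins = AAStringSet(prots),
                           cds = DNAStringSet(cds))
    geneTabs[[id]] <- data.frame(id = g$id, contig = "chr",
                                 start = newStart, end = newEnd,
                                 strand = g$strand,
                                 stringsAsFactors = FALSE)
  }
  orthologPairs <- expand.grid(gene = ancestor$genes$id,
                               stringsAsFactors = FALSE)
  list(genomes = genomes, proteomes = proteomes, genes = geneTabs,
       truth = list(identity = idMat,
                    branch_substitutions = branchSubs,
                    ortholog_pairs = orthologPairs$gene,
                    flagged_genes = flagged,
                    markers = ancestor$markers))
}

#' Write a named fixture scenario to disk
#'
#' Emits FASTA inputs (genome \code{.fna}, proteome \code{.faa}, CDS
#' \code{.ffn} per genome) plus a \code{truth.json} for one of the
#' named validation scenarios, all fully determined by \code{seed}:
#' \describe{
#'   \item{two_species}{3 genomes on a star tree; exactly one
#'     conspecific pair (sister tips at ~1\% pairwise nucleotide
#'     divergence, a typical within-species distance; third tip far
#'     beyond the species cutoffs).}
#'   \item{two_clades}{8 genomes on a balanced two-clade tree with
#'     deep stems (emulating a marine/freshwater-style split).}
#'   \item{ortholog_families}{3 genomes sharing 50 single-copy gene
#'     families at high within-family identity.}
#'   \item{marker_set}{4 genomes carrying 5 planted marker genes
#'     (rrsA-like lengths) plus a reference marker FASTA.}
#' }
#'
#' @param name scenario name.
#' @param dir output directory (created).
#' @param seed integer seed (default 42).
#' @return (Invisibly) the scenario list: config, ancestor, evolved
#'   set, and file paths.
#' @export
fixtureSuite <- function(name = c("two_species", "two_clades",
                                  "ortholog_families", "marker_set"),
                         dir, seed = 42L) {
  name <- match.arg(name)
  cfg <- switch(name,
    two_species = simConfig(seed, ancestorLength = 60000L, nGenes = 25L,
                            geneLengthCodons = c(min = 80L, mode = 150L,
                                                 max = 250L),
                            tree = "(g1:0.005,g2:0.005,g3:0.10);"),
    two_clades = simConfig(seed, ancestorLength = 50000L, nGenes = 20L,
                           geneLengthCodons = c(min = 80L, mode = 150L,
                                                max = 250L),
                           tree = paste0(
      "(((t1:0.02,t2:0.02):0.02,(t3:0.02,t4:0.02):0.02):0.08,",
      "((t5:0.02,t6:0.02):0.02,(t7:0.02,t8:0.02):0.02):0.08);")),
    ortholog_families = simConfig(seed, ancestorLength = 120000L,
                                  nGenes = 50L,
                                  geneLengthCodons = c(min = 100L,
                                                       mode = 180L,
                                                       max = 300L),
                                  tree = "(g1:0.05,g2:0.05,g3:0.05);"),
    marker_set = {
      set.seed(seed + 999L)
      mk <- c(rrsA = 1500L, gyrB = 1200L, pyrH = 700L, recA = 1050L,
              rpoB = 1200L)
      refs <- vapply(mk, function(n)
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
              collapse = ""), character(1))
      simConfig(seed, ancestorLength = 60000L, nGenes = 15L,
                geneLengthCodons = c(min = 80L, mode = 150L,
                                     max = 250L),
                tree = "((g1:0.01,g2:0.01):0.02,(g3:0.01,g4:0.01):0.02);",
                markerSet = refs)
    })
  anc <- makeAncestor(cfg)
  ev <- evolveGenomes(anc, cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (id in names(ev$genomes)) {
    fna <- file.path(dir, paste0(id, ".fna"))
    writeFasta(stats::setNames(
      as.character(contigs(ev$genomes[[id]])), paste0(id, "_chr")), fna)
    faa <- file.path(dir, paste0(id, ".faa"))
    writeFasta(as.character(proteins(ev$proteomes[[id]])), faa)
    ffn <- file.path(dir, paste0(id, ".ffn"))
    writeFasta(as.character(cdsSeqs(ev$proteomes[[id]])), ffn)
    files[[id]] <- list(genome = fna, proteome = faa, cds = ffn)
  }
  if (name == "marker_set")
    files$marker_refs <- writeFasta(cfg$markerSet,
                                    file.path(dir, "marker_refs.fna"))
  truth <- list(scenario = name, seed = seed,
                tree = cfg$tree, p = cfg$p,
                genome_ids = names(ev$genomes),
                identity = list(labels = rownames(ev$truth$identity),
                                values = unname(ev$truth$identity)),
                n_genes = nrow(anc$genes),
                flagged_genes = ev$truth$flagged_genes,
                markers = if (!is.null(anc$markers))
                  anc$markers else NULL)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(list(config = cfg, ancestor = anc, evolved = ev,
                 files = files, truthFile = file.path(dir, "truth.json")))
}
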