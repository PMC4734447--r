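#' @include aaicalc.R
NULL

#' Build the all-vs-all protein similarity graph
#'
#' Smith-Waterman aligns every protein pair across (and within) the
#' given proteomes; an undirected edge is kept when the pair's e-value
#' (computed against the pooled database of all residues, using the
#' shorter protein as query length) passes the cutoff. Edge weight is
#' \code{-log10(evalue)}, capped at 200. Within-genome edges are kept
#' so paralogs can be detected; self-edges are excluded. Vertices are
#' the genome-prefixed gene ids (\code{"genome|gene"}), sorted
#' lexicographically, so the graph is independent of proteome input
#' order.
#'
#' @param proteomes list of >= 2 \code{\linkS4class{Proteome}} objects.
#' @param maxEvalue similarity cutoff (default 1e-5).
#' @param scheme amino-acid \code{\linkS4class{ScoringScheme}}.
#' @return An \code{igraph} undirected weighted graph.
#' @export
buildSimilarityGraph <- function(proteomes, maxEvalue = 1e-5,
                                 scheme = scoringScheme("aa")) {
  stopifnot(length(proteomes) >= 2)
  ids <- vapply(proteomes, genomeId, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids among proteomes")
  seqs <- do.call(c, unname(lapply(proteomes, function(p) {
    s <- as.character(proteins(p))
    names(s) <- paste0(genomeId(p), "|", names(s))
    s
  })))
  seqs <- seqs[order(names(seqs), method = "radix")]
  dbSize <- sum(nchar(seqs))
  search <- .aaSearch(seqs, seqs, scheme, dbSize)
  ev <- .evalue(search$bitscore,
                outer(nchar(seqs), nchar(seqs), pmin), dbSize)
  hit <- ev <= maxEvalue & search$score > 0
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(seqs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = names(seqs))
  if (nrow(idx)) {
    w <- pmin(-log10(pmax(ev[idx], 1e-200)), 200)
    g <- igraph::add_edges(g, t(cbind(idx[, 1], idx[, 2])),
                           weight = w)
  }
  g
}

#' Markov clustering of a similarity graph
#'
#' Plain MCL on the weighted adjacency matrix: self-loops are set to
#' each node's maximum incident weight, columns are normalized to a
#' stochastic matrix, then expansion (matrix squaring) and inflation
#' (entrywise power + renormalization) alternate, pruning entries
#' below \code{prune}, until the matrix changes by less than
#' \code{tol} or \code{maxIter} is reached (a warning is issued on
#' non-convergence and the current matrix is interpreted). Clusters
#' are the connected components of the converged non-zero structure;
#' isolated genes come out as single-member groups. Genes are sorted
#' lexicographically before matrix construction so group ids are
#' stable. An optional OrthoMCL-style normalization (dividing
#' inter-genome weights by their genome-pair average) can be switched
#' on with \code{orthoNormalize}; its state is recorded in the result.
#'
#' @param graph \code{igraph} similarity graph from
#'   \code{\link{buildSimilarityGraph}}.
#' @param inflation inflation exponent (default 1.25).
#' @param maxIter iteration cap (default 100).
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max entry change.
#' @param orthoNormalize apply genome-pair mean weight normalization
#'   before clustering (default FALSE).
#' @return A \code{\linkS4class{HomologGroups}} partition of all
#'   vertices.
#' @export
mclCluster <- function(graph, inflation = 1.25, maxIter = 100L,
                       prune = 1e-5, tol = 1e-6,
                       orthoNormalize = FALSE) {
  nodes <- sort(igraph::V(graph)$name, method = "radix")
  n <- length(nodes)
  if (!n) stop("empty graph")
  A <- igraph::as_adjacency_matrix(graph, attr = if (igraph::ecount(graph))
    "weight" else NULL, sparse = TRUE)
  A <- A[nodes, nodes]
  A <- methods::as(A, "generalMatrix")
  if (orthoNormalize) A <- .orthoNormalize(A, nodes)
  mx <- apply(A, 1, max)
  diag(A) <- ifelse(mx > 0, mx, 1)
  M <- A %*% Matrix::Diagonal(x = 1 / Matrix::colSums(A))
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2@x[M2@x < prune] <- 0
    M2 <- Matrix::drop0(M2)
    cs <- Matrix::colSums(M2)
    empty <- which(cs == 0)
    if (length(empty)) {
      M2[cbind(empty, empty)] <- 1
      cs[empty] <- 1
    }
    M2 <- M2 %*% Matrix::Diagonal(x = 1 / cs)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", maxIter,
            " iterations; interpreting current matrix")
  S <- M + Matrix::t(M)
  cg <- igraph::graph_from_adjacency_matrix(S > 0, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(cg)$membership
  names(comp) <- nodes
  # stable group ids: number groups by their smallest member gene
  first <- tapply(nodes, comp, min)
  ord <- order(first, method = "radix")
  remap <- stats::setNames(seq_along(ord), names(first)[ord])
  gid <- sprintf("HG%05d", remap[as.character(comp)])
  tab <- data.frame(gene = nodes,
                    genome = sub("\\|.*$", "", nodes),
                    group = gid, stringsAsFactors = FALSE)
  tab <- tab[order(tab$group, tab$gene, method = "radix"), ]
  rownames(tab) <- NULL
  new("HomologGroups", table = tab,
      genomeIds = sort(unique(tab$genome)), inflation = inflation)
}

# OrthoMCL-style weight normalization: divide each inter-genome edge
# weight by the mean weight observed between that genome pair
.orthoNormalize <- function(A, nodes) {
  gn <- sub("\\|.*$", "", nodes)
  T <- methods::as(Matrix::triu(A, 1), "TsparseMatrix")
  if (!length(T@x)) return(A)
  pair <- paste(pmin(gn[T@i + 1L], gn[T@j + 1L]),
                pmax(gn[T@i + 1L], gn[T@j + 1L]), sep = "\r")
  mw <- tapply(T@x, pair, mean)
  T@x <- T@x / as.numeric(mw[pair])
  out <- Matrix::sparseMatrix(i = T@i + 1L, j = T@j + 1L, x = T@x,
                              dims = dim(A), symmetric = FALSE)
  out <- out + Matrix::t(out)
  dimnames(out) <- dimnames(A)
  methods::as(out, "generalMatrix")
}

#' Summarize a homolog-group partition
#'
#' Computes the pan-genome partition statistics: total groups, core
#' groups (every genome >= 1 copy), single-copy core groups (every
#' genome exactly 1 copy), genes exclusive to a single genome, and
#' among those the orphans (exclusive genes with no paralog, i.e.
#' single-member groups) versus exclusive genes with a paralog
#' (multi-member single-genome groups); orphans plus
#' exclusive-with-paralog always equals the exclusive gene count.
#'
#' @param hg a \code{\linkS4class{HomologGroups}}.
#' @param genomeIds genomes the partition should be assessed against
#'   (default: the genomes present in the partition).
#' @return List with counts \code{n_groups}, \code{n_core},
#'   \code{n_single_copy_core}, \code{n_exclusive_genes},
#'   \code{n_orphans}, \code{n_exclusive_with_paralog}, and a
#'   group-level data.frame \code{groups} with per-group flags.
#' @export
pangenomeSummary <- function(hg, genomeIds = NULL) {
  stopifnot(is(hg, "HomologGroups"))
  if (is.null(genomeIds)) genomeIds <- hg@genomeIds
  tab <- hg@table
  cnt <- table(tab$group, factor(tab$genome, levels = genomeIds))
  size <- rowSums(cnt)
  is_core <- apply(cnt >= 1, 1, all)
  is_scc <- apply(cnt == 1, 1, all)
  n_genomes_in <- rowSums(cnt >= 1)
  exclusive <- n_genomes_in == 1
  excl_to <- ifelse(exclusive,
                    colnames(cnt)[apply(cnt, 1, which.max)],
                    NA_character_)
  groups <- data.frame(group = rownames(cnt), size = as.integer(size),
                       n_genomes = as.integer(n_genomes_in),
                       is_core = is_core, is_single_copy_core = is_scc,
                       exclusive_to = excl_to, stringsAsFactors = FALSE)
  n_excl_genes <- sum(size[exclusive])
  n_orphans <- sum(exclusive & size == 1)
  list(n_groups = nrow(groups),
       n_core = sum(is_core),
       n_single_copy_core = sum(is_scc),
       n_exclusive_genes = as.integer(n_excl_genes),
       n_orphans = as.integer(n_orphans),
       n_exclusive_with_paralog = as.integer(n_excl_genes - n_orphans),
       groups = groups)
}

#' Single-copy core groups
#'
#' Groups present exactly once in every genome: the input for
#' concatenated-gene phylogenomics.
#'
#' @param hg a \code{\linkS4class{HomologGroups}}.
#' @param genomeIds genome set to assess against (default: all in the
#'   partition).
#' @return data.frame with columns \code{group}, \code{genome},
#'   \code{gene} (genome-prefixed id).
#' @export
singleCopyCore <- function(hg, genomeIds = NULL) {
  summ <- pangenomeSummary(hg, genomeIds)
  scc <- summ$groups$group[summ$groups$is_single_copy_core]
  out <- hg@table[hg@table$group %in% scc, c("group", "genome", "gene")]
  rownames(out) <- NULL
  out
}
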