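#' @include alignkern.R
NULL

#' Construct an Msa object
#'
#' @param seqs named character vector of equal-length gapped rows
#'   ('-' as gap).
#' @param alphabet \code{"nt"} or \code{"aa"}.
#' @param genes optional concatenation map (columns \code{gene},
#'   \code{start}, \code{end}; 0-based half-open column ranges).
#' @return An \code{\linkS4class{Msa}}.
#' @export
msa <- function(seqs, alphabet = c("nt", "aa"), genes = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(genes))
    genes <- data.frame(gene = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  new("Msa", seqs = toupper(seqs), alphabet = alphabet, genes = genes)
}

# k-mer count cosine distance matrix used for the guide tree
.kmerDistance <- function(seqs, k) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character()))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  kmers <- unique(unlist(lapply(counts, names)))
  V <- vapply(counts, function(ct) {
    v <- numeric(length(kmers)); names(v) <- kmers
    v[names(ct)] <- as.numeric(ct)
    v
  }, numeric(length(kmers)))
  nrm <- sqrt(colSums(V^2))
  nrm[nrm == 0] <- 1
  cosim <- crossprod(sweep(V, 2, nrm, "/"))
  d <- 1 - cosim
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

# residue frequency profile of an alignment block (gap mass omitted)
.profileOf <- function(rows, letters) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  p <- matrix(0, length(letters), L, dimnames = list(letters, NULL))
  for (j in seq_len(L)) {
    tb <- table(m[, j])
    tb <- tb[names(tb) %in% letters]
    if (length(tb)) p[names(tb), j] <- as.numeric(tb) / nrow(m)
  }
  p
}

# merge two alignment blocks by profile-profile global alignment
.mergeBlocks <- function(A, B, S, letters, gapOpen, gapExtend) {
  pA <- .profileOf(A, letters)
  pB <- .profileOf(B, letters)
  colscore <- t(pA) %*% S[letters, letters] %*% pB
  path <- cpp_nw_path(colscore, gapOpen, gapExtend)
  buildRows <- function(rows, idx) {
    m <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow(m), length(idx))
    nz <- idx > 0
    out[, nz] <- m[, idx[nz], drop = FALSE]
    stats::setNames(apply(out, 1, paste, collapse = ""), names(rows))
  }
  c(buildRows(A, path$ai), buildRows(B, path$bi))
}

#' Progressive multiple sequence alignment
#'
#' Progressive alignment in the spirit of the standard multiple
#' aligners: a neighbor-joining guide tree is built on k-mer cosine
#' distances (k = 3 for proteins, 6 for nucleotides), and profiles are
#' merged leaf-to-root by affine-gap profile-profile global alignment
#' with mean-column substitution scores. Sequences are processed in
#' lexicographic label order (so the result does not depend on input
#' order); output rows are returned in input order. Iterative
#' refinement is not performed.
#'
#' @param seqs named character vector or \code{XStringSet} (>= 1
#'   sequence).
#' @param scheme \code{\linkS4class{ScoringScheme}} matching the
#'   alphabet.
#' @return An \code{\linkS4class{Msa}}; ungapping row i reproduces
#'   input sequence i exactly.
#' @export
progressiveMsa <- function(seqs, scheme = scoringScheme("aa")) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique labels")
  inOrder <- names(seqs)
  if (length(seqs) == 1L) return(msa(seqs, scheme@kind))
  S <- .subMatrix(scheme)
  letters <- if (scheme@kind == "nt") c("A", "C", "G", "T")
             else setdiff(rownames(S), c("*", "-"))
  seqs <- seqs[order(names(seqs), method = "radix")]
  if (length(seqs) == 2L) {
    al <- globalAlign(seqs[[1]], seqs[[2]], scheme)
    rows <- stats::setNames(c(al@alignedQuery, al@alignedSubject),
                            names(seqs))
    return(msa(rows[inOrder], scheme@kind))
  }
  k <- if (scheme@kind == "nt") 6L else 3L
  gt <- njTree(.kmerDistance(seqs, k))
  mergeNode <- function(node) {
    if (node <= length(gt$tip.label))
      return(stats::setNames(seqs[gt$tip.label[node]],
                             gt$tip.label[node]))
    kids <- gt$edge[gt$edge[, 1] == node, 2]
    acc <- mergeNode(kids[1])
    for (kid in kids[-1])
      acc <- .mergeBlocks(acc, mergeNode(kid), S, letters,
                          scheme@gapOpen, scheme@gapExtend)
    acc
  }
  rows <- mergeNode(length(gt$tip.label) + 1L)
  msa(rows[inOrder], scheme@kind)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column becomes its source codon; gap columns become
#' \code{"---"}, so the output has exactly 3x the input columns and
#' ungapping any output row reproduces its CDS. For every label the
#' CDS (after trimming one trailing stop codon, if present) must have
#' length 3x the ungapped protein length and translate to the protein;
#' violations raise an error naming the label and offset.
#'
#' @param msaAa an amino-acid \code{\linkS4class{Msa}}.
#' @param cds named character vector or \code{DNAStringSet} of coding
#'   sequences covering every alignment label.
#' @return A nucleotide \code{\linkS4class{Msa}}.
#' @export
backtranslate <- function(msaAa, cds) {
  stopifnot(is(msaAa, "Msa"), msaAa@alphabet == "aa")
  if (is(cds, "XStringSet")) cds <- as.character(cds)
  cds <- toupper(cds)
  missing <- setdiff(names(msaAa@seqs), names(cds))
  if (length(missing))
    stop("no CDS for label(s): ", paste(missing, collapse = ", "))
  out <- character(length(msaAa@seqs))
  names(out) <- names(msaAa@seqs)
  for (lab in names(msaAa@seqs)) {
    row <- strsplit(msaAa@seqs[[lab]], "")[[1]]
    aa <- row[row != "-"]
    nt <- cds[[lab]]
    if (nchar(nt) == 3 * (length(aa) + 1) &&
        substr(nt, nchar(nt) - 2, nchar(nt)) %in% c("TAA", "TAG", "TGA"))
      nt <- substr(nt, 1, nchar(nt) - 3)
    if (nchar(nt) != 3 * length(aa))
      stop("CDS length mismatch for '", lab, "': ", nchar(nt),
           " nt vs ", length(aa), " aa (expected ", 3 * length(aa), ")")
    trans <- strsplit(as.character(suppressWarnings(
      translate(DNAString(nt), if.fuzzy.codon = "X"))), "")[[1]]
    bad <- which(trans != aa)
    if (length(bad))
      stop("CDS of '", lab, "' does not translate to its protein at ",
           "residue ", bad[1])
    codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    cells <- rep("---", length(row))
    cells[row != "-"] <- codons
    out[[lab]] <- paste(cells, collapse = "")
  }
  msa(out, "nt")
}

#' Concatenate alignments sharing a label set
#'
#' Row-wise concatenation in the given order; a per-gene column map is
#' retained (0-based half-open) for gene-wise bootstrap resampling.
#'
#' @param alignments named list of \code{\linkS4class{Msa}} objects
#'   with identical label sets and alphabet (callers typically sort
#'   the list by group id first).
#' @return A concatenated \code{\linkS4class{Msa}} whose \code{genes}
#'   map records each source alignment's columns.
#' @export
concatenateMsa <- function(alignments) {
  stopifnot(length(alignments) >= 1)
  if (is.null(names(alignments)))
    names(alignments) <- paste0("gene", seq_along(alignments))
  labels <- sort(names(alignments[[1]]@seqs))
  alpha <- alignments[[1]]@alphabet
  for (nm in names(alignments)) {
    al <- alignments[[nm]]
    if (!identical(sort(names(al@seqs)), labels)) {
      d1 <- setdiff(labels, names(al@seqs))
      d2 <- setdiff(names(al@seqs), labels)
      stop("label mismatch in alignment '", nm, "': missing [",
           paste(d1, collapse = ","), "] extra [",
           paste(d2, collapse = ","), "]")
    }
    if (al@alphabet != alpha) stop("alphabet mismatch in '", nm, "'")
  }
  widths <- vapply(alignments, function(a) nchar(a@seqs[[1]]), numeric(1))
  ends <- cumsum(widths)
  genes <- data.frame(gene = names(alignments),
                      start = as.integer(ends - widths),
                      end = as.integer(ends), stringsAsFactors = FALSE)
  rows <- vapply(labels, function(lab) {
    paste(vapply(alignments, function(a) a@seqs[[lab]], character(1)),
          collapse = "")
  }, character(1))
  msa(rows, alpha, genes)
}

#' Tajima-Nei (equal-input) distance matrix
#'
#' For each sequence pair, columns containing a gap or ambiguity code
#' in either sequence are removed (pairwise complete deletion; set
#' \code{deletion = "complete"} to remove such columns across the
#' whole alignment first). With p the mismatch proportion, g the
#' pair-pooled base frequencies and x the mismatch-pair frequencies,
#' the distance is d = -b log(1 - p/b) with
#' b = (1 - sum(g^2) + p^2/h) / 2 and
#' h = sum over base pairs i<j of x_ij^2 / (2 g_i g_j).
#' A pair with p >= b is saturated: reported as \code{NA} with a
#' warning. Identical rows give 0.
#'
#' @param msaNt nucleotide \code{\linkS4class{Msa}} with >= 2 rows.
#' @param deletion \code{"pairwise"} (default) or \code{"complete"}.
#' @return Symmetric labelled distance matrix (zero diagonal).
#' @export
tajimaNei <- function(msaNt, deletion = c("pairwise", "complete")) {
  stopifnot(is(msaNt, "Msa"), msaNt@alphabet == "nt",
            length(msaNt@seqs) >= 2)
  deletion <- match.arg(deletion)
  M <- do.call(rbind, strsplit(msaNt@seqs, ""))
  rownames(M) <- names(msaNt@seqs)
  ok <- M %in% c("A", "C", "G", "T")
  dim(ok) <- dim(M)
  if (deletion == "complete") {
    keep <- colSums(ok) == nrow(M)
    if (!any(keep)) stop("no comparable columns after complete deletion")
    M <- M[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    if (!any(use))
      stop("no comparable columns between '", rownames(M)[i], "' and '",
           rownames(M)[j], "'")
    a <- M[i, use]; b <- M[j, use]
    D[i, j] <- D[j, i] <- .tajimaNeiPair(a, b)
  }
  D
}

# scalar Tajima-Nei distance for two gap-free base vectors
.tajimaNeiPair <- function(a, b) {
  L <- length(a)
  diff <- a != b
  p <- sum(diff) / L
  if (p == 0) return(0)
  bases <- c("A", "C", "G", "T")
  cnt <- table(factor(a, bases)) + table(factor(b, bases))
  g <- as.numeric(cnt) / (2 * L)
  pairKey <- ifelse(a[diff] < b[diff], paste0(a[diff], b[diff]),
                    paste0(b[diff], a[diff]))
  keys <- c("AC", "AG", "AT", "CG", "CT", "GT")
  x <- as.numeric(table(factor(pairKey, keys))) / L
  gi <- c(g[1] * g[2], g[1] * g[3], g[1] * g[4], g[2] * g[3],
          g[2] * g[4], g[3] * g[4])
  # a mismatch pair implies both bases occur, so x > 0 => gi > 0;
  # zero-x terms contribute nothing and avoid 0/0
  h <- sum((x^2 / (2 * gi))[x > 0])
  bb <- 0.5 * (1 - sum(g^2) + p^2 / h)
  if (p >= bb) {
    warning("saturated pair (p = ", signif(p, 4), " >= b = ",
            signif(bb, 4), "); distance undefined")
    return(NA_real_)
  }
  -bb * log(1 - p / bb)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The standard agglomerative algorithm minimizing the Q-criterion.
#' Ties are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest leaf). Negative
#' branch lengths are clamped to zero with the deficit shifted to the
#' sister branch, so path lengths are preserved. The output is an
#' unrooted \code{ape} \code{phylo} (trifurcating root node). Additive
#' distance matrices are recovered exactly (topology and branch
#' lengths).
#'
#' @param dm symmetric labelled distance matrix with >= 3 labels and
#'   finite entries.
#' @return An object of class \code{phylo}.
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  if (is.null(labels)) stop("distance matrix must carry labels")
  n <- length(labels)
  if (n < 3) stop("need >= 3 labels for neighbor-joining")
  if (any(!is.finite(dm))) stop("non-finite distances")
  nwk <- labels            # growing newick fragment per active cluster
  minleaf <- labels        # smallest leaf label per cluster (tie rule)
  D <- dm
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.10g", x)
  while (length(active) > 3) {
    r <- length(active)
    Da <- D[active, active]
    R <- rowSums(Da)
    Q <- (r - 2) * Da - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      lab <- sort(c(minleaf[active[ij[1]]], minleaf[active[ij[2]]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(key, method = "radix")[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    dij <- D[i, j]
    li <- dij / 2 + (R[pick[1]] - R[pick[2]]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newD <- (D[i, active] + D[j, active] - dij) / 2
    D[i, active] <- newD
    D[active, i] <- newD
    D[i, i] <- 0
    nwk[i] <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":",
                     fmt(lj), ")")
    minleaf[i] <- min(minleaf[i], minleaf[j])
    active <- setdiff(active, j)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  ord <- order(c(minleaf[a], minleaf[b], minleaf[c3]), method = "radix")
  parts <- c(paste0(nwk[a], ":", fmt(la)), paste0(nwk[b], ":", fmt(lb)),
             paste0(nwk[c3], ":", fmt(lc)))[ord]
  tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","),
                                       ");"))
  tree
}

# leaf bipartition keys for every internal edge of an unrooted tree;
# canonicalized so the side not containing the alphabetically first
# leaf is used
.splitKeys <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root <- ntip + 1L
  keys <- character(0)
  nodes <- integer(0)
  for (node in seq.int(ntip + 1L, ntip + tree$Nnode)) {
    if (node == root) next
    side <- below[[node]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2) next        # trivial split
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  list(keys = keys, nodes = nodes, ntip = ntip)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the point-estimate tree from the full alignment
#' (Tajima-Nei + neighbor-joining), then resamples alignment columns
#' (or whole genes, using the concatenation map) with replacement,
#' recomputes the tree per replicate, and reports for each internal
#' split of the point tree the percentage of successful replicates
#' containing it, stored as internal node labels. Replicates
#' containing a saturated pair are dropped and counted; a warning is
#' issued when more than 20\% are dropped. Fully reproducible for a
#' given \code{seed}.
#'
#' @param msaNt nucleotide \code{\linkS4class{Msa}} with >= 4 rows.
#' @param nReps bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @param mode \code{"column"} (default) or \code{"gene"} (requires a
#'   concatenation map from \code{\link{concatenateMsa}}).
#' @param deletion passed to \code{\link{tajimaNei}}.
#' @return The point-estimate \code{phylo} with \code{node.label}
#'   holding percent supports ("" for the root) and attributes
#'   \code{n_dropped} / \code{n_used}.
#' @export
bootstrapTree <- function(msaNt, nReps = 1000L, seed = 1L,
                          mode = c("column", "gene"),
                          deletion = "pairwise") {
  stopifnot(is(msaNt, "Msa"), length(msaNt@seqs) >= 4)
  mode <- match.arg(mode)
  if (mode == "gene" && !nrow(msaNt@genes))
    stop("gene mode needs a concatenation map (see concatenateMsa)")
  dm <- tajimaNei(msaNt, deletion)
  if (any(is.na(dm))) stop("saturated pair in full alignment")
  point <- njTree(dm)
  sp <- .splitKeys(point)
  counts <- stats::setNames(numeric(length(sp$keys)), sp$keys)
  rowsM <- do.call(rbind, strsplit(msaNt@seqs, ""))
  rownames(rowsM) <- names(msaNt@seqs)
  L <- ncol(rowsM)
  set.seed(seed)
  dropped <- 0L
  for (rep in seq_len(nReps)) {
    cols <- if (mode == "column") {
      sample.int(L, L, replace = TRUE)
    } else {
      gi <- sample.int(nrow(msaNt@genes), nrow(msaNt@genes),
                       replace = TRUE)
      unlist(lapply(gi, function(g)
        seq.int(msaNt@genes$start[g] + 1L, msaNt@genes$end[g])))
    }
    rmsa <- msa(apply(rowsM[, cols, drop = FALSE], 1, paste,
                      collapse = ""), "nt")
    dmr <- suppressWarnings(tajimaNei(rmsa, deletion))
    if (any(is.na(dmr))) { dropped <- dropped + 1L; next }
    rt <- njTree(dmr)
    rk <- .splitKeys(rt)$keys
    hit <- sp$keys %in% rk
    counts[hit] <- counts[hit] + 1
  }
  used <- nReps - dropped
  if (dropped > 0.2 * nReps)
    warning(dropped, " of ", nReps, " replicates dropped (saturated pairs)")
  if (used == 0) stop("all bootstrap replicates dropped")
  support <- 100 * counts / used
  ntip <- length(point$tip.label)
  node.label <- rep("", point$Nnode)
  node.label[sp$nodes - ntip] <- sprintf("%g", round(support, 1))
  point$node.label <- node.label
  attr(point, "n_dropped") <- dropped
  attr(point, "n_used") <- used
  point
}

#' Write a tree in Newick format
#'
#' Branch lengths to 6 decimals; bootstrap supports (node labels) kept.
#'
#' @param tree a \code{phylo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
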