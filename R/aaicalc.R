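#' @include alignkern.R seqio.R
NULL

# all-vs-all scores between two protein sets; returns matrices plus
# derived bitscore/evalue given the scheme and database size
.aaSearch <- function(seqsA, seqsB, scheme, dbSize) {
  res <- cpp_aa_allvsall(seqsA, seqsB, .subMatrix(scheme),
                         scheme@gapOpen, scheme@gapExtend)
  bits <- .bitscore(res$score, scheme)
  ev <- .evalue(bits, matrix(nchar(seqsA), nrow = length(seqsA),
                             ncol = length(seqsB)), dbSize)
  dimnames(res$score) <- dimnames(res$n_id) <- dimnames(res$aln_len) <-
    dimnames(bits) <- dimnames(ev) <- list(names(seqsA), names(seqsB))
  c(res, list(bitscore = bits, evalue = ev))
}

# best hit per row of a score search: highest bitscore passing the
# e-value cutoff; ties by higher identity, then lexicographically
# smaller subject id
.bestPerRow <- function(search, maxEvalue) {
  idn <- 100 * search$n_id / pmax(search$aln_len, 1L)
  out <- character(nrow(search$score))
  names(out) <- rownames(search$score)
  for (i in seq_len(nrow(search$score))) {
    pass <- which(search$evalue[i, ] <= maxEvalue & search$score[i, ] > 0)
    if (!length(pass)) { out[i] <- NA_character_; next }
    ord <- order(-search$bitscore[i, pass], -idn[i, pass],
                 colnames(search$score)[pass], method = "radix")
    out[i] <- colnames(search$score)[pass[ord[1]]]
  }
  out
}

#' Best protein hits from one proteome into another
#'
#' For each gene of \code{pa}, the highest-bitscore Smith-Waterman hit
#' in \code{pb} passing the e-value cutoff (ties: higher identity,
#' then lexicographically smaller subject gene id). Genes without a
#' passing hit are absent from the result.
#'
#' @param pa,pb \code{\linkS4class{Proteome}} objects.
#' @param maxEvalue e-value cutoff (default 1e-5); the database size
#'   used is the total residue count of \code{pb}.
#' @param scheme amino-acid \code{\linkS4class{ScoringScheme}}.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{identity}, \code{aln_len}, \code{cov_shorter} (\% of the
#'   shorter protein covered), \code{bitscore}, \code{evalue}.
#' @export
bestHits <- function(pa, pb, maxEvalue = 1e-5, scheme = scoringScheme("aa")) {
  stopifnot(is(pa, "Proteome"), is(pb, "Proteome"))
  if (!length(proteins(pa)) || !length(proteins(pb)))
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), aln_len = integer(),
                      cov_shorter = numeric(), bitscore = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  sa <- as.character(proteins(pa)); sb <- as.character(proteins(pb))
  search <- .aaSearch(sa, sb, scheme, sum(nchar(sb)))
  best <- .bestPerRow(search, maxEvalue)
  keep <- which(!is.na(best))
  ga <- names(best)[keep]; gb <- unname(best[keep])
  idx <- cbind(match(ga, rownames(search$score)),
               match(gb, colnames(search$score)))
  shorter <- pmin(nchar(sa)[idx[, 1]], nchar(sb)[idx[, 2]])
  # coverage of the shorter protein: aligned columns minus gap columns
  # cannot exceed the span, so use matched columns (n_id <= matches).
  matched <- search$aln_len[idx]
  data.frame(
    gene_a = ga, gene_b = gb,
    identity = 100 * search$n_id[idx] / pmax(search$aln_len[idx], 1L),
    aln_len = search$aln_len[idx],
    cov_shorter = 100 * pmin(matched, shorter) / shorter,
    bitscore = search$bitscore[idx], evalue = search$evalue[idx],
    stringsAsFactors = FALSE)
}

#' Average amino acid identity over reciprocal best hits
#'
#' Best hits are computed in both directions from one all-vs-all
#' Smith-Waterman search; a gene pair is a reciprocal best hit (RBH)
#' when each member is the other's best hit. RBH pairs failing
#' \code{minIdentity}\% identity or \code{minCov}\% coverage of the
#' shorter protein are discarded; AAI is the mean identity over the
#' surviving pairs (symmetric by construction). Zero surviving pairs
#' yield an explicit no-signal state.
#'
#' @param pa,pb \code{\linkS4class{Proteome}} objects.
#' @param minIdentity,minCov retention thresholds (defaults 30 / 70).
#' @param maxEvalue best-hit e-value cutoff (default 1e-5).
#' @param scheme amino-acid \code{\linkS4class{ScoringScheme}}.
#' @return An \code{\linkS4class{AaiResult}}.
#' @export
aai <- function(pa, pb, minIdentity = 30, minCov = 70, maxEvalue = 1e-5,
                scheme = scoringScheme("aa")) {
  stopifnot(is(pa, "Proteome"), is(pb, "Proteome"))
  sa <- as.character(proteins(pa)); sb <- as.character(proteins(pb))
  if (!length(sa) || !length(sb)) stop("proteomes must be non-empty")
  search <- .aaSearch(sa, sb, scheme, sum(nchar(sb)))
  bestAB <- .bestPerRow(search, maxEvalue)
  # reuse the same alignments for the reverse direction (SW is symmetric)
  rev_search <- list(score = t(search$score), n_id = t(search$n_id),
                     aln_len = t(search$aln_len),
                     bitscore = t(search$bitscore))
  rev_search$evalue <- .evalue(rev_search$bitscore,
                               matrix(nchar(sb), nrow = length(sb),
                                      ncol = length(sa)), sum(nchar(sa)))
  bestBA <- .bestPerRow(rev_search, maxEvalue)
  ga <- names(bestAB)[!is.na(bestAB)]
  rbh <- ga[!is.na(bestBA[bestAB[ga]]) & bestBA[bestAB[ga]] == ga]
  if (length(rbh)) {
    gb <- unname(bestAB[rbh])
    idx <- cbind(match(rbh, rownames(search$score)),
                 match(gb, colnames(search$score)))
    identity <- 100 * search$n_id[idx] / pmax(search$aln_len[idx], 1L)
    shorter <- pmin(nchar(sa)[idx[, 1]], nchar(sb)[idx[, 2]])
    cov <- 100 * pmin(search$aln_len[idx], shorter) / shorter
    keep <- identity >= minIdentity & cov >= minCov
    pairs <- data.frame(gene_a = rbh, gene_b = gb, identity = identity,
                        aln_len = search$aln_len[idx], cov_shorter = cov,
                        stringsAsFactors = FALSE)[keep, ]
  } else {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        identity = numeric(), aln_len = integer(),
                        cov_shorter = numeric(), stringsAsFactors = FALSE)
  }
  n <- nrow(pairs)
  new("AaiResult",
      genomeA = genomeId(pa), genomeB = genomeId(pb),
      aai = if (n) mean(pairs$identity) else NA_real_,
      nRbh = as.integer(n),
      fractionMatched = n / min(length(sa), length(sb)),
      noSignal = n == 0L,
      pairs = pairs)
}

#' All-vs-all AAI matrix
#'
#' @param proteomes list of \code{\linkS4class{Proteome}} objects.
#' @param ... parameters passed to \code{\link{aai}}.
#' @return Symmetric matrix of AAI values (\%), diagonal 100.
#' @export
aaiMatrix <- function(proteomes, ...) {
  ids <- vapply(proteomes, genomeId, character(1))
  n <- length(proteomes)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  if (n >= 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- aai(proteomes[[i]], proteomes[[j]], ...)
      m[i, j] <- m[j, i] <- r@aai
    }
  m
}
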