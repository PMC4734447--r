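#' @include alignkern.R seqio.R
NULL

#' One-way fragment-based average nucleotide identity
#'
#' The query genome is cut into non-overlapping fragments
#' (\code{\link{fragmentGenome}}) and each fragment is aligned to every
#' subject contig by seed-and-extend local alignment; a fragment is
#' retained when its best alignment reaches at least
#' \code{minIdentity}\% identity over at least \code{minFragCov}\% of
#' the fragment length. The one-way ANI is the mean identity over
#' retained fragments. When no fragment is retained the result is an
#' explicit no-signal state (never 0).
#'
#' @param query,subject \code{\linkS4class{Genome}} objects.
#' @param fragLen fragment length in bp (default 1020).
#' @param minIdentity retention threshold on percent identity
#'   (default 30).
#' @param minFragCov retention threshold on percent of the fragment
#'   covered by the alignment (default 70).
#' @param scheme nucleotide \code{\linkS4class{ScoringScheme}}.
#' @param k,band,maxWindows seed-and-extend controls, see
#'   \code{\link{localAlignNt}}.
#' @return A list with \code{mean_identity} (\% or \code{NA}),
#'   \code{n_used}, \code{n_fragments}, \code{aligned_fraction},
#'   \code{no_signal}, and \code{fragments}: per-fragment data.frame
#'   with identity, \code{n_id}, \code{aln_len} and retention flag
#'   (used for pooled genome distances).
#' @seealso \code{\link{ani}}, \code{\link{genomeDistance}}
#' @export
aniOneway <- function(query, subject, fragLen = 1020L, minIdentity = 30,
                      minFragCov = 70, scheme = scoringScheme("nt"),
                      k = 11L, band = 32L, maxWindows = 8L) {
  stopifnot(is(query, "Genome"), is(subject, "Genome"))
  frags <- fragmentGenome(query, fragLen)
  if (!length(frags))
    return(list(mean_identity = NA_real_, n_used = 0L, n_fragments = 0L,
                aligned_fraction = 0, no_signal = TRUE,
                fragments = NULL))
  fr_chr <- as.character(frags)
  sub <- .subMatrix(scheme)
  best <- NULL
  for (ci in seq_along(contigs(subject))) {
    hits <- cpp_frag_map(fr_chr, as.character(contigs(subject)[[ci]]),
                         sub, scheme@gapOpen, scheme@gapExtend,
                         as.integer(k), as.integer(band),
                         as.integer(maxWindows))
    if (is.null(best)) {
      best <- hits
    } else {
      better <- !is.na(hits$score) &
        (is.na(best$score) | hits$score > best$score)
      best[better, ] <- hits[better, ]
    }
  }
  flen <- nchar(fr_chr)
  identity <- 100 * best$n_id / best$aln_len
  qcov <- 100 * (best$qend - best$qstart) / flen
  retained <- !is.na(best$score) & identity >= minIdentity &
    qcov >= minFragCov
  fragments <- data.frame(fragment = names(frags), length = flen,
                          identity = identity, n_id = best$n_id,
                          aln_len = best$aln_len, qcov = qcov,
                          strand = best$strand, retained = retained,
                          stringsAsFactors = FALSE)
  n_used <- sum(retained)
  list(
    mean_identity = if (n_used) mean(identity[retained]) else NA_real_,
    n_used = n_used,
    n_fragments = length(frags),
    aligned_fraction = n_used / length(frags),
    no_signal = n_used == 0L,
    fragments = fragments)
}

#' Two-way average nucleotide identity
#'
#' Runs \code{\link{aniOneway}} in both directions; the two-way ANI is
#' the arithmetic mean of the two one-way means (symmetric by
#' construction). If one direction has no signal the other direction's
#' mean is reported; if both have none the result is flagged
#' no-signal.
#'
#' @param a,b \code{\linkS4class{Genome}} objects.
#' @param ... parameters passed to \code{\link{aniOneway}}.
#' @return An \code{\linkS4class{AniResult}}.
#' @examples
#' g <- genome("g", c(c1 = paste(rep("ACGTTGCA", 400), collapse = "")))
#' ani(g, g)
#' @export
ani <- function(a, b, ...) {
  ab <- aniOneway(a, b, ...)
  ba <- aniOneway(b, a, ...)
  vals <- c(ab$mean_identity, ba$mean_identity)
  ok <- !is.na(vals)
  new("AniResult",
      genomeA = genomeId(a), genomeB = genomeId(b),
      aniAB = ab$mean_identity, aniBA = ba$mean_identity,
      ani = if (any(ok)) mean(vals[ok]) else NA_real_,
      nFragmentsAB = ab$n_used, nFragmentsBA = ba$n_used,
      alignedFractionAB = ab$aligned_fraction,
      alignedFractionBA = ba$aligned_fraction,
      noSignal = !any(ok),
      details = list(ab = ab, ba = ba))
}

#' All-vs-all ANI matrix
#'
#' @param genomes list of \code{\linkS4class{Genome}} objects.
#' @param ... parameters passed to \code{\link{ani}}.
#' @return Symmetric matrix of two-way ANI values (\%), diagonal 100;
#'   \code{NA} for no-signal pairs.
#' @export
aniMatrix <- function(genomes, ...) {
  ids <- vapply(genomes, genomeId, character(1))
  n <- length(genomes)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  if (n >= 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- ani(genomes[[i]], genomes[[j]], ...)
      m[i, j] <- m[j, i] <- r@ani
    }
  m
}
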