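#' @include AllClasses.R
NULL

#' Create a scoring scheme
#'
#' Defaults: nucleotide +1 match / -2 mismatch, amino-acid BLOSUM62;
#' gap open 11, gap extend 1 (a gap of length L costs
#' \code{gapOpen + L * gapExtend}); Karlin-Altschul constants are the
#' standard published gapped values for these scorings (nt: lambda
#' 1.28, K 0.46; BLOSUM62: lambda 0.267, K 0.041).
#'
#' @param kind \code{"nt"} or \code{"aa"}.
#' @param match,mismatch nucleotide scores (ignored for \code{"aa"}).
#' @param matrixName amino-acid substitution matrix (one of the
#'   matrices shipped with Biostrings, e.g. \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend affine gap penalties.
#' @param lambda,K Karlin-Altschul parameters for bitscore/e-value
#'   conversion; defaults follow \code{kind}.
#' @return A \code{\linkS4class{ScoringScheme}}.
#' @export
scoringScheme <- function(kind = c("nt", "aa"), match = 1, mismatch = -2,
                          matrixName = "BLOSUM62", gapOpen = 11,
                          gapExtend = 1, lambda = NULL, K = NULL) {
  kind <- match.arg(kind)
  if (is.null(lambda)) lambda <- if (kind == "nt") 1.28 else 0.267
  if (is.null(K)) K <- if (kind == "nt") 0.46 else 0.041
  new("ScoringScheme", kind = kind, match = match, mismatch = mismatch,
      matrixName = matrixName, gapOpen = gapOpen, gapExtend = gapExtend,
      lambda = lambda, K = K)
}

# substitution matrix for a scheme: nt = match/mismatch over the IUPAC
# alphabet (every ambiguity code, including N, scores as a mismatch
# against everything, itself included); aa = named matrix from
# Biostrings, cached after first load
.matrixCache <- new.env(parent = emptyenv())
.subMatrix <- function(scheme) {
  if (scheme@kind == "nt") {
    key <- paste0("nt_", scheme@match, "_", scheme@mismatch)
    if (is.null(.matrixCache[[key]])) {
      chars <- strsplit(.NT_CHARS, "")[[1]]
      m <- matrix(scheme@mismatch, length(chars), length(chars),
                  dimnames = list(chars, chars))
      for (b in c("A", "C", "G", "T")) m[b, b] <- scheme@match
      .matrixCache[[key]] <- m
    }
    .matrixCache[[key]]
  } else {
    if (is.null(.matrixCache[[scheme@matrixName]]))
      .matrixCache[[scheme@matrixName]] <-
        get(data(list = scheme@matrixName, package = "Biostrings",
                 envir = environment())[1], envir = environment())
    .matrixCache[[scheme@matrixName]]
  }
}

.bitscore <- function(score, scheme)
  (scheme@lambda * score - log(scheme@K)) / log(2)

.evalue <- function(bitscore, m, n) m * n * 2^(-bitscore)

# build an AlignmentResult from a kernel hit list
.alnResult <- function(hit, queryId, subjectId, scheme, m, n,
                       strand = NULL) {
  bs <- .bitscore(hit$score, scheme)
  if (is.null(strand)) strand <- if (is.null(hit$strand)) "+" else hit$strand
  new("AlignmentResult",
      queryId = queryId, subjectId = subjectId,
      queryStart = as.integer(hit$qstart), queryEnd = as.integer(hit$qend),
      subjectStart = as.integer(hit$sstart),
      subjectEnd = as.integer(hit$send),
      alignedQuery = if (is.null(hit$aligned_query)) NA_character_
                     else hit$aligned_query,
      alignedSubject = if (is.null(hit$aligned_subject)) NA_character_
                       else hit$aligned_subject,
      nIdentical = as.integer(hit$n_id), alnLen = as.integer(hit$aln_len),
      score = hit$score, bitscore = bs, evalue = .evalue(bs, m, n),
      strand = strand)
}

.asSeqChar <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  toupper(x[[1]])
}

#' Nucleotide local alignment by seed-and-extend
#'
#' Finds the best local alignment of \code{query} against
#' \code{subject} on both strands: exact k-mer seeds are located on an
#' index of the subject, seeds on nearby diagonals are grouped, and
#' each candidate region is resolved by affine-gap Smith-Waterman
#' restricted to a window around the seeds (small subjects are aligned
#' in full, where the result equals exhaustive Smith-Waterman). Ties
#' between strands go to "+"; within a strand to the smaller subject
#' start. Minus-strand hits report query coordinates on the original
#' query with \code{strand = "-"}.
#'
#' @param query,subject nucleotide sequences (character or
#'   \code{DNAString(Set)}).
#' @param scheme a nucleotide \code{\linkS4class{ScoringScheme}}.
#' @param k seed length (default 11).
#' @param band diagonal grouping tolerance / window margin in bp.
#' @param maxWindows candidate windows evaluated per strand on large
#'   subjects.
#' @param dbSize database size for e-value computation (default:
#'   subject length).
#' @param queryId,subjectId labels carried into the result.
#' @return An \code{\linkS4class{AlignmentResult}}, or \code{NULL} when
#'   no seed matches (e.g. sequences shorter than \code{k}).
#' @export
localAlignNt <- function(query, subject, scheme = scoringScheme("nt"),
                         k = 11L, band = 32L, maxWindows = 8L,
                         dbSize = NULL, queryId = "query",
                         subjectId = "subject") {
  stopifnot(scheme@kind == "nt")
  q <- .asSeqChar(query); s <- .asSeqChar(subject)
  if (nchar(q) < k || nchar(s) < k) return(NULL)
  hit <- cpp_seed_extend(q, s, .subMatrix(scheme), scheme@gapOpen,
                         scheme@gapExtend, as.integer(k),
                         as.integer(band), as.integer(maxWindows), TRUE)
  if (is.null(hit)) return(NULL)
  if (is.null(dbSize)) dbSize <- nchar(s)
  .alnResult(hit, queryId, subjectId, scheme, nchar(q), dbSize)
}

#' Protein local alignment (full Smith-Waterman)
#'
#' Exhaustive affine-gap Smith-Waterman with the configured
#' substitution matrix; no heuristic, affordable at proteome scale.
#'
#' @param query,subject amino-acid sequences.
#' @param scheme an amino-acid \code{\linkS4class{ScoringScheme}}.
#' @param dbSize total residues of the database searched, for the
#'   e-value (default: subject length).
#' @param queryId,subjectId labels carried into the result.
#' @return An \code{\linkS4class{AlignmentResult}}, or \code{NULL} when
#'   no positive-scoring window exists.
#' @export
localAlignAa <- function(query, subject, scheme = scoringScheme("aa"),
                         dbSize = NULL, queryId = "query",
                         subjectId = "subject") {
  stopifnot(scheme@kind == "aa")
  q <- .asSeqChar(query); s <- .asSeqChar(subject)
  if (!nchar(q) || !nchar(s)) stop("sequences must be non-empty")
  hit <- cpp_sw_align(q, s, .subMatrix(scheme), scheme@gapOpen,
                      scheme@gapExtend, FALSE, TRUE)
  if (is.null(hit)) return(NULL)
  if (is.null(dbSize)) dbSize <- nchar(s)
  .alnResult(hit, queryId, subjectId, scheme, nchar(q), dbSize)
}

#' Global alignment (Needleman-Wunsch, affine gaps)
#'
#' End-to-end alignment; identity is computed over all columns, a gap
#' column counting as a non-identity, so
#' \code{identityPercent} is symmetric in the two inputs.
#'
#' @param a,b sequences of the scheme's alphabet.
#' @param scheme a \code{\linkS4class{ScoringScheme}}.
#' @param queryId,subjectId labels carried into the result.
#' @return An \code{\linkS4class{AlignmentResult}} spanning both
#'   sequences fully.
#' @export
globalAlign <- function(a, b, scheme = scoringScheme("nt"),
                        queryId = "a", subjectId = "b") {
  sa <- .asSeqChar(a); sb <- .asSeqChar(b)
  if (!nchar(sa) || !nchar(sb)) stop("sequences must be non-empty")
  hit <- cpp_nw_align(sa, sb, .subMatrix(scheme), scheme@gapOpen,
                      scheme@gapExtend, scheme@kind == "nt")
  .alnResult(hit, queryId, subjectId, scheme, nchar(sa), nchar(sb))
}
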