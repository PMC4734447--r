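#' @include alignkern.R phylogeny.R
NULL

#' Extract a marker gene from a genome by homology
#'
#' Locates the best local alignment of a reference marker sequence
#' (e.g. a 16S rRNA gene) against every contig of the genome, both
#' strands, and extracts the aligned subject span. Minus-strand hits
#' are reverse-complemented to reference orientation. Returns
#' \code{NULL} when the best alignment covers less than
#' \code{minCov} of the reference.
#'
#' @param g a \code{\linkS4class{Genome}}.
#' @param refSeq reference marker sequence (character or
#'   \code{DNAString}).
#' @param name marker name (e.g. \code{"rrsA"}).
#' @param minCov minimum fraction of the reference covered
#'   (default 0.5).
#' @param scheme nucleotide \code{\linkS4class{ScoringScheme}}.
#' @return A \code{\linkS4class{MarkerHit}} or \code{NULL}.
#' @export
extractMarker <- function(g, refSeq, name, minCov = 0.5,
                          scheme = scoringScheme("nt")) {
  stopifnot(is(g, "Genome"))
  ref <- .asSeqChar(refSeq)
  if (!nchar(ref)) stop("reference marker sequence must be non-empty")
  best <- NULL
  bestContig <- NULL
  for (ci in seq_along(contigs(g))) {
    al <- localAlignNt(ref, contigs(g)[[ci]], scheme,
                       queryId = name, subjectId = names(contigs(g))[ci])
    if (is.null(al)) next
    if (is.null(best) || al@score > best@score) {
      best <- al
      bestContig <- names(contigs(g))[ci]
    }
  }
  if (is.null(best)) return(NULL)
  if ((best@queryEnd - best@queryStart) / nchar(ref) < minCov)
    return(NULL)
  seq <- as.character(subseq(contigs(g)[[bestContig]],
                             best@subjectStart + 1L, best@subjectEnd))
  if (best@strand == "-") seq <- cpp_revcomp(seq)
  new("MarkerHit", genomeId = g@genomeId, marker = name, seq = seq,
      contig = bestContig, start = best@subjectStart,
      end = best@subjectEnd, strand = best@strand,
      identity = identityPercent(best))
}

#' Pairwise identity matrix for one marker
#'
#' Global-alignment percent identity between the extracted marker
#' sequences of each genome pair (gap columns count as non-identity);
#' diagonal 100. Genomes lacking the marker are excluded and listed in
#' the \code{"missing"} attribute.
#'
#' @param hits named list of \code{\linkS4class{MarkerHit}} or
#'   \code{NULL} per genome (as from \code{\link{extractMarker}}).
#' @param scheme nucleotide \code{\linkS4class{ScoringScheme}}.
#' @return Symmetric percent-identity matrix over carrier genomes.
#' @export
markerIdentityMatrix <- function(hits, scheme = scoringScheme("nt")) {
  carriers <- names(hits)[!vapply(hits, is.null, logical(1))]
  if (length(carriers) < 2)
    stop("need >= 2 genomes carrying the marker")
  n <- length(carriers)
  m <- matrix(100, n, n, dimnames = list(carriers, carriers))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- globalAlign(hits[[carriers[i]]]@seq, hits[[carriers[j]]]@seq,
                      scheme)
    m[i, j] <- m[j, i] <- identityPercent(al)
  }
  attr(m, "missing") <- setdiff(names(hits), carriers)
  m
}

.MLSA_ORDER <- c("rrsA", "gyrB", "pyrH", "recA", "rpoB")

#' Multi-locus sequence analysis
#'
#' Extracts each marker from each genome by homology to the supplied
#' references, aligns every marker across its carriers
#' (\code{\link{progressiveMsa}}), pads genomes lacking a marker with
#' gap columns, concatenates the marker alignments in the fixed order
#' rrsA, gyrB, pyrH, recA, rpoB (other reference names follow in the
#' given order), and computes a p-distance matrix on the concatenation
#' (pairwise deletion of gap/ambiguous columns). Genomes carrying
#' fewer than \code{minMarkers} markers are excluded with a warning.
#'
#' @param genomes list of \code{\linkS4class{Genome}} objects.
#' @param refs named list/\code{DNAStringSet} of reference marker
#'   sequences.
#' @param minMarkers minimum markers per genome (default 3).
#' @param scheme nucleotide \code{\linkS4class{ScoringScheme}}.
#' @return List with \code{perMarkerIdentity} (list of identity
#'   matrices), \code{concatenated} (\code{\linkS4class{Msa}}),
#'   \code{distance} (p-distance matrix), \code{markersMissing}
#'   (named list), and \code{hits}.
#' @export
mlsa <- function(genomes, refs, minMarkers = 3L,
                 scheme = scoringScheme("nt")) {
  if (is(refs, "XStringSet")) refs <- as.list(as.character(refs))
  markerNames <- c(intersect(.MLSA_ORDER, names(refs)),
                   setdiff(names(refs), .MLSA_ORDER))
  ids <- vapply(genomes, genomeId, character(1))
  names(genomes) <- ids
  hits <- lapply(markerNames, function(mk) {
    h <- lapply(genomes, extractMarker, refSeq = refs[[mk]], name = mk,
                scheme = scheme)
    names(h) <- ids
    h
  })
  names(hits) <- markerNames
  carried <- vapply(ids, function(g)
    sum(vapply(hits, function(h) !is.null(h[[g]]), logical(1))),
    numeric(1))
  keep <- ids[carried >= minMarkers]
  if (length(drop <- setdiff(ids, keep)))
    warning("genome(s) below the marker floor excluded: ",
            paste(drop, collapse = ", "))
  if (length(keep) < 2) stop("fewer than 2 genomes pass the marker floor")
  missingList <- lapply(keep, function(g)
    markerNames[vapply(hits, function(h) is.null(h[[g]]), logical(1))])
  names(missingList) <- keep
  blocks <- list()
  for (mk in markerNames) {
    carriers <- keep[!vapply(hits[[mk]][keep], is.null, logical(1))]
    if (length(carriers) < 2) next
    seqs <- vapply(hits[[mk]][carriers], function(h) h@seq, character(1))
    al <- progressiveMsa(seqs, scheme)
    w <- nchar(al@seqs[[1]])
    rows <- stats::setNames(rep(strrep("-", w), length(keep)), keep)
    rows[carriers] <- al@seqs[carriers]
    blocks[[mk]] <- msa(rows, "nt")
  }
  if (!length(blocks)) stop("no marker alignable across >= 2 genomes")
  concat <- concatenateMsa(blocks)
  idMats <- lapply(markerNames, function(mk) {
    carriers <- names(hits[[mk]])[!vapply(hits[[mk]], is.null,
                                          logical(1))]
    if (length(carriers) >= 2) markerIdentityMatrix(hits[[mk]], scheme)
    else NULL
  })
  names(idMats) <- markerNames
  list(perMarkerIdentity = idMats, concatenated = concat,
       distance = pDistance(concat), markersMissing = missingList,
       hits = hits)
}

#' p-distance matrix of a nucleotide alignment
#'
#' Proportion of mismatching columns per pair, over columns where both
#' sequences hold an unambiguous base (pairwise deletion). Zero
#' diagonal; \code{NA} when a pair shares no comparable column.
#'
#' @param msaNt a nucleotide \code{\linkS4class{Msa}}.
#' @return Symmetric distance matrix.
#' @export
pDistance <- function(msaNt) {
  stopifnot(is(msaNt, "Msa"), msaNt@alphabet == "nt")
  M <- do.call(rbind, strsplit(msaNt@seqs, ""))
  rownames(M) <- names(msaNt@seqs)
  ok <- M %in% c("A", "C", "G", "T")
  dim(ok) <- dim(M)
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    D[i, j] <- D[j, i] <- if (any(use))
      sum(M[i, use] != M[j, use]) / sum(use) else NA_real_
  }
  D
}
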