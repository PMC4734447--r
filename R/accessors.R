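#' @include AllClasses.R
NULL

#' Accessors for GenomicTaxonomy objects
#'
#' Small accessor generics: \code{genomeId} returns the genome label of
#' an object; \code{contigs} the \code{DNAStringSet} of a
#' \code{Genome}; \code{proteins} and \code{cdsSeqs} the sequence sets
#' of a \code{Proteome}; \code{identityPercent} the percent identity of
#' an \code{AlignmentResult} (100 * identical columns / alignment
#' columns, gap columns counting as non-identity); \code{alignedSeqs}
#' the named gapped rows of an \code{Msa}; \code{rhoValues} the 16
#' dinucleotide odds ratios of a \code{DinucProfile};
#' \code{groupTable} the gene-to-group assignment of a
#' \code{HomologGroups}.
#'
#' @param x an object of the documented class.
#' @return See each accessor's description.
#' @name accessors
#' @aliases genomeId contigs proteins cdsSeqs identityPercent
#'   alignedSeqs rhoValues groupTable
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))
#' @rdname accessors
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))
#' @rdname accessors
#' @export
setGeneric("identityPercent", function(x) standardGeneric("identityPercent"))
#' @rdname accessors
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))
#' @rdname accessors
#' @export
setGeneric("rhoValues", function(x) standardGeneric("rhoValues"))
#' @rdname accessors
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))

setMethod("genomeId", "Genome", function(x) x@genomeId)
setMethod("genomeId", "Proteome", function(x) x@genomeId)
setMethod("genomeId", "DinucProfile", function(x) x@genomeId)
setMethod("contigs", "Genome", function(x) x@contigs)
setMethod("proteins", "Proteome", function(x) x@proteins)
setMethod("cdsSeqs", "Proteome", function(x) x@cds)
setMethod("identityPercent", "AlignmentResult",
          function(x) 100 * x@nIdentical / x@alnLen)
setMethod("alignedSeqs", "Msa", function(x) x@seqs)
setMethod("rhoValues", "DinucProfile", function(x) x@rho)
setMethod("groupTable", "HomologGroups", function(x) x@table)

setMethod("show", "Genome", function(object) {
  cat("Genome '", object@genomeId, "': ", length(object@contigs),
      " contig(s), ", sum(width(object@contigs)), " bp\n", sep = "")
})

setMethod("show", "Proteome", function(object) {
  cat("Proteome '", object@genomeId, "': ", length(object@proteins),
      " proteins", if (length(object@cds)) " (with CDS)" else "",
      "\n", sep = "")
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult %s vs %s [%s]: score %.1f, identity %.2f%% (%d/%d), evalue %.3g\n",
    object@queryId, object@subjectId, object@strand, object@score,
    identityPercent(object), object@nIdentical, object@alnLen,
    object@evalue))
  cat(sprintf("  query [%d,%d)  subject [%d,%d)\n", object@queryStart,
              object@queryEnd, object@subjectStart, object@subjectEnd))
})

setMethod("show", "AniResult", function(object) {
  if (object@noSignal) {
    cat(sprintf("ANI %s vs %s: no signal\n", object@genomeA,
                object@genomeB))
  } else {
    cat(sprintf(
      "ANI %s vs %s: %.2f%% (a->b %.2f%%, b->a %.2f%%; fragments %d/%d)\n",
      object@genomeA, object@genomeB, object@ani, object@aniAB,
      object@aniBA, object@nFragmentsAB, object@nFragmentsBA))
  }
})

setMethod("show", "AaiResult", function(object) {
  if (object@noSignal) {
    cat(sprintf("AAI %s vs %s: no signal\n", object@genomeA,
                object@genomeB))
  } else {
    cat(sprintf("AAI %s vs %s: %.2f%% over %d reciprocal best hits\n",
                object@genomeA, object@genomeB, object@aai, object@nRbh))
  }
})

setMethod("show", "DinucProfile", function(object) {
  cat("Dinucleotide signature of '", object@genomeId, "' (",
      format(object@nDinucs, big.mark = ","), " dinucleotides)\n",
      sep = "")
  print(round(object@rho, 4))
})

setMethod("show", "GenomeDistance", function(object) {
  if (object@noSignal)
    cat(sprintf("Genome distance %s vs %s: no signal\n", object@genomeA,
                object@genomeB))
  else
    cat(sprintf("Genome distance %s vs %s: d = %.4f (%s/%s columns identical)\n",
                object@genomeA, object@genomeB, object@d,
                format(object@nIdentical, big.mark = ","),
                format(object@nColumns, big.mark = ",")))
})

setMethod("show", "DdhEstimate", function(object) {
  cat(sprintf(
    "In-silico DDH %s vs %s: %.1f%% (d = %.4f; logistic alpha %.3f, beta %.3f)\n",
    object@genomeA, object@genomeB, object@predictedDdh, object@d,
    object@alpha, object@beta))
})

setMethod("show", "Msa", function(object) {
  cat("Msa (", object@alphabet, "): ", length(object@seqs), " rows x ",
      nchar(object@seqs[1]), " columns\n", sep = "")
  if (nrow(object@genes))
    cat("  concatenation of", nrow(object@genes), "genes\n")
})

setMethod("show", "HomologGroups", function(object) {
  cat("HomologGroups:", length(unique(object@table$group)), "groups over",
      nrow(object@table), "genes from", length(object@genomeIds),
      "genomes (inflation", object@inflation, ")\n")
})

setMethod("show", "MarkerHit", function(object) {
  cat(sprintf("MarkerHit %s/%s: %s[%d,%d) strand %s, identity %.2f%%\n",
              object@genomeId, object@marker, object@contig,
              object@start, object@end, object@strand, object@identity))
})

setMethod("show", "TaxonomyCall", function(object) {
  cat(sprintf("TaxonomyCall %s vs %s: consensus %s\n", object@genomeA,
              object@genomeB, object@consensus))
  for (m in names(object@verdicts))
    cat(sprintf("  %-6s %10.4g  -> %s\n", m, object@values[[m]],
                object@verdicts[[m]]))
})
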