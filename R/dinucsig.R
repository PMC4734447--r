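#' @include seqio.R
NULL

.DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))

#' Dinucleotide relative-abundance signature
#'
#' Computes the 16 Karlin odds ratios rho*XY = f*XY / (f*X f*Y), with
#' mono- and dinucleotide frequencies counted per contig on the contig
#' concatenated with its reverse complement (so the profile is
#' strand-invariant by construction). Dinucleotides are not counted
#' across contig junctions or across the concatenation seam, and any
#' pair containing an ambiguity code is skipped.
#'
#' @param g a \code{\linkS4class{Genome}}.
#' @return A \code{\linkS4class{DinucProfile}}.
#' @examples
#' g <- genome("g", c(c1 = paste(rep("ACGT", 100), collapse = "")))
#' rhoValues(dinucProfile(g))
#' @export
dinucProfile <- function(g) {
  stopifnot(is(g, "Genome"))
  both <- c(g@contigs, reverseComplement(g@contigs))
  mono <- colSums(alphabetFrequency(both)[, c("A", "C", "G", "T"),
                                          drop = FALSE])
  if (any(mono == 0))
    stop("rho undefined: base(s) ",
         paste(names(mono)[mono == 0], collapse = ","),
         " absent from genome '", g@genomeId, "'")
  di <- colSums(dinucleotideFrequency(both))[.DINUCS]
  ndi <- sum(di)
  if (ndi == 0) stop("rho undefined: fewer than 2 unambiguous bases")
  f_mono <- mono / sum(mono)
  f_di <- di / ndi
  expect <- as.vector(outer(f_mono, f_mono)) # row = first base, col = second
  names(expect) <- .DINUCS
  new("DinucProfile", genomeId = g@genomeId,
      rho = f_di / expect[.DINUCS], nDinucs = ndi)
}

#' Delta distance between two dinucleotide signatures
#'
#' delta(a, b) = (1/16) sum over the 16 dinucleotides of
#' |rho*XY(a) - rho*XY(b)|: a scaled L1 metric (non-negative,
#' symmetric, zero on identical profiles, triangle inequality). The
#' value is reported on the raw scale used by the 0.01 species cutoff;
#' set \code{times1000 = TRUE} for the conventional x1000 display
#' scale.
#'
#' @param a,b \code{\linkS4class{DinucProfile}} objects.
#' @param times1000 report on the x1000 display scale (default FALSE).
#' @return Numeric delta distance.
#' @export
deltaDistance <- function(a, b, times1000 = FALSE) {
  stopifnot(is(a, "DinucProfile"), is(b, "DinucProfile"))
  d <- mean(abs(a@rho[.DINUCS] - b@rho[.DINUCS]))
  if (times1000) 1000 * d else d
}

#' All-vs-all delta distance matrix
#'
#' @param genomes list of \code{\linkS4class{Genome}} objects.
#' @param times1000 report on the x1000 display scale.
#' @return Symmetric matrix of delta distances, zero diagonal.
#' @export
deltaMatrix <- function(genomes, times1000 = FALSE) {
  profiles <- lapply(genomes, dinucProfile)
  ids <- vapply(profiles, genomeId, character(1))
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- deltaDistance(profiles[[i]], profiles[[j]],
                                          times1000)
  m
}
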