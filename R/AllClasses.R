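#' @include GenomicTaxonomy-package.R
NULL

#' Genome: one replicon set
#'
#' Holds the nucleotide sequence(s) of one genome: a short unique label,
#' an ordered \code{DNAStringSet} of contigs (stored uppercase), and
#' free-form provenance metadata (e.g. source, accession).
#'
#' @slot genomeId single character label, unique within a run.
#' @slot contigs \code{DNAStringSet} of contig sequences, named.
#' @slot metadata named list of provenance key/values.
#' @seealso \code{\link{genome}}, \code{\link{readGenome}},
#'   \code{\link{genomeStats}}
#' @exportClass Genome
setClass("Genome",
  representation(genomeId = "character", contigs = "DNAStringSet",
                 metadata = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@genomeId) != 1L || is.na(object@genomeId) ||
        !nzchar(object@genomeId))
      msg <- c(msg, "genomeId must be a single non-empty string")
    if (length(object@contigs) == 0L || sum(width(object@contigs)) == 0L)
      msg <- c(msg, "genome must contain at least one non-empty contig")
    nm <- names(object@contigs)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "contigs must carry unique non-empty names")
    if (is.null(msg)) TRUE else msg
  })

#' Proteome: per-genome gene products
#'
#' Amino-acid sequences keyed by gene id, optionally paired 1:1 with the
#' nucleotide CDS they were translated from. When CDS are present the
#' constructor verifies that each CDS translates to its protein (up to a
#' trailing stop codon).
#'
#' @slot genomeId genome label the proteome belongs to.
#' @slot proteins named \code{AAStringSet}, one entry per gene id.
#' @slot cds named \code{DNAStringSet} of coding sequences (may be empty).
#' @seealso \code{\link{proteome}}, \code{\link{readProteome}}
#' @exportClass Proteome
setClass("Proteome",
  representation(genomeId = "character", proteins = "AAStringSet",
                 cds = "DNAStringSet"),
  validity = function(object) {
    msg <- NULL
    if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
      msg <- c(msg, "genomeId must be a single non-empty string")
    nm <- names(object@proteins)
    if (length(object@proteins) &&
        (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))))
      msg <- c(msg, "proteins must carry unique non-empty gene ids")
    if (length(object@cds)) {
      if (!setequal(names(object@cds), nm))
        msg <- c(msg, "cds gene ids must match protein gene ids")
      if (any(width(object@cds) %% 3L != 0L))
        msg <- c(msg, "every CDS length must be divisible by 3")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Pairwise alignment scoring configuration
#'
#' Scoring used by all alignment kernels. Nucleotide mode scores
#' match/mismatch (ambiguity codes, including N, always score as
#' mismatches); amino-acid mode uses a named substitution matrix
#' (BLOSUM62 by default). Gap of length L costs
#' \code{gapOpen + L * gapExtend}. \code{lambda}/\code{K} are the
#' Karlin-Altschul parameters used to convert raw scores to bit scores
#' and e-values; the defaults are the standard published gapped
#' constants (nucleotide +1/-2: lambda 1.28, K 0.46; BLOSUM62 gapped:
#' lambda 0.267, K 0.041).
#'
#' @slot kind \code{"nt"} or \code{"aa"}.
#' @slot match,mismatch nucleotide match/mismatch scores.
#' @slot matrixName amino-acid substitution matrix name.
#' @slot gapOpen,gapExtend affine gap penalties (positive).
#' @slot lambda,K Karlin-Altschul statistics parameters.
#' @seealso \code{\link{scoringScheme}}
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(kind = "character", match = "numeric",
                 mismatch = "numeric", matrixName = "character",
                 gapOpen = "numeric", gapExtend = "numeric",
                 lambda = "numeric", K = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("nt", "aa"))
      msg <- c(msg, "kind must be 'nt' or 'aa'")
    if (object@gapOpen < object@gapExtend || object@gapExtend < 0)
      msg <- c(msg, "need gapOpen >= gapExtend >= 0")
    if (object@lambda <= 0 || object@K <= 0)
      msg <- c(msg, "Karlin-Altschul parameters must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Result of one pairwise alignment
#'
#' Coordinates are 0-based half-open on the ungapped input sequences.
#' \code{bitscore = (lambda * score - log(K)) / log(2)} and
#' \code{evalue = m * n * 2^-bitscore} with m the query length and n the
#' database size used for the search.
#'
#' @seealso \code{\link{localAlignNt}}, \code{\link{localAlignAa}},
#'   \code{\link{globalAlign}}, \code{\link{identityPercent}}
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(queryId = "character", subjectId = "character",
                 queryStart = "integer", queryEnd = "integer",
                 subjectStart = "integer", subjectEnd = "integer",
                 alignedQuery = "character", alignedSubject = "character",
                 nIdentical = "integer", alnLen = "integer",
                 score = "numeric", bitscore = "numeric",
                 evalue = "numeric", strand = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@nIdentical > object@alnLen)
      msg <- c(msg, "nIdentical cannot exceed alnLen")
    if (object@evalue < 0) msg <- c(msg, "evalue must be >= 0")
    if (!object@strand %in% c("+", "-"))
      msg <- c(msg, "strand must be '+' or '-'")
    if (is.null(msg)) TRUE else msg
  })

#' Two-way average nucleotide identity result
#'
#' @seealso \code{\link{ani}}
#' @exportClass AniResult
setClass("AniResult",
  representation(genomeA = "character", genomeB = "character",
                 aniAB = "numeric", aniBA = "numeric", ani = "numeric",
                 nFragmentsAB = "integer", nFragmentsBA = "integer",
                 alignedFractionAB = "numeric",
                 alignedFractionBA = "numeric",
                 noSignal = "logical", details = "list"))

#' Reciprocal-best-hit average amino acid identity result
#'
#' @seealso \code{\link{aai}}
#' @exportClass AaiResult
setClass("AaiResult",
  representation(genomeA = "character", genomeB = "character",
                 aai = "numeric", nRbh = "integer",
                 fractionMatched = "numeric", noSignal = "logical",
                 pairs = "data.frame"))

#' Dinucleotide relative-abundance signature
#'
#' The 16 odds ratios rho*XY = f*XY / (f*X f*Y), with frequencies
#' computed on each contig concatenated with its reverse complement
#' (strand-symmetrized; dinucleotides are never counted across contig
#' junctions or the concatenation seam, and pairs containing ambiguity
#' codes are skipped).
#'
#' @seealso \code{\link{dinucProfile}}, \code{\link{deltaDistance}}
#' @exportClass DinucProfile
setClass("DinucProfile",
  representation(genomeId = "character", rho = "numeric",
                 nDinucs = "numeric"),
  validity = function(object) {
    if (length(object@rho) != 16L)
      return("rho must hold exactly 16 dinucleotide odds ratios")
    TRUE
  })

#' Genome-wide alignment distance
#'
#' d = 1 - (identical columns) / (alignment columns), pooled over all
#' retained ANI fragment alignments from both directions.
#'
#' @seealso \code{\link{genomeDistance}}, \code{\link{ddhEstimate}}
#' @exportClass GenomeDistance
setClass("GenomeDistance",
  representation(genomeA = "character", genomeB = "character",
                 d = "numeric", nIdentical = "numeric",
                 nColumns = "numeric", noSignal = "logical"))

#' In-silico DNA-DNA hybridization estimate
#'
#' predictedDdh = 100 / (1 + exp(alpha + beta * d)), beta > 0.
#'
#' @seealso \code{\link{ddhEstimate}}, \code{\link{ddhModel}}
#' @exportClass DdhEstimate
setClass("DdhEstimate",
  representation(genomeA = "character", genomeB = "character",
                 predictedDdh = "numeric", alpha = "numeric",
                 beta = "numeric", d = "numeric"))

#' Multiple sequence alignment
#'
#' Equal-length gapped rows ('-' as gap) over a nucleotide or amino-acid
#' alphabet. Ungapping row i reproduces input sequence i exactly. For
#' concatenated alignments, \code{genes} maps each source gene to its
#' column range (0-based half-open).
#'
#' @seealso \code{\link{progressiveMsa}}, \code{\link{concatenateMsa}},
#'   \code{\link{backtranslate}}
#' @exportClass Msa
setClass("Msa",
  representation(seqs = "character", alphabet = "character",
                 genes = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (length(object@seqs) == 0L)
      msg <- c(msg, "alignment must contain at least one row")
    if (length(unique(nchar(object@seqs))) > 1L)
      msg <- c(msg, "all alignment rows must have equal length")
    if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
      msg <- c(msg, "rows must carry unique labels")
    if (!object@alphabet %in% c("nt", "aa"))
      msg <- c(msg, "alphabet must be 'nt' or 'aa'")
    if (is.null(msg)) TRUE else msg
  })

#' Homolog groups from Markov clustering
#'
#' A partition of all clustered genes into groups. \code{table} has one
#' row per gene with columns \code{gene} (genome-prefixed id),
#' \code{genome}, and \code{group}.
#'
#' @seealso \code{\link{mclCluster}}, \code{\link{pangenomeSummary}},
#'   \code{\link{singleCopyCore}}
#' @exportClass HomologGroups
setClass("HomologGroups",
  representation(table = "data.frame", genomeIds = "character",
                 inflation = "numeric"),
  validity = function(object) {
    need <- c("gene", "genome", "group")
    if (!all(need %in% names(object@table)))
      return("table needs columns gene, genome, group")
    if (anyDuplicated(object@table$gene))
      return("groups must partition genes: duplicated gene id")
    TRUE
  })

#' One extracted marker gene
#'
#' @seealso \code{\link{extractMarker}}
#' @exportClass MarkerHit
setClass("MarkerHit",
  representation(genomeId = "character", marker = "character",
                 seq = "character", contig = "character",
                 start = "integer", end = "integer", strand = "character",
                 identity = "numeric"))

#' Species-boundary verdicts for one genome pair
#'
#' Per-metric verdicts under the cutoff rules (ANI >= 95, AAI >= 95,
#' DDH >= 70 same species; delta <= 0.01 same species) and a consensus
#' call.
#'
#' @seealso \code{\link{callPair}}
#' @exportClass TaxonomyCall
setClass("TaxonomyCall",
  representation(genomeA = "character", genomeB = "character",
                 values = "numeric", verdicts = "character",
                 consensus = "character"))
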