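#' @include AllClasses.R
NULL

.NT_CHARS <- "ACGTNRYSWKMBDHV"
.AA_CHARS <- "ACDEFGHIKLMNPQRSTVWYX*"

#' Read a FASTA file with strict validation
#'
#' Reads nucleotide or amino-acid FASTA. Record ids are the first
#' whitespace-delimited token of each header; sequences are uppercased.
#' Nucleotide mode accepts A,C,G,T,N and IUPAC ambiguity codes;
#' amino-acid mode accepts the 20 amino acids plus X and '*'. Errors on
#' empty files ("no records"), duplicate ids, or illegal characters
#' (reported with record and position).
#'
#' @param path path to a FASTA file.
#' @param alphabet \code{"nt"} or \code{"aa"}.
#' @return A named \code{DNAStringSet} (\code{"nt"}) or
#'   \code{AAStringSet} (\code{"aa"}).
#' @examples
#' tf <- tempfile(fileext = ".fna")
#' writeLines(c(">g1 some description", "ACGT", "ACGT"), tf)
#' readFasta(tf, "nt")
#' @export
readFasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(readBStringSet(path),
                  error = function(e) stop("no records in ", path))
  if (length(raw) == 0L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record id '", dup[1], "' in ", path)
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record '", ids[which(nchar(seqs) == 0L)[1]],
         "' in ", path)
  legal <- if (alphabet == "nt") .NT_CHARS else .AA_CHARS
  bad <- regexpr(paste0("[^", gsub("\\*", "\\\\*", legal), "]"), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("illegal character '", substr(seqs[i], bad[i], bad[i]),
         "' at position ", bad[i], " of record '", ids[i], "'")
  }
  out <- if (alphabet == "nt") DNAStringSet(seqs) else AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param x a named \code{XStringSet} or named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- BStringSet(x)
  if (is.null(names(x))) stop("sequences must be named")
  writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Construct a Genome object
#'
#' @param genomeId short unique genome label.
#' @param contigsIn contig sequences: \code{DNAStringSet} or named
#'   character vector (uppercased on construction; unnamed single
#'   sequences get the name \code{"contig1"}).
#' @param metadata optional named list (source, accession, ...).
#' @return A \code{\linkS4class{Genome}}.
#' @examples
#' g <- genome("g1", c(chr = "ACGTACGT"))
#' genomeStats(g)
#' @export
genome <- function(genomeId, contigsIn, metadata = list()) {
  if (is.character(contigsIn)) {
    if (is.null(names(contigsIn)))
      names(contigsIn) <- paste0("contig", seq_along(contigsIn))
    contigsIn <- DNAStringSet(toupper(contigsIn))
  }
  new("Genome", genomeId = as.character(genomeId), contigs = contigsIn,
      metadata = metadata)
}

#' Read a genome FASTA into a Genome object
#'
#' @param path nucleotide FASTA path.
#' @param genomeId genome label; default the file name without extension.
#' @param metadata optional named list.
#' @return A \code{\linkS4class{Genome}}.
#' @export
readGenome <- function(path, genomeId = NULL, metadata = list()) {
  if (is.null(genomeId))
    genomeId <- sub("\\.[^.]*$", "", basename(path))
  genome(genomeId, readFasta(path, "nt"),
         c(metadata, list(source_file = path)))
}

#' Construct a Proteome object
#'
#' When \code{cds} is supplied, every CDS must have length divisible by
#' 3 and translate to its protein; a trailing stop codon on the CDS is
#' allowed and retained.
#'
#' @param genomeId genome label.
#' @param proteinsIn named \code{AAStringSet} or character vector.
#' @param cds optional named \code{DNAStringSet} or character vector of
#'   coding sequences matching the protein gene ids.
#' @return A \code{\linkS4class{Proteome}}.
#' @export
proteome <- function(genomeId, proteinsIn, cds = NULL) {
  if (is.character(proteinsIn)) proteinsIn <- AAStringSet(toupper(proteinsIn))
  if (is.null(cds)) {
    cds <- DNAStringSet()
  } else {
    if (is.character(cds)) cds <- DNAStringSet(toupper(cds))
    cds <- cds[names(proteinsIn)]
    .checkTranslation(proteinsIn, cds)
  }
  new("Proteome", genomeId = as.character(genomeId),
      proteins = proteinsIn, cds = cds)
}

.checkTranslation <- function(prots, cds) {
  aa <- .translateBatch(as.character(cds))
  want <- as.character(prots)[names(aa)]
  bad <- names(aa)[aa != want]
  if (length(bad))
    stop("CDS of gene '", bad[1], "' does not translate to its protein")
  invisible(TRUE)
}

# translate CDS vector, dropping one trailing stop if present
.translateBatch <- function(nt) {
  aa <- as.character(suppressWarnings(
    translate(DNAStringSet(nt), if.fuzzy.codon = "X")))
  stats::setNames(sub("\\*$", "", aa), names(nt))
}

.translateCds <- function(nt) unname(.translateBatch(c(x = nt)))

#' Read paired protein/CDS FASTA files into a Proteome
#'
#' @param proteinPath amino-acid FASTA.
#' @param cdsPath optional matching nucleotide CDS FASTA (same gene
#'   ids; translation consistency is checked).
#' @param genomeId genome label; default from the protein file name.
#' @return A \code{\linkS4class{Proteome}}.
#' @export
readProteome <- function(proteinPath, cdsPath = NULL, genomeId = NULL) {
  if (is.null(genomeId))
    genomeId <- sub("\\.[^.]*$", "", basename(proteinPath))
  prots <- readFasta(proteinPath, "aa")
  cds <- if (is.null(cdsPath)) NULL else readFasta(cdsPath, "nt")
  proteome(genomeId, prots, cds)
}

#' Per-genome summary statistics
#'
#' Total length, GC percent (over unambiguous A/C/G/T only, reported to
#' 2 decimals), contig count, and CDS count when a proteome is given.
#' GC is invariant under reverse complementation.
#'
#' @param g a \code{\linkS4class{Genome}}.
#' @param proteomeObj optional matching \code{\linkS4class{Proteome}};
#'   its size is reported as \code{n_cds}.
#' @return One-row \code{data.frame} with columns \code{genome_id},
#'   \code{length_bp}, \code{gc_percent}, \code{n_contigs},
#'   \code{n_cds}.
#' @export
genomeStats <- function(g, proteomeObj = NULL) {
  stopifnot(is(g, "Genome"))
  freq <- colSums(alphabetFrequency(g@contigs)[, c("A", "C", "G", "T"),
                                               drop = FALSE])
  tot <- sum(freq)
  if (tot == 0L) stop("no unambiguous bases in genome '", g@genomeId, "'")
  data.frame(
    genome_id = g@genomeId,
    length_bp = sum(width(g@contigs)),
    gc_percent = round(100 * (freq[["G"]] + freq[["C"]]) / tot, 2),
    n_contigs = length(g@contigs),
    n_cds = if (is.null(proteomeObj)) NA_integer_
            else length(proteins(proteomeObj)),
    stringsAsFactors = FALSE)
}

#' Write a genome statistics table as TSV
#'
#' @param stats data.frame as returned by \code{\link{genomeStats}}
#'   (rows may be bound over genomes).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeStats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cut a genome into consecutive non-overlapping fragments
#'
#' Each contig is tiled with windows of \code{fragLen}; the terminal
#' remainder is kept when at least \code{fragLen / 2} long, otherwise
#' dropped (this avoids biasing fragment-based ANI with tiny
#' fragments). Fragments never span contigs. Coordinates are 0-based
#' half-open on the source contig.
#'
#' @param g a \code{\linkS4class{Genome}}.
#' @param fragLen fragment window length (>= 100); default 1020.
#' @return A \code{DNAStringSet} of fragments with \code{mcols} columns
#'   \code{genome_id}, \code{contig_id}, \code{start}, \code{end}.
#' @export
fragmentGenome <- function(g, fragLen = 1020L) {
  stopifnot(is(g, "Genome"))
  fragLen <- as.integer(fragLen)
  if (fragLen < 100L) stop("fragLen must be >= 100")
  res <- list()
  meta <- list()
  for (ci in seq_along(g@contigs)) {
    cid <- names(g@contigs)[ci]
    len <- width(g@contigs)[ci]
    nfull <- len %/% fragLen
    starts <- seq.int(0L, by = fragLen, length.out = nfull)
    ends <- starts + fragLen
    rem <- len - nfull * fragLen
    if (rem >= fragLen / 2) {
      starts <- c(starts, nfull * fragLen)
      ends <- c(ends, len)
    }
    if (!length(starts)) next
    fr <- subseq(rep(g@contigs[ci], length(starts)), start = starts + 1L,
                 end = ends)
    names(fr) <- sprintf("%s:%s:%d-%d", g@genomeId, cid, starts, ends)
    res[[length(res) + 1L]] <- fr
    meta[[length(meta) + 1L]] <- data.frame(
      genome_id = g@genomeId, contig_id = cid, start = starts,
      end = ends, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    out <- DNAStringSet()
    mcols(out) <- DataFrame(genome_id = character(), contig_id = character(),
                            start = integer(), end = integer())
    return(out)
  }
  out <- do.call(c, res)
  mcols(out) <- DataFrame(do.call(rbind, meta))
  out
}
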