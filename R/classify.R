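#' @include anicalc.R aaicalc.R dinucsig.R ddhest.R
NULL

.CUTOFFS <- c(ani = 95, aai = 95, ddh = 70, delta = 0.01)

#' Species-boundary verdicts for one genome pair
#'
#' Applies the conventional cutoff rules: ANI >= 95\% same species,
#' AAI >= 95\% same species, DDH >= 70\% same species, delta <= 0.01
#' same species (boundary values inclusive on the same-species side;
#' failures lie "below"/"above" the cutoffs). 16S identity and MLSA
#' distance, when supplied, are reported without a cutoff verdict.
#' The consensus is same-species iff every available verdict among
#' ANI/AAI/DDH is same-species and the delta verdict (if available)
#' is not different-species; it is the package's own combination rule,
#' the individual metrics stand on their own.
#'
#' @param ani,aai,ddh,delta,s16,mlsaDist per-metric values
#'   (\code{NA} = not computed / no signal). At least one must be
#'   present.
#' @param genomeA,genomeB labels carried into the call.
#' @return A \code{\linkS4class{TaxonomyCall}}; consensus is one of
#'   \code{"same-species"}, \code{"different-species"},
#'   \code{"no-call"}.
#' @examples
#' callPair(ani = 96.2, ddh = 74, delta = 0.004)
#' @export
callPair <- function(ani = NA_real_, aai = NA_real_, ddh = NA_real_,
                     delta = NA_real_, s16 = NA_real_,
                     mlsaDist = NA_real_, genomeA = "a", genomeB = "b") {
  values <- c(ani = ani, aai = aai, ddh = ddh, delta = delta,
              s16 = s16, mlsa = mlsaDist)
  if (all(is.na(values))) stop("no metric available: no-call")
  verdict <- function(metric) {
    v <- values[[metric]]
    if (is.na(v)) return("no-signal")
    if (metric == "delta") {
      if (v <= .CUTOFFS["delta"]) "same-species" else "different-species"
    } else if (v >= .CUTOFFS[metric]) "same-species"
    else "different-species"
  }
  verdicts <- c(ani = verdict("ani"), aai = verdict("aai"),
                ddh = verdict("ddh"), delta = verdict("delta"),
                s16 = if (is.na(s16)) "no-signal" else "reported",
                mlsa = if (is.na(mlsaDist)) "no-signal" else "reported")
  main <- verdicts[c("ani", "aai", "ddh")]
  avail <- main[main != "no-signal"]
  consensus <- if (!length(avail) && verdicts["delta"] == "no-signal") {
    "no-call"
  } else if (length(avail) && all(avail == "same-species") &&
             verdicts["delta"] != "different-species") {
    "same-species"
  } else if (!length(avail) && verdicts["delta"] == "same-species") {
    "same-species"
  } else {
    "different-species"
  }
  new("TaxonomyCall", genomeA = genomeA, genomeB = genomeB,
      values = values, verdicts = verdicts, consensus = consensus)
}

#' Run the full genomic-taxonomy workflow over a genome set
#'
#' Computes the requested metric matrices (ANI, AAI, genome distance +
#' DDH, dinucleotide delta) for every genome pair, applies the cutoff
#' rules per pair, and optionally writes per-metric TSV matrices, a
#' per-pair calls table, a JSON report and a parameter log to
#' \code{outDir}. Failures of a single pair are isolated: the pair is
#' reported with \code{NA} values and the run continues.
#'
#' @param genomes list of >= 2 \code{\linkS4class{Genome}} objects.
#' @param proteomes optional list of matching
#'   \code{\linkS4class{Proteome}} objects (same order/ids); required
#'   for AAI.
#' @param metrics subset of \code{c("ani", "aai", "ddh", "dinuc")}.
#' @param outDir optional output directory.
#' @param aniParams list of parameters for \code{\link{aniOneway}}
#'   (fragLen, minIdentity, minFragCov, ...).
#' @param model DDH logistic model from \code{\link{ddhModel}}.
#' @return (Invisibly) a list with the metric matrices, the list of
#'   \code{\linkS4class{TaxonomyCall}}s, a per-pair \code{calls}
#'   data.frame, and the parameter log.
#' @export
classifyGenomes <- function(genomes, proteomes = NULL,
                            metrics = c("ani", "aai", "ddh", "dinuc"),
                            outDir = NULL, aniParams = list(),
                            model = ddhModel()) {
  stopifnot(length(genomes) >= 2)
  metrics <- match.arg(metrics, several.ok = TRUE)
  ids <- vapply(genomes, genomeId, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  names(genomes) <- ids
  if (!is.null(proteomes)) {
    names(proteomes) <- vapply(proteomes, genomeId, character(1))
    if ("aai" %in% metrics && !all(ids %in% names(proteomes)))
      stop("proteome missing for: ",
           paste(setdiff(ids, names(proteomes)), collapse = ", "))
  } else if ("aai" %in% metrics) {
    stop("AAI requested but no proteomes supplied")
  }
  n <- length(ids)
  emptyMat <- function(diagval) {
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    diag(m) <- diagval
    m
  }
  mats <- list()
  if ("ani" %in% metrics) mats$ani <- emptyMat(100)
  if ("aai" %in% metrics) mats$aai <- emptyMat(100)
  if ("ddh" %in% metrics) { mats$d <- emptyMat(0); mats$ddh <- emptyMat(100) }
  if ("dinuc" %in% metrics) mats$delta <- emptyMat(0)
  profiles <- if ("dinuc" %in% metrics)
    lapply(genomes, function(g) tryCatch(dinucProfile(g),
                                         error = function(e) NULL))
  else NULL
  calls <- list()
  failures <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pair <- paste(ids[i], ids[j], sep = " vs ")
    vals <- list(ani = NA_real_, aai = NA_real_, ddh = NA_real_,
                 delta = NA_real_)
    tryCatch({
      oneway <- NULL
      if (any(c("ani", "ddh") %in% metrics)) {
        ab <- do.call(aniOneway, c(list(genomes[[i]], genomes[[j]]),
                                   aniParams))
        ba <- do.call(aniOneway, c(list(genomes[[j]], genomes[[i]]),
                                   aniParams))
        oneway <- list(ab = ab, ba = ba)
      }
      if ("ani" %in% metrics) {
        v <- c(oneway$ab$mean_identity, oneway$ba$mean_identity)
        vals$ani <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
        mats$ani[i, j] <- mats$ani[j, i] <- vals$ani
      }
      if ("ddh" %in% metrics) {
        pool <- function(x) {
          keep <- x$fragments$retained
          c(sum(x$fragments$n_id[keep]), sum(x$fragments$aln_len[keep]))
        }
        tot <- pool(oneway$ab) + pool(oneway$ba)
        if (tot[2] > 0) {
          dgd <- 1 - tot[1] / tot[2]
          mats$d[i, j] <- mats$d[j, i] <- dgd
          vals$ddh <- ddhEstimate(dgd, model)@predictedDdh
          mats$ddh[i, j] <- mats$ddh[j, i] <- vals$ddh
        }
      }
      if ("aai" %in% metrics) {
        r <- aai(proteomes[[ids[i]]], proteomes[[ids[j]]])
        vals$aai <- r@aai
        mats$aai[i, j] <- mats$aai[j, i] <- vals$aai
      }
      if ("dinuc" %in% metrics &&
          !is.null(profiles[[ids[i]]]) && !is.null(profiles[[ids[j]]])) {
        vals$delta <- deltaDistance(profiles[[ids[i]]],
                                    profiles[[ids[j]]])
        mats$delta[i, j] <- mats$delta[j, i] <- vals$delta
      }
    }, error = function(e) {
      failures <<- c(failures, paste0(pair, ": ", conditionMessage(e)))
    })
    calls[[pair]] <- tryCatch(
      callPair(ani = vals$ani, aai = vals$aai, ddh = vals$ddh,
               delta = vals$delta, genomeA = ids[i], genomeB = ids[j]),
      error = function(e) NULL)
  }
  callsDf <- do.call(rbind, lapply(calls, function(cl) {
    if (is.null(cl)) return(NULL)
    data.frame(genome_a = cl@genomeA, genome_b = cl@genomeB,
               ani = cl@values[["ani"]], aai = cl@values[["aai"]],
               ddh = cl@values[["ddh"]], delta = cl@values[["delta"]],
               consensus = cl@consensus, stringsAsFactors = FALSE)
  }))
  rownames(callsDf) <- NULL
  params <- list(metrics = metrics, aniParams = aniParams,
                 ddh_model = model, cutoffs = as.list(.CUTOFFS))
  out <- list(matrices = mats, calls = calls, callsTable = callsDf,
              parameters = params, failures = failures)
  if (!is.null(outDir)) .writeReport(out, outDir)
  invisible(out)
}

.writeReport <- function(out, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(out$matrices))
    write.table(out$matrices[[nm]],
                file.path(outDir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(out$callsTable))
    write.table(out$callsTable, file.path(outDir, "calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    parameters = out$parameters,
    matrices = lapply(out$matrices, function(m)
      list(labels = rownames(m), values = unname(m))),
    calls = lapply(unname(out$calls), function(cl) {
      if (is.null(cl)) return(NULL)
      list(genome_a = cl@genomeA, genome_b = cl@genomeB,
           values = as.list(cl@values), verdicts = as.list(cl@verdicts),
           consensus = cl@consensus)
    }),
    failures = out$failures)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(c(paste("run at:", format(Sys.time())),
               paste("metrics:", paste(out$parameters$metrics,
                                       collapse = ",")),
               paste("failures:", length(out$failures)),
               out$failures),
             file.path(outDir, "run.log"))
  invisible(outDir)
}
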