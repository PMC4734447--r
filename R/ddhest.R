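#' @include anicalc.R
NULL

#' Genome-wide alignment distance
#'
#' d = 1 - (identical columns) / (alignment columns), pooled over the
#' retained fragment alignments of both ANI directions (symmetric by
#' construction). This is the identities-over-alignment-length formula
#' family used by genome-to-genome distance methods.
#'
#' @param a,b \code{\linkS4class{Genome}} objects.
#' @param ... fragment/retention parameters passed to
#'   \code{\link{aniOneway}}.
#' @return A \code{\linkS4class{GenomeDistance}}; no retained fragment
#'   in either direction yields an explicit no-signal state.
#' @export
genomeDistance <- function(a, b, ...) {
  ab <- aniOneway(a, b, ...)
  ba <- aniOneway(b, a, ...)
  pool <- function(x) {
    if (is.null(x$fragments)) return(c(0, 0))
    keep <- x$fragments$retained
    c(sum(x$fragments$n_id[keep]), sum(x$fragments$aln_len[keep]))
  }
  tot <- pool(ab) + pool(ba)
  new("GenomeDistance",
      genomeA = genomeId(a), genomeB = genomeId(b),
      d = if (tot[2] > 0) 1 - tot[1] / tot[2] else NA_real_,
      nIdentical = tot[1], nColumns = tot[2],
      noSignal = tot[2] == 0)
}

#' Logistic model mapping genome distance to DDH
#'
#' predictedDdh = 100 / (1 + exp(alpha + beta * d)). The bundled
#' default is calibrated on simulated genome pairs so that d = 0.05
#' maps to ~70\% DDH (the classical species boundary) and d = 0 maps
#' to >= 99\%: alpha = -6, beta = (log(3/7) - alpha) / 0.05. This is a
#' calibration choice of this package, not a reproduction of any
#' published regression fit; supply your own coefficients to use a
#' different mapping.
#'
#' @param alpha intercept.
#' @param beta slope; must be positive (DDH decreasing in d).
#' @return Named list with \code{alpha} and \code{beta}.
#' @export
ddhModel <- function(alpha = -6, beta = (log(3 / 7) - alpha) / 0.05) {
  if (beta <= 0) stop("ddh model misconfigured: beta must be positive")
  list(alpha = alpha, beta = beta)
}

#' In-silico DNA-DNA hybridization estimate
#'
#' Maps a pooled genome-wide alignment distance to a predicted DDH
#' percentage through a logistic model (see \code{\link{ddhModel}}).
#' The prediction is clamped to (0, 100] and is strictly decreasing in
#' d.
#'
#' @param gd a \code{\linkS4class{GenomeDistance}} (or a bare numeric
#'   distance in [0, 1]).
#' @param model coefficients from \code{\link{ddhModel}}.
#' @return A \code{\linkS4class{DdhEstimate}}.
#' @examples
#' ddhEstimate(0.05)   # ~70% with the bundled calibration
#' @export
ddhEstimate <- function(gd, model = ddhModel()) {
  if (is.null(model$beta) || model$beta <= 0)
    stop("ddh model misconfigured: beta must be positive")
  if (is(gd, "GenomeDistance")) {
    if (gd@noSignal) stop("no-signal genome distance: DDH undefined")
    d <- gd@d; ga <- gd@genomeA; gb <- gd@genomeB
  } else {
    d <- as.numeric(gd); ga <- "a"; gb <- "b"
    if (is.na(d) || d < 0 || d > 1) stop("distance must be in [0, 1]")
  }
  ddh <- 100 / (1 + exp(model$alpha + model$beta * d))
  ddh <- min(max(ddh, .Machine$double.xmin), 100)
  new("DdhEstimate", genomeA = ga, genomeB = gb, predictedDdh = ddh,
      alpha = model$alpha, beta = model$beta, d = d)
}
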