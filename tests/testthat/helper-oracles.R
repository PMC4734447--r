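# Shared helpers: tiny sequence generators and independently coded
# oracles (exhaustive DP via Biostrings, dense MCL, brute-force
# dinucleotide counting) used to cross-check the package kernels.

rndSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute a fraction p of residues (guaranteed different amino acid)
mutateAa <- function(s, p) {
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
           "P","S","T","W","Y","V")
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(aas, v[i]), 1)
  paste(v, collapse = "")
}

# substitute a fraction p of sites (guaranteed different base)
mutateSeq <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < p)
  bases <- c("A", "C", "G", "T")
  for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1)
  paste(v, collapse = "")
}

ntOracleMatrix <- function(match = 1, mismatch = -2) {
  m <- matrix(mismatch, 4, 4,
              dimnames = list(c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")))
  diag(m) <- match
  m
}

# exhaustive local DP score via Biostrings (independent oracle)
bioLocalAlign <- function(a, b, gapOpen = 11, gapExtend = 1,
                          matrix = ntOracleMatrix()) {
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = matrix,
                                gapOpening = gapOpen,
                                gapExtension = gapExtend)
}

# dense, plainly-written MCL reference: same algorithm spec, written
# against base R matrices only
denseMclOracle <- function(W, inflation = 1.25, maxIter = 100,
                           prune = 1e-5, tol = 1e-6) {
  n <- nrow(W)
  A <- as.matrix(W)
  for (i in seq_len(n)) {
    mx <- max(A[i, ])
    A[i, i] <- if (mx > 0) mx else 1
  }
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(maxIter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    zero <- cs == 0
    if (any(zero)) {
      M2[cbind(which(zero), which(zero))] <- 1
      cs[zero] <- 1
    }
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  S <- (M + t(M)) > 0
  diag(S) <- FALSE
  seen <- rep(FALSE, n)
  groups <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i
    repeat {
      nxt <- sort(unique(c(comp, which(apply(S[comp, , drop = FALSE],
                                             2, any)))))
      if (length(nxt) == length(comp)) break
      comp <- nxt
    }
    seen[comp] <- TRUE
    groups[[length(groups) + 1]] <- sort(rownames(W)[comp])
  }
  groups[order(vapply(groups, `[`, character(1), 1))]
}

# brute-force dinucleotide signature: explicit sliding-window counts
# over each contig and its reverse complement
bruteDinucRho <- function(contigSeqs) {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  rcStr <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    v <- rev(strsplit(s, "")[[1]])
    paste(ifelse(v %in% names(comp), comp[v], v), collapse = "")
  }
  mono <- setNames(numeric(4), c("A", "C", "G", "T"))
  di <- setNames(numeric(16), dinucs)
  for (s in contigSeqs) for (str in c(s, rcStr(s))) {
    v <- strsplit(str, "")[[1]]
    for (ch in v) if (ch %in% names(mono)) mono[ch] <- mono[ch] + 1
    if (length(v) >= 2)
      for (i in seq_len(length(v) - 1)) {
        key <- paste0(v[i], v[i + 1])
        if (key %in% dinucs) di[key] <- di[key] + 1
      }
  }
  fm <- mono / sum(mono)
  fd <- di / sum(di)
  rho <- fd
  for (x in c("A", "C", "G", "T")) for (y in c("A", "C", "G", "T"))
    rho[paste0(x, y)] <- fd[paste0(x, y)] / (fm[x] * fm[y])
  rho
}

# simulated flat-divergence genome pair (memoized per (p, len, seed))
.simPairCache <- new.env(parent = emptyenv())
simPair <- function(p, len = 30000L, nGenes = 12L, seed = 101L) {
  key <- paste(p, len, nGenes, seed, sep = "_")
  if (!is.null(.simPairCache[[key]])) return(.simPairCache[[key]])
  cfg <- simConfig(seed = seed, ancestorLength = len, nGenes = nGenes,
                   geneLengthCodons = c(min = 80L, mode = 140L,
                                        max = 220L), p = p)
  ev <- evolveGenomes(makeAncestor(cfg), cfg)
  .simPairCache[[key]] <- ev
  ev
}

writeTempFasta <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}
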