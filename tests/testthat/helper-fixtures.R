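# Shared fixtures and independent oracles used across the suite.

# small expression matrix with fixed dimnames
toyMatrix <- function(values, nGenes = NULL, nSamples = NULL, scale = "rpkm") {
  if (is.matrix(values)) {
    m <- values
  } else {
    m <- matrix(values, nrow = nGenes, ncol = nSamples)
  }
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  ExpressionMatrix(m, scale)
}

# brute-force pair-score oracle: explicit per-sample counting, independent of
# the package's vectorized/C++ path
bruteDelta <- function(a, b, labels) {
  ind <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  s <- which(labels == "sensitive"); r <- which(labels == "resistant")
  pS <- mean(mapply(ind, a[s], b[s]))
  pR <- mean(mapply(ind, a[r], b[r]))
  abs(pS - pR)
}

# brute-force AUROC oracle: exhaustive loop over all cross-class pairs
bruteAuroc <- function(truth, scores) {
  pos <- scores[truth == "sensitive"]
  neg <- scores[truth == "resistant"]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# unordered-pair keys for recall computations
pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

truthRecall <- function(model, cohort) {
  tp <- truthPairs(cohort)
  r <- modelRules(model)
  mean(pairKey(tp$geneA, tp$geneB) %in% pairKey(r$geneA, r$geneB))
}

# a small, fast synthetic configuration for tests that only need structure,
# not the full study-scale cohort
smallConfig <- function(seed, ...) {
  args <- list(nGenes = 120L, nSensitive = 15L, nResistant = 40L,
               nTruthPairs = 4L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(syntheticConfig, args)
}

# seven-point dilution series used throughout
dilution7 <- c(10, 3.333, 1.111, 0.370, 0.123, 0.0412, 0.0137)

# dense-grid DSS oracle: no bisection, everything read off a fine grid
denseGridDss <- function(fit, aMin = 10, version = 1, nGrid = 1e5) {
  x <- seq(fit@xLo, fit@xHi, length.out = nGrid)
  v <- 100 * pnorm(fit@intercept + fit@slope * x)
  r <- 100 - pmin(v, 100)
  rMax <- max(r)
  if (rMax <= aMin) return(0)
  above <- r >= aMin
  interp <- function(i1, i2) {
    # linear interpolation of the crossing between grid points
    x[i1] + (aMin - r[i1]) * (x[i2] - x[i1]) / (r[i2] - r[i1])
  }
  x1 <- if (above[1]) x[1] else { i <- which(above)[1]; interp(i - 1, i) }
  x2 <- if (above[nGrid]) x[nGrid] else { j <- max(which(above)); interp(j + 1, j) }
  xx <- seq(x1, x2, length.out = nGrid)
  rr <- 100 - pmin(100 * pnorm(fit@intercept + fit@slope * xx), 100)
  aucResp <- sum(diff(xx) * (rr[-1] + rr[-nGrid]) / 2)
  dss1 <- (aucResp - aMin * (x2 - x1)) / ((100 - aMin) * (fit@xHi - fit@xLo))
  if (version == 1) return(dss1)
  dss2 <- dss1 / log10(rMax)
  if (version == 2) return(dss2)
  dss2 * (x2 - x1) / (fit@xHi - fit@xLo)
}
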