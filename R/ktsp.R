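# kTSP core: pair scoring, greedy disjoint rule selection, k selection by a
# standardized vote-sum separation criterion, and majority-vote prediction.
# Training depends only on within-sample gene orderings, which is what makes
# the classifier invariant to monotone (per-sample) transformations.

#' Score a single gene pair
#'
#' Primary score: `delta = |P(a > b | sensitive) - P(a > b | resistant)|`
#' with within-class empirical fractions and expression ties `a == b`
#' contributing 1/2. Secondary (tie-break) score:
#' `gamma = |mean_S(rank_a - rank_b) - mean_R(rank_a - rank_b)|` computed
#' from within-sample ranks; when rank vectors are not supplied the raw
#' values are used (ranks and values induce the same ordering for a
#' two-gene comparison).
#'
#' @param aValues,bValues numeric vectors, one value per sample.
#' @param labels per-sample `"sensitive"`/`"resistant"`.
#' @param aRanks,bRanks optional within-sample ranks of the two genes within
#'   their full expression profiles.
#' @return named numeric: `delta`, `gamma`, plus the oriented class
#'   fractions `pSens`, `pRes`.
#' @export
pairScore <- function(aValues, bValues, labels, aRanks = aValues,
                      bRanks = bValues) {
  labels <- asBinaryLabels(labels)
  n <- length(aValues)
  if (length(bValues) != n || length(labels) != n) {
    stop("aValues, bValues and labels must have equal length")
  }
  isS <- labels == "sensitive"
  if (!any(isS) || all(isS)) stop("both classes must be non-empty")
  ind <- ifelse(aValues > bValues, 1, ifelse(aValues == bValues, 0.5, 0))
  pS <- mean(ind[isS]); pR <- mean(ind[!isS])
  rd <- aRanks - bRanks
  c(delta = abs(pS - pR), gamma = abs(mean(rd[isS]) - mean(rd[!isS])),
    pSens = pS, pRes = pR)
}

extractLog2Matrix <- function(m) {
  if (is(m, "ExpressionMatrix")) exprValues(m) else as.matrix(m)
}

#' Rank and greedily select gene-disjoint top-scoring pairs
#'
#' Scores every unordered gene pair, orients each so that
#' `P(geneA > geneB | sensitive) >= P(geneA > geneB | resistant)`, sorts by
#' (delta descending, gamma descending, then the lexicographic unordered
#' gene pair), and greedily accepts pairs, skipping any that shares a gene
#' with an already accepted pair, until `maxPairs` pairs are accepted or the
#' list is exhausted. Deterministic for a fixed input. Above `geneCap` genes
#' the matrix is first reduced to the `geneCap` most variable genes (with a
#' message), keeping the all-pairs scan tractable.
#'
#' @param m an [ExpressionMatrix-class] (log2 scale) or plain genes x samples
#'   matrix with dimnames.
#' @param labels per-sample `"sensitive"`/`"resistant"` (in column order, or
#'   named by sample).
#' @param maxPairs maximum number of rules to accept (default 15).
#' @param geneCap variance cap on the number of genes scanned
#'   (default 5000; `Inf` disables).
#' @return data.frame of accepted rules: `geneA`, `geneB`, `delta`, `gamma`.
#' @export
rankDisjointPairs <- function(m, labels, maxPairs = 15L, geneCap = 5000L) {
  X <- extractLog2Matrix(m)
  if (nrow(X) < 2L) stop("at least 2 genes are required")
  labels <- alignLabels(labels, colnames(X))
  isS <- labels == "sensitive"
  if (!any(isS) || all(isS)) stop("both classes must be non-empty")
  if (is.finite(geneCap) && nrow(X) > geneCap) {
    message(sprintf(
      "rankDisjointPairs: reducing %d genes to the %d most variable before the all-pairs scan",
      nrow(X), as.integer(geneCap)))
    keep <- order(apply(X, 1L, var), decreasing = TRUE)[seq_len(geneCap)]
    X <- X[sort(keep), , drop = FALSE]
  }
  Rm <- apply(X, 2L, rank)
  st <- pairScoreStats(X, Rm, isS)
  genes <- rownames(X)
  delta <- abs(st[, "pS"] - st[, "pR"])
  gamma <- abs(st[, "rdS"] - st[, "rdR"])
  flip <- st[, "pS"] < st[, "pR"]
  iA <- st[, "i"]; iB <- st[, "j"]
  iA[flip] <- st[flip, "j"]; iB[flip] <- st[flip, "i"]
  # orientation-independent lexicographic tie-break on the unordered pair,
  # via integer codes in gene-name order (fast radix sort)
  lex <- match(genes, sort(genes))
  cA <- lex[iA]; cB <- lex[iB]
  ord <- order(-delta, -gamma, pmin(cA, cB), pmax(cA, cB), method = "radix")

  used <- logical(length(genes))
  accA <- integer(0); accB <- integer(0); accD <- numeric(0); accG <- numeric(0)
  for (idx in ord) {
    a <- iA[idx]; b <- iB[idx]
    if (used[a] || used[b]) next
    used[a] <- TRUE; used[b] <- TRUE
    accA <- c(accA, a); accB <- c(accB, b)
    accD <- c(accD, delta[idx]); accG <- c(accG, gamma[idx])
    if (length(accA) >= maxPairs) break
  }
  data.frame(geneA = genes[accA], geneB = genes[accB], delta = accD,
             gamma = accG, stringsAsFactors = FALSE)
}

alignLabels <- function(labels, sampleNames) {
  labels <- asBinaryLabels(labels)
  if (!is.null(names(labels)) && !is.null(sampleNames)) {
    miss <- setdiff(sampleNames, names(labels))
    if (length(miss)) {
      stop(sprintf("labels missing for sample(s): %s",
                   paste(head(miss, 5L), collapse = ", ")))
    }
    labels <- labels[sampleNames]
  }
  labels
}

ruleVotes <- function(rules, X) {
  miss <- setdiff(c(rules$geneA, rules$geneB), rownames(X))
  if (length(miss)) {
    stop(sprintf("gene(s) required by the model are missing: %s",
                 paste(miss, collapse = ", ")))
  }
  A <- X[rules$geneA, , drop = FALSE]
  B <- X[rules$geneB, , drop = FALSE]
  ifelse(A > B, 1L, -1L)  # ties count as the rule not applying (-1)
}

#' Select the number of rules k
#'
#' For each candidate k, the per-training-sample vote sums under the first k
#' rules are summarized by a Welch-type standardized mean difference between
#' the classes:
#' `|mean(votes|S) - mean(votes|R)| / sqrt(varS/nS + varR/nR)`.
#' Each class variance is floored at `4k/n` -- the sample variance produced
#' by one discordant vote per rule -- so that a perfectly separating rule
#' set gets a large but finite score that still grows (like `sqrt(k)`) as
#' further perfectly-separating rules are added; without the floor, perfect
#' training separation would pin k at its smallest degenerate value and
#' discard informative rules (see the methods vignette). The k maximizing
#' the criterion is returned; ties resolve to the smallest k.
#'
#' @inheritParams rankDisjointPairs
#' @param candidates ordered rules data.frame from [rankDisjointPairs()].
#' @param kRange integer(2), inclusive search range for k (default `c(1, 15)`).
#' @return integer(1) selected k.
#' @export
selectK <- function(m, labels, candidates, kRange = c(1L, 15L)) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("candidates must be non-empty")
  }
  X <- extractLog2Matrix(m)
  labels <- alignLabels(labels, colnames(X))
  isS <- labels == "sensitive"
  kMin <- max(1L, as.integer(kRange[1L]))
  kMax <- min(as.integer(kRange[2L]), nrow(candidates))
  if (kMax < kMin) kMax <- kMin
  votes <- ruleVotes(candidates, X)          # k x n
  cums <- apply(votes, 2L, cumsum)
  if (is.null(dim(cums))) cums <- matrix(cums, nrow = 1L)
  nS <- sum(isS); nR <- sum(!isS)
  scores <- vapply(kMin:kMax, function(k) {
    vs <- cums[k, ]
    mS <- mean(vs[isS]); mR <- mean(vs[!isS])
    vS <- max(var(vs[isS]), 4 * k / nS)
    vR <- max(var(vs[!isS]), 4 * k / nR)
    abs(mS - mR) / sqrt(vS / nS + vR / nR)
  }, numeric(1))
  as.integer((kMin:kMax)[which.max(scores)])
}

#' Fit a kTSP classifier
#'
#' Composition of [rankDisjointPairs()] (with `maxPairs = kRange[2]`) and
#' [selectK()], truncating the accepted rules to the selected k. Training is
#' deterministic: refitting on identical input yields an identical model.
#'
#' @inheritParams selectK
#' @param tiePolicy label to emit when the majority vote is tied
#'   (default `"resistant"`, the conservative call).
#' @param geneCap see [rankDisjointPairs()].
#' @return A [KTSPModel-class].
#' @export
fitKtsp <- function(m, labels, kRange = c(1L, 15L), tiePolicy = "resistant",
                    geneCap = 5000L) {
  X <- extractLog2Matrix(m)
  labels <- alignLabels(labels, colnames(X))
  isS <- labels == "sensitive"
  if (sum(isS) < 2L || sum(!isS) < 2L) {
    stop("both classes need at least 2 training samples")
  }
  cand <- rankDisjointPairs(X, labels, maxPairs = as.integer(kRange[2L]),
                            geneCap = geneCap)
  if (nrow(cand) == 0L) stop("no candidate pairs could be formed")
  k <- selectK(X, labels, cand, kRange = kRange)
  new("KTSPModel",
      rules = cand[seq_len(k), , drop = FALSE],
      k = k, tiePolicy = tiePolicy,
      classLabels = c(positive = "sensitive", negative = "resistant"),
      trainingMeta = list(nSensitive = sum(isS), nResistant = sum(!isS),
                          kMax = as.integer(kRange[2L]),
                          geneCap = geneCap))
}

#' Vote sum of a model on one sample
#'
#' Each rule contributes +1 when `geneA > geneB` holds in the sample and -1
#' otherwise (ties count as the rule not applying, hence -1). The sum lies in
#' `[-k, k]` and measures how consistently the rule set points toward
#' sensitivity.
#'
#' @param model a [KTSPModel-class].
#' @param sample named numeric vector of expression values covering every
#'   model gene.
#' @return integer(1) vote sum.
#' @export
voteSum <- function(model, sample) {
  stopifnot(is(model, "KTSPModel"))
  X <- matrix(sample, ncol = 1L, dimnames = list(names(sample), "sample"))
  sum(ruleVotes(model@rules, X))
}

#' Vote sums of a model across samples
#'
#' @param model a [KTSPModel-class].
#' @param newdata an [ExpressionMatrix-class] or genes x samples matrix.
#' @return named integer vector of per-sample vote sums in `[-k, k]`.
#' @export
voteSums <- function(model, newdata) {
  stopifnot(is(model, "KTSPModel"))
  X <- extractLog2Matrix(newdata)
  colSums(ruleVotes(model@rules, X))
}

#' Continuous decision score
#'
#' `(voteSum + k) / (2k)`, mapping the vote sum to `[0, 1]` with higher
#' values indicating sensitivity; used as the ranking score for AUROC.
#'
#' @inheritParams voteSums
#' @return named numeric vector in `[0, 1]`.
#' @export
decisionScore <- function(model, newdata) {
  k <- model@k
  (voteSums(model, newdata) + k) / (2 * k)
}

#' Predict sensitivity labels by unweighted majority vote
#'
#' A sample is called `"sensitive"` iff its vote sum is strictly positive; a
#' tied vote (possible for even k) resolves to the model's tie policy
#' (default `"resistant"`).
#'
#' @param object a [KTSPModel-class].
#' @param newdata an [ExpressionMatrix-class] or genes x samples matrix.
#' @param ... unused.
#' @return named character vector of `"sensitive"`/`"resistant"`.
#' @export
setMethod("predict", "KTSPModel", function(object, newdata, ...) {
  vs <- voteSums(object, newdata)
  out <- ifelse(vs > 0, "sensitive",
                ifelse(vs < 0, "resistant", object@tiePolicy))
  names(out) <- names(vs)
  out
})

#' Check invariance of predictions under monotone per-sample transforms
#'
#' Applies a strictly increasing map to every sample (a single function, or
#' one function per sample) and checks that predictions are unchanged.
#' Because rules compare genes within a sample, this must hold for any
#' strictly increasing map -- the property that makes the classifier robust
#' to batch effects and usable on single samples.
#'
#' @inheritParams voteSums
#' @param transform a strictly increasing function, or a list of one such
#'   function per sample.
#' @return logical(1): TRUE iff predictions are identical pre/post transform.
#' @export
checkRankInvariance <- function(model, newdata, transform) {
  X <- extractLog2Matrix(newdata)
  Xt <- X
  if (is.function(transform)) transform <- rep(list(transform), ncol(X))
  if (length(transform) != ncol(X)) {
    stop("provide one transform, or one per sample")
  }
  for (j in seq_len(ncol(X))) Xt[, j] <- transform[[j]](X[, j])
  identical(unname(predict(model, X)), unname(predict(model, Xt)))
}
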