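# Synthetic cohort generator. Emulates the statistical structure the
# classifier assumes -- a minority of gene pairs whose within-sample ordering
# differs by class, sensitive/resistant imbalance, strictly monotone
# per-batch distortions, and seven-point probit dose-response curves -- so
# the whole pipeline is testable without any data download. It does not
# imitate real AML expression marginals or gene-gene correlation.

DILUTION_SERIES <- c(10, 3.333, 1.111, 0.370, 0.123, 0.0412, 0.0137)

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study conditions the generator is meant to emulate: a
#' pronounced sensitive/resistant imbalance (30/150), a small set of
#' informative gene pairs hidden among noise genes, log2-scale expression
#' with unit noise, and class-conditional AUC distributions on either side
#' of the AUC = 100 sensitivity cutoff.
#'
#' @param nGenes total genes (default 1000).
#' @param nSensitive,nResistant class sizes (defaults 30 and 150).
#' @param nTruthPairs number of embedded discriminative pairs (default 10).
#' @param theta pair fidelity in (0.5, 1]: probability that a sensitive
#'   sample receives the sensitive-associated ordering boost (default 0.9);
#'   resistant samples are mirrored. 0.5 is the null.
#' @param delta effect size on the log2 scale (default 1.5).
#' @param noiseSd background standard deviation on the log2 scale
#'   (default 1).
#' @param pairSpacing spacing of the per-pair baseline offsets on the log2
#'   scale (default 3). Both genes of truth pair i share the baseline
#'   `8 + pairSpacing * (i - (m + 1) / 2)`, which pins the ordering of genes
#'   from different pairs to the same direction in both classes; without it,
#'   cross-pairings of boosted genes would be exactly as class-discriminative
#'   as the embedded pairings and the ground truth would not be identifiable
#'   (see the methods vignette).
#' @param aucSensitive,aucResistant uniform AUC ranges for the two classes
#'   (defaults `c(60, 95)` and `c(100, 150)`).
#' @param drugId drug identifier for the generated response (default
#'   "drug1").
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nGenes = 1000L, nSensitive = 30L,
                            nResistant = 150L, nTruthPairs = 10L,
                            theta = 0.9, delta = 1.5, noiseSd = 1,
                            pairSpacing = 3,
                            aucSensitive = c(60, 95),
                            aucResistant = c(100, 150),
                            drugId = "drug1", seed = 1L) {
  if (2L * nTruthPairs > nGenes) stop("need 2 * nTruthPairs <= nGenes")
  if (!(theta >= 0.5 && theta <= 1)) stop("theta must lie in [0.5, 1]")
  if (nSensitive < 2L || nResistant < 2L) stop("class sizes must be >= 2")
  if (delta <= 0) stop("delta must be positive")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  structure(list(nGenes = as.integer(nGenes),
                 nSensitive = as.integer(nSensitive),
                 nResistant = as.integer(nResistant),
                 nTruthPairs = as.integer(nTruthPairs),
                 theta = theta, delta = delta, noiseSd = noiseSd,
                 pairSpacing = pairSpacing,
                 aucSensitive = aucSensitive, aucResistant = aucResistant,
                 drugId = drugId, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic cohort with known truth pairs
#'
#' Background expression is iid Normal(8, noiseSd) on the log2 scale. Truth
#' pairs occupy the first `2 * nTruthPairs` genes (pair i is
#' `(g_{2i-1}, g_{2i})`), so two cohorts generated from configs differing
#' only in their seed share the same signal structure -- a requirement of
#' any train/test design. Both genes of pair i sit on a shared baseline
#' offset (`pairSpacing` apart across pairs), and for each sensitive sample,
#' with probability `theta` gene a receives a `+delta` boost, otherwise gene
#' b does; resistant samples are mirrored (b boosted with probability
#' `theta`). Per-sample AUC values are drawn from the class-conditional
#' uniform ranges, so [labelByAuc()] recovers the intended labels exactly.
#'
#' @param config a [syntheticConfig()].
#' @return A [SyntheticCohort-class].
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cf <- config
  withSeed(cf$seed, {
    n <- cf$nSensitive + cf$nResistant
    genes <- sprintf("g%04d", seq_len(cf$nGenes))
    samples <- sprintf("s%03d", seq_len(n))
    labels <- c(rep("sensitive", cf$nSensitive), rep("resistant", cf$nResistant))
    names(labels) <- samples
    X <- matrix(rnorm(cf$nGenes * n, mean = 8, sd = cf$noiseSd),
                nrow = cf$nGenes, dimnames = list(genes, samples))
    m <- cf$nTruthPairs
    tp <- data.frame(geneA = genes[2L * seq_len(m) - 1L],
                     geneB = genes[2L * seq_len(m)],
                     stringsAsFactors = FALSE)
    spacing <- if (is.null(cf$pairSpacing)) 3 else cf$pairSpacing
    for (i in seq_len(m)) {
      offset <- spacing * (i - (m + 1) / 2)
      X[tp$geneA[i], ] <- X[tp$geneA[i], ] + offset
      X[tp$geneB[i], ] <- X[tp$geneB[i], ] + offset
      boostA <- ifelse(labels == "sensitive",
                       runif(n) < cf$theta,   # sensitive: boost a w.p. theta
                       runif(n) >= cf$theta)  # resistant: boost b w.p. theta
      X[tp$geneA[i], boostA] <- X[tp$geneA[i], boostA] + cf$delta
      X[tp$geneB[i], !boostA] <- X[tp$geneB[i], !boostA] + cf$delta
    }
    auc <- ifelse(labels == "sensitive",
                  runif(n, cf$aucSensitive[1], cf$aucSensitive[2]),
                  runif(n, cf$aucResistant[1], cf$aucResistant[2]))
    aucDf <- data.frame(sample_id = samples, drug_id = cf$drugId,
                        auc = unname(auc), stringsAsFactors = FALSE)
    new("SyntheticCohort",
        expression = ExpressionMatrix(X, "log2tpm"),
        labels = labels, truthPairs = tp, auc = aucDf,
        config = unclass(cf))
  })
}

# strictly increasing cubic-plus-linear map; alpha >= 0, beta > 0 guarantee
# a positive derivative everywhere
monotoneMap <- function(alpha, beta, center, shift) {
  force(alpha); force(beta); force(center); force(shift)
  function(x) alpha * (x - center)^3 + beta * x + shift
}

#' Apply strictly monotone per-batch distortions
#'
#' Emulates a batch effect that shifts and warps per-sample expression
#' distributions while leaving every within-sample gene ordering unchanged
#' (the regime in which a rank-based classifier is provably unaffected).
#' Each batch receives a map `x -> alpha * (x - c)^3 + beta * x + gamma`
#' with `alpha >= 0`, `beta > 0` drawn from the seed -- strictly increasing
#' for all x by construction.
#'
#' @param m an [ExpressionMatrix-class].
#' @param batchSpec either an integer number of batches (samples split
#'   contiguously) or a named list mapping batch name -> character vector of
#'   sample ids covering all samples.
#' @param seed integer seed for the per-batch parameter draws.
#' @return list with `expression` (distorted [ExpressionMatrix-class]) and
#'   `batches` (named character vector sample -> batch).
#' @export
applyMonotoneBatch <- function(m, batchSpec = 2L, seed = 1L) {
  stopifnot(is(m, "ExpressionMatrix"))
  X <- exprValues(m)
  ids <- colnames(X)
  if (is.numeric(batchSpec) && length(batchSpec) == 1L) {
    nb <- as.integer(batchSpec)
    batches <- split(ids, rep_len(seq_len(nb), length(ids)))
    names(batches) <- sprintf("batch%d", seq_len(nb))
  } else {
    batches <- batchSpec
    if (!setequal(unlist(batches), ids)) {
      stop("batchSpec must cover exactly the samples of m")
    }
  }
  ctr <- mean(X)
  withSeed(seed, {
    tag <- character(length(ids)); names(tag) <- ids
    for (b in names(batches)) {
      alpha <- runif(1, 0, 0.5)
      beta <- runif(1, 0.5, 2)
      f <- monotoneMap(alpha, beta, center = ctr, shift = rnorm(1, 0, 3))
      if (!(alpha >= 0 && beta > 0)) stop("internal error: non-increasing map drawn")
      X[, batches[[b]]] <- f(X[, batches[[b]], drop = FALSE])
      tag[batches[[b]]] <- b
    }
    list(expression = ExpressionMatrix(X, exprScale(m)), batches = tag)
  })
}

#' Generate seven-point probit dose-response curves
#'
#' Viability is `100 * pnorm(intercept + slope * log10(conc))` plus Gaussian
#' noise, clipped to `[0, 300]`, on the standard seven-point 3-fold dilution
#' series from 10 µM down to 0.0137 µM.
#'
#' @param params data.frame with columns `sample_id`, `drug_id`,
#'   `intercept`, `slope` (one row per curve).
#' @param noiseSd viability noise standard deviation in percent (default 0).
#' @param seed integer seed.
#' @param concentrations concentration series in µM (default the 7-point
#'   3-fold dilution from 10).
#' @return list of [doseResponseCurve()] objects.
#' @export
generateDoseResponse <- function(params, noiseSd = 0, seed = 1L,
                                 concentrations = DILUTION_SERIES) {
  need <- c("sample_id", "drug_id", "intercept", "slope")
  if (!all(need %in% names(params))) {
    stop(sprintf("params must have columns: %s", paste(need, collapse = ", ")))
  }
  x <- log10(concentrations)
  withSeed(seed, {
    lapply(seq_len(nrow(params)), function(i) {
      v <- 100 * pnorm(params$intercept[i] + params$slope[i] * x)
      if (noiseSd > 0) v <- v + rnorm(length(x), 0, noiseSd)
      doseResponseCurve(concentrations, clip(v, 0, 300),
                        sampleId = params$sample_id[i],
                        drugId = params$drug_id[i])
    })
  })
}
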