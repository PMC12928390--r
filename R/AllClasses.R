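#' @import methods
#' @importFrom stats pnorm qnorm rnorm runif var sd quantile wilcox.test
#'   p.adjust predict optim lm coef dist
#' @importFrom utils read.table write.csv read.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @useDynLib pairVote, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

EXPR_SCALES <- c("rpkm", "counts", "tpm", "log2tpm")
TPM_TOTAL <- 1e6
TPM_RTOL <- 1e-6

#' ExpressionMatrix: a genes x samples expression assay with a scale tag
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] carrying a
#' single `"exprs"` assay plus a `scale` tag recording where the values sit in
#' the normalization chain: `"rpkm"`, `"counts"`, `"tpm"` or `"log2tpm"`.
#' Validity enforces finite values, non-negativity on the linear scales,
#' column sums of 1e6 (relative tolerance 1e-6) for `"tpm"`, and unique,
#' non-empty gene and sample identifiers.
#'
#' @slot scale character(1), one of `"rpkm"`, `"counts"`, `"tpm"`, `"log2tpm"`.
#' @name ExpressionMatrix-class
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(scale = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msgs <- character()
  if (length(object@scale) != 1L || !object@scale %in% EXPR_SCALES) {
    msgs <- c(msgs, sprintf("scale must be one of: %s",
                            paste(EXPR_SCALES, collapse = ", ")))
  }
  if (!"exprs" %in% SummarizedExperiment::assayNames(object)) {
    return(c(msgs, "assay 'exprs' is required"))
  }
  v <- SummarizedExperiment::assay(object, "exprs")
  g <- rownames(v); s <- colnames(v)
  if (is.null(g) || is.null(s)) {
    return(c(msgs, "gene (row) and sample (column) identifiers are required"))
  }
  if (anyDuplicated(g)) {
    msgs <- c(msgs, sprintf("duplicated gene ids: %s",
                            paste(unique(g[duplicated(g)]), collapse = ", ")))
  }
  if (anyDuplicated(s)) {
    msgs <- c(msgs, sprintf("duplicated sample ids: %s",
                            paste(unique(s[duplicated(s)]), collapse = ", ")))
  }
  if (!all(is.finite(v))) msgs <- c(msgs, "values must be finite")
  if (length(object@scale) == 1L && object@scale %in% c("rpkm", "counts", "tpm") &&
      all(is.finite(v)) && any(v < 0)) {
    msgs <- c(msgs, sprintf("negative values not allowed on scale '%s'",
                            object@scale))
  }
  if (length(object@scale) == 1L && object@scale == "tpm" &&
      all(is.finite(v)) && ncol(v) > 0) {
    cs <- colSums(v)
    bad <- abs(cs - TPM_TOTAL) > TPM_RTOL * TPM_TOTAL
    if (any(bad)) {
      msgs <- c(msgs, sprintf(
        "tpm column sums must equal 1e6 (off for: %s)",
        paste(s[bad], collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param scale character(1): `"rpkm"`, `"counts"`, `"tpm"` or `"log2tpm"`.
#' @return A validated [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "rpkm")
#' @export
ExpressionMatrix <- function(values, scale = c("rpkm", "counts", "tpm", "log2tpm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(exprs = values))
  new("ExpressionMatrix", se, scale = scale)
}

#' ProbitFit: a fitted probit dose-response model
#'
#' Viability (percent) is modelled as `v(x) = 100 * pnorm(intercept + slope * x)`
#' with `x = log10(concentration)`. A perfectly flat viability series is
#' represented by `slope = 0` plus the observed mean stored in `flatLevel`
#' (which may exceed 100 when cells outgrow controls); non-flat fits have
#' `flatLevel = NA`.
#'
#' @slot intercept,slope numeric(1) probit coefficients.
#' @slot converged logical(1), optimizer convergence.
#' @slot xLo,xHi numeric(1) log10-concentration bounds of the screened range.
#' @slot flatLevel numeric(1) observed mean viability for flat series, else NA.
#' @name ProbitFit-class
#' @exportClass ProbitFit
setClass("ProbitFit", slots = c(
  intercept = "numeric", slope = "numeric", converged = "logical",
  xLo = "numeric", xHi = "numeric", flatLevel = "numeric"
))

setValidity("ProbitFit", function(object) {
  msgs <- character()
  if (isTRUE(object@converged) &&
      !(is.finite(object@intercept) && is.finite(object@slope))) {
    msgs <- c(msgs, "converged fits must have finite parameters")
  }
  if (!isTRUE(object@xLo < object@xHi)) {
    msgs <- c(msgs, "xLo must be < xHi")
  }
  if (length(msgs)) msgs else TRUE
})

#' KTSPModel: an ordered, gene-disjoint list of top-scoring pair rules
#'
#' Each rule is an oriented gene pair: observing `geneA > geneB` in a sample
#' contributes a +1 ("sensitive") vote, otherwise (including ties) -1.
#' Prediction is by unweighted majority vote over the k rules.
#'
#' @slot rules data.frame with columns `geneA`, `geneB`, `delta`, `gamma`,
#'   sorted by (delta desc, gamma desc, gene pair); length k.
#' @slot k integer(1), number of rules, in `[1, kMax]`.
#' @slot tiePolicy character(1), label returned when the vote sum is 0
#'   (default `"resistant"`).
#' @slot classLabels named character(2): `positive` ("sensitive") and
#'   `negative` ("resistant") class names.
#' @slot trainingMeta list: `nSensitive`, `nResistant`, `kMax`, `geneCap`.
#' @name KTSPModel-class
#' @exportClass KTSPModel
setClass("KTSPModel", slots = c(
  rules = "data.frame", k = "integer", tiePolicy = "character",
  classLabels = "character", trainingMeta = "list"
))

setValidity("KTSPModel", function(object) {
  msgs <- character()
  r <- object@rules
  need <- c("geneA", "geneB", "delta", "gamma")
  if (!all(need %in% names(r))) {
    return(sprintf("rules must have columns %s", paste(need, collapse = ", ")))
  }
  kMax <- object@trainingMeta$kMax
  if (is.null(kMax)) kMax <- 15L
  if (object@k < 1L || object@k > kMax) {
    msgs <- c(msgs, sprintf("k must be in [1, %d]", kMax))
  }
  if (object@k != nrow(r)) msgs <- c(msgs, "k must equal nrow(rules)")
  genes <- c(r$geneA, r$geneB)
  if (anyDuplicated(genes)) {
    msgs <- c(msgs, "each gene may appear in at most one rule")
  }
  if (any(r$geneA == r$geneB)) msgs <- c(msgs, "geneA must differ from geneB")
  if (any(r$delta < 0 | r$delta > 1)) msgs <- c(msgs, "delta must be in [0, 1]")
  if (any(r$gamma < 0)) msgs <- c(msgs, "gamma must be >= 0")
  if (is.unsorted(rev(r$delta))) {
    msgs <- c(msgs, "rules must be sorted by decreasing delta")
  }
  if (!object@tiePolicy %in% c("sensitive", "resistant")) {
    msgs <- c(msgs, "tiePolicy must be 'sensitive' or 'resistant'")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCohort: a generated expression cohort with known truth
#'
#' Holds log2-scale expression, per-sample sensitivity labels, the embedded
#' (gene-disjoint, oriented) ground-truth discriminative pairs, generated
#' per-sample AUC drug-response values, and the generating configuration.
#'
#' @slot expression [ExpressionMatrix-class] on the `log2tpm` scale.
#' @slot labels named character, `"sensitive"`/`"resistant"` per sample.
#' @slot truthPairs data.frame with columns `geneA`, `geneB` (orientation:
#'   `geneA > geneB` is the sensitive-associated ordering).
#' @slot auc data.frame with columns `sample_id`, `drug_id`, `auc`.
#' @slot config list, the generating [syntheticConfig()] (includes the seed).
#' @name SyntheticCohort-class
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", slots = c(
  expression = "ExpressionMatrix", labels = "character",
  truthPairs = "data.frame", auc = "data.frame", config = "list"
))

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  genes <- c(object@truthPairs$geneA, object@truthPairs$geneB)
  if (anyDuplicated(genes)) msgs <- c(msgs, "truth pairs must be gene-disjoint")
  if (!all(object@labels %in% c("sensitive", "resistant"))) {
    msgs <- c(msgs, "labels must be 'sensitive' or 'resistant'")
  }
  if (!identical(sort(names(object@labels)),
                 sort(sampleIds(object@expression)))) {
    msgs <- c(msgs, "labels must be named by the expression sample ids")
  }
  if (length(msgs)) msgs else TRUE
})
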