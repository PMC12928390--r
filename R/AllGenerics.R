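#' @name pairVote-accessors
#' @title Accessors for pairVote classes
#' @description Accessor generics for the core data objects.
#' @param x,object a pairVote object.
#' @param ... further arguments (unused).
NULL

#' @rdname pairVote-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname pairVote-accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname pairVote-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname pairVote-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname pairVote-accessors
#' @export
setGeneric("modelRules", function(x) standardGeneric("modelRules"))

#' @rdname pairVote-accessors
#' @export
setGeneric("modelK", function(x) standardGeneric("modelK"))

#' @rdname pairVote-accessors
#' @export
setGeneric("cohortExpression", function(x) standardGeneric("cohortExpression"))

#' @rdname pairVote-accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' @rdname pairVote-accessors
#' @export
setGeneric("truthPairs", function(x) standardGeneric("truthPairs"))

#' @rdname pairVote-accessors
#' @export
setGeneric("cohortAuc", function(x) standardGeneric("cohortAuc"))

#' @rdname pairVote-accessors
setMethod("exprValues", "ExpressionMatrix", function(x) {
  SummarizedExperiment::assay(x, "exprs")
})

#' @rdname pairVote-accessors
setMethod("exprScale", "ExpressionMatrix", function(x) x@scale)

#' @rdname pairVote-accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname pairVote-accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname pairVote-accessors
setMethod("modelRules", "KTSPModel", function(x) x@rules)

#' @rdname pairVote-accessors
setMethod("modelK", "KTSPModel", function(x) x@k)

#' @rdname pairVote-accessors
setMethod("cohortExpression", "SyntheticCohort", function(x) x@expression)

#' @rdname pairVote-accessors
setMethod("cohortLabels", "SyntheticCohort", function(x) x@labels)

#' @rdname pairVote-accessors
setMethod("truthPairs", "SyntheticCohort", function(x) x@truthPairs)

#' @rdname pairVote-accessors
setMethod("cohortAuc", "SyntheticCohort", function(x) x@auc)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(object), ncol(object), object@scale))
})

setMethod("show", "ProbitFit", function(object) {
  if (is.finite(object@flatLevel)) {
    cat(sprintf("ProbitFit (flat): level %.2f%% over log10 conc [%.3f, %.3f]\n",
                object@flatLevel, object@xLo, object@xHi))
  } else {
    cat(sprintf(
      "ProbitFit: intercept %.4f, slope %.4f (%s) over log10 conc [%.3f, %.3f]\n",
      object@intercept, object@slope,
      if (object@converged) "converged" else "NOT converged",
      object@xLo, object@xHi))
  }
})

setMethod("show", "KTSPModel", function(object) {
  cat(sprintf("KTSPModel: k = %d gene-pair rules (tie policy: %s)\n",
              object@k, object@tiePolicy))
  r <- object@rules
  for (i in seq_len(min(nrow(r), 5L))) {
    cat(sprintf("  %2d. %s > %s  (delta = %.3f, gamma = %.2f)\n",
                i, r$geneA[i], r$geneB[i], r$delta[i], r$gamma[i]))
  }
  if (nrow(r) > 5L) cat(sprintf("  ... and %d more\n", nrow(r) - 5L))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@labels)
  cat(sprintf(
    "SyntheticCohort: %d genes x %d samples (%d sensitive / %d resistant), %d truth pairs\n",
    nrow(object@expression), ncol(object@expression),
    tab[["sensitive"]], tab[["resistant"]], nrow(object@truthPairs)))
})
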