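# End-to-end study orchestration: train on one cohort, test on another,
# one model per drug, kTSP against the comparator harness, balanced and/or
# unbalanced. Training decisions (rules, k, hyperparameters, z-score
# constants) are frozen before any test data is touched.

#' Run configuration for a train/test study
#'
#' The train and test inputs are either [SyntheticCohort-class] objects, or
#' lists with an `expression` [ExpressionMatrix-class] (log2 scale) and a
#' `response` data.frame (`sample_id`, `drug_id`, `auc`).
#'
#' @param train,test cohort inputs (see above).
#' @param thresholds drug-inclusion counts, default `c(20, 20, 10, 10)`
#'   (train sensitive/resistant, test sensitive/resistant minima).
#' @param kRange kTSP search range for k, default `c(1, 15)`.
#' @param comparators list of [comparatorSpec()] objects (may be empty).
#' @param balanced `"both"`, `"on"` or `"off"`: run comparators with SMOTE,
#'   without, or both variants.
#' @param sdssPercentile percentile for sDSS-based labelling when the
#'   response table carries `sdss` instead of `auc` (default 95).
#' @param outDir optional directory for CSV artifacts.
#' @param seed integer seed stamped into comparator specs and artifacts.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(train, test, thresholds = c(20L, 20L, 10L, 10L),
                      kRange = c(1L, 15L), comparators = list(),
                      balanced = c("both", "on", "off"),
                      sdssPercentile = 95, outDir = NULL, seed = 1L) {
  balanced <- match.arg(balanced)
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (kRange[1] < 1L || kRange[2] > 15L || kRange[1] > kRange[2]) {
    stop("kRange must lie within [1, 15]")
  }
  structure(list(train = train, test = test, thresholds = thresholds,
                 kRange = kRange, comparators = comparators,
                 balanced = balanced, sdssPercentile = sdssPercentile,
                 outDir = outDir, seed = as.integer(seed)),
            class = "RunConfig")
}

cohortParts <- function(x) {
  if (is(x, "SyntheticCohort")) {
    list(expression = cohortExpression(x), response = cohortAuc(x))
  } else if (is.list(x) && all(c("expression", "response") %in% names(x))) {
    x
  } else {
    stop("cohort input must be a SyntheticCohort or list(expression, response)")
  }
}

labelResponse <- function(response, sdssPercentile) {
  if ("auc" %in% names(response)) {
    response$label <- labelByAuc(response$auc)
    response
  } else if ("sdss" %in% names(response)) {
    labelBySdssPercentile(response, sdssPercentile)
  } else {
    stop("response table must carry 'auc' or 'sdss'")
  }
}

metricsRow <- function(drug, modelName, balancedTag, truth, predicted, scores) {
  cm <- confusionMetrics(truth, predicted)
  auroc <- aurocScore(truth, scores)
  data.frame(drug = drug, model = modelName, balanced = balancedTag,
             metric = c("sensitivity", "specificity", "balanced_accuracy",
                        "auroc"),
             value = c(cm$sensitivity, cm$specificity, cm$balancedAccuracy,
                       auroc),
             stringsAsFactors = FALSE)
}

#' Run the full train/test study
#'
#' Labels both cohorts, applies the drug-inclusion filter, and, for each
#' included drug: fits a kTSP model on the training cohort (genes restricted
#' to the train/test intersection, mismatch fraction reported), fits every
#' configured comparator in the requested balanced/unbalanced variants, and
#' evaluates everything on the test cohort (sensitivity, specificity,
#' balanced accuracy, AUROC). Also emits the rules table, per-cohort
#' rule-compliance profiles, and the cross-drug gene-recurrence table. All
#' randomness derives from the config seed; identical configs give
#' identical reports.
#'
#' @param config a [runConfig()].
#' @return list of class `"RunReport"`: `metrics` (long data.frame),
#'   `models`, `comparators`, `includedDrugs`, `counts`, `compliance`,
#'   `recurrence`, `geneOverlap`, `seed`.
#' @export
runTrainTest <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  tr <- cohortParts(config$train)
  te <- cohortParts(config$test)

  # ---- training-side preparation (no test expression touched yet) ----
  trResp <- labelResponse(tr$response, config$sdssPercentile)
  teResp <- labelResponse(te$response, config$sdssPercentile)

  drugs <- sort(unique(trResp$drug_id))
  counts <- do.call(rbind, lapply(drugs, function(d) {
    trd <- trResp[trResp$drug_id == d, ]
    ted <- teResp[teResp$drug_id == d, ]
    data.frame(drug = d,
               train_sens = sum(trd$label == "sensitive"),
               train_res = sum(trd$label == "resistant"),
               test_sens = sum(ted$label == "sensitive"),
               test_res = sum(ted$label == "resistant"))
  }))
  included <- drugInclusionFilter(counts, config$thresholds)
  if (length(included) == 0L) {
    stop("no drugs pass the inclusion filter; nothing to run")
  }

  genesTr <- geneIds(tr$expression)
  genesTe <- geneIds(te$expression)
  common <- intersect(genesTr, genesTe)
  overlap <- length(common) / length(union(genesTr, genesTe))
  if (length(common) < 2L) stop("train and test share fewer than 2 genes")
  message(sprintf("gene intersection: %d genes (overlap fraction %.3f)",
                  length(common), overlap))
  Xtr <- exprValues(tr$expression)[common, , drop = FALSE]

  balancedTags <- switch(config$balanced,
                         both = c("NB", "B"), on = "B", off = "NB")

  models <- list(); comparators <- list(); trainLabels <- list()
  for (d in included) {
    trd <- trResp[trResp$drug_id == d, ]
    ids <- intersect(colnames(Xtr), trd$sample_id)
    lab <- trd$label[match(ids, trd$sample_id)]
    names(lab) <- ids
    models[[d]] <- fitKtsp(Xtr[, ids, drop = FALSE], lab,
                           kRange = config$kRange)
    trainLabels[[d]] <- lab
    comparators[[d]] <- list()
    for (spec in config$comparators) {
      for (btag in balancedTags) {
        sp <- spec
        sp$balance <- if (btag == "B") "smote" else "none"
        sp$seed <- config$seed + sp$seed
        nm <- paste(sp$kind, btag, sep = ".")
        comparators[[d]][[nm]] <- tuneAndTrain(
          sp, t(Xtr[, ids, drop = FALSE]), lab)
      }
    }
  }

  # ---- test-side evaluation (training artifacts frozen above) ----
  Xte <- exprValues(te$expression)[common, , drop = FALSE]
  metrics <- list(); compliance <- list()
  for (d in included) {
    ted <- teResp[teResp$drug_id == d, ]
    ids <- intersect(colnames(Xte), ted$sample_id)
    truth <- ted$label[match(ids, ted$sample_id)]
    Xd <- Xte[, ids, drop = FALSE]
    pred <- predict(models[[d]], Xd)
    sc <- decisionScore(models[[d]], Xd)
    metrics[[length(metrics) + 1L]] <-
      metricsRow(d, "ktsp", "NB", truth, unname(pred), unname(sc))
    for (nm in names(comparators[[d]])) {
      pr <- predictComparator(comparators[[d]][[nm]], t(Xd))
      btag <- sub(".*\\.", "", nm)
      kind <- sub("\\.[^.]*$", "", nm)
      metrics[[length(metrics) + 1L]] <-
        metricsRow(d, kind, btag, truth, pr$label, pr$score)
    }
    trIds <- names(trainLabels[[d]])
    bothX <- cbind(Xtr[, trIds, drop = FALSE], Xd)
    # cohorts may reuse sample ids (e.g. seeded generators); disambiguate
    colnames(bothX) <- c(paste0("train:", trIds), paste0("test:", ids))
    tags <- c(rep("train", length(trIds)), rep("test", length(ids)))
    names(tags) <- colnames(bothX)
    compliance[[d]] <- ruleComplianceProfile(models[[d]], bothX, tags,
                                             seed = config$seed)
  }
  metrics <- do.call(rbind, metrics)
  recurrence <- geneRecurrence(models)

  report <- structure(list(metrics = metrics, models = models,
                           comparators = comparators,
                           includedDrugs = included, counts = counts,
                           compliance = compliance, recurrence = recurrence,
                           geneOverlap = overlap, seed = config$seed),
                      class = "RunReport")
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(config$outDir, "metrics.csv"),
                     row.names = FALSE)
    writeRulesTable(models, file.path(config$outDir, "rules.csv"))
    utils::write.csv(recurrence$table,
                     file.path(config$outDir, "gene_recurrence.csv"),
                     row.names = FALSE)
    comp <- do.call(rbind, lapply(names(compliance), function(d) {
      cbind(drug = d, compliance[[d]]$profile)
    }))
    utils::write.csv(comp, file.path(config$outDir, "compliance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = config$seed,
                              thresholds = config$thresholds,
                              kRange = config$kRange,
                              balanced = config$balanced),
                         file.path(config$outDir, "run_config.json"),
                         auto_unbox = TRUE)
  }
  report
}
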