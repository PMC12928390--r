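# Evaluation metrics and secondary analyses: confusion metrics, AUROC
# (Mann-Whitney form), the drug-inclusion filter, one-sided Wilcoxon sDSS
# group tests with Benjamini-Hochberg correction, rule-compliance profiles
# and gene recurrence across classifiers.

#' Confusion-matrix metrics with "sensitive" as the positive class
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), balanced accuracy =
#' their arithmetic mean. When a class is absent from the truth the
#' corresponding rate (and the balanced accuracy) is `NA` -- undefined, not
#' zero.
#'
#' @param truth,predicted character vectors of `"sensitive"`/`"resistant"`.
#' @return list with `sensitivity`, `specificity`, `balancedAccuracy`, and
#'   `counts` (named TP, FP, TN, FN).
#' @export
confusionMetrics <- function(truth, predicted) {
  truth <- asBinaryLabels(truth, "truth")
  predicted <- asBinaryLabels(predicted, "predicted")
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  tp <- sum(truth == "sensitive" & predicted == "sensitive")
  fn <- sum(truth == "sensitive" & predicted == "resistant")
  tn <- sum(truth == "resistant" & predicted == "resistant")
  fp <- sum(truth == "resistant" & predicted == "sensitive")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       balancedAccuracy = (sens + spec) / 2,
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' AUROC by the Mann-Whitney formulation
#'
#' `P(score_sensitive > score_resistant) + 0.5 * P(equal)` over all
#' cross-class pairs, computed from mid-ranks.
#'
#' @param truth character vector of `"sensitive"`/`"resistant"`.
#' @param scores numeric scores, higher = more sensitive.
#' @return numeric(1) in `[0, 1]`; `NA` (with a warning) if only one class
#'   is present.
#' @export
aurocScore <- function(truth, scores) {
  truth <- asBinaryLabels(truth, "truth")
  if (length(truth) != length(scores)) {
    stop("truth and scores must have equal length")
  }
  pos <- truth == "sensitive"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)  # mid-ranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Drug inclusion filter on per-cohort class counts
#'
#' A drug is included iff it has at least `thresholds[1]` sensitive and
#' `thresholds[2]` resistant samples in the training cohort and at least
#' `thresholds[3]` sensitive and `thresholds[4]` resistant samples in the
#' test cohort (all comparisons `>=`).
#'
#' @param counts data.frame with columns `drug`, `train_sens`, `train_res`,
#'   `test_sens`, `test_res`.
#' @param thresholds integer(4), default `c(20, 20, 10, 10)`.
#' @return character vector of included drug ids (possibly empty).
#' @export
drugInclusionFilter <- function(counts, thresholds = c(20L, 20L, 10L, 10L)) {
  if (nrow(counts) == 0L) return(character(0))
  need <- c("drug", "train_sens", "train_res", "test_sens", "test_res")
  if (!all(need %in% names(counts))) {
    stop(sprintf("counts must have columns: %s", paste(need, collapse = ", ")))
  }
  keep <- counts$train_sens >= thresholds[1] &
    counts$train_res >= thresholds[2] &
    counts$test_sens >= thresholds[3] &
    counts$test_res >= thresholds[4]
  counts$drug[keep]
}

#' Per-drug one-sided Wilcoxon tests on sDSS with BH correction
#'
#' For each drug, tests whether the sDSS values of predicted-sensitive
#' samples are stochastically greater than those of predicted-resistant
#' samples (one-sided Wilcoxon rank-sum; exact null when both groups have at
#' most 25 samples and no ties, otherwise the normal approximation with
#' continuity and tie correction). Raw p-values are Benjamini-Hochberg
#' adjusted across the tested drugs. Drugs with an empty predicted group are
#' reported as untested (`NA`), not as p = 1.
#'
#' @param records data.frame with columns `drug_id`, `sdss`, `predicted`
#'   (`"sensitive"`/`"resistant"`).
#' @return data.frame with one row per drug: `drug_id`, `n_sens`, `n_res`,
#'   `p`, `p_adj`, `tested`.
#' @export
sdssGroupTest <- function(records) {
  need <- c("drug_id", "sdss", "predicted")
  if (!all(need %in% names(records))) {
    stop(sprintf("records must have columns: %s", paste(need, collapse = ", ")))
  }
  drugs <- unique(records$drug_id)
  rows <- lapply(drugs, function(d) {
    sub <- records[records$drug_id == d, ]
    s <- sub$sdss[sub$predicted == "sensitive"]
    r <- sub$sdss[sub$predicted == "resistant"]
    if (length(s) == 0L || length(r) == 0L) {
      return(data.frame(drug_id = d, n_sens = length(s), n_res = length(r),
                        p = NA_real_, tested = FALSE))
    }
    exact <- length(s) <= 25L && length(r) <= 25L &&
      !anyDuplicated(c(s, r))
    p <- suppressWarnings(
      wilcox.test(s, r, alternative = "greater", exact = exact,
                  correct = TRUE)$p.value)
    data.frame(drug_id = d, n_sens = length(s), n_res = length(r),
               p = p, tested = TRUE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$tested)) stop("no drug has both predicted groups non-empty")
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- p.adjust(out$p[out$tested], method = "BH")
  out
}

#' Rule-compliance profile of a model across sample groups
#'
#' Computes the per-sample vote sum (+1 per satisfied rule, -1 otherwise)
#' and summarizes it by group tag (e.g. temporal cohort, de novo status).
#' For exactly two groups, the difference of group means is quantified with
#' a seeded two-group bootstrap percentile confidence interval.
#'
#' @param model a [KTSPModel-class].
#' @param m an [ExpressionMatrix-class] or genes x samples matrix containing
#'   every model gene.
#' @param groups character vector of group tags, one per sample (named by
#'   sample id or in column order).
#' @param nBoot bootstrap resamples for the two-group comparison
#'   (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list with `profile` (data.frame `sample_id`, `group`,
#'   `vote_sum`), `summary` (per-group n/mean/sd), and, for two groups,
#'   `difference` (estimate and bootstrap CI).
#' @export
ruleComplianceProfile <- function(model, m, groups, nBoot = 1000L, seed = 1L,
                                  conf = 0.95) {
  X <- extractLog2Matrix(m)
  vs <- voteSums(model, X)
  ids <- colnames(X)
  if (!is.null(names(groups))) {
    miss <- setdiff(ids, names(groups))
    if (length(miss)) {
      stop(sprintf("no group tag for sample(s): %s",
                   paste(head(miss, 5L), collapse = ", ")))
    }
    groups <- groups[ids]
  } else if (length(groups) != ncol(X)) {
    stop("groups must have one tag per sample")
  }
  groups <- as.character(groups)
  profile <- data.frame(sample_id = ids, group = groups, vote_sum = unname(vs),
                        stringsAsFactors = FALSE)
  tags <- sort(unique(groups))
  summ <- do.call(rbind, lapply(tags, function(g) {
    v <- vs[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = sd(v))
  }))
  out <- list(profile = profile, summary = summ)
  if (length(tags) == 2L) {
    v1 <- vs[groups == tags[1L]]
    v2 <- vs[groups == tags[2L]]
    est <- mean(v1) - mean(v2)
    boots <- withSeed(seed, {
      vapply(seq_len(nBoot), function(i) {
        mean(sample(v1, replace = TRUE)) - mean(sample(v2, replace = TRUE))
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
    out$difference <- list(groups = tags, estimate = est, ci = ci,
                           nBoot = nBoot, seed = seed, conf = conf)
  }
  out
}

#' Gene recurrence across per-drug classifiers
#'
#' Counts, for each gene, how many distinct classifiers use it, and reports
#' the fraction of genes appearing in exactly one classifier together with
#' each gene's orientation per drug: a gene appearing as `geneA`
#' (overexpression votes sensitive) is tagged "over", as `geneB` "under".
#'
#' @param models named list of [KTSPModel-class] objects (names = drugs).
#' @return list with `table` (data.frame `gene`, `n_classifiers`, `n_over`,
#'   `n_under`, sorted by decreasing recurrence), `fractionUnique`, and
#'   `orientation` (data.frame `gene`, `drug`, `orientation`).
#' @export
geneRecurrence <- function(models) {
  if (length(models) < 1L) stop("at least one model is required")
  if (is.null(names(models))) stop("models must be named by drug")
  orient <- do.call(rbind, lapply(names(models), function(d) {
    r <- modelRules(models[[d]])
    data.frame(gene = c(r$geneA, r$geneB), drug = d,
               orientation = rep(c("over", "under"), each = nrow(r)),
               stringsAsFactors = FALSE)
  }))
  counts <- tapply(orient$drug, orient$gene, function(x) length(unique(x)))
  nOver <- tapply(orient$orientation == "over", orient$gene, sum)
  nUnder <- tapply(orient$orientation == "under", orient$gene, sum)
  genes <- names(counts)
  tab <- data.frame(gene = genes, n_classifiers = as.integer(counts),
                    n_over = as.integer(nOver[genes]),
                    n_under = as.integer(nUnder[genes]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$n_classifiers, tab$gene), ]
  rownames(tab) <- NULL
  list(table = tab,
       fractionUnique = mean(tab$n_classifiers == 1L),
       orientation = orient)
}
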