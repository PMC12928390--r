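test_that("confusion metrics match hand-computed values", {
  truth <- c(rep("sensitive", 4), rep("resistant", 4))
  pred <- c("sensitive", "sensitive", "sensitive", "resistant",
            "sensitive", "sensitive", "resistant", "resistant")
  cm <- confusionMetrics(truth, pred)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 0.5)
  expect_equal(cm$balancedAccuracy, 0.625)
  expect_identical(cm$counts, c(TP = 3L, FP = 2L, TN = 2L, FN = 1L))

  perfect <- confusionMetrics(truth, truth)
  expect_equal(perfect$balancedAccuracy, 1)

  # the imbalance failure mode: predicting only the majority class
  collapse <- confusionMetrics(truth, rep("resistant", 8))
  expect_equal(collapse$sensitivity, 0)
  expect_equal(collapse$balancedAccuracy, 0.5)

  expect_error(confusionMetrics(truth, pred[1:5]), "equal length")
})

test_that("balanced accuracy is always the mean of sensitivity and specificity", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(4:60, 1)
    truth <- sample(c("sensitive", "resistant"), n, replace = TRUE)
    pred <- sample(c("sensitive", "resistant"), n, replace = TRUE)
    cm <- confusionMetrics(truth, pred)
    if (is.na(cm$balancedAccuracy)) {
      expect_true(length(unique(truth)) == 1L)
    } else {
      expect_identical(cm$balancedAccuracy,
                       (cm$sensitivity + cm$specificity) / 2)
    }
  }
})

test_that("absent classes yield undefined rates, not zero", {
  cm <- confusionMetrics(rep("resistant", 5), rep("resistant", 5))
  expect_true(is.na(cm$sensitivity))
  expect_equal(cm$specificity, 1)
  expect_true(is.na(cm$balancedAccuracy))
})

test_that("AUROC equals exhaustive cross-pair counting", {
  truth <- c(rep("sensitive", 3), rep("resistant", 3))
  expect_equal(aurocScore(truth, c(3, 2.5, 2, 1, 0.5, 0)), 1)
  expect_equal(aurocScore(truth, rep(1, 6)), 0.5)

  set.seed(52)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    truth <- sample(c("sensitive", "resistant"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("sensitive", "resistant")
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(aurocScore(truth, scores), bruteAuroc(truth, scores))
  }

  expect_warning(out <- aurocScore(rep("sensitive", 4), 1:4), "one class")
  expect_true(is.na(out))
})

test_that("drug inclusion filter applies all four thresholds inclusively", {
  counts <- data.frame(
    drug = c("d1", "d2", "d3", "d4", "d5"),
    train_sens = c(20, 19, 100, 20, 20),
    train_res = c(20, 40, 100, 20, 19),
    test_sens = c(10, 10, 9, 10, 50),
    test_res = c(10, 10, 50, 9, 50))
  expect_identical(drugInclusionFilter(counts), "d1")
  expect_identical(drugInclusionFilter(counts[0, ]), character(0))
  # thresholds configurable
  expect_identical(drugInclusionFilter(counts, c(19, 19, 9, 9)),
                   c("d1", "d2", "d3", "d4", "d5"))
})

test_that("sdss group tests are one-sided with BH correction across drugs", {
  set.seed(53)
  # wrong direction: sensitive group markedly lower
  rec <- data.frame(
    drug_id = "d1",
    sdss = c(rnorm(10, -5), rnorm(10, 5)),
    predicted = rep(c("sensitive", "resistant"), each = 10))
  out <- sdssGroupTest(rec)
  expect_gte(out$p, 0.5)
  # single tested drug: adjusted equals raw
  expect_equal(out$p_adj, out$p)

  # right direction: small p
  rec2 <- rec
  rec2$sdss <- c(rnorm(10, 5), rnorm(10, -5))
  expect_lt(sdssGroupTest(rec2)$p, 0.01)

  # untested drugs are flagged, not assigned p = 1
  rec3 <- rbind(rec2,
                data.frame(drug_id = "d9", sdss = rnorm(5),
                           predicted = rep("resistant", 5)))
  out3 <- sdssGroupTest(rec3)
  expect_false(out3$tested[out3$drug_id == "d9"])
  expect_true(is.na(out3$p[out3$drug_id == "d9"]))

  expect_error(sdssGroupTest(rec3[rec3$drug_id == "d9", ]), "non-empty")
})

test_that("BH adjustment in sdssGroupTest is monotone and never below raw p", {
  set.seed(54)
  recs <- do.call(rbind, lapply(1:8, function(i) {
    shift <- runif(1, 0, 3)
    data.frame(drug_id = paste0("d", i),
               sdss = c(rnorm(12, shift), rnorm(15, 0)),
               predicted = rep(c("sensitive", "resistant"), c(12, 15)))
  }))
  out <- sdssGroupTest(recs)
  expect_true(all(out$p_adj >= out$p - 1e-12))
  ord <- order(out$p)
  expect_true(all(diff(out$p_adj[ord]) >= -1e-12))
})

test_that("rule compliance profiles summarize vote sums by group", {
  rules <- data.frame(geneA = c("a1", "a2"), geneB = c("b1", "b2"),
                      delta = c(0.9, 0.8), gamma = c(2, 1))
  m <- new("KTSPModel", rules = rules, k = 2L, tiePolicy = "resistant",
           classLabels = c(positive = "sensitive", negative = "resistant"),
           trainingMeta = list(kMax = 15L))
  X <- matrix(rep(c(2, 1, 2, 1), 6), 4, 6,
              dimnames = list(c("a1", "b1", "a2", "b2"), paste0("s", 1:6)))
  groups <- setNames(rep(c("w12", "w34"), each = 3), paste0("s", 1:6))
  cp <- ruleComplianceProfile(m, X, groups)
  expect_true(all(cp$profile$vote_sum == 2))
  expect_equal(cp$summary$mean, c(2, 2))
  expect_equal(cp$difference$estimate, 0)

  expect_error(ruleComplianceProfile(m, X, groups[-1]), "s1")
  Xmiss <- X[-1, , drop = FALSE]
  expect_error(ruleComplianceProfile(m, Xmiss, groups), "a1")
})

test_that("bootstrap CI covers zero for groups from the same generator", {
  co <- generateCohort(smallConfig(55))
  X <- exprValues(cohortExpression(co))
  m <- fitKtsp(X, cohortLabels(co), kRange = c(1, 5))
  covered <- 0L
  for (s in 1:40) {
    grp <- withr::with_seed(700 + s, {
      setNames(sample(rep(c("gA", "gB"), length.out = ncol(X))), colnames(X))
    })
    cp <- ruleComplianceProfile(m, X, grp, nBoot = 400, seed = s)
    ci <- cp$difference$ci
    if (ci[1] <= 0 && 0 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 32L)  # >= 80% coverage under the null
})

test_that("gene recurrence counts classifiers per gene", {
  r1 <- data.frame(geneA = c("gA", "gB"), geneB = c("gC", "gD"),
                   delta = c(0.9, 0.8), gamma = c(2, 1))
  r2 <- data.frame(geneA = "gE", geneB = "gA", delta = 0.7, gamma = 1)
  mk <- function(r) new("KTSPModel", rules = r, k = nrow(r),
                        tiePolicy = "resistant",
                        classLabels = c(positive = "sensitive",
                                        negative = "resistant"),
                        trainingMeta = list(kMax = 15L))
  gr <- geneRecurrence(list(d1 = mk(r1), d2 = mk(r2)))
  tab <- gr$table
  expect_identical(tab$n_classifiers[tab$gene == "gA"], 2L)
  expect_equal(gr$fractionUnique, 4 / 5)
  # gA votes sensitive when over-expressed in d1, under-expressed in d2
  oA <- gr$orientation[gr$orientation$gene == "gA", ]
  expect_setequal(oA$orientation, c("over", "under"))

  # disjoint models: every gene unique
  r3 <- data.frame(geneA = "gX", geneB = "gY", delta = 0.6, gamma = 1)
  expect_equal(geneRecurrence(list(d1 = mk(r1), d3 = mk(r3)))$fractionUnique, 1)

  # same model under two drug names: all counts 2, none unique
  gr2 <- geneRecurrence(list(d1 = mk(r1), d2 = mk(r1)))
  expect_true(all(gr2$table$n_classifiers == 2L))
  expect_equal(gr2$fractionUnique, 0)
})
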