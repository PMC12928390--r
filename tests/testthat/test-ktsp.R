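test_that("pairScore handles separation, equality and errors", {
  lab <- rep(c("sensitive", "resistant"), each = 6)
  a <- c(5, 6, 7, 5, 6, 7, 1, 2, 3, 1, 2, 3)
  b <- c(1, 2, 3, 1, 2, 3, 5, 6, 7, 5, 6, 7)
  ps <- pairScore(a, b, lab)
  expect_equal(unname(ps["delta"]), 1)

  # a > b in half of each class: no signal
  a2 <- rep(c(2, 0), 6)
  b2 <- rep(1, 12)
  expect_equal(unname(pairScore(a2, b2, lab)["delta"]), 0)

  expect_error(pairScore(a, b, rep("sensitive", 12)), "both classes")
  expect_error(pairScore(a, b[1:5], lab[1:5]), "equal length")
})

test_that("pairScore equals brute-force counting, including ties", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    # quantized values guarantee ties occur
    a <- sample(1:5, n, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    lab <- sample(c("sensitive", "resistant"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("sensitive", "resistant")
    expect_equal(unname(pairScore(a, b, lab)["delta"]),
                 bruteDelta(a, b, lab))
  }
})

test_that("rankDisjointPairs is greedy on disjoint genes", {
  # g1 > g2 separates perfectly; g1 > g3 nearly; g4 vs g5 weakly
  lab <- setNames(rep(c("sensitive", "resistant"), each = 10), paste0("s", 1:20))
  set.seed(32)
  X <- matrix(rnorm(5 * 20, sd = 0.01), 5, 20,
              dimnames = list(paste0("g", 1:5), names(lab)))
  X["g1", ] <- ifelse(lab == "sensitive", 10, 0)
  X["g2", ] <- 5
  X["g3", ] <- c(11, rep(5, 19))  # one sensitive sample violates g1 > g3
  X["g4", ] <- ifelse(lab == "sensitive", c(rep(1, 6), rep(-1, 4)), -1)

  rules <- rankDisjointPairs(X, lab, maxPairs = 3)
  expect_identical(rules$geneA[1], "g1")
  expect_identical(rules$geneB[1], "g2")
  # (g1, g3) has the next-highest delta but shares g1, so it is skipped
  expect_false(any(rules$geneA[-1] == "g1" | rules$geneB[-1] == "g1"))
  genes <- c(rules$geneA, rules$geneB)
  expect_identical(anyDuplicated(genes), 0L)

  two <- rankDisjointPairs(X[1:2, ], lab, maxPairs = 5)
  expect_identical(nrow(two), 1L)

  expect_error(rankDisjointPairs(X[1, , drop = FALSE], lab), "2 genes")
})

test_that("selectK prefers the single perfect rule over coin-flip rules", {
  wins <- 0L
  for (s in 1:100) {
    set.seed(400 + s)
    n <- 50
    lab <- setNames(rep(c("sensitive", "resistant"), each = n / 2),
                    paste0("s", 1:n))
    X <- matrix(rnorm(12 * n), 12, n,
                dimnames = list(paste0("g", 1:12), names(lab)))
    X["g1", ] <- ifelse(lab == "sensitive", 1, -1)
    X["g2", ] <- 0
    cand <- data.frame(
      geneA = paste0("g", c(1, 3, 5, 7, 9, 11)),
      geneB = paste0("g", c(2, 4, 6, 8, 10, 12)),
      delta = c(1, rep(0, 5)), gamma = 0)
    if (selectK(X, lab, cand) == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 90L)
})

test_that("selectK respects its bounds and degenerate inputs", {
  co <- generateCohort(smallConfig(33))
  X <- exprValues(cohortExpression(co)); lab <- cohortLabels(co)
  cand <- rankDisjointPairs(X, lab, maxPairs = 15)
  expect_identical(selectK(X, lab, cand[1, , drop = FALSE]), 1L)
  k <- selectK(X, lab, cand)
  expect_gte(k, 1L); expect_lte(k, 15L)
  expect_error(selectK(X, lab, cand[0, ]), "non-empty")
})

test_that("fitKtsp composes deterministically and validates inputs", {
  co <- generateCohort(smallConfig(34))
  X <- exprValues(cohortExpression(co)); lab <- cohortLabels(co)
  m1 <- fitKtsp(X, lab)
  m2 <- fitKtsp(X, lab)
  expect_equal(modelRules(m1), modelRules(m2))
  expect_identical(modelK(m1), modelK(m2))
  expect_identical(m1@trainingMeta$nSensitive, 15L)

  expect_error(fitKtsp(X, setNames(rep("sensitive", ncol(X)), colnames(X))),
               "both classes|2 training")
})

test_that("perfectly separable two-gene toy yields that single rule", {
  lab <- setNames(rep(c("sensitive", "resistant"), each = 5), paste0("s", 1:10))
  X <- rbind(gUp = ifelse(lab == "sensitive", 2, 0),
             gRef = rep(1, 10))
  colnames(X) <- names(lab)
  m <- fitKtsp(X, lab, kRange = c(1, 15))
  expect_identical(modelK(m), 1L)
  expect_identical(modelRules(m)$geneA, "gUp")
  expect_identical(modelRules(m)$geneB, "gRef")
  expect_equal(modelRules(m)$delta, 1)
})

test_that("vote sums count satisfied rules and flag missing genes", {
  rules <- data.frame(geneA = c("a1", "a2", "a3"),
                      geneB = c("b1", "b2", "b3"),
                      delta = c(0.9, 0.8, 0.7), gamma = c(3, 2, 1))
  m <- new("KTSPModel", rules = rules, k = 3L, tiePolicy = "resistant",
           classLabels = c(positive = "sensitive", negative = "resistant"),
           trainingMeta = list(kMax = 15L))
  allYes <- c(a1 = 2, b1 = 1, a2 = 2, b2 = 1, a3 = 2, b3 = 1)
  expect_identical(voteSum(m, allYes), 3L)
  allNo <- c(a1 = 1, b1 = 2, a2 = 1, b2 = 2, a3 = 1, b3 = 2)
  expect_identical(voteSum(m, allNo), -3L)
  twoOfThree <- c(a1 = 2, b1 = 1, a2 = 2, b2 = 1, a3 = 1, b3 = 2)
  expect_identical(voteSum(m, twoOfThree), 1L)
  # a tied rule counts as not applying
  tied <- c(a1 = 1, b1 = 1, a2 = 2, b2 = 1, a3 = 2, b3 = 1)
  expect_identical(voteSum(m, tied), 1L)
  expect_error(voteSum(m, allYes[-2]), "b1")
})

test_that("prediction uses majority vote with the configured tie policy", {
  rules2 <- data.frame(geneA = c("a1", "a2"), geneB = c("b1", "b2"),
                       delta = c(0.9, 0.8), gamma = c(2, 1))
  mR <- new("KTSPModel", rules = rules2, k = 2L, tiePolicy = "resistant",
            classLabels = c(positive = "sensitive", negative = "resistant"),
            trainingMeta = list(kMax = 15L))
  mS <- new("KTSPModel", rules = rules2, k = 2L, tiePolicy = "sensitive",
            classLabels = c(positive = "sensitive", negative = "resistant"),
            trainingMeta = list(kMax = 15L))
  split <- matrix(c(2, 1, 1, 2), 4, 1,
                  dimnames = list(c("a1", "b1", "a2", "b2"), "s1"))
  expect_identical(unname(predict(mR, split)), "resistant")
  expect_identical(unname(predict(mS, split)), "sensitive")
  expect_equal(unname(decisionScore(mR, split)), 0.5)

  yes <- matrix(c(2, 1, 2, 1), 4, 1,
                dimnames = list(c("a1", "b1", "a2", "b2"), "s1"))
  expect_identical(unname(predict(mR, yes)), "sensitive")
  expect_equal(unname(decisionScore(mR, yes)), 1)
})

test_that("flipping all labels flips orientations and negates vote sums", {
  co <- generateCohort(smallConfig(36))
  X <- exprValues(cohortExpression(co))
  lab <- cohortLabels(co)
  flip <- setNames(ifelse(lab == "sensitive", "resistant", "sensitive"),
                   names(lab))
  r1 <- rankDisjointPairs(X, lab, maxPairs = 6)
  r2 <- rankDisjointPairs(X, flip, maxPairs = 6)
  expect_identical(r1$geneA, r2$geneB)
  expect_identical(r1$geneB, r2$geneA)
  m1 <- new("KTSPModel", rules = r1, k = nrow(r1), tiePolicy = "resistant",
            classLabels = c(positive = "sensitive", negative = "resistant"),
            trainingMeta = list(kMax = 15L))
  m2 <- new("KTSPModel", rules = r2, k = nrow(r2), tiePolicy = "resistant",
            classLabels = c(positive = "sensitive", negative = "resistant"),
            trainingMeta = list(kMax = 15L))
  vs1 <- voteSums(m1, X); vs2 <- voteSums(m2, X)
  # with continuous data there are no expression ties, so votes negate
  expect_identical(vs1, -vs2)
})

test_that("predictions are invariant under strictly monotone per-sample maps", {
  co <- generateCohort(smallConfig(37))
  X <- exprValues(cohortExpression(co))
  m <- fitKtsp(X, cohortLabels(co))
  expect_true(checkRankInvariance(m, X, function(x) 2 * x + 7))
  expect_true(checkRankInvariance(m, X, function(x) x^3))
  set.seed(38)
  fams <- list(function(x) exp(x / 4), function(x) x^3,
               function(x) 5 * x - 2, function(x) x + sin(x) / 10 + x / 5)
  maps <- lapply(seq_len(ncol(X)), function(i) fams[[sample(4, 1)]])
  expect_true(checkRankInvariance(m, X, maps))
})
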