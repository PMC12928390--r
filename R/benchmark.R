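# Benchmarking harness: SMOTE, z-score discipline, stratified CV with
# random-search tuning. The learners themselves are delegated to e1071
# (SVM), randomForest and glmnet; this file owns only the harness contract
# (fold construction, SMOTE placement inside folds, standardization with
# training constants only, balanced-accuracy selection).

#' SMOTE oversampling of the minority class
#'
#' Generates synthetic minority samples `x_new = x + u * (x_nn - x)` with
#' `u ~ Uniform(0, 1)` and `x_nn` one of the `kNeighbors` nearest minority
#' neighbours (Euclidean), until the minority class matches the majority
#' count. Deterministic given `seed`. The effective neighbour count is
#' `min(kNeighbors, minority size - 1)`.
#'
#' @param x samples x features numeric matrix.
#' @param labels per-sample class labels (two classes).
#' @param kNeighbors number of nearest minority neighbours (default 5).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return list with `x` (augmented matrix) and `labels`.
#' @export
smoteBalance <- function(x, labels, kNeighbors = 5L, seed = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("labels must match rows of x")
  tab <- table(labels)
  if (length(tab) != 2L) stop("exactly two classes are required")
  minority <- names(tab)[which.min(tab)]
  nMin <- min(tab); nMaj <- max(tab)
  if (nMin == nMaj) return(list(x = x, labels = labels))
  if (nMin < 2L) stop("minority class must have at least 2 samples")
  if (kNeighbors < 1L) stop("kNeighbors must be >= 1")
  kEff <- min(as.integer(kNeighbors), nMin - 1L)
  idxMin <- which(labels == minority)
  Xm <- x[idxMin, , drop = FALSE]
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  nn <- do.call(rbind, lapply(seq_len(nMin),
                              function(i) order(D[i, ])[seq_len(kEff)]))
  nSynth <- nMaj - nMin
  synth <- withSeed(seed, {
    base <- sample.int(nMin, nSynth, replace = TRUE)
    pick <- nn[cbind(base, sample.int(kEff, nSynth, replace = TRUE))]
    u <- runif(nSynth)
    Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  })
  rownames(synth) <- sprintf("smote_%d", seq_len(nSynth))
  list(x = rbind(x, synth),
       labels = c(labels, rep(minority, nSynth)))
}

#' Fit z-score standardization constants on training data
#'
#' @param train samples x features matrix (training portion only).
#' @return list with per-feature `mean` and `sd` (`sd` of 0 is kept; see
#'   [zscoreApply()]).
#' @export
zscoreFit <- function(train) {
  train <- as.matrix(train)
  list(mean = colMeans(train), sd = apply(train, 2L, sd))
}

#' Apply z-score constants
#'
#' Features with zero training standard deviation map to 0 (no division
#' error). Test data must be transformed with training constants only.
#'
#' @param constants from [zscoreFit()].
#' @param data samples x features matrix.
#' @return standardized matrix.
#' @export
zscoreApply <- function(constants, data) {
  data <- as.matrix(data)
  s <- constants$sd
  s[s == 0 | !is.finite(s)] <- Inf   # zero-variance feature -> column of 0s
  sweep(sweep(data, 2L, constants$mean, "-"), 2L, s, "/")
}

#' Comparator specification
#'
#' @param kind one of `"svm_linear"`, `"svm_rbf"`, `"random_forest"`,
#'   `"elastic_net"`.
#' @param nRandomDraws random-search draws (default 20).
#' @param folds CV folds (default 5).
#' @param seed integer seed driving fold assignment, hyperparameter draws
#'   and SMOTE.
#' @param balance `"none"` or `"smote"` (SMOTE is applied inside each fold,
#'   to the fold's training portion only).
#' @param standardize z-score features with training constants
#'   (default TRUE for SVM and elastic net, FALSE for random forest).
#' @return list of class `"ComparatorSpec"`.
#' @export
comparatorSpec <- function(kind = c("svm_linear", "svm_rbf", "random_forest",
                                    "elastic_net"),
                           nRandomDraws = 20L, folds = 5L, seed = 1L,
                           balance = c("none", "smote"),
                           standardize = NULL) {
  kind <- match.arg(kind)
  balance <- match.arg(balance)
  if (folds < 2L) stop("folds must be >= 2")
  if (nRandomDraws < 1L) stop("nRandomDraws must be >= 1")
  if (is.null(standardize)) {
    standardize <- kind %in% c("svm_linear", "svm_rbf", "elastic_net")
  }
  structure(list(kind = kind, nRandomDraws = as.integer(nRandomDraws),
                 folds = as.integer(folds), seed = as.integer(seed),
                 balance = balance, standardize = isTRUE(standardize)),
            class = "ComparatorSpec")
}

drawHyper <- function(kind, p) {
  switch(kind,
    svm_linear   = list(cost = 10^runif(1, -3, 3)),
    svm_rbf      = list(cost = 10^runif(1, -3, 3),
                        gamma = 10^runif(1, -5, 1)),
    random_forest = list(ntree = 500L,
                         mtry = sample.int(max(1L, min(p, ceiling(2 * sqrt(p)))), 1L)),
    elastic_net  = list(alpha = runif(1), lambda = 10^runif(1, -4, 1)))
}

fitLearner <- function(kind, x, y, hp) {
  # y: factor with levels c("resistant", "sensitive")
  switch(kind,
    svm_linear = e1071::svm(x, y, kernel = "linear", cost = hp$cost,
                            scale = FALSE),
    svm_rbf = e1071::svm(x, y, kernel = "radial", cost = hp$cost,
                         gamma = hp$gamma, scale = FALSE),
    random_forest = randomForest::randomForest(x, y, ntree = hp$ntree,
                                               mtry = hp$mtry),
    elastic_net = glmnet::glmnet(x, y, family = "binomial",
                                 alpha = hp$alpha, lambda = hp$lambda))
}

learnerScore <- function(kind, fit, x, hp) {
  switch(kind,
    svm_linear = ,
    svm_rbf = {
      dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
      drop(dv)  # sign calibrated against training labels by the caller
    },
    random_forest = unname(predict(fit, x, type = "prob")[, "sensitive"]),
    elastic_net = drop(predict(fit, x, type = "response", s = hp$lambda)))
}

learnerLabel <- function(kind, fit, x, hp, score) {
  switch(kind,
    svm_linear = ,
    svm_rbf = as.character(predict(fit, x)),
    random_forest = as.character(predict(fit, x)),
    elastic_net = ifelse(score > 0.5, "sensitive", "resistant"))
}

stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                   cl, length(idx), k))
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fitOne <- function(spec, hp, x, y) {
  # returns fitted learner + standardization constants + svm sign calibration
  if (spec$balance == "smote") {
    bal <- smoteBalance(x, as.character(y), seed = NULL)
    x <- bal$x
    y <- factor(bal$labels, levels = levels(y))
  }
  constants <- NULL
  if (spec$standardize) {
    constants <- zscoreFit(x)
    x <- zscoreApply(constants, x)
  }
  fit <- fitLearner(spec$kind, x, y, hp)
  flip <- FALSE
  if (spec$kind %in% c("svm_linear", "svm_rbf")) {
    sc <- learnerScore(spec$kind, fit, x, hp)
    flip <- aurocScore(as.character(y), sc) < 0.5
  }
  list(fit = fit, constants = constants, flip = flip)
}

predictOne <- function(spec, hp, trained, x) {
  if (!is.null(trained$constants)) x <- zscoreApply(trained$constants, x)
  score <- learnerScore(spec$kind, trained$fit, x, hp)
  if (isTRUE(trained$flip)) score <- -score
  label <- learnerLabel(spec$kind, trained$fit, x, hp, score)
  list(label = label, score = score)
}

#' Tune and train a comparator classifier
#'
#' Random-search tuning under stratified k-fold cross-validation: each
#' hyperparameter draw is scored by its mean balanced accuracy across folds,
#' with SMOTE (when enabled) applied inside each fold to the training
#' portion only, and z-scoring fitted on the fold training portion and
#' applied to the held-out fold. The best draw is refit on the full
#' (optionally SMOTE-balanced) training data. Hyperparameter ranges:
#' SVM cost log-uniform on `[1e-3, 1e3]`; RBF gamma log-uniform on
#' `[1e-5, 1e1]`; random forest 500 trees with `mtry` uniform on
#' `[1, 2*sqrt(p)]`; elastic-net mixing uniform on `[0, 1]` and penalty
#' log-uniform on `[1e-4, 1e1]`. Training never touches test data.
#'
#' @param spec a [comparatorSpec()].
#' @param x samples x features training matrix.
#' @param labels per-sample `"sensitive"`/`"resistant"`.
#' @return list of class `"TrainedComparator"`: the fitted learner, chosen
#'   hyperparameters, standardization constants (train-derived), CV table,
#'   and score direction (higher = sensitive).
#' @export
tuneAndTrain <- function(spec, x, labels) {
  stopifnot(inherits(spec, "ComparatorSpec"))
  x <- as.matrix(x)
  labels <- asBinaryLabels(labels)
  if (length(unique(labels)) != 2L) stop("both classes must be present")
  y <- factor(labels, levels = c("resistant", "sensitive"))
  p <- ncol(x)

  withSeed(spec$seed, {
    fold <- stratifiedFolds(labels, spec$folds)
    draws <- lapply(seq_len(spec$nRandomDraws), function(i) drawHyper(spec$kind, p))
    cvScore <- vapply(draws, function(hp) {
      bas <- vapply(seq_len(spec$folds), function(f) {
        trIdx <- fold != f
        trained <- fitOne(spec, hp, x[trIdx, , drop = FALSE], y[trIdx])
        pr <- predictOne(spec, hp, trained, x[!trIdx, , drop = FALSE])
        confusionMetrics(labels[!trIdx], pr$label)$balancedAccuracy
      }, numeric(1))
      mean(bas, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(cvScore)
    hp <- draws[[best]]
    trained <- fitOne(spec, hp, x, y)
    structure(list(spec = spec, hyper = hp, fit = trained$fit,
                   constants = trained$constants, flip = trained$flip,
                   cv = data.frame(draw = seq_along(cvScore),
                                   balancedAccuracy = cvScore),
                   bestDraw = best,
                   features = colnames(x)),
              class = "TrainedComparator")
  })
}

#' Predict with a trained comparator
#'
#' @param model a `"TrainedComparator"` from [tuneAndTrain()].
#' @param x samples x features matrix (same feature order as training).
#' @return list with `label` (character) and `score` (numeric, higher =
#'   sensitive).
#' @export
predictComparator <- function(model, x) {
  stopifnot(inherits(model, "TrainedComparator"))
  x <- as.matrix(x)
  predictOne(model$spec, model$hyper, model, x)
}
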