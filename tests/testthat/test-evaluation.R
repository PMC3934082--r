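# ROC/Az, thresholded rates, stratified resampling, stability experiment.

test_that("ROC curves reproduce known areas and sweep invariants", {
  perfect <- scoredPredictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_equal(rocAz(rocCurve(perfect)), 1)

  flat <- scoredPredictions(rep(0.5, 6), rep(c(1, -1), 3))
  expect_equal(rocAz(rocCurve(flat)), 0.5)

  # 3 of 4 positive/negative pairs concordant
  mixed <- scoredPredictions(c(0.1, 0.4, 0.35, 0.8), c(-1, -1, 1, 1))
  expect_equal(rocAz(rocCurve(mixed)), 0.75)

  curve <- rocCurve(mixed)
  expect_equal(curve@tpr[1], 0); expect_equal(curve@fpr[1], 0)
  expect_equal(curve@tpr[length(curve@tpr)], 1)
  expect_equal(curve@fpr[length(curve@fpr)], 1)
  expect_true(!is.unsorted(curve@tpr) && !is.unsorted(curve@fpr))

  expect_error(rocCurve(scoredPredictions(1:3, rep(1, 3))), "both classes")
})

test_that("trapezoidal area equals pair-counting area including ties", {
  for (s in 1:100) {
    preds <- withSeed(s, {
      n <- sample(6:40, 1)
      scoredPredictions(sample(seq(0, 1, by = 0.1), n, replace = TRUE),
                        c(1, -1, sample(c(1, -1), n - 2, replace = TRUE)))
    })
    expect_equal(rocAz(rocCurve(preds)), aucPairOracle(preds),
                 tolerance = 1e-12)
  }
  # flipping labels and negating scores leaves the area unchanged
  preds <- withSeed(7, scoredPredictions(rnorm(30),
                                         c(1, -1, sample(c(1, -1), 28, TRUE))))
  flipped <- scoredPredictions(-predScores(preds), -predLabels(preds))
  expect_equal(rocAz(rocCurve(preds)), rocAz(rocCurve(flipped)),
               tolerance = 1e-12)
})

test_that("Az agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  preds <- withSeed(13, scoredPredictions(rnorm(60),
                                          rep(c(1, -1), each = 30)))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(predLabels(preds), levels = c(-1, 1)),
    predictor = predScores(preds), quiet = TRUE, direction = "<")))
  expect_equal(rocAz(rocCurve(preds)), ref, tolerance = 1e-12)
})

test_that("sensitivity and specificity follow their definitions", {
  preds <- scoredPredictions(c(10, 9, 8, 7, 6, 5, 4, 3),
                             c(1, 1, 1, -1, 1, -1, -1, -1))
  expect_equal(sensSpec(preds, threshold = 0),
               c(sensitivity = 1, specificity = 0))
  expect_equal(sensSpec(preds, threshold = 11),
               c(sensitivity = 0, specificity = 1))

  # 2x2 table: TP = 9, FN = 1, TN = 8, FP = 2 at threshold 0
  counts <- scoredPredictions(c(rep(1, 9), -1, rep(-1, 8), rep(1, 2)),
                              c(rep(1, 10), rep(-1, 10)))
  expect_equal(sensSpec(counts, threshold = 0),
               c(sensitivity = 0.9, specificity = 0.8))
})

test_that("stratified k-fold partitions preserve class balance", {
  labels <- rep(c(1, -1), each = 5)
  folds <- stratifiedKFold(labels, k = 5, seed = 1)
  for (f in folds) {
    expect_length(f, 2)
    expect_equal(sum(labels[f] == 1), 1)
  }
  expect_setequal(unlist(folds), 1:10)
  expect_equal(sum(lengths(folds)), 10)

  big <- rep(c(1, -1), c(23, 17))
  folds <- stratifiedKFold(big, k = 5, seed = 2)
  counts <- vapply(folds, function(f) sum(big[f] == 1), numeric(1))
  expect_true(all(abs(counts - 23 / 5) <= 1))
  expect_setequal(unlist(folds), seq_along(big))

  same <- stratifiedKFold(big, k = 5, seed = 2)
  expect_identical(folds, same)
  different <- vapply(1:10, function(s)
    !identical(folds, stratifiedKFold(big, k = 5, seed = 100 + s)),
    logical(1))
  expect_true(any(different))

  expect_error(stratifiedKFold(rep(c(1, -1), c(3, 20)), k = 5), "fewer than")
})

test_that("stratified splits respect the training fraction per class", {
  labels <- rep(c(1, -1), each = 100)
  sp <- trainTestSplit(labels, 0.75, seed = 1)
  expect_equal(sum(labels[sp$train] == 1), 75)
  expect_equal(sum(labels[sp$train] == -1), 75)
  expect_length(sp$test, 50)
  expect_setequal(c(sp$train, sp$test), 1:200)

  tiny <- trainTestSplit(c(1, 1, -1, -1), 0.5, seed = 3)
  expect_length(tiny$train, 2)
  expect_length(tiny$test, 2)

  expect_error(trainTestSplit(labels, 1.2), "between 0 and 1")
})

# cheap deterministic method: score by distance to the class centroids
centroidMethod <- list(
  train = function(x, labels)
    list(mp = rowMeans(x[, labels == 1, drop = FALSE]),
         mn = rowMeans(x[, labels == -1, drop = FALSE])),
  score = function(fit, x)
    colSums((x - fit$mn)^2) - colSums((x - fit$mp)^2))

test_that("stability experiment aggregates repeats per fraction", {
  fx <- generateClusterFixture(list(c(-1.5, 0), c(1.5, 0)), sd = 0.4,
                               n = 40, seed = 5)
  x <- t(fx$x)

  constant <- list(train = function(x, labels) NULL,
                   score = function(fit, x) rep(0.5, ncol(x)))
  rep0 <- stabilityExperiment(x, fx$labels, constant, repeats = 2,
                              trainFractions = 0.5, seed = 1)
  expect_equal(rep0@summary$azSd, 0)
  expect_equal(rep0@summary$azMean, 0.5)

  rep1 <- stabilityExperiment(x, fx$labels, centroidMethod, repeats = 2,
                              trainFractions = c(0.9, 0.5), seed = 2)
  expect_equal(nrow(rep1@perRepeat), 4)
  expect_equal(nrow(rep1@summary), 2)
  expect_true(all(rep1@perRepeat$az > 0.9))

  # extending the repeat count preserves the earlier per-repeat results
  rep2 <- stabilityExperiment(x, fx$labels, centroidMethod, repeats = 4,
                              trainFractions = c(0.9, 0.5), seed = 2)
  first <- rep1@perRepeat
  again <- rep2@perRepeat[rep2@perRepeat$repeatIdx <= 2, ]
  rownames(first) <- rownames(again) <- NULL
  expect_equal(again, first)

  expect_error(stabilityExperiment(x, fx$labels, centroidMethod,
                                   repeats = 1), "at least 2")
})

test_that("failing repeats are excluded and counted", {
  fx <- generateClusterFixture(list(c(-1, 0), c(1, 0)), sd = 0.3, n = 20,
                               seed = 9)
  x <- t(fx$x)
  flaky <- list(
    train = function(x, labels) {
      if (ncol(x) < 20) stop("training set too small for this method")
      NULL
    },
    score = function(fit, x) rep(0, ncol(x)))
  # train pool has 15 per class: fraction 0.9 gives 28 samples (works),
  # fraction 0.6 gives 18 (method refuses)
  rep <- suppressWarnings(
    stabilityExperiment(x, fx$labels, flaky, repeats = 3,
                        trainFractions = c(0.9, 0.6), seed = 4))
  expect_equal(rep@failures, 3L)
  expect_equal(nrow(rep@perRepeat), 3)
})
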