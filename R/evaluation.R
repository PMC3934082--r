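# ROC/Az evaluation, stratified resampling, and the repeated-subsampling
# stability experiment.

#' Bundle scores and labels for evaluation
#'
#' @param scores numeric classifier scores, larger = more class +1.
#' @param labels true labels, +1/-1.
#' @param source provenance string.
#' @param details optional per-sample data.frame.
#' @return a \linkS4class{ScoredPredictions}.
#' @export
scoredPredictions <- function(scores, labels, source = "",
                              details = data.frame()) {
  new("ScoredPredictions", scores = as.numeric(scores),
      labels = as.numeric(labels), source = source, details = details)
}

#' @describeIn scoredPredictions score accessor.
#' @param x a \code{ScoredPredictions}.
#' @export
predScores <- function(x) x@scores

#' @describeIn scoredPredictions label accessor.
#' @export
predLabels <- function(x) x@labels

#' @describeIn scoredPredictions per-sample details accessor.
#' @export
predDetails <- function(x) x@details

setMethod("show", "ScoredPredictions", function(object) {
  cat(sprintf("ScoredPredictions: %d samples (%d pos / %d neg)%s\n",
              length(object@scores), sum(object@labels == 1),
              sum(object@labels == -1),
              if (nzchar(object@source))
                paste0(" from '", object@source, "'") else ""))
})

.checkTwoClass <- function(labels) {
  if (!any(labels == 1) || !any(labels == -1))
    stop("ROC analysis needs both classes present")
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over the unique scores in descending order (tied scores
#' grouped at a single threshold, the standard convention), predicting +1 at
#' score >= threshold, and integrates the area by the trapezoidal rule.
#'
#' @param preds a \linkS4class{ScoredPredictions} with both classes present.
#' @return a \linkS4class{ROCCurve}; the sweep starts at (0, 0) and ends at
#'   (1, 1).
#' @export
rocCurve <- function(preds) {
  scores <- preds@scores; labels <- preds@labels
  .checkTwoClass(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)   # group ties at one threshold
  tp <- cumsum(l == 1)[last]
  fp <- cumsum(l == -1)[last]
  nP <- sum(labels == 1); nN <- sum(labels == -1)
  tpr <- c(0, tp / nP); fpr <- c(0, fp / nN)
  az <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  new("ROCCurve", thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr, az = az)
}

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d operating points, Az = %.4f\n",
              length(object@tpr), object@az))
})

#' @describeIn rocCurve area-under-curve accessor.
#' @param curve a \code{ROCCurve}.
#' @export
rocAz <- function(curve) curve@az

#' Pairwise (Mann-Whitney) area under the ROC curve
#'
#' Independent of the threshold sweep: counts positive/negative score pairs,
#' \eqn{Az = (\#concordant + \#tied/2) / (n_+ n_-)}. Agrees with the
#' trapezoidal area of \code{\link{rocCurve}} to numerical precision.
#'
#' @param preds a \linkS4class{ScoredPredictions}.
#' @return scalar Az in [0, 1].
#' @export
aucPairOracle <- function(preds) {
  scores <- preds@scores; labels <- preds@labels
  .checkTwoClass(labels)
  pos <- scores[labels == 1]; neg <- scores[labels == -1]
  total <- 0
  for (p in pos)
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

#' Sensitivity and specificity at a threshold
#'
#' Predicts +1 when score >= threshold; sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP).
#'
#' @param preds a \linkS4class{ScoredPredictions}.
#' @param threshold decision threshold (default 0).
#' @return named numeric c(sensitivity, specificity).
#' @export
sensSpec <- function(preds, threshold = 0) {
  pred <- ifelse(preds@scores >= threshold, 1, -1)
  lab <- preds@labels
  tp <- sum(pred == 1 & lab == 1); fn <- sum(pred == -1 & lab == 1)
  tn <- sum(pred == -1 & lab == -1); fp <- sum(pred == 1 & lab == -1)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Stratified k-fold partition
#'
#' Shuffles each class with the given seed and deals indices round-robin
#' into k folds, so per-fold class counts are within one of proportional.
#'
#' @param labels +1/-1 vector; each class needs at least k members.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of k integer index vectors (a partition of seq_along(labels)).
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  classes <- unique(labels)
  for (cl in classes)
    if (sum(labels == cl) < k)
      stop("class ", cl, " has fewer than k = ", k, " members")
  folds <- vector("list", k)
  withSeed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      for (i in seq_along(idx)) {
        f <- ((i - 1) %% k) + 1
        folds[[f]] <- c(folds[[f]], idx[i])
      }
    }
  })
  lapply(folds, sort)
}

#' Stratified train/test split
#'
#' @param labels +1/-1 vector.
#' @param trainFraction fraction per class assigned to training (default
#'   0.75, i.e. a 75/25 split).
#' @param seed integer seed.
#' @return list(train, test) of index vectors.
#' @export
trainTestSplit <- function(labels, trainFraction = 0.75, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  train <- integer(0)
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      nTrain <- round(trainFraction * length(idx))
      train <- c(train, idx[seq_len(nTrain)])
    }
  })
  test <- setdiff(seq_along(labels), train)
  if (length(train) == 0 || length(test) == 0)
    stop("split left one side empty")
  list(train = sort(train), test = sort(test))
}

#' Repeated-subsampling stability experiment
#'
#' Holds out a fixed stratified test pool, then for every training fraction
#' in the grid and every repeat subsamples the training pool, trains the
#' supplied method, and scores the test pool. Reports per-repeat
#' sensitivity, specificity and Az plus per-fraction mean and standard
#' deviation. Defaults mirror a 50-repeat, 0.95 down to 0.05 fraction grid
#' protocol with a 75/25 pool split.
#'
#' @param x feature matrix, one sample per column.
#' @param labels +1/-1 per sample.
#' @param method list with \code{train = function(x, labels)} returning a
#'   fitted object and \code{score = function(fit, x)} returning numeric
#'   scores (larger = more +1); \code{\link{srcMethod}} and
#'   \code{\link{twsvmSRMethod}} build these, and any external baseline can
#'   be hooked in the same shape.
#' @param repeats number of repeats per fraction (>= 2).
#' @param trainFractions fractions of the training pool to use.
#' @param poolFraction fraction of samples in the training pool.
#' @param threshold decision threshold for sensitivity/specificity.
#' @param seed global seed; per-repeat seeds are derived from it so that
#'   extending \code{repeats} preserves earlier repeats.
#' @return an \linkS4class{EvalReport}. Failed repeats are excluded from the
#'   aggregates and counted in \code{@failures}.
#' @export
stabilityExperiment <- function(x, labels, method, repeats = 50L,
                                trainFractions = seq(0.95, 0.05, by = -0.05),
                                poolFraction = 0.75, threshold = 0,
                                seed = 1L) {
  if (repeats < 2) stop("repeats must be at least 2")
  x <- as.matrix(x)
  pool <- trainTestSplit(labels, poolFraction, moduleSeed(seed, "pool"))
  xTest <- x[, pool$test, drop = FALSE]
  yTest <- labels[pool$test]
  rows <- list(); failures <- 0L; seeds <- integer(0)
  for (f in trainFractions) {
    for (r in seq_len(repeats)) {
      rs <- moduleSeed(seed, sprintf("stab-%.6f-%d", f, r))
      seeds <- c(seeds, rs)
      sub <- withSeed(rs, {
        unlist(lapply(unique(labels[pool$train]), function(cl) {
          idx <- pool$train[labels[pool$train] == cl]
          sample(idx, max(1, round(f * length(idx))))
        }))
      })
      res <- tryCatch({
        fit <- method$train(x[, sub, drop = FALSE], labels[sub])
        sc <- method$score(fit, xTest)
        preds <- scoredPredictions(sc, yTest)
        ss <- sensSpec(preds, threshold)
        data.frame(fraction = f, repeatIdx = r,
                   sensitivity = ss[["sensitivity"]],
                   specificity = ss[["specificity"]],
                   az = rocCurve(preds)@az)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- failures + 1L
        warning("repeat ", r, " at fraction ", f, " failed: ",
                conditionMessage(res))
      } else rows[[length(rows) + 1L]] <- res
    }
  }
  perRepeat <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(perRepeat, perRepeat$fraction),
    function(d) data.frame(
      fraction = d$fraction[1], n = nrow(d),
      sensMean = mean(d$sensitivity), sensSd = sd(d$sensitivity),
      specMean = mean(d$specificity), specSd = sd(d$specificity),
      azMean = mean(d$az), azSd = sd(d$az))))
  agg <- agg[order(-agg$fraction), , drop = FALSE]
  rownames(agg) <- NULL
  new("EvalReport", perRepeat = perRepeat, summary = agg,
      config = list(repeats = repeats, trainFractions = trainFractions,
                    poolFraction = poolFraction, threshold = threshold,
                    seed = seed),
      seeds = seeds, failures = failures)
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d repeats x %d fractions (%d failures)\n",
              object@config$repeats, length(object@config$trainFractions),
              object@failures))
  print(object@summary, digits = 4)
})

#' Method adapters for the stability experiment
#'
#' \code{srcMethod} wraps sparse-representation classification: training
#' assembles a vocabulary from the (transformed, normalized) training
#' columns; scoring is the residual difference. \code{twsvmSRMethod}
#' splits the training samples into a vocabulary half and a classifier half
#' (\code{\link{vocabularySplit}}), codes the classifier half against the
#' vocabulary, and trains a twin SVM on those sparse codes; test samples
#' are coded against the same vocabulary.
#'
#' @param transform \linkS4class{FeatureTransform} or NULL.
#' @param settings \linkS4class{SolverSettings} for the sparse coder.
#' @param c1,c2,kernel,ridge twin-SVM parameters (defaults: RBF sigma 15,
#'   c1 = c2 = 1000).
#' @return a list(train, score) usable by \code{\link{stabilityExperiment}}.
#' @name methodAdapters
NULL

#' @rdname methodAdapters
#' @export
srcMethod <- function(transform = NULL, settings = solverSettings()) {
  list(
    train = function(x, labels) {
      xt <- if (is.null(transform)) x else applyTransform(transform, x)
      Vocabulary(xt, labels, transformId =
                   if (is.null(transform)) "identity" else transform@kind)
    },
    score = function(fit, x) {
      predScores(srcScoreBatch(fit, x, transform, settings,
                               labels = rep(1, ncol(as.matrix(x)))))
    })
}

#' @rdname methodAdapters
#' @export
twsvmSRMethod <- function(transform = NULL, settings = solverSettings(),
                          c1 = 1000, c2 = 1000, kernel = rbfKernel(15),
                          ridge = 1e-7) {
  codeMatrix <- function(vocab, x) {
    x <- as.matrix(x)
    gram <- crossprod(atomMatrix(vocab))
    out <- matrix(0, ncol(atomMatrix(vocab)), ncol(x))
    for (i in seq_len(ncol(x))) {
      yt <- if (is.null(transform)) x[, i] else applyTransform(transform, x[, i])
      yt <- yt / sqrt(sum(yt^2))
      out[, i] <- solveL1LS(vocab, yt, settings, gram = gram)@coefficients
    }
    out
  }
  list(
    train = function(x, labels) {
      x <- as.matrix(x)
      # vocabulary and classifier halves must be disjoint: coding a sample
      # against a vocabulary containing itself yields a degenerate self-code
      sel <- vocabularySplit(labels)
      xv <- if (is.null(transform)) x[, sel, drop = FALSE]
            else applyTransform(transform, x[, sel, drop = FALSE])
      vocab <- Vocabulary(xv, labels[sel], transformId =
                            if (is.null(transform)) "identity" else transform@kind)
      codes <- codeMatrix(vocab, x[, !sel, drop = FALSE])
      clab <- labels[!sel]
      model <- trainTWSVM(twsvmProblem(t(codes[, clab == 1, drop = FALSE]),
                                       t(codes[, clab == -1, drop = FALSE]),
                                       c1 = c1, c2 = c2, kernel = kernel,
                                       ridge = ridge))
      list(vocab = vocab, model = model)
    },
    score = function(fit, x) {
      codes <- codeMatrix(fit$vocab, x)
      predict(fit$model, t(codes))$score
    })
}
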