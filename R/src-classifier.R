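# Sparse-representation classification (SRC): code a test sample against the
# labelled vocabulary, mask the code per class, and classify by the smaller
# class-restricted reconstruction residual.

#' Restrict a sparse code to one class
#'
#' Keeps the coefficients on vocabulary columns of the requested class and
#' zeroes the rest. The two class restrictions partition the code:
#' \code{classRestrictedCode(c, l, +1) + classRestrictedCode(c, l, -1) == c}.
#'
#' @param code a \linkS4class{SparseCode} or plain numeric vector.
#' @param labels per-column class labels aligned with the code.
#' @param class +1 or -1.
#' @return numeric vector of the same length.
#' @export
classRestrictedCode <- function(code, labels, class) {
  coef <- if (is(code, "SparseCode")) code@coefficients else as.numeric(code)
  if (length(coef) != length(labels))
    stop("labels must align with code coefficients")
  if (!class %in% c(-1, 1)) stop("unknown class label: ", class)
  out <- numeric(length(coef))
  keep <- labels == class
  out[keep] <- coef[keep]
  out
}

#' Class-restricted reconstruction residual
#'
#' \eqn{r_i(y) = \|y - A \delta_i(c)\|_2} for a normalized vocabulary A and
#' normalized test vector y.
#'
#' @param vocab a normalized \linkS4class{Vocabulary}.
#' @param y normalized feature vector.
#' @param restrictedCode output of \code{\link{classRestrictedCode}}.
#' @return nonnegative scalar.
#' @export
srcResidual <- function(vocab, y, restrictedCode) {
  A <- atomMatrix(vocab)
  if (length(y) != nrow(A)) stop("y length must match vocabulary features")
  if (length(restrictedCode) != ncol(A))
    stop("code length must match vocabulary columns")
  sqrt(sum((y - as.numeric(A %*% restrictedCode))^2))
}

#' Classify one sample by sparse representation
#'
#' Runs the full pipeline on a raw patch vector: feature transform,
#' unit-normalization, l1-regularized sparse coding, per-class restricted
#' residuals, argmin. The continuous score is r(-1) - r(+1), so larger
#' scores are more cluster-like; at an exact residual tie the sample is
#' assigned to class +1 (favouring sensitivity in a screening context) with
#' score 0.
#'
#' @param vocab a normalized \linkS4class{Vocabulary} containing both classes.
#' @param y raw patch/feature vector (pre-transform space).
#' @param transform \linkS4class{FeatureTransform} or NULL for identity.
#' @param settings \linkS4class{SolverSettings}.
#' @param gram optional precomputed vocabulary Gram matrix.
#' @return an \linkS4class{SRCResult}. Solver non-convergence is attached as
#'   a warning, never hidden.
#' @export
classifySRC <- function(vocab, y, transform = NULL,
                        settings = solverSettings(), gram = NULL) {
  yt <- if (is.null(transform)) as.numeric(y) else applyTransform(transform, y)
  ny <- sqrt(sum(yt^2))
  if (ny == 0) stop("test vector is identically zero")
  yt <- yt / ny
  code <- solveL1LS(vocab, yt, settings, gram = gram)
  if (!code@converged)
    warning("sparse-coding solver did not reach the gap tolerance; ",
            "classifying with the returned (flagged) code")
  labels <- atomLabels(vocab)
  rPos <- srcResidual(vocab, yt, classRestrictedCode(code, labels, 1))
  rNeg <- srcResidual(vocab, yt, classRestrictedCode(code, labels, -1))
  predicted <- if (rPos <= rNeg) 1 else -1   # tie -> +1
  new("SRCResult", residuals = c("+1" = rPos, "-1" = rNeg),
      predicted = predicted, score = rNeg - rPos, code = code)
}

setMethod("show", "SRCResult", function(object) {
  cat(sprintf("SRCResult: predicted %+d (score %.4g; r+1 = %.4g, r-1 = %.4g)\n",
              object@predicted, object@score,
              object@residuals[["+1"]], object@residuals[["-1"]]))
})

#' Score a batch of patches with SRC
#'
#' Applies \code{\link{classifySRC}} to every column of a patch matrix (or
#' every patch of a \linkS4class{PatchSet}), preserving order. Per-patch
#' failures are recorded in the details and scored NA; the batch continues.
#'
#' @param vocab a normalized \linkS4class{Vocabulary}.
#' @param patches a \linkS4class{PatchSet} or a matrix with one raw patch
#'   vector per column.
#' @param transform \linkS4class{FeatureTransform} or NULL.
#' @param settings \linkS4class{SolverSettings}.
#' @param labels true labels per patch; taken from the PatchSet when present.
#' @param source provenance string for the result.
#' @return a \linkS4class{ScoredPredictions}; \code{predDetails()} exposes
#'   per-patch residuals, predictions and convergence flags.
#' @export
srcScoreBatch <- function(vocab, patches, transform = NULL,
                          settings = solverSettings(), labels = NULL,
                          source = "src") {
  if (is(patches, "PatchSet")) {
    if (is.null(labels)) labels <- patchLabels(patches)
    patches <- patchMatrix(patches)
  }
  patches <- as.matrix(patches)
  n <- ncol(patches)
  if (n == 0) stop("empty patch set")
  gram <- crossprod(atomMatrix(vocab))
  score <- pred <- rPos <- rNeg <- rep(NA_real_, n)
  conv <- rep(NA, n)
  err <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      withCallingHandlers(
        classifySRC(vocab, patches[, i], transform, settings, gram = gram),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(res, "error")) {
      err[i] <- conditionMessage(res)
    } else {
      score[i] <- res@score; pred[i] <- res@predicted
      rPos[i] <- res@residuals[["+1"]]; rNeg[i] <- res@residuals[["-1"]]
      conv[i] <- res@code@converged
    }
  }
  nfail <- sum(nzchar(err))
  if (nfail > 0)
    warning(nfail, " patch(es) failed to score; see predDetails()$error")
  if (is.null(labels)) labels <- rep(NA_real_, n)
  details <- data.frame(score = score, predicted = pred, rPos = rPos,
                        rNeg = rNeg, converged = conv, error = err,
                        stringsAsFactors = FALSE)
  ok <- !is.na(score)
  new("ScoredPredictions", scores = score[ok], labels = as.numeric(labels)[ok],
      source = source, details = details)
}
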