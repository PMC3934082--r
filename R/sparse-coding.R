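# Vocabulary construction, feature transforms and the l1-regularized
# least-squares solver used for sparse coding of test patches.

#' Normalize matrix columns to unit Euclidean length
#'
#' @param x numeric matrix with no all-zero column.
#' @return list with \code{matrix} (unit-norm columns) and \code{scales}
#'   (original norms; \code{matrix \%*\% diag(scales)} restores the input).
#' @examples
#' normalizeColumns(cbind(c(3, 4)))
#' @export
normalizeColumns <- function(x) {
  x <- as.matrix(x)
  norms <- sqrt(colSums(x^2))
  bad <- which(norms == 0)
  if (length(bad))
    stop("zero column(s) at index ", paste(bad, collapse = ", "),
         ": cannot normalize")
  list(matrix = sweep(x, 2, norms, "/"), scales = norms)
}

#' Construct a vocabulary from labelled training columns
#'
#' @param columns d x n numeric matrix, one training sample per column.
#' @param labels +1/-1 per column; both classes must be present.
#' @param normalize normalize columns to unit length (default TRUE; the
#'   sparse-coding contract requires a normalized vocabulary).
#' @param transformId provenance tag of the feature transform applied.
#' @return a \linkS4class{Vocabulary}.
#' @export
Vocabulary <- function(columns, labels, normalize = TRUE,
                       transformId = "identity") {
  columns <- as.matrix(columns)
  labels <- as.numeric(labels)
  if (normalize) {
    nc <- normalizeColumns(columns)
    new("Vocabulary", columns = nc$matrix, labels = labels,
        scales = nc$scales, normalized = TRUE, transformId = transformId)
  } else {
    new("Vocabulary", columns = columns, labels = labels,
        scales = rep(1, ncol(columns)), normalized = FALSE,
        transformId = transformId)
  }
}

#' @describeIn Vocabulary the column matrix.
#' @param object,x a \code{Vocabulary}.
#' @export
atomMatrix <- function(x) x@columns

#' @describeIn Vocabulary the per-column class labels.
#' @export
atomLabels <- function(x) x@labels

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d features x %d atoms (%d pos / %d neg), %s, transform '%s'\n",
              nrow(object@columns), ncol(object@columns),
              sum(object@labels == 1), sum(object@labels == -1),
              if (object@normalized) "unit-norm" else "raw",
              object@transformId))
})

# --- feature transforms ----------------------------------------------------

#' Feature transforms for patch vectors
#'
#' Linear maps applied to raw patch vectors before sparse coding:
#' \code{identityTransform} passes vectors through; \code{downsampleTransform}
#' averages consecutive blocks of a 1-D vector; \code{patchDownsampleTransform}
#' block-averages a row-major vectorized m x m patch by an integer factor
#' (output side m / factor); \code{randomProjectionTransform} draws a
#' Gaussian projection with entries N(0, 1/outDim).
#'
#' @param n,inDim input vector length.
#' @param m patch side in pixels.
#' @param factor integer downsampling factor dividing the input length/side.
#' @param outDim number of output features.
#' @param seed integer seed making the projection reproducible.
#' @return a \linkS4class{FeatureTransform}.
#' @name transforms
NULL

#' @rdname transforms
#' @export
identityTransform <- function(n) {
  new("FeatureTransform", matrix = diag(n), kind = "identity")
}

#' @rdname transforms
#' @export
downsampleTransform <- function(n, factor) {
  if (n %% factor != 0)
    stop("factor ", factor, " does not divide input length ", n)
  nOut <- n %/% factor
  mat <- matrix(0, nOut, n)
  for (i in seq_len(nOut))
    mat[i, ((i - 1) * factor + 1):(i * factor)] <- 1 / factor
  new("FeatureTransform", matrix = mat, kind = "downsample")
}

#' @rdname transforms
#' @export
patchDownsampleTransform <- function(m, factor) {
  if (m %% factor != 0)
    stop("factor ", factor, " does not divide patch side ", m)
  mOut <- m %/% factor
  mat <- matrix(0, mOut^2, m^2)
  for (br in seq_len(mOut)) for (bc in seq_len(mOut)) {
    out <- (br - 1) * mOut + bc
    rows <- ((br - 1) * factor + 1):(br * factor)
    cols <- ((bc - 1) * factor + 1):(bc * factor)
    # row-major vectorization: pixel (r, c) of the patch sits at (r-1)*m + c
    idx <- as.vector(outer((rows - 1) * m, cols, "+"))
    mat[out, idx] <- 1 / factor^2
  }
  new("FeatureTransform", matrix = mat, kind = "downsample")
}

#' @rdname transforms
#' @export
randomProjectionTransform <- function(outDim, inDim, seed = 1L) {
  mat <- withSeed(seed, matrix(rnorm(outDim * inDim, sd = 1 / sqrt(outDim)),
                               outDim, inDim))
  new("FeatureTransform", matrix = mat, kind = "random_projection")
}

#' @rdname transforms
#' @export
centeringTransform <- function(n) {
  new("FeatureTransform", matrix = diag(n) - matrix(1 / n, n, n),
      kind = "centering")
}

#' Compose two feature transforms
#'
#' Returns the transform applying \code{inner} first, then \code{outer}
#' (matrix product). Used to build the pipeline's default feature map,
#' mean removal after block-mean downsampling: without mean removal the
#' base intensity level dominates every unit-normalized patch and sparse
#' codes carry no class information.
#'
#' @param outer,inner \linkS4class{FeatureTransform}s with conforming
#'   dimensions.
#' @return a \linkS4class{FeatureTransform} of kind "composite".
#' @export
composeTransforms <- function(outer, inner) {
  if (ncol(outer@matrix) != nrow(inner@matrix))
    stop(sprintf("cannot compose: outer expects %d inputs, inner yields %d",
                 ncol(outer@matrix), nrow(inner@matrix)))
  new("FeatureTransform", matrix = outer@matrix %*% inner@matrix,
      kind = "composite")
}

#' Default patch feature map: block-mean downsample then mean removal
#'
#' @param m patch side in pixels.
#' @param factor integer block side dividing m.
#' @param center remove the feature mean (default TRUE).
#' @return a \linkS4class{FeatureTransform}.
#' @export
patchFeatureTransform <- function(m, factor, center = TRUE) {
  ds <- patchDownsampleTransform(m, factor)
  if (!center) return(ds)
  composeTransforms(centeringTransform((m %/% factor)^2), ds)
}

#' Apply a feature transform
#'
#' @param transform a \linkS4class{FeatureTransform}.
#' @param x numeric vector, or a matrix with one sample per column.
#' @return the transformed vector/matrix D x (identity returns x unchanged).
#' @export
applyTransform <- function(transform, x) {
  d <- ncol(transform@matrix)
  if (is.matrix(x)) {
    if (nrow(x) != d)
      stop(sprintf("transform expects %d rows, input has %d", d, nrow(x)))
    if (transform@kind == "identity") return(x)
    return(transform@matrix %*% x)
  }
  if (length(x) != d)
    stop(sprintf("transform expects length %d, input has length %d",
                 d, length(x)))
  if (transform@kind == "identity") return(as.numeric(x))
  as.numeric(transform@matrix %*% x)
}

# --- solver ----------------------------------------------------------------

#' Solver settings
#'
#' @param lambda regularization weight of the l1 penalty (> 0).
#' @param gapTol relative duality-gap tolerance: the solver stops when
#'   gap <= gapTol * (1 + |objective|).
#' @param maxIter cap on coordinate-descent sweeps.
#' @param ridge tiny diagonal stabilizer for inner linear systems.
#' @return a \linkS4class{SolverSettings}.
#' @export
solverSettings <- function(lambda = 0.01, gapTol = 1e-4, maxIter = 500L,
                           ridge = 1e-10) {
  new("SolverSettings", lambda = lambda, gapTol = gapTol,
      maxIter = as.integer(maxIter), ridge = ridge)
}

#' l1-regularized least-squares objective
#'
#' Evaluates \eqn{\|Ac - y\|_2^2 + \lambda \|c\|_1} as a pure function.
#'
#' @param vocab a \linkS4class{Vocabulary} (or a plain matrix A).
#' @param y observation vector.
#' @param coefficients code vector c.
#' @param lambda penalty weight.
#' @export
l1Objective <- function(vocab, y, coefficients, lambda) {
  A <- if (is(vocab, "Vocabulary")) vocab@columns else as.matrix(vocab)
  if (length(y) != nrow(A)) stop("y length must match nrow(A)")
  if (length(coefficients) != ncol(A))
    stop("coefficient length must match ncol(A)")
  r <- as.numeric(A %*% coefficients) - y
  sum(r^2) + lambda * sum(abs(coefficients))
}

#' Solve the l1-regularized least-squares problem
#'
#' Minimizes \eqn{\|Ac - y\|_2^2 + \lambda \|c\|_1} by cyclic coordinate
#' descent on the Gram formulation, certifying optimality with the duality
#' gap at the scaled dual feasible point \eqn{\nu = 2 s (Ac - y)},
#' \eqn{s = \min(1, \lambda / \|2 A^T (Ac-y)\|_\infty)}. The path is fully
#' deterministic for fixed inputs.
#'
#' @param vocab a normalized \linkS4class{Vocabulary}.
#' @param y feature vector, unit-normalized (the classification pipeline
#'   normalizes the test vector before solving).
#' @param settings a \linkS4class{SolverSettings}.
#' @param gram optional precomputed crossprod(atomMatrix(vocab)); supply it
#'   when coding many vectors against one vocabulary.
#' @return a \linkS4class{SparseCode}. When the gap tolerance is not reached
#'   within \code{maxIter} sweeps the result is flagged
#'   \code{converged = FALSE}, never silently returned as converged.
#' @export
solveL1LS <- function(vocab, y, settings = solverSettings(), gram = NULL) {
  stopifnot(is(vocab, "Vocabulary"), is(settings, "SolverSettings"))
  if (!vocab@normalized) stop("vocabulary must be normalized before solving")
  A <- vocab@columns
  if (length(y) != nrow(A))
    stop(sprintf("y has length %d, vocabulary has %d features",
                 length(y), nrow(A)))
  if (any(!is.finite(y)) || any(!is.finite(A)))
    stop("NaN/Inf in solver inputs")
  if (is.null(gram)) gram <- crossprod(A)
  Aty <- as.numeric(crossprod(A, y))
  yty <- sum(y^2)
  fit <- .cd_lasso_gram(gram, Aty, yty, settings@lambda, settings@gapTol,
                        settings@maxIter)
  coef <- as.numeric(fit$coefficients)
  gap <- max(0, fit$gap)
  converged <- isTRUE(fit$converged)
  # active-set refinement: solve the KKT system on the support exactly;
  # removes the slow tail of coordinate descent on correlated dictionaries
  pol <- .polishLasso(gram, Aty, yty, settings@lambda, coef, settings@ridge)
  if (!is.null(pol)) {
    coef <- pol$coefficients
    gap <- pol$gap
    converged <- converged || gap <= settings@gapTol * (1 + abs(pol$objective))
  }
  obj <- l1Objective(vocab, y, coef, settings@lambda) # recomputed directly
  new("SparseCode", coefficients = coef, lambda = settings@lambda,
      objective = obj, dualityGap = gap,
      iterations = as.integer(fit$iterations),
      converged = converged)
}

# Duality gap at c from the Gram quantities (same certificate as the C++
# solver: scaled dual feasible point nu = 2 s (Ac - y)).
.lassoGap <- function(gram, Aty, yty, lambda, coef) {
  q <- as.numeric(gram %*% coef)
  rsq <- max(0, sum(coef * q) - 2 * sum(coef * Aty) + yty)
  obj <- rsq + lambda * sum(abs(coef))
  maxAtr <- max(abs(q - Aty))
  s <- if (2 * maxAtr > lambda && maxAtr > 0) lambda / (2 * maxAtr) else 1
  dual <- -s^2 * rsq - 2 * s * (sum(coef * Aty) - yty)
  list(objective = obj, gap = max(0, obj - dual))
}

# Exact minimization over the sign orthant of the current support, with a
# null-space walk for rank-deficient dictionaries (near-duplicate atoms):
# within the orthant the objective is smooth, so the minimizer solves
# G_SS c_S = Aty_S - (lambda/2) s on the range of G_SS; any null component
# of s gives a linear descent direction along which a coordinate must hit
# zero and leave the support. The outer loop re-admits coordinates whose
# gradient violates the l1 subgradient bound. Objective-guarded: returns
# NULL unless it actually improves on the coordinate-descent point.
.polishLasso <- function(gram, Aty, yty, lambda, coef, ridge) {
  base <- .lassoGap(gram, Aty, yty, lambda, coef)
  best <- NULL
  S <- which(coef != 0)
  if (!length(S)) return(NULL)
  for (round in seq_len(50 + 2 * length(coef))) {
    if (!length(S)) break
    s <- sign(coef[S])
    eg <- eigen(gram[S, S, drop = FALSE], symmetric = TRUE)
    tol <- max(eg$values[1], 0) * 1e-10 + 1e-300
    rng <- eg$values > tol
    V0 <- eg$vectors[, !rng, drop = FALSE]
    sNull <- as.numeric(crossprod(V0, s))
    if (any(abs(sNull) > 1e-10)) {
      # linear descent along the null space: walk until a coordinate exits
      v <- -as.numeric(V0 %*% sNull)
      cs <- coef[S]
      leaving <- which(v * sign(cs) < 0 & cs != 0)
      if (!length(leaving)) break
      tHit <- -cs[leaving] / v[leaving]
      tStar <- min(tHit)
      cs <- cs + tStar * v
      drop <- leaving[tHit <= tStar * (1 + 1e-12)]
      cs[drop] <- 0
      coef[S] <- cs
      S <- S[coef[S] != 0]
      next
    }
    V1 <- eg$vectors[, rng, drop = FALSE]
    b <- Aty[S] - lambda / 2 * s
    sol <- as.numeric(V1 %*% (crossprod(V1, b) / eg$values[rng]))
    flip <- sign(sol) * s < 0
    if (any(flip)) {               # entries leaving the active set
      coef[S[flip]] <- 0
      S <- S[!flip]
      next
    }
    cand <- numeric(length(coef))
    cand[S] <- sol
    g <- 2 * (as.numeric(gram %*% cand) - Aty)
    viol <- setdiff(which(abs(g) > lambda * (1 + 1e-12)), S)
    check <- .lassoGap(gram, Aty, yty, lambda, cand)
    if (check$objective <= base$objective + 1e-12 &&
        (is.null(best) || check$objective < best$objective))
      best <- list(coefficients = cand, objective = check$objective,
                   gap = check$gap)
    if (!length(viol)) break
    j <- viol[which.max(abs(g[viol]))]
    coef <- cand
    coef[j] <- -1e-12 * sign(g[j])  # seed the sign for the next round
    S <- sort(c(S, j))
  }
  best
}

setMethod("show", "SparseCode", function(object) {
  cat(sprintf("SparseCode: %d coefficients (%d nonzero), lambda = %g\n",
              length(object@coefficients), sum(object@coefficients != 0),
              object@lambda))
  cat(sprintf("  objective %.6g, duality gap %.3g, %d sweeps, %s\n",
              object@objective, object@dualityGap, object@iterations,
              if (object@converged) "converged" else "NOT converged"))
})

#' @describeIn solveL1LS coefficient accessor.
#' @param code a \code{SparseCode}.
#' @export
codeCoefficients <- function(code) code@coefficients
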