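#' @import methods
#' @importFrom stats rnorm runif sd quantile optim setNames
#' @importFrom utils head modifyList write.csv read.csv
#' @useDynLib mcdetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Sparse coding
# ---------------------------------------------------------------------------

#' Vocabulary of labelled training patches
#'
#' The "dictionary" against which test samples are sparsely coded: a matrix
#' whose columns are (transformed, unit-normalized) vectorized training
#' patches, with a class label in \{+1, -1\} per column (+1 = contains a
#' microcalcification cluster, -1 = normal tissue).
#'
#' @slot columns d x n numeric matrix, one column per training sample.
#' @slot labels numeric vector of +1/-1, one per column.
#' @slot scales Euclidean norms of the original columns (restores them).
#' @slot normalized logical; \code{TRUE} when every column has unit norm.
#' @slot transformId identifier of the feature transform applied ("identity"
#'   when none).
#' @export
setClass("Vocabulary",
  representation(columns = "matrix", labels = "numeric", scales = "numeric",
                 normalized = "logical", transformId = "character"))

setValidity("Vocabulary", function(object) {
  msg <- character()
  d <- nrow(object@columns); n <- ncol(object@columns)
  if (d < 1L || n < 2L)
    msg <- c(msg, "vocabulary must be d >= 1 by n >= 2")
  if (length(object@labels) != n)
    msg <- c(msg, "labels length must equal number of columns")
  if (!all(object@labels %in% c(-1, 1)))
    msg <- c(msg, "labels must be +1 or -1")
  if (length(unique(object@labels)) < 2L)
    msg <- c(msg, "both classes must be present")
  if (length(object@scales) != n)
    msg <- c(msg, "scales length must equal number of columns")
  if (isTRUE(object@normalized)) {
    norms <- sqrt(colSums(object@columns^2))
    if (any(abs(norms - 1) > 1e-9))
      msg <- c(msg, "normalized vocabulary must have unit-norm columns")
  }
  if (length(msg)) msg else TRUE
})

#' Linear feature transform
#'
#' A linear map applied to raw patch vectors before sparse coding: identity,
#' block-mean downsampling, or a Gaussian random projection.
#'
#' @slot matrix numeric d x m matrix implementing the map.
#' @slot kind one of "identity", "random_projection", "downsample".
#' @export
setClass("FeatureTransform",
  representation(matrix = "matrix", kind = "character"))

setValidity("FeatureTransform", function(object) {
  msg <- character()
  kinds <- c("identity", "random_projection", "downsample", "centering",
             "composite")
  if (!object@kind %in% kinds)
    msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (object@kind == "identity" && nrow(object@matrix) != ncol(object@matrix))
    msg <- c(msg, "identity transform must be square")
  if (object@kind == "random_projection") {
    if (qr(object@matrix)$rank < nrow(object@matrix))
      msg <- c(msg, "random projection must have full row rank")
  }
  if (length(msg)) msg else TRUE
})

#' Sparse code of a test sample
#'
#' Solution of the l1-regularized least-squares problem
#' \eqn{\min_c \|Ac - y\|_2^2 + \lambda \|c\|_1} together with its optimality
#' certificate (duality gap) and solver metadata.
#'
#' @slot coefficients numeric vector c, one entry per vocabulary column.
#' @slot lambda the regularization weight used.
#' @slot objective value of the objective at \code{coefficients}.
#' @slot dualityGap nonnegative duality gap at the returned point.
#' @slot iterations coordinate-descent sweeps performed.
#' @slot converged logical; gap within tolerance.
#' @export
setClass("SparseCode",
  representation(coefficients = "numeric", lambda = "numeric",
                 objective = "numeric", dualityGap = "numeric",
                 iterations = "integer", converged = "logical"))

setValidity("SparseCode", function(object) {
  msg <- character()
  if (object@lambda <= 0) msg <- c(msg, "lambda must be positive")
  if (object@dualityGap < 0) msg <- c(msg, "duality gap must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Solver settings for the l1-regularized least-squares solver
#'
#' @slot lambda regularization weight (> 0).
#' @slot gapTol relative duality-gap tolerance.
#' @slot maxIter sweep cap.
#' @slot ridge tiny diagonal stabilizer for inner linear systems.
#' @export
setClass("SolverSettings",
  representation(lambda = "numeric", gapTol = "numeric",
                 maxIter = "integer", ridge = "numeric"))

setValidity("SolverSettings", function(object) {
  ok <- object@lambda > 0 && object@gapTol > 0 && object@maxIter > 0 &&
    object@ridge > 0
  if (ok) TRUE else "all solver settings must be positive"
})

# ---------------------------------------------------------------------------
# SRC
# ---------------------------------------------------------------------------

#' Result of sparse-representation classification of one sample
#'
#' @slot residuals named numeric: class-restricted reconstruction residual
#'   for classes "+1" and "-1".
#' @slot predicted +1 or -1, the argmin-residual class.
#' @slot score continuous MC-ness score r(-1) - r(+1): larger means more
#'   cluster-like.
#' @slot code the \linkS4class{SparseCode} used.
#' @export
setClass("SRCResult",
  representation(residuals = "numeric", predicted = "numeric",
                 score = "numeric", code = "SparseCode"))

setValidity("SRCResult", function(object) {
  msg <- character()
  if (!all(c("+1", "-1") %in% names(object@residuals)))
    msg <- c(msg, "residuals must be named '+1' and '-1'")
  if (any(object@residuals < 0)) msg <- c(msg, "residuals must be nonnegative")
  if (!object@predicted %in% c(-1, 1)) msg <- c(msg, "predicted must be +1/-1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# TWSVM
# ---------------------------------------------------------------------------

#' Kernel specification for twin support vector machines
#'
#' @slot kind "linear" or "rbf".
#' @slot sigma RBF width (used iff kind == "rbf");
#'   \eqn{K(x,z) = \exp(-\|x-z\|^2 / (2\sigma^2))}.
#' @export
setClass("KernelSpec", representation(kind = "character", sigma = "numeric"))

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("linear", "rbf"))
    msg <- c(msg, "kind must be linear or rbf")
  if (object@kind == "rbf" && (length(object@sigma) != 1L || object@sigma <= 0))
    msg <- c(msg, "sigma must be a positive scalar for the rbf kernel")
  if (length(msg)) msg else TRUE
})

#' Twin SVM training problem
#'
#' @slot A matrix of class +1 patterns, one row per pattern.
#' @slot B matrix of class -1 patterns, one row per pattern.
#' @slot c1,c2 positive box parameters of the two dual QPs.
#' @slot kernel a \linkS4class{KernelSpec}.
#' @slot ridge relative diagonal stabilizer for the Gram inverses
#'   (scaled by the mean diagonal of the matrix being inverted).
#' @export
setClass("TWSVMProblem",
  representation(A = "matrix", B = "matrix", c1 = "numeric", c2 = "numeric",
                 kernel = "KernelSpec", ridge = "numeric"))

setValidity("TWSVMProblem", function(object) {
  msg <- character()
  if (nrow(object@A) < 1L || nrow(object@B) < 1L)
    msg <- c(msg, "both classes must be nonempty")
  if (ncol(object@A) != ncol(object@B))
    msg <- c(msg, "A and B must have the same number of feature columns")
  if (object@c1 <= 0 || object@c2 <= 0) msg <- c(msg, "c1, c2 must be positive")
  if (object@ridge <= 0) msg <- c(msg, "ridge must be positive")
  if (length(msg)) msg else TRUE
})

#' Trained twin support vector machine
#'
#' Two nonparallel separating surfaces, each close to one class and at
#' unit-margin distance from the other. In kernel mode the augmented weight
#' vectors u, v weight kernel columns against the stacked reference matrix
#' C = rbind(A, B).
#'
#' @slot u augmented vector c(w1, b1) for the class +1 plane.
#' @slot v augmented vector c(w2, b2) for the class -1 plane.
#' @slot kernel the \linkS4class{KernelSpec} used.
#' @slot reference training patterns retained for kernel evaluation
#'   (zero-row matrix in linear mode).
#' @slot wnorm lengths ||w1||, ||w2|| in the (kernel) feature space, used for
#'   the normalized plane distances.
#' @slot dual list with dual vectors alpha, gamma, objectives and solver
#'   status for both dual QPs.
#' @slot dim raw feature dimension the model expects.
#' @export
setClass("TWSVMModel",
  representation(u = "numeric", v = "numeric", kernel = "KernelSpec",
                 reference = "matrix", wnorm = "numeric", dual = "list",
                 dim = "integer"))

# ---------------------------------------------------------------------------
# Images, patches, truth
# ---------------------------------------------------------------------------

#' A mammogram-like intensity image
#'
#' @slot pixels numeric matrix of nonnegative intensities (rows = image rows).
#' @slot pitchUm physical pixel pitch in micrometres (default 43.5).
#' @slot bitDepth 8, 12 or 16; intensities live in [0, 2^bitDepth - 1].
#' @export
setClass("MammogramImage",
  representation(pixels = "matrix", pitchUm = "numeric", bitDepth = "integer"))

setValidity("MammogramImage", function(object) {
  msg <- character()
  if (!object@bitDepth %in% c(8L, 12L, 16L))
    msg <- c(msg, "bitDepth must be 8, 12 or 16")
  if (object@pitchUm <= 0) msg <- c(msg, "pixel pitch must be positive")
  mx <- 2^object@bitDepth - 1
  if (any(object@pixels < 0) || any(object@pixels > mx))
    msg <- c(msg, sprintf("intensities must lie in [0, %d]", mx))
  if (length(msg)) msg else TRUE
})

#' Set of vectorized image patches
#'
#' Extends \linkS4class{SummarizedExperiment}: the "pixels" assay holds one
#' column per patch (length m^2, row-major vectorization of the m x m
#' window); \code{colData} carries the 0-based top-left window coordinates
#' and, when labelled, the +1/-1 class. \code{metadata(x)$m} stores the
#' window side.
#'
#' @import SummarizedExperiment
#' @export
setClass("PatchSet", contains = "SummarizedExperiment")

setValidity("PatchSet", function(object) {
  msg <- character()
  if (!"pixels" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "PatchSet needs a 'pixels' assay")
  m <- S4Vectors::metadata(object)$m
  if (is.null(m))
    msg <- c(msg, "metadata(x)$m (window side) is required")
  else if (nrow(object) != m * m)
    msg <- c(msg, "assay rows must equal m^2")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("row", "col") %in% colnames(cd)))
    msg <- c(msg, "colData needs 'row' and 'col' (0-based top-left)")
  if ("label" %in% colnames(cd) && !all(cd$label %in% c(-1, 1)))
    msg <- c(msg, "labels must be +1/-1")
  if (length(msg)) msg else TRUE
})

#' Ground-truth spot annotations for one image
#'
#' @slot centers integer matrix with columns row, col (0-based pixel
#'   coordinates of spot centers).
#' @slot diametersMm spot diameters in millimetres.
#' @slot clusterBox numeric c(row0, col0, row1, col1) bounding box of the
#'   cluster (0-based, half-open), or length-0 when no cluster.
#' @export
setClass("GroundTruth",
  representation(centers = "matrix", diametersMm = "numeric",
                 clusterBox = "numeric"))

setValidity("GroundTruth", function(object) {
  if (nrow(object@centers) != length(object@diametersMm))
    "one diameter per spot center" else TRUE
})

#' Phantom generation settings
#'
#' Describes the DDSM-like synthetic images: a textured, slowly varying
#' background plus Gaussian-profile bright spots gathered in sub-5 mm
#' clusters.
#'
#' @slot imageSizePx side of the (square) generated image, pixels.
#' @slot pitchUm pixel pitch in micrometres.
#' @slot bitDepth container bit depth (12-bit data in 16-bit files).
#' @slot background list(base, corrLenPx, textureAmp, gradientAmp): base
#'   intensity level, texture correlation length in px, texture standard
#'   deviation and peak-to-peak amplitude of the planar gradient, all in
#'   intensity units.
#' @slot spots list(diameterRangeMm, peakContrast): spot diameter range in mm
#'   and peak amplitude expressed as a multiple of the background texture
#'   standard deviation.
#' @slot cluster list(minSpots, maxSpots, extentMm): number of spots drawn
#'   uniformly in [minSpots, maxSpots] and the side of the square cluster
#'   box in mm.
#' @export
setClass("PhantomSpec",
  representation(imageSizePx = "integer", pitchUm = "numeric",
                 bitDepth = "integer", background = "list", spots = "list",
                 cluster = "list"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  b <- object@background; s <- object@spots; cl <- object@cluster
  need <- function(l, keys, nm)
    if (!all(keys %in% names(l))) sprintf("%s needs fields %s", nm,
                                          paste(keys, collapse = ", "))
  msg <- c(msg, need(b, c("base", "corrLenPx", "textureAmp", "gradientAmp"),
                     "background"))
  msg <- c(msg, need(s, c("diameterRangeMm", "peakContrast"), "spots"))
  msg <- c(msg, need(cl, c("minSpots", "maxSpots", "extentMm"), "cluster"))
  msg <- msg[!vapply(msg, is.null, TRUE)]
  if (length(msg)) return(unlist(msg))
  if (any(s$diameterRangeMm < 0.05) || any(s$diameterRangeMm > 2))
    msg <- c(msg, "spot diameters must lie within [0.05, 2] mm")
  if (cl$minSpots < 1) msg <- c(msg, "at least one spot per cluster")
  if (b$textureAmp < 0 || b$gradientAmp < 0 || s$peakContrast < 0)
    msg <- c(msg, "amplitudes must be nonnegative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Evaluation
# ---------------------------------------------------------------------------

#' Scores with true labels, ready for ROC analysis
#'
#' @slot scores numeric classifier scores (larger = more class +1).
#' @slot labels true labels, +1/-1.
#' @slot source provenance string.
#' @slot details per-sample data.frame of extras (residuals, convergence...).
#' @export
setClass("ScoredPredictions",
  representation(scores = "numeric", labels = "numeric", source = "character",
                 details = "data.frame"))

setValidity("ScoredPredictions", function(object) {
  msg <- character()
  if (length(object@scores) != length(object@labels))
    msg <- c(msg, "scores and labels must have equal length")
  if (!all(object@labels %in% c(-1, 1) | is.na(object@labels)))
    msg <- c(msg, "labels must be +1/-1 (or NA when unknown)")
  if (length(msg)) msg else TRUE
})

#' ROC curve with trapezoidal area
#'
#' @slot thresholds descending score thresholds (ties grouped).
#' @slot tpr sensitivity at each threshold.
#' @slot fpr 1 - specificity at each threshold.
#' @slot az trapezoidal area under the curve.
#' @export
setClass("ROCCurve",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 az = "numeric"))

setValidity("ROCCurve", function(object) {
  msg <- character()
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    msg <- c(msg, "tpr and fpr must be non-decreasing along the sweep")
  if (object@az < 0 || object@az > 1) msg <- c(msg, "az must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Stability-experiment report
#'
#' @slot perRepeat data.frame with one row per (fraction, repeat):
#'   sensitivity, specificity, az.
#' @slot summary data.frame of per-fraction means and standard deviations.
#' @slot config list snapshot of the experiment configuration.
#' @slot seeds integer vector of per-repeat seeds.
#' @slot failures number of repeats excluded after method failure.
#' @export
setClass("EvalReport",
  representation(perRepeat = "data.frame", summary = "data.frame",
                 config = "list", seeds = "integer", failures = "integer"))
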