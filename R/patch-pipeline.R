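# Images -> labelled patch datasets: preprocessing (clip, background
# flattening, contrast rescale), sliding-window extraction, cluster-rule
# labelling and vocabulary assembly.
#
# Conventions, used everywhere: pixel coordinates are 0-based; windows are
# half-open [r, r+m) x [c, c+m); patch vectorization is row-major. With the
# default 43.5 um pitch an m = 115 window spans 5.0025 mm, the ~5 mm scale of
# the clinical cluster rule (>= 3 spots per 5 mm x 5 mm).

#' Construct a mammogram-like image
#'
#' @param pixels numeric matrix of intensities.
#' @param pitchUm pixel pitch in micrometres (default 43.5).
#' @param bitDepth 8, 12 or 16 (default 12).
#' @return a \linkS4class{MammogramImage}.
#' @export
MammogramImage <- function(pixels, pitchUm = 43.5, bitDepth = 12L) {
  new("MammogramImage", pixels = as.matrix(pixels), pitchUm = pitchUm,
      bitDepth = as.integer(bitDepth))
}

#' @describeIn MammogramImage pixel matrix accessor.
#' @param x a \code{MammogramImage}.
#' @export
imagePixels <- function(x) x@pixels

setMethod("show", "MammogramImage", function(object) {
  cat(sprintf("MammogramImage: %d x %d px, %g um/px, %d-bit, range [%g, %g]\n",
              nrow(object@pixels), ncol(object@pixels), object@pitchUm,
              object@bitDepth, min(object@pixels), max(object@pixels)))
})

#' Separable moving-average (box) filter with edge renormalization
#' @noRd
.boxSmooth <- function(x, window) {
  half <- window %/% 2
  run1d <- function(m) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  t(run1d(t(run1d(x))))
}

#' Preprocess a mammogram-like image
#'
#' Applies, in order: (1) clipping to the valid intensity range, (2)
#' background flattening -- subtract a large-window moving-average background
#' estimate (window at least 4 times the analysis window m, so the ~5 mm
#' structures of interest survive) and re-centre on the background mean --
#' and (3) linear contrast rescaling to [0, 2^bitDepth - 1]. Each stage can
#' be toggled; with all stages off the image passes through unchanged. Fully
#' deterministic.
#'
#' @param image a \linkS4class{MammogramImage}.
#' @param clip,flatten,rescale stage toggles.
#' @param flattenWindow background-estimate window in px (default 4 * m with
#'   m = 115); must not exceed either image dimension.
#' @param m analysis window side used to derive the default flatten window.
#' @return a preprocessed \linkS4class{MammogramImage}.
#' @export
preprocessImage <- function(image, clip = TRUE, flatten = TRUE,
                            rescale = TRUE, flattenWindow = NULL, m = 115L) {
  px <- image@pixels
  mx <- 2^image@bitDepth - 1
  if (clip) px <- pmin(pmax(px, 0), mx)
  if (flatten) {
    if (is.null(flattenWindow)) flattenWindow <- 4L * m
    if (flattenWindow > nrow(px) || flattenWindow > ncol(px))
      stop(sprintf("flatten window %d exceeds image size %d x %d",
                   flattenWindow, nrow(px), ncol(px)))
    bg <- .boxSmooth(px, flattenWindow)
    px <- px - bg + mean(bg)
    px <- pmin(pmax(px, 0), mx)
  }
  if (rescale) {
    rng <- range(px)
    if (diff(rng) > 0) px <- (px - rng[1]) / diff(rng) * mx
    else px <- px - rng[1]          # flat field -> all zero detail
  }
  MammogramImage(px, image@pitchUm, image@bitDepth)
}

#' Build a PatchSet
#'
#' @param vectors matrix with one row-major vectorized m x m patch per
#'   column.
#' @param coords integer matrix (n x 2) of 0-based top-left (row, col)
#'   window positions.
#' @param m window side in pixels.
#' @param labels optional +1/-1 per patch.
#' @param sourceId provenance string.
#' @param pitchUm pixel pitch carried along for physical-size bookkeeping.
#' @return a \linkS4class{PatchSet}.
#' @export
PatchSet <- function(vectors, coords, m, labels = NULL, sourceId = "",
                     pitchUm = 43.5) {
  vectors <- as.matrix(vectors)
  coords <- matrix(as.integer(coords), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  cd <- S4Vectors::DataFrame(row = coords[, 1], col = coords[, 2])
  if (!is.null(labels)) cd$label <- as.numeric(labels)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pixels = vectors), colData = cd,
    metadata = list(m = as.integer(m), sourceId = sourceId,
                    pitchUm = pitchUm))
  new("PatchSet", se)
}

#' @describeIn PatchSet patch-vector matrix (one column per patch).
#' @param x a \code{PatchSet}.
#' @export
patchMatrix <- function(x) SummarizedExperiment::assay(x, "pixels")

#' @describeIn PatchSet 0-based top-left window coordinates (n x 2).
#' @export
patchCoords <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  cbind(row = cd$row, col = cd$col)
}

#' @describeIn PatchSet labels, or NULL when unlabelled.
#' @export
patchLabels <- function(x) SummarizedExperiment::colData(x)$label

#' @describeIn PatchSet window side m in pixels.
#' @export
windowSize <- function(x) S4Vectors::metadata(x)$m

#' Extract sliding-window patches
#'
#' Row-major scan over 0-based, half-open windows [r, r+m) x [c, c+m) with
#' the given stride; each window is vectorized row-major. The patch count is
#' floor((H-m)/stride + 1) * floor((W-m)/stride + 1).
#'
#' @param image a \linkS4class{MammogramImage}.
#' @param m window side in pixels (<= both image dimensions).
#' @param stride step between window origins (>= 1; default 1).
#' @return an unlabelled \linkS4class{PatchSet}.
#' @export
extractPatches <- function(image, m, stride = 1L) {
  px <- image@pixels
  H <- nrow(px); W <- ncol(px)
  if (m > H || m > W)
    stop(sprintf("window m = %d exceeds image size %d x %d", m, H, W))
  if (stride < 1) stop("stride must be >= 1")
  rows <- seq(0L, H - m, by = stride)
  cols <- seq(0L, W - m, by = stride)
  coords <- cbind(rep(rows, each = length(cols)),
                  rep(cols, times = length(rows)))
  vectors <- vapply(seq_len(nrow(coords)), function(i) {
    r <- coords[i, 1]; c <- coords[i, 2]
    as.vector(t(px[(r + 1):(r + m), (c + 1):(c + m)]))  # row-major
  }, numeric(m * m))
  PatchSet(matrix(vectors, nrow = m * m), coords, m,
           sourceId = "extractPatches", pitchUm = image@pitchUm)
}

#' Construct ground truth
#'
#' @param centers n x 2 matrix of 0-based (row, col) spot-center pixels.
#' @param diametersMm spot diameters in mm.
#' @param clusterBox optional c(row0, col0, row1, col1) half-open box.
#' @return a \linkS4class{GroundTruth}.
#' @export
GroundTruth <- function(centers, diametersMm, clusterBox = numeric(0)) {
  centers <- matrix(as.numeric(centers), ncol = 2,
                    dimnames = list(NULL, c("row", "col")))
  new("GroundTruth", centers = centers, diametersMm = as.numeric(diametersMm),
      clusterBox = as.numeric(clusterBox))
}

#' Label patches by the cluster rule
#'
#' A patch is labelled +1 iff at least \code{minSpots} ground-truth spot
#' centers fall inside its half-open window (at m = 115 px and 43.5 um/px
#' the window spans about 5 mm, matching the clinical rule of >= 3
#' microcalcifications per 5 mm x 5 mm); otherwise -1.
#'
#' @param patchset a \linkS4class{PatchSet}.
#' @param truth a \linkS4class{GroundTruth} in the same pixel frame.
#' @param minSpots cluster threshold (default 3).
#' @param imageDim optional c(H, W); truth spots outside it are dropped with
#'   a warning.
#' @return numeric vector of +1/-1 labels.
#' @export
labelPatches <- function(patchset, truth, minSpots = 3L, imageDim = NULL) {
  centers <- truth@centers
  if (!is.null(imageDim) && nrow(centers)) {
    outside <- centers[, 1] < 0 | centers[, 1] >= imageDim[1] |
      centers[, 2] < 0 | centers[, 2] >= imageDim[2]
    if (any(outside)) {
      warning(sum(outside), " truth spot(s) outside image bounds; ignored")
      centers <- centers[!outside, , drop = FALSE]
    }
  }
  m <- windowSize(patchset)
  coords <- patchCoords(patchset)
  vapply(seq_len(nrow(coords)), function(i) {
    r <- coords[i, 1]; c <- coords[i, 2]
    inWin <- centers[, 1] >= r & centers[, 1] < r + m &
      centers[, 2] >= c & centers[, 2] < c + m
    if (sum(inWin) >= minSpots) 1 else -1
  }, numeric(1))
}

#' Preprocess every patch of a patch set
#'
#' Runs \code{\link{preprocessImage}} on each patch viewed as its own small
#' image. The default flatten window, about 0.8 of the window side (~4 mm
#' at DDSM geometry for m = 115), is several times the largest spot diameter,
#' so spot contrast survives while the base level, gradient and coarse
#' background structure are removed. Rescaling is off by default so
#' relative contrast across patches is preserved for the downstream
#' normalization.
#'
#' @param patchset a \linkS4class{PatchSet}.
#' @param clip,flatten,rescale stage toggles (see
#'   \code{\link{preprocessImage}}).
#' @param flattenWindow background window in px; default
#'   \code{2 * floor(0.4 * m) + 1}.
#' @return a \linkS4class{PatchSet} with preprocessed pixel vectors.
#' @export
preprocessPatches <- function(patchset, clip = FALSE, flatten = TRUE,
                              rescale = FALSE, flattenWindow = NULL) {
  m <- windowSize(patchset)
  if (is.null(flattenWindow)) flattenWindow <- 2L * ((m * 2L) %/% 5L) + 1L
  pitch <- S4Vectors::metadata(patchset)$pitchUm
  x <- patchMatrix(patchset)
  if (ncol(x) == 0) return(patchset)
  out <- apply(x, 2, function(v) {
    img <- MammogramImage(matrix(v, m, m, byrow = TRUE), pitch)
    as.vector(t(imagePixels(preprocessImage(
      img, clip = clip, flatten = flatten, rescale = rescale,
      flattenWindow = flattenWindow, m = m))))
  })
  PatchSet(out, patchCoords(patchset), m, labels = patchLabels(patchset),
           sourceId = paste0(S4Vectors::metadata(patchset)$sourceId,
                             "|preprocessed"),
           pitchUm = pitch)
}

#' Deterministic stratified half-split of training indices
#'
#' Alternates samples of each class between the vocabulary half (TRUE) and
#' the classifier half (FALSE). Used by the TWSVMs-SR composition: sparse
#' codes fed to the classifier must be computed against a vocabulary that
#' does not contain the coded samples themselves, otherwise each training
#' sample simply selects itself and the training codes are degenerate.
#'
#' @param labels +1/-1 vector.
#' @return logical vector, TRUE = vocabulary half.
#' @export
vocabularySplit <- function(labels) {
  sel <- logical(length(labels))
  for (cl in unique(labels)) {
    w <- which(labels == cl)
    sel[w[seq_along(w) %% 2 == 1]] <- TRUE
  }
  sel
}

#' Assemble a vocabulary from a labelled patch set
#'
#' Applies the feature transform to every patch vector, optionally
#' subsamples the larger class to balance (seeded, reproducible), and
#' normalizes columns to unit length.
#'
#' @param patchset a labelled \linkS4class{PatchSet} with both classes.
#' @param transform \linkS4class{FeatureTransform} or NULL for identity.
#' @param balance subsample the majority class to the minority size.
#' @param seed seed for the balancing subsample.
#' @return a normalized \linkS4class{Vocabulary}.
#' @export
assembleVocabulary <- function(patchset, transform = NULL, balance = FALSE,
                               seed = 1L) {
  labels <- patchLabels(patchset)
  if (is.null(labels)) stop("patch set must be labelled")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  x <- patchMatrix(patchset)
  if (balance) {
    nMin <- min(table(labels))
    keep <- withSeed(seed, {
      unlist(lapply(c(1, -1), function(cl) {
        idx <- which(labels == cl)
        if (length(idx) > nMin) sort(sample(idx, nMin)) else idx
      }))
    })
    keep <- sort(keep)
    x <- x[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  if (!is.null(transform)) x <- applyTransform(transform, x)
  Vocabulary(x, labels,
             transformId = if (is.null(transform)) "identity"
                           else transform@kind)
}
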