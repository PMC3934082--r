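# DDSM-like phantom generator: textured background + Gaussian-profile bright
# spots gathered in sub-5 mm clusters, with exact ground truth. Also the
# low-dimensional fixtures (independent subspaces, Gaussian clouds) used to
# exercise the classifiers under controlled conditions.

#' Phantom generation settings
#'
#' Defaults emulate a screening-mammogram patch at DDSM geometry: 43.5 um
#' pixel pitch, 12-bit intensities, a mid-grey base with correlated
#' parenchymal texture (correlation length 23 px = 1 mm, the tissue scale:
#' microcalcifications are detectable in real mammograms because they are
#' sharper than tissue structure) and a gentle planar gradient, spots of
#' 0.1-1 mm diameter, and clusters of 3-6 spots inside a 4 mm box (so a
#' cluster always fits the ~5 mm analysis window).
#'
#' @param imageSizePx image side in pixels.
#' @param pitchUm pixel pitch in micrometres.
#' @param bitDepth container bit depth.
#' @param base background base intensity (digital numbers).
#' @param corrLenPx texture correlation length in pixels.
#' @param textureAmp texture standard deviation (digital numbers).
#' @param gradientAmp peak-to-peak amplitude of the planar gradient.
#' @param diameterRangeMm spot diameter range, within [0.05, 2] mm.
#' @param peakContrast spot peak amplitude as a multiple of
#'   \code{textureAmp}.
#' @param minSpots,maxSpots spots per cluster, drawn uniformly.
#' @param extentMm side of the square cluster box in mm (<= 5 so the cluster
#'   fits one analysis window).
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(imageSizePx = 115L, pitchUm = 43.5, bitDepth = 12L,
                        base = 1200, corrLenPx = 23, textureAmp = 60,
                        gradientAmp = 120, diameterRangeMm = c(0.1, 1.0),
                        peakContrast = 8, minSpots = 3L, maxSpots = 6L,
                        extentMm = 4) {
  new("PhantomSpec", imageSizePx = as.integer(imageSizePx), pitchUm = pitchUm,
      bitDepth = as.integer(bitDepth),
      background = list(base = base, corrLenPx = corrLenPx,
                        textureAmp = textureAmp, gradientAmp = gradientAmp),
      spots = list(diameterRangeMm = diameterRangeMm,
                   peakContrast = peakContrast),
      cluster = list(minSpots = as.integer(minSpots),
                     maxSpots = as.integer(maxSpots), extentMm = extentMm))
}

setMethod("show", "PhantomSpec", function(object) {
  b <- object@background; s <- object@spots; cl <- object@cluster
  cat(sprintf("PhantomSpec: %d px @ %g um (%d-bit)\n", object@imageSizePx,
              object@pitchUm, object@bitDepth))
  cat(sprintf("  background: base %g, texture sd %g (corr %g px), gradient %g\n",
              b$base, b$textureAmp, b$corrLenPx, b$gradientAmp))
  cat(sprintf("  spots: %g-%g mm, peak %gx texture sd; cluster %d-%d spots in %g mm\n",
              s$diameterRangeMm[1], s$diameterRangeMm[2], s$peakContrast,
              cl$minSpots, cl$maxSpots, cl$extentMm))
})

#' Separable Gaussian blur via banded row/column operators (edge-renormalized)
#' @noRd
.gaussSmooth <- function(x, sigma) {
  band <- function(n) {
    half <- max(1L, ceiling(3 * sigma))
    k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1, i - half):pmin(n, i + half)
      w <- k[j - i + half + 1]
      M[i, j] <- w / sum(w)
    }
    M
  }
  Kr <- band(nrow(x)); Kc <- band(ncol(x))
  Kr %*% x %*% t(Kc)
}

#' Generate a textured phantom background
#'
#' Base level plus Gaussian-smoothed white noise (smoothing length =
#' configured correlation length, then rescaled so the texture standard
#' deviation equals \code{textureAmp} exactly) plus a random planar gradient
#' of the configured peak-to-peak amplitude. Bit-identical for equal
#' (spec, seed).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer seed.
#' @return a \linkS4class{MammogramImage}.
#' @export
generateBackground <- function(spec, seed = 1L) {
  n <- spec@imageSizePx
  b <- spec@background
  px <- withSeed(seed, {
    out <- matrix(b$base, n, n)
    if (b$textureAmp > 0) {
      tex <- .gaussSmooth(matrix(rnorm(n * n), n, n), b$corrLenPx)
      out <- out + tex / sd(tex) * b$textureAmp
    }
    if (b$gradientAmp > 0) {
      theta <- runif(1, 0, 2 * pi)
      g <- outer(seq(0, 1, length.out = n) * cos(theta),
                 seq(0, 1, length.out = n) * sin(theta), "+")
      out <- out + (g - mean(g)) * b$gradientAmp
    }
    out
  })
  MammogramImage(pmin(pmax(px, 0), 2^spec@bitDepth - 1), spec@pitchUm,
                 spec@bitDepth)
}

#' Add a microcalcification cluster to an image
#'
#' Draws k spots (k uniform in [minSpots, maxSpots]) at integer pixel
#' positions uniformly inside a square cluster box of the configured extent,
#' centred in the image with jitter up to a quarter of the image side so the
#' cluster is never clipped. Placement is hard-core: candidate positions are
#' rejected while they fall closer than ~2.9 spot sigmas to an accepted
#' spot, so each bump's peak is its own (spots stay individually resolvable,
#' as clinical microcalcifications are). Each spot is an additive
#' Gaussian-profile bump whose FWHM equals its diameter (drawn uniformly in
#' the configured mm range) and whose peak amplitude is
#' \code{peakContrast * textureAmp}. Exact ground truth is recorded (also at
#' zero contrast).
#'
#' @param image a \linkS4class{MammogramImage}.
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer seed.
#' @return list(image, truth).
#' @export
addMCCluster <- function(image, spec, seed = 1L) {
  px <- image@pixels
  n <- nrow(px)
  cl <- spec@cluster; s <- spec@spots; b <- spec@background
  boxPx <- round(cl$extentMm * 1000 / spec@pitchUm)
  if (boxPx > n) stop("cluster box (", boxPx, " px) does not fit the image")
  amp <- s$peakContrast * b$textureAmp
  res <- withSeed(seed, {
    k <- sample(cl$minSpots:cl$maxSpots, 1)
    jitterMax <- max(0, min((n - boxPx) %/% 2, n %/% 4))
    origin <- (n - boxPx) %/% 2 +
      if (jitterMax > 0) sample(seq(-jitterMax, jitterMax), 2, replace = TRUE)
      else c(0L, 0L)
    origin <- pmin(pmax(origin, 0L), n - boxPx)
    # hard-core placement: separation > 2.9 sigma of the widest spot keeps
    # every bump's contribution at other centers below ~1.5% of the peak
    maxSigmaPx <- s$diameterRangeMm[2] * 1000 / spec@pitchUm /
      (2 * sqrt(2 * log(2)))
    sepPx <- 2.9 * maxSigmaPx
    centers <- matrix(0, 0, 2)
    for (i in seq_len(k)) {
      best <- NULL; bestDist <- -Inf
      for (try in seq_len(200)) {
        cand <- origin + c(sample(0:(boxPx - 1), 1), sample(0:(boxPx - 1), 1))
        d <- if (nrow(centers)) min(sqrt(rowSums(sweep(centers, 2, cand)^2)))
             else Inf
        if (d > bestDist) { best <- cand; bestDist <- d }
        if (d >= sepPx) break
      }
      centers <- rbind(centers, best)
    }
    diam <- runif(k, s$diameterRangeMm[1], s$diameterRangeMm[2])
    list(k = k, centers = centers, diam = diam, origin = origin)
  })
  fwhmPx <- res$diam * 1000 / spec@pitchUm
  sigmaPx <- fwhmPx / (2 * sqrt(2 * log(2)))
  for (i in seq_len(res$k)) {
    r0 <- res$centers[i, 1]; c0 <- res$centers[i, 2]
    half <- ceiling(4 * sigmaPx[i])
    rr <- max(0, r0 - half):min(n - 1, r0 + half)
    cc <- max(0, c0 - half):min(n - 1, c0 + half)
    bump <- amp * exp(-outer((rr - r0)^2, (cc - c0)^2, "+") /
                        (2 * sigmaPx[i]^2))
    px[rr + 1, cc + 1] <- px[rr + 1, cc + 1] + bump
  }
  truth <- GroundTruth(res$centers, res$diam,
                       clusterBox = c(res$origin, res$origin + boxPx))
  list(image = MammogramImage(pmin(px, 2^spec@bitDepth - 1), spec@pitchUm,
                              spec@bitDepth),
       truth = truth)
}

#' Generate a labelled phantom patch dataset
#'
#' Builds nPos positive m x m patches (each one phantom background carrying
#' one cluster) and nNeg background-only patches, labelled by
#' \code{\link{labelPatches}} against the recorded truth. Reproducible per
#' seed. The default sizes 3000 + 3000 match a full-scale training corpus;
#' tests and examples use far fewer.
#'
#' @param spec a \linkS4class{PhantomSpec} (its imageSizePx is overridden by
#'   m: each patch is generated at exactly the window size).
#' @param nPos,nNeg patch counts per class.
#' @param m window side in pixels (default 115, ~5 mm at DDSM pitch).
#' @param seed integer seed.
#' @param minSpots cluster labelling threshold.
#' @return list(patches = labelled \linkS4class{PatchSet},
#'   truths = per-positive-patch \linkS4class{GroundTruth}).
#' @export
generateDataset <- function(spec, nPos = 3000L, nNeg = 3000L, m = 115L,
                            seed = 1L, minSpots = 3L) {
  stopifnot(nPos >= 1, nNeg >= 1)
  spec@imageSizePx <- as.integer(m)
  vectors <- matrix(0, m * m, nPos + nNeg)
  truths <- vector("list", nPos)
  labels <- numeric(nPos + nNeg)
  for (i in seq_len(nPos)) {
    bg <- generateBackground(spec, moduleSeed(seed, paste0("pos-bg-", i)))
    out <- addMCCluster(bg, spec, moduleSeed(seed, paste0("pos-cl-", i)))
    vectors[, i] <- as.vector(t(out$image@pixels))
    truths[[i]] <- out$truth
    ps1 <- PatchSet(vectors[, i, drop = FALSE], c(0L, 0L), m)
    labels[i] <- labelPatches(ps1, out$truth, minSpots = minSpots)
  }
  for (i in seq_len(nNeg)) {
    bg <- generateBackground(spec, moduleSeed(seed, paste0("neg-bg-", i)))
    vectors[, nPos + i] <- as.vector(t(bg@pixels))
    labels[nPos + i] <- -1
  }
  coords <- matrix(0L, nPos + nNeg, 2)
  list(patches = PatchSet(vectors, coords, m, labels = labels,
                          sourceId = sprintf("phantom-seed-%d", seed),
                          pitchUm = spec@pitchUm),
       truths = truths)
}

#' Independent-subspace fixture for SRC tests
#'
#' Two classes supported on mutually orthogonal random subspaces (QR of a
#' Gaussian matrix); each sample is a subspace point plus isotropic noise.
#' This is the structural assumption sparse-representation classification
#' relies on: samples of one class are linear combinations of that class's
#' training columns.
#'
#' @param dim ambient dimension (>= 2 * rankPerClass).
#' @param rankPerClass subspace rank per class.
#' @param nTrain,nTest samples per class.
#' @param noiseSd isotropic noise standard deviation.
#' @param seed integer seed.
#' @return list(vocab = \linkS4class{Vocabulary} of the training samples,
#'   testX = dim x (2 nTest) matrix, testLabels, bases = list(pos, neg)).
#' @export
generateSubspaceFixture <- function(dim, rankPerClass, nTrain, nTest,
                                    noiseSd = 0, seed = 0L) {
  stopifnot(2 * rankPerClass <= dim)
  withSeed(seed, {
    Q <- qr.Q(qr(matrix(rnorm(dim * 2 * rankPerClass), dim)))
    Upos <- Q[, seq_len(rankPerClass), drop = FALSE]
    Uneg <- Q[, rankPerClass + seq_len(rankPerClass), drop = FALSE]
    draw <- function(U, n)
      U %*% matrix(rnorm(rankPerClass * n), rankPerClass) +
        matrix(rnorm(dim * n, sd = noiseSd), dim)
    trainX <- cbind(draw(Upos, nTrain), draw(Uneg, nTrain))
    testX <- cbind(draw(Upos, nTest), draw(Uneg, nTest))
    list(vocab = Vocabulary(trainX, rep(c(1, -1), each = nTrain),
                            transformId = "identity"),
         testX = testX, testLabels = rep(c(1, -1), each = nTest),
         bases = list(pos = Upos, neg = Uneg))
  })
}

#' Two-Gaussian-cloud fixture for TWSVM tests
#'
#' @param means list or 2-row matrix of the two class means (+1 first).
#' @param sd isotropic standard deviation.
#' @param n points per class.
#' @param seed integer seed.
#' @return list(x = (2n) x d row-pattern matrix, labels = +1/-1).
#' @export
generateClusterFixture <- function(means, sd = 0.3, n = 50L, seed = 1L) {
  if (is.list(means)) means <- do.call(rbind, means)
  stopifnot(nrow(means) == 2)
  d <- ncol(means)
  withSeed(seed, {
    x <- rbind(matrix(rnorm(n * d, sd = sd), n, d, byrow = TRUE) +
                 matrix(means[1, ], n, d, byrow = TRUE),
               matrix(rnorm(n * d, sd = sd), n, d, byrow = TRUE) +
                 matrix(means[2, ], n, d, byrow = TRUE))
    list(x = x, labels = rep(c(1, -1), each = n))
  })
}
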