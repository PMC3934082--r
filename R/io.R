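# Format plumbing: PNG/TIFF image I/O (12-bit data in 16-bit containers),
# ground-truth CSV, and portable serialization of vocabularies, models and
# patch sets.

#' Read and write mammogram-like images
#'
#' PNG (8-bit write, 8/16-bit read) and TIFF (16-bit) round-trips.
#' Intensities are stored scaled to the file container; 12-bit data travels
#' in 16-bit TIFF containers, where integer values are preserved exactly.
#'
#' @param image a \linkS4class{MammogramImage}.
#' @param path file path ending in .png, .tif or .tiff.
#' @param pitchUm,bitDepth metadata applied on read (files carry none).
#' @return \code{readImage} returns a \linkS4class{MammogramImage};
#'   \code{writeImage} returns \code{path} invisibly.
#' @name imageIO
NULL

#' @rdname imageIO
#' @export
writeImage <- function(image, path) {
  containerBits <- if (image@bitDepth == 8L) 8L else 16L
  norm <- round(image@pixels) / (2^containerBits - 1)
  norm <- pmin(pmax(norm, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (containerBits != 8L)
      stop("PNG output is 8-bit; write ", image@bitDepth,
           "-bit data to TIFF instead")
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' @rdname imageIO
#' @export
readImage <- function(path, pitchUm = 43.5, bitDepth = 12L) {
  ext <- tolower(tools::file_ext(path))
  norm <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: .", ext)
  if (length(dim(norm)) == 3) norm <- norm[, , 1]
  containerBits <- if (bitDepth == 8L) 8L else 16L
  MammogramImage(round(norm * (2^containerBits - 1)), pitchUm,
                 as.integer(bitDepth))
}

#' Ground-truth CSV I/O
#'
#' Columns: image_id, center_row_px, center_col_px, diameter_mm.
#'
#' @param truths named list of \linkS4class{GroundTruth} (names = image ids).
#' @param path CSV path.
#' @return \code{readGroundTruthCsv} returns a named list of
#'   \linkS4class{GroundTruth}.
#' @name truthIO
NULL

#' @rdname truthIO
#' @export
writeGroundTruthCsv <- function(truths, path) {
  rows <- do.call(rbind, lapply(names(truths), function(id) {
    tr <- truths[[id]]
    if (nrow(tr@centers) == 0) return(NULL)
    data.frame(image_id = id, center_row_px = tr@centers[, 1],
               center_col_px = tr@centers[, 2],
               diameter_mm = tr@diametersMm)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname truthIO
#' @export
readGroundTruthCsv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$image_id), function(g)
    GroundTruth(cbind(g$center_row_px, g$center_col_px), g$diameter_mm))
}

#' Serialize package objects
#'
#' Vocabularies, twin-SVM models and patch sets are written as
#' self-contained RDS files (columns/labels/scales/transform id for a
#' vocabulary; u, v, kernel spec, reference matrix and dual metadata for a
#' model). Round-trips are exact and byte-deterministic.
#'
#' @param object the object to write.
#' @param path file path.
#' @return read functions return the object; write functions return
#'   \code{path} invisibly.
#' @name serialization
NULL

#' @rdname serialization
#' @export
writeVocabulary <- function(object, path) {
  stopifnot(is(object, "Vocabulary"))
  saveRDS(list(format = "mcdetect-vocabulary-1", columns = object@columns,
               labels = object@labels, scales = object@scales,
               normalized = object@normalized,
               transformId = object@transformId), path)
  invisible(path)
}

#' @rdname serialization
#' @export
readVocabulary <- function(path) {
  x <- readRDS(path)
  stopifnot(identical(x$format, "mcdetect-vocabulary-1"))
  new("Vocabulary", columns = x$columns, labels = x$labels,
      scales = x$scales, normalized = x$normalized,
      transformId = x$transformId)
}

#' @rdname serialization
#' @export
writeTWSVMModel <- function(object, path) {
  stopifnot(is(object, "TWSVMModel"))
  saveRDS(list(format = "mcdetect-twsvm-1", u = object@u, v = object@v,
               kernelKind = object@kernel@kind, sigma = object@kernel@sigma,
               reference = object@reference, wnorm = object@wnorm,
               dual = object@dual, dim = object@dim), path)
  invisible(path)
}

#' @rdname serialization
#' @export
readTWSVMModel <- function(path) {
  x <- readRDS(path)
  stopifnot(identical(x$format, "mcdetect-twsvm-1"))
  new("TWSVMModel", u = x$u, v = x$v,
      kernel = new("KernelSpec", kind = x$kernelKind, sigma = x$sigma),
      reference = x$reference, wnorm = x$wnorm, dual = x$dual, dim = x$dim)
}

#' @rdname serialization
#' @export
writePatchSet <- function(object, path) {
  stopifnot(is(object, "PatchSet"))
  saveRDS(list(format = "mcdetect-patchset-1", vectors = patchMatrix(object),
               coords = patchCoords(object), m = windowSize(object),
               labels = patchLabels(object),
               sourceId = S4Vectors::metadata(object)$sourceId,
               pitchUm = S4Vectors::metadata(object)$pitchUm), path)
  invisible(path)
}

#' @rdname serialization
#' @export
readPatchSet <- function(path) {
  x <- readRDS(path)
  stopifnot(identical(x$format, "mcdetect-patchset-1"))
  PatchSet(x$vectors, x$coords, x$m, labels = x$labels,
           sourceId = x$sourceId, pitchUm = x$pitchUm)
}
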