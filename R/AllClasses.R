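#' @useDynLib dermrestore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' RasterImage: an RGB pixel grid
#'
#' The universal pixel container of the package: an H x W x 3 numeric array
#' with channels ordered red, green, blue and intensities on the 0--255 scale.
#' Pixels are indexed \code{[row, col, channel]} with row 1 at the top.
#' Internal arithmetic is kept in floating point; quantisation to whole
#' intensities happens only at file boundaries (\code{\link{writeRaster}}).
#'
#' @slot .Data numeric array, H x W x 3, finite values in [0, 255].
#' @seealso \code{\link{RasterImage}}, \code{\link{readRaster}}
#' @export
setClass("RasterImage", contains = "array", validity = function(object) {
  d <- dim(object)
  if (length(d) != 3L || d[3] != 3L)
    return("RasterImage must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) return("image dimensions must be positive")
  if (!is.numeric(object@.Data)) return("pixel values must be numeric")
  if (!all(is.finite(object@.Data))) return("pixel values must be finite")
  rng <- range(object@.Data)
  if (rng[1] < -1e-9 || rng[2] > 255 + 1e-9)
    return("pixel values must lie in [0, 255]")
  TRUE
})

#' GrayImage: a single-channel pixel grid
#'
#' H x W numeric matrix of intensities in [0, 255], typically produced by
#' \code{\link{toGrayscale}} and consumed by the morphology operators.
#'
#' @slot .Data numeric matrix with finite values in [0, 255].
#' @export
setClass("GrayImage", contains = "matrix", validity = function(object) {
  if (!is.numeric(object@.Data)) return("pixel values must be numeric")
  if (!all(is.finite(object@.Data))) return("pixel values must be finite")
  rng <- range(object@.Data)
  if (rng[1] < -1e-9 || rng[2] > 255 + 1e-9)
    return("pixel values must lie in [0, 255]")
  TRUE
})

#' LabImage: CIELAB pixel grid
#'
#' H x W x 3 numeric array holding the CIELAB channels L (lightness, 0--100)
#' and a, b (chroma, unbounded, typically within [-128, 127]). Produced by
#' \code{\link{rgbToLab}} under the D65 white point and the sRGB transfer
#' curve.
#'
#' @slot .Data numeric array, H x W x 3 (L, a, b).
#' @export
setClass("LabImage", contains = "array", validity = function(object) {
  d <- dim(object)
  if (length(d) != 3L || d[3] != 3L)
    return("LabImage must be an H x W x 3 array (L, a, b)")
  if (!all(is.finite(object@.Data))) return("channel values must be finite")
  TRUE
})

#' BinaryMask: a boolean pixel grid
#'
#' H x W logical matrix; \code{TRUE} marks the region Omega to be restored
#' (hair pixels for the dehairing pipeline).
#'
#' @slot .Data logical matrix.
#' @export
setClass("BinaryMask", contains = "matrix", validity = function(object) {
  if (!is.logical(object@.Data)) return("mask must be logical")
  if (anyNA(object@.Data)) return("mask must not contain NA")
  TRUE
})

#' Construct a RasterImage
#'
#' @param pixels numeric H x W x 3 array on the 0--255 scale.
#' @return a \code{RasterImage}.
#' @examples
#' img <- RasterImage(array(128, dim = c(4, 4, 3)))
#' @export
RasterImage <- function(pixels) {
  new("RasterImage", array(as.double(pixels), dim = dim(pixels)))
}

#' Construct a GrayImage
#' @param pixels numeric H x W matrix on the 0--255 scale.
#' @return a \code{GrayImage}.
#' @export
GrayImage <- function(pixels) {
  m <- as.matrix(pixels)
  storage.mode(m) <- "double"
  new("GrayImage", m)
}

#' Construct a LabImage
#' @param pixels numeric H x W x 3 array with channels L, a, b.
#' @return a \code{LabImage}.
#' @export
LabImage <- function(pixels) {
  new("LabImage", array(as.double(pixels), dim = dim(pixels)))
}

#' Construct a BinaryMask
#' @param pixels logical (or coercible) H x W matrix; \code{TRUE} marks the
#'   region to restore.
#' @return a \code{BinaryMask}.
#' @export
BinaryMask <- function(pixels) {
  m <- as.matrix(pixels)
  storage.mode(m) <- "logical"
  new("BinaryMask", m)
}

#' Image dimension accessors
#'
#' @param x a \code{RasterImage}, \code{GrayImage}, \code{LabImage} or
#'   \code{BinaryMask}.
#' @return integer scalar: the number of pixel rows (height) or columns
#'   (width).
#' @export
setGeneric("imgHeight", function(x) standardGeneric("imgHeight"))

#' @rdname imgHeight
#' @export
setGeneric("imgWidth", function(x) standardGeneric("imgWidth"))

setMethod("imgHeight", "RasterImage", function(x) dim(x@.Data)[1])
setMethod("imgHeight", "GrayImage", function(x) dim(x@.Data)[1])
setMethod("imgHeight", "LabImage", function(x) dim(x@.Data)[1])
setMethod("imgHeight", "BinaryMask", function(x) dim(x@.Data)[1])
setMethod("imgWidth", "RasterImage", function(x) dim(x@.Data)[2])
setMethod("imgWidth", "GrayImage", function(x) dim(x@.Data)[2])
setMethod("imgWidth", "LabImage", function(x) dim(x@.Data)[2])
setMethod("imgWidth", "BinaryMask", function(x) dim(x@.Data)[2])

#' Extract raw pixel values
#'
#' @param x an image object of this package.
#' @return the underlying numeric array/matrix (logical for masks), without
#'   the class wrapper.
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))
setMethod("pixelValues", "RasterImage", function(x) {
  a <- x@.Data; attributes(a) <- list(dim = dim(a)); a
})
setMethod("pixelValues", "GrayImage", function(x) unclass(x@.Data))
setMethod("pixelValues", "LabImage", function(x) {
  a <- x@.Data; attributes(a) <- list(dim = dim(a)); a
})
setMethod("pixelValues", "BinaryMask", function(x) unclass(x@.Data))

setMethod("show", "RasterImage", function(object) {
  cat(sprintf("RasterImage %d x %d x 3 (RGB, 0-255)\n",
              imgHeight(object), imgWidth(object)))
  cat(sprintf("  range: [%.2f, %.2f]  mean: %.2f\n",
              min(object@.Data), max(object@.Data), mean(object@.Data)))
})
setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %d x %d (0-255)\n",
              imgHeight(object), imgWidth(object)))
  cat(sprintf("  range: [%.2f, %.2f]  mean: %.2f\n",
              min(object@.Data), max(object@.Data), mean(object@.Data)))
})
setMethod("show", "LabImage", function(object) {
  cat(sprintf("LabImage %d x %d x 3 (CIELAB, D65)\n",
              imgHeight(object), imgWidth(object)))
  cat(sprintf("  L range: [%.2f, %.2f]\n",
              min(object@.Data[, , 1]), max(object@.Data[, , 1])))
})
setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d  (%d / %d pixels marked)\n",
              imgHeight(object), imgWidth(object),
              sum(object@.Data), length(object@.Data)))
})

#' StructuringElement: a morphological neighbourhood
#'
#' K x K logical grid with the anchor at the centre cell; parameterises the
#' grayscale morphology operators. The anchor cell must be \code{TRUE}.
#'
#' @slot .Data logical K x K matrix, K odd.
#' @seealso \code{\link{makeCrossElement}}
#' @export
setClass("StructuringElement", contains = "matrix", validity = function(object) {
  d <- dim(object)
  if (d[1] != d[2]) return("structuring element must be square")
  if (d[1] %% 2L == 0L) return("structuring element size must be odd")
  if (!is.logical(object@.Data)) return("cells must be logical")
  c0 <- (d[1] + 1L) %/% 2L
  if (!isTRUE(object@.Data[c0, c0])) return("anchor (centre) cell must be TRUE")
  TRUE
})

setMethod("show", "StructuringElement", function(object) {
  cat(sprintf("StructuringElement %d x %d (%d active cells)\n",
              nrow(object@.Data), ncol(object@.Data), sum(object@.Data)))
})
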