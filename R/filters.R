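# Smoothing and grayscale-morphology operators of the dehairing pipeline.
# All filters use reflect (symmetric, edge-included) padding so that border
# behaviour is identical across operators and their test oracles.

# sigma derived from kernel size when not given explicitly
derive_sigma <- function(ksize) 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8

#' Discrete normalised Gaussian kernel
#'
#' @param ksize odd kernel width.
#' @param sigma standard deviation in pixels; when \code{NULL} or
#'   non-positive it is derived from the kernel size as
#'   \code{0.3 * ((k - 1) * 0.5 - 1) + 0.8}.
#' @return numeric vector of length \code{ksize} summing to 1.
#' @export
gaussianKernel <- function(ksize, sigma = NULL) {
  ksize <- odd_check(ksize, "kernel size")
  if (is.null(sigma) || sigma <= 0) sigma <- derive_sigma(ksize)
  r <- (ksize - 1) / 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

apply_per_channel <- function(image, fn) {
  if (is(image, "GrayImage") || (is.matrix(image) && !is(image, "BinaryMask")))
    return(GrayImage(fn(as_gray_matrix(image))))
  a <- as_rgb_array(image)
  out <- array(0, dim = dim(a))
  for (ch in 1:3) out[, , ch] <- fn(a[, , ch])
  RasterImage(clip01(out))
}

#' Gaussian blur
#'
#' Separable convolution with the normalised discrete Gaussian kernel,
#' reflect padding, applied per channel. A constant image is returned
#' unchanged (the kernel sums to 1).
#'
#' @param image a \code{RasterImage} or \code{GrayImage} (or bare
#'   array/matrix).
#' @param ksize odd kernel width; the dehairing pipeline default is 3.
#' @param sigma Gaussian standard deviation; derived from \code{ksize}
#'   when \code{NULL}.
#' @return the same kind of image as the input.
#' @export
gaussianBlur <- function(image, ksize = 3L, sigma = NULL) {
  k <- gaussianKernel(ksize, sigma)
  apply_per_channel(image, function(m) .gaussian_sep_cpp(m, k))
}

#' Median blur
#'
#' Replaces every pixel (per channel) by the median of its
#' \code{ksize x ksize} reflect-padded neighbourhood. Nonlinear, edge
#' preserving; the pipeline default neighbourhood is 3 x 3.
#'
#' @inheritParams gaussianBlur
#' @return the same kind of image as the input.
#' @export
medianBlur <- function(image, ksize = 3L) {
  ksize <- odd_check(ksize, "kernel size")
  apply_per_channel(image, function(m) .median_cpp(m, ksize))
}

#' Cross-shaped structuring element
#'
#' A \code{size x size} grid that is \code{TRUE} exactly on the centre row
#' and centre column (\code{2 * size - 1} active cells). The dehairing
#' pipeline uses an 11 x 11 cross, whose long thin arms respond to
#' curvilinear hair while ignoring compact lesion structure.
#'
#' @param size odd side length.
#' @return a \code{\link{StructuringElement}}.
#' @examples
#' sum(pixelValues(makeCrossElement(11))) # 21 active cells
#' @export
makeCrossElement <- function(size) {
  size <- odd_check(size, "structuring element size")
  m <- matrix(FALSE, size, size)
  c0 <- (size + 1L) %/% 2L
  m[c0, ] <- TRUE
  m[, c0] <- TRUE
  new("StructuringElement", m)
}

setMethod("pixelValues", "StructuringElement", function(x) unclass(x@.Data))

#' Grayscale dilation and erosion
#'
#' Flat grayscale morphology with reflect padding: dilation takes the
#' maximum, erosion the minimum, over the structuring element's active
#' offsets.
#'
#' @param image a \code{GrayImage} or numeric matrix.
#' @param se a \code{\link{StructuringElement}} or logical matrix.
#' @return a \code{GrayImage}.
#' @export
dilateGray <- function(image, se) {
  GrayImage(.morph_cpp(as_gray_matrix(image), as_se_matrix(se), TRUE))
}

#' @rdname dilateGray
#' @export
erodeGray <- function(image, se) {
  GrayImage(.morph_cpp(as_gray_matrix(image), as_se_matrix(se), FALSE))
}

#' Morphological closing
#'
#' Dilation followed by erosion; fills dark gaps narrower than the
#' structuring element. Extensive (output >= input) and idempotent.
#'
#' @inheritParams dilateGray
#' @return a \code{GrayImage}.
#' @export
morphClose <- function(image, se) {
  erodeGray(dilateGray(image, se), se)
}

#' Blackhat transform
#'
#' Closing minus the input: a non-negative response that highlights dark
#' structures thinner than the structuring element (hair strands) against a
#' brighter background.
#'
#' @inheritParams dilateGray
#' @return a \code{GrayImage} holding the (non-negative) response.
#' @export
blackhat <- function(image, se) {
  m <- as_gray_matrix(image)
  GrayImage(pixelValues(morphClose(m, se)) - m)
}

#' Binary threshold
#'
#' Marks every pixel whose value strictly exceeds \code{thresh}; ties are
#' excluded. \code{maxval} only matters when the mask is exported as a u8
#' image and is kept for interface fidelity.
#'
#' @param image a \code{GrayImage} or numeric matrix (e.g. a blackhat
#'   response).
#' @param thresh threshold on the 0--255 scale; default 10, the conventional
#'   choice for blackhat hair masking.
#' @param maxval export value for marked pixels; must exceed \code{thresh}.
#' @return a \code{\link{BinaryMask}}.
#' @export
thresholdBinary <- function(image, thresh = 10, maxval = 255) {
  if (!(thresh >= 0 && thresh < maxval && maxval <= 255))
    stop("need 0 <= thresh < maxval <= 255")
  BinaryMask(as_gray_matrix(image) > thresh)
}

#' Label connected components of a mask
#'
#' 8-connected labelling; labels are assigned in column-major scan order of
#' each component's first pixel.
#'
#' @param mask a \code{BinaryMask} or logical matrix.
#' @return integer matrix of labels (0 = background).
#' @export
labelComponents <- function(mask) {
  .label_cpp(as_mask_matrix(mask))
}
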