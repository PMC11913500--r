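# Non-local means denoising: every pixel is replaced by a convex combination
# of the pixels in its search window, weighted by the similarity of the
# surrounding patches. Color images are denoised in CIELAB, with the
# luminance and the two chroma channels filtered separately.

#' Non-local means parameters
#'
#' @param h filter strength for the luminance channel; 10 (on the 0--255
#'   scale) is the conventional setting for dermoscopic images.
#' @param hColor filter strength for the chroma channels.
#' @param templateRadius patch half-width in pixels (default 3, a 7 x 7
#'   patch).
#' @param searchRadius search-window half-width in pixels (default 10, a
#'   21 x 21 window). Must be at least \code{templateRadius}.
#' @param selfWeight \code{"max"} (default): the centre pixel's own weight is
#'   set to the maximum of the other weights in its window, the standard
#'   stabilisation; \code{"one"}: the literal exp(0) = 1.
#' @param fullImage when \code{TRUE}, sum over the whole image instead of the
#'   search window (the literal whole-image average; practical only for small
#'   images).
#' @return a list of class \code{NLMeansParams}.
#' @export
nlMeansParams <- function(h = 10, hColor = 10, templateRadius = 3L,
                          searchRadius = 10L, selfWeight = c("max", "one"),
                          fullImage = FALSE) {
  selfWeight <- match.arg(selfWeight)
  stopifnot(h > 0, hColor > 0, templateRadius >= 1,
            searchRadius >= templateRadius)
  structure(list(h = h, hColor = hColor,
                 templateRadius = as.integer(templateRadius),
                 searchRadius = as.integer(searchRadius),
                 selfWeight = selfWeight, fullImage = isTRUE(fullImage)),
            class = "NLMeansParams")
}

#' Mean squared distance between two patches
#'
#' Mean of the squared differences over the \code{(2r+1)^2} cells of the
#' reflect-padded patches centred at \code{i} and \code{j}. Zero iff the
#' patches are identical.
#'
#' @param v numeric matrix of pixel values.
#' @param i,j length-2 (row, col) patch centres, 1-based.
#' @param templateRadius patch half-width r.
#' @return a non-negative scalar.
#' @export
patchDistance <- function(v, i, j, templateRadius = 3L) {
  H <- nrow(v); W <- ncol(v); r <- templateRadius
  rf <- function(k, n) ifelse(k < 1, 1 - k, ifelse(k > n, 2 * n + 1 - k, k))
  d <- 0
  for (di in -r:r) for (dj in -r:r) {
    a <- v[rf(i[1] + di, H), rf(i[2] + dj, W)]
    b <- v[rf(j[1] + di, H), rf(j[2] + dj, W)]
    d <- d + (a - b)^2
  }
  d / (2 * r + 1)^2
}

#' Robust noise standard-deviation estimate
#'
#' Convolves the image with the 3 x 3 high-pass operator
#' \code{[1 -2 1; -2 4 -2; 1 -2 1]} (which annihilates constant and linear
#' trends, so smooth structure does not inflate the estimate) and scales the
#' median absolute deviation of the interior response into sigma units.
#'
#' @param v a \code{GrayImage} or numeric matrix, at least 3 x 3.
#' @return estimated noise sigma (>= 0) in intensity units.
#' @export
estimateNoiseSigma <- function(v) {
  m <- as_gray_matrix(v)
  if (nrow(m) < 3 || ncol(m) < 3) stop("image must be at least 3 x 3")
  H <- nrow(m); W <- ncol(m)
  i <- 2:(H - 1); j <- 2:(W - 1)
  L <- m[i - 1, j - 1] - 2 * m[i - 1, j] + m[i - 1, j + 1] -
    2 * m[i, j - 1] + 4 * m[i, j] - 2 * m[i, j + 1] +
    m[i + 1, j - 1] - 2 * m[i + 1, j] + m[i + 1, j + 1]
  # MAD -> sigma: 0.6745 is the normal-consistency constant, 6 the kernel's
  # coefficient L2 norm
  stats::median(abs(L)) / (0.6745 * 6)
}

#' Non-local means on a single channel
#'
#' Windowed weighted average with weights
#' \code{exp(-max(patch_mse - 2 * sigma^2, 0) / h^2)}, normalised to sum to
#' 1 at every pixel; the \code{2 sigma^2} offset discounts the patch
#' distance contributed by the noise itself. Output values stay within the
#' input range (convex combination).
#'
#' @param v a \code{GrayImage} or numeric matrix.
#' @param params an \code{\link{nlMeansParams}} object; \code{h} is used for
#'   this channel.
#' @param sigma noise standard deviation for the offset; estimated from
#'   \code{v} via \code{\link{estimateNoiseSigma}} when \code{NULL}.
#' @return a matrix (same shape as \code{v}) of denoised values.
#' @export
nlMeansGray <- function(v, params = nlMeansParams(), sigma = NULL) {
  m <- as_gray_matrix(v)
  if (is.null(sigma)) sigma <- estimateNoiseSigma(m)
  .nlm_cpp(m, params$h, params$templateRadius, params$searchRadius,
           sigma, if (params$selfWeight == "max") 0L else 1L,
           params$fullImage)
}

#' Non-local means for color images
#'
#' Converts to CIELAB, rescales the channels to the 0--255 convention (L by
#' 255/100, a and b shifted by +128) so the \code{h} parameters keep their
#' usual meaning, denoises L with \code{h} and each chroma channel with
#' \code{hColor}, converts back to RGB and clips to [0, 255]. The noise
#' offset sigma is estimated per channel.
#'
#' @param image a \code{RasterImage} (or H x W x 3 array).
#' @param params an \code{\link{nlMeansParams}} object.
#' @return a denoised \code{RasterImage}.
#' @export
nlMeansColored <- function(image, params = nlMeansParams()) {
  lab <- pixelValues(rgbToLab(image))
  scl <- function(ch, s, o) ch * s + o
  L <- scl(lab[, , 1], 2.55, 0)
  A <- scl(lab[, , 2], 1, 128)
  B <- scl(lab[, , 3], 1, 128)
  pl <- params; pl$hColor <- params$h
  pc <- params; pc$h <- params$hColor
  Ld <- nlMeansGray(L, pl)
  Ad <- nlMeansGray(A, pc)
  Bd <- nlMeansGray(B, pc)
  out <- array(0, dim = dim(lab))
  out[, , 1] <- Ld / 2.55
  out[, , 2] <- Ad - 128
  out[, , 3] <- Bd - 128
  labToRgb(LabImage(out))
}
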