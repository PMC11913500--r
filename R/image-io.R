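#' Read a PNG or JPEG image
#'
#' Decodes an image file into a \code{\link{RasterImage}} on the 0--255 scale.
#' Grayscale files are broadcast to three identical channels; an alpha channel,
#' if present, is dropped.
#'
#' @param path path to an existing PNG or JPEG file.
#' @return a \code{RasterImage}.
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeRaster(RasterImage(array(128, dim = c(4, 4, 3))), f)
#' img <- readRaster(f)
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode '", path, "': ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img) # x (col) major, values in [0, 1]
  d <- dim(a)
  if (length(d) == 2L) {
    m <- t(a) * 255
    return(RasterImage(array(rep(m, 3L), dim = c(dim(m), 3L))))
  }
  if (d[3] >= 3L) a <- a[, , 1:3, drop = FALSE] else
    a <- array(rep(a[, , 1], 3L), dim = c(d[1], d[2], 3L))
  RasterImage(clip01(aperm(a, c(2, 1, 3)) * 255))
}

#' Write an image to PNG or JPEG
#'
#' Values are rounded to the nearest whole intensity and clipped to [0, 255]
#' before encoding. PNG is lossless: a u8-valued image round-trips bit-exactly
#' through \code{writeRaster}/\code{\link{readRaster}}.
#'
#' @param image a \code{RasterImage} (or H x W x 3 array).
#' @param path output path; the extension selects the codec (.png or
#'   .jpg/.jpeg).
#' @return the path, invisibly.
#' @export
writeRaster <- function(image, path) {
  a <- as_rgb_array(image)
  if (!dir.exists(dirname(path))) stop("directory does not exist: ",
                                       dirname(path))
  u8 <- clip01(round(a)) / 255
  EBImage::writeImage(EBImage::Image(aperm(u8, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write a binary mask as a 0/255 single-channel PNG
#'
#' @param mask a \code{BinaryMask} (or logical matrix).
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  EBImage::writeImage(EBImage::Image(t(m) * 1), path)
  invisible(path)
}

#' Read a 0/255 mask PNG written by \code{\link{writeMask}}
#'
#' @param path PNG path; any strictly positive pixel is treated as marked.
#' @return a \code{BinaryMask}.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  BinaryMask(t(a) > 0.5)
}

#' Convert an RGB image to grayscale
#'
#' Uses the Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B, rounded to the
#' nearest whole intensity, so a pure gray pixel (R = G = B) maps to its
#' channel value exactly.
#'
#' @param image a \code{RasterImage} (or H x W x 3 array).
#' @return a \code{GrayImage}.
#' @export
toGrayscale <- function(image) {
  a <- as_rgb_array(image)
  g <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  GrayImage(round(g))
}

# sRGB transfer curve (electro-optical) on [0, 1]
srgb_to_linear <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}
linear_to_srgb <- function(v) {
  v <- pmax(v, 0)
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

# D65 reference white in XYZ (2 degree observer), Y normalised to 1
.white_d65 <- c(X = 0.95047, Y = 1.0, Z = 1.08883)

# sRGB (linear) -> XYZ matrix, IEC 61966-2-1
.rgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                     0.2126729, 0.7151522, 0.0721750,
                     0.0193339, 0.1191920, 0.9503041),
                   nrow = 3, byrow = TRUE)
.xyz2rgb <- solve(.rgb2xyz)

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
lab_finv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert an RGB image to CIELAB
#'
#' Pipeline: sRGB transfer curve to linear RGB, linear RGB to XYZ (D65 white,
#' IEC 61966-2-1 primaries), XYZ to CIELAB. L is in [0, 100]; a and b are
#' unbounded chroma components.
#'
#' @param image a \code{RasterImage} (or H x W x 3 array, 0--255).
#' @return a \code{LabImage}.
#' @seealso \code{\link{labToRgb}}
#' @export
rgbToLab <- function(image) {
  a <- as_rgb_array(image)
  d <- dim(a)
  rgb_lin <- srgb_to_linear(matrix(a, ncol = 3) / 255)
  xyz <- rgb_lin %*% t(.rgb2xyz)
  fx <- lab_f(xyz[, 1] / .white_d65[1])
  fy <- lab_f(xyz[, 2] / .white_d65[2])
  fz <- lab_f(xyz[, 3] / .white_d65[3])
  out <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  LabImage(array(out, dim = d))
}

#' Convert a CIELAB image back to RGB
#'
#' Inverse of \code{\link{rgbToLab}}; out-of-gamut results are clipped to
#' [0, 255]. For in-gamut colors the round trip changes no channel by more
#' than one intensity level.
#'
#' @param image a \code{LabImage} (or H x W x 3 array with channels L, a, b).
#' @return a \code{RasterImage}.
#' @export
labToRgb <- function(image) {
  a <- if (is(image, "LabImage")) pixelValues(image) else
    array(as.double(image), dim = dim(image))
  d <- dim(a)
  m <- matrix(a, ncol = 3)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(lab_finv(fx) * .white_d65[1],
               lab_finv(fy) * .white_d65[2],
               lab_finv(fz) * .white_d65[3])
  rgb_lin <- xyz %*% t(.xyz2rgb)
  out <- clip01(linear_to_srgb(rgb_lin) * 255)
  RasterImage(array(out, dim = d))
}

#' Resize an image with bilinear interpolation
#'
#' Pixel-centre aligned sampling: output pixel (i, j) samples the source at
#' ((i + 0.5) * H/H' - 0.5, (j + 0.5) * W/W' - 0.5) in 0-based coordinates,
#' clamped to the image. Resizing to the same dimensions is the identity, and
#' by bilinear convexity the output range never exceeds the input range.
#'
#' @param image a \code{RasterImage} (or H x W x 3 array).
#' @param height,width positive target dimensions.
#' @return a \code{RasterImage} of exactly \code{height x width x 3}.
#' @export
resizeImage <- function(image, height, width) {
  if (height < 1 || width < 1) stop("target dimensions must be positive")
  a <- as_rgb_array(image)
  H <- dim(a)[1]; W <- dim(a)[2]
  sy <- clip01((seq_len(height) - 0.5) * H / height - 0.5, 0, H - 1)
  sx <- clip01((seq_len(width) - 0.5) * W / width - 0.5, 0, W - 1)
  y0 <- pmin(floor(sy), H - 1); fy <- sy - y0
  x0 <- pmin(floor(sx), W - 1); fx <- sx - x0
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  i0 <- y0 + 1L; i1 <- y1 + 1L; j0 <- x0 + 1L; j1 <- x1 + 1L
  out <- array(0, dim = c(height, width, 3L))
  wy <- matrix(fy, height, width)
  wx <- matrix(fx, height, width, byrow = TRUE)
  for (ch in 1:3) {
    p <- a[, , ch]
    out[, , ch] <- (1 - wy) * (1 - wx) * p[i0, j0, drop = FALSE] +
      (1 - wy) * wx * p[i0, j1, drop = FALSE] +
      wy * (1 - wx) * p[i1, j0, drop = FALSE] +
      wy * wx * p[i1, j1, drop = FALSE]
  }
  RasterImage(out)
}
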