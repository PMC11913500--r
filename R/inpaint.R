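# Fast-marching (TELEA-style) inpainting. The masked region Omega is filled
# from its boundary inward: pixels are processed in non-decreasing order of
# their fast-marching distance T to the initial boundary (the known pixels
# 4-adjacent to Omega, where T = 0), and each is estimated as a normalised
# weighted sum of first-order extrapolations from nearby known pixels.

#' Fast-marching distance field of a mask
#'
#' Solves the discrete eikonal equation |grad T| = 1 with T = 0 on the
#' initial boundary (known pixels 4-adjacent to the mask). Inside the mask T
#' is positive; outside it is the negated analogous distance, which feeds the
#' level-set component of the inpainting weight.
#'
#' @param mask a \code{BinaryMask} or logical matrix; must not be all
#'   \code{TRUE}.
#' @return a list with \code{T} (signed numeric matrix), \code{flag}
#'   (integer matrix: 0 known, 1 initial boundary, 2 inside) and \code{pops}
#'   (the non-decreasing sequence of distances at which pixels were
#'   finalised).
#' @export
computeDistanceField <- function(mask) {
  m <- as_mask_matrix(mask)
  if (all(m)) stop("mask covers the whole image; no known pixels to propagate from")
  .fmm_distance_cpp(m)
}

#' One quadratic upwind eikonal update
#'
#' Solves the discretised |grad T| = 1 at pixel (i, j) from the smallest
#' usable horizontal and vertical neighbour values (usable = flag 0 or 1,
#' i.e. not interior). When the two directions differ by 1 or more the
#' quadratic has no valid root and the solve degenerates to
#' \code{1 + min(T)}.
#'
#' @param T numeric matrix of current distance values.
#' @param i,j 1-based pixel coordinates.
#' @param flag integer matrix of pixel states (0 known, 1 band, 2 inside).
#' @return the updated scalar distance.
#' @examples
#' T <- matrix(0, 3, 3); fl <- matrix(2L, 3, 3)
#' fl[1, 2] <- 0L; fl[2, 1] <- 0L
#' eikonalUpdate(T, 2, 2, fl) # 1/sqrt(2) from two zero-valued neighbours
#' @export
eikonalUpdate <- function(T, i, j, flag) {
  H <- nrow(T); W <- ncol(T)
  usable <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W &&
    flag[r, c] != 2L
  tv <- Inf; th <- Inf
  if (usable(i - 1, j)) tv <- min(tv, T[i - 1, j])
  if (usable(i + 1, j)) tv <- min(tv, T[i + 1, j])
  if (usable(i, j - 1)) th <- min(th, T[i, j - 1])
  if (usable(i, j + 1)) th <- min(th, T[i, j + 1])
  if (!is.finite(th) && !is.finite(tv))
    stop("no usable neighbour for the eikonal update at (", i, ", ", j, ")")
  a <- min(th, tv); b <- max(th, tv)
  if (!is.finite(b) || b - a >= 1) return(a + 1)
  (th + tv + sqrt(2 - (th - tv)^2)) / 2
}

#' Inpainting weight between a target and a known pixel
#'
#' The product of three components: \code{dir}, alignment of q with the
#' propagation direction (the normal N(p) of the advancing boundary, i.e.
#' the normalised gradient of T at p, floored at 1e-6); \code{dst}, inverse
#' squared geometric distance scaled by \code{d0}; and \code{lev}, closeness
#' of the two pixels' boundary distances scaled by \code{T0}.
#'
#' @param p,q length-2 (row, col) coordinates, 1-based; \code{p != q}.
#' @param T signed distance field from \code{\link{computeDistanceField}}.
#' @param d0,T0 geometric and level-set distance scales in pixels.
#' @return a positive scalar weight.
#' @export
fmmWeight <- function(p, q, T, d0 = 1, T0 = 1) {
  if (all(p == q)) stop("p and q must differ")
  H <- nrow(T); W <- ncol(T)
  rf <- function(i, n) if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  ny <- (T[rf(p[1] + 1, H), p[2]] - T[rf(p[1] - 1, H), p[2]]) / 2
  nx <- (T[p[1], rf(p[2] + 1, W)] - T[p[1], rf(p[2] - 1, W)]) / 2
  nl <- sqrt(ny^2 + nx^2)
  if (nl > 1e-12) { ny <- ny / nl; nx <- nx / nl } else { ny <- 0; nx <- 0 }
  dy <- p[1] - q[1]; dx <- p[2] - q[2]
  len <- sqrt(dy^2 + dx^2)
  dir <- max(abs(dy * ny + dx * nx) / len, 1e-6)
  dst <- d0^2 / len^2
  lev <- T0 / (T0 + abs(T[p[1], p[2]] - T[q[1], q[2]]))
  dir * dst * lev
}

#' First-order inpainting estimate at one pixel
#'
#' Reference (R-level) form of the per-pixel estimate: each known pixel q in
#' the Chebyshev eps-ball around p contributes its value extrapolated by its
#' image gradient, weighted by \code{\link{fmmWeight}}; the sum is
#' normalised and clipped to [0, 255]. Image gradients use central
#' differences over known pixels only, falling back to one-sided differences
#' at known/unknown interfaces and to zero for isolated known pixels.
#'
#' @param image a \code{RasterImage} (or H x W x 3 array) whose known pixels
#'   are valid.
#' @param p (row, col) of the pixel to estimate, 1-based.
#' @param known logical matrix: \code{TRUE} where pixel values may be used.
#' @param T signed distance field.
#' @param eps neighbourhood radius in pixels (Chebyshev); \code{eps = 1} is
#'   the 8-neighbourhood.
#' @param d0,T0 weight scales, see \code{\link{fmmWeight}}.
#' @return numeric length-3 estimated RGB value.
#' @export
inpaintPixel <- function(image, p, known, T, eps = 1, d0 = 1, T0 = 1) {
  a <- as_rgb_array(image)
  H <- dim(a)[1]; W <- dim(a)[2]
  r <- ceiling(eps)
  acc <- c(0, 0, 0); wsum <- 0
  for (qi in max(1, p[1] - r):min(H, p[1] + r)) {
    for (qj in max(1, p[2] - r):min(W, p[2] + r)) {
      if (qi == p[1] && qj == p[2]) next
      if (max(abs(qi - p[1]), abs(qj - p[2])) > eps) next
      if (!known[qi, qj]) next
      w <- fmmWeight(p, c(qi, qj), T, d0, T0)
      dy <- p[1] - qi; dx <- p[2] - qj
      up <- qi > 1 && known[qi - 1, qj]; dn <- qi < H && known[qi + 1, qj]
      lf <- qj > 1 && known[qi, qj - 1]; rt <- qj < W && known[qi, qj + 1]
      for (ch in 1:3) {
        gy <- if (up && dn) (a[qi + 1, qj, ch] - a[qi - 1, qj, ch]) / 2
        else if (dn) a[qi + 1, qj, ch] - a[qi, qj, ch]
        else if (up) a[qi, qj, ch] - a[qi - 1, qj, ch] else 0
        gx <- if (lf && rt) (a[qi, qj + 1, ch] - a[qi, qj - 1, ch]) / 2
        else if (rt) a[qi, qj + 1, ch] - a[qi, qj, ch]
        else if (lf) a[qi, qj, ch] - a[qi, qj - 1, ch] else 0
        acc[ch] <- acc[ch] + w * (a[qi, qj, ch] + gy * dy + gx * dx)
      }
      wsum <- wsum + w
    }
  }
  if (wsum <= 0) stop("no known pixel within the eps-ball of (",
                      p[1], ", ", p[2], ")")
  clip01(acc / wsum)
}

#' Fast-marching inpainting of a masked region
#'
#' Fills every masked pixel in non-decreasing order of its boundary distance
#' (ties broken by row, then column, for determinism); freshly inpainted
#' pixels become known for pixels processed later. Channels are inpainted
#' independently but share the distance field and weights. Pixels outside
#' the mask are returned bit-identical to the input.
#'
#' @param image a \code{RasterImage} (or H x W x 3 array).
#' @param mask a \code{BinaryMask} or logical matrix marking the region to
#'   restore; must not cover the whole image.
#' @param eps neighbourhood radius (Chebyshev) of the per-pixel estimate;
#'   default 1 (the 8-neighbourhood), the pipeline's radius.
#' @param d0,T0 weight scales in pixels, see \code{\link{fmmWeight}}.
#' @return a \code{RasterImage} with the mask filled.
#' @examples
#' img <- RasterImage(array(rep(10 * (1:16), each = 16 * 3),
#'                          dim = c(16, 16, 3)))
#' mask <- matrix(FALSE, 16, 16); mask[6:9, 6:9] <- TRUE
#' out <- inpaintImage(img, mask)
#' @export
inpaintImage <- function(image, mask, eps = 1, d0 = 1, T0 = 1) {
  a <- as_rgb_array(image)
  m <- as_mask_matrix(mask)
  if (!all(dim(m) == dim(a)[1:2])) stop("mask and image shapes differ")
  if (all(m)) stop("mask covers the whole image")
  if (!any(m)) return(RasterImage(a))
  res <- .inpaint_cpp(list(a[, , 1], a[, , 2], a[, , 3]), m,
                      as.double(eps), as.double(d0), as.double(T0))
  out <- array(0, dim = dim(a))
  for (ch in 1:3) out[, , ch] <- res$channels[[ch]]
  RasterImage(out)
}
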