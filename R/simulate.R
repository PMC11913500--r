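# Synthetic corpus generation: lesion phantoms on skin-toned backgrounds,
# procedural hair occlusion with ground-truth masks, and zero-mean additive
# Gaussian noise. Every generator is a pure function of its seed, so paired
# (clean, corrupted, truth-mask, label) fixtures can be rebuilt bit-exactly
# anywhere.

#' Add zero-mean Gaussian noise
#'
#' Adds i.i.d. N(0, sigma^2) noise per pixel per channel in floating point,
#' then clips to [0, 255]. The dermoscopic noise regime of interest is
#' sigma in [1, 30]; sigma = 0 returns the input unchanged.
#'
#' @param image a \code{RasterImage} (or H x W x 3 array).
#' @param sigma noise scale in intensity units; must be >= 0.
#' @param seed integer seed making the draw reproducible; \code{NULL} uses
#'   the current RNG state.
#' @return a noisy \code{RasterImage}.
#' @export
addGaussianNoise <- function(image, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  a <- as_rgb_array(image)
  if (sigma == 0) return(RasterImage(a))
  noise <- with_seed(seed, stats::rnorm(length(a), 0, sigma))
  RasterImage(clip01(a + array(noise, dim = dim(a))))
}

#' Hair-occlusion parameters
#'
#' @param nHairs number of hair strands to draw.
#' @param thicknessRange inclusive integer range of stroke thickness in
#'   pixels.
#' @param intensityRange inclusive range of the dark hair base intensity
#'   (0--255).
#' @param curvature control-point jitter scale, as a fraction of the image
#'   diagonal, governing how curved the strands are.
#' @param seed integer seed.
#' @return a list of class \code{HairParams}.
#' @export
hairParams <- function(nHairs = 15L, thicknessRange = c(1L, 4L),
                       intensityRange = c(10, 90), curvature = 0.25,
                       seed = 1L) {
  stopifnot(nHairs >= 0, thicknessRange[1] >= 1)
  structure(list(nHairs = as.integer(nHairs),
                 thicknessRange = as.integer(thicknessRange),
                 intensityRange = intensityRange,
                 curvature = curvature, seed = as.integer(seed)),
            class = "HairParams")
}

# Rasterize one quadratic Bezier stroke; returns a logical mask.
rasterize_stroke <- function(H, W, p0, p1, p2, thickness) {
  chord <- sqrt(sum((p2 - p0)^2)) + sqrt(sum((p1 - p0)^2)) +
    sqrt(sum((p2 - p1)^2))
  n <- max(16L, ceiling(3 * chord))
  t <- seq(0, 1, length.out = n)
  by <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  bx <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  m <- matrix(FALSE, H, W)
  r <- (thickness - 1) / 2
  ri <- ceiling(r)
  for (k in seq_len(n)) {
    ys <- max(1, floor(by[k] - ri)):min(H, ceiling(by[k] + ri))
    xs <- max(1, floor(bx[k] - ri)):min(W, ceiling(bx[k] + ri))
    for (y in ys) for (x in xs)
      if ((y - by[k])^2 + (x - bx[k])^2 <= max(r, 0.5)^2) m[y, x] <- TRUE
  }
  m
}

#' Draw procedural hair strands on a clean image
#'
#' Superimposes \code{nHairs} random quadratic Bezier strokes with per-hair
#' thickness and dark brownish intensity. Strands are re-drawn (up to 60
#' attempts each) so that they do not touch each other, which keeps the
#' ground-truth mask's connected-component count equal to the strand count.
#'
#' @param clean a \code{RasterImage} (or H x W x 3 array).
#' @param params a \code{\link{hairParams}} object.
#' @return a list (class \code{SyntheticPair}) with elements \code{clean},
#'   \code{corrupted} (both \code{RasterImage}), \code{truthMask}
#'   (\code{BinaryMask}), \code{label} (\code{NA} here) and
#'   \code{provenance}.
#' @export
drawProceduralHairs <- function(clean, params = hairParams()) {
  a <- as_rgb_array(clean)
  H <- dim(a)[1]; W <- dim(a)[2]
  diag_len <- sqrt(H^2 + W^2)
  out <- a
  union_mask <- matrix(FALSE, H, W)
  # dilated occupancy keeps strands from touching even diagonally
  occupied <- matrix(FALSE, H, W)
  with_seed(params$seed, {
    for (hair in seq_len(params$nHairs)) {
      for (attempt in 1:60) {
        p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 0.4, 0.9) * diag_len * 0.7
        p2 <- p0 + len * c(sin(ang), cos(ang))
        p2 <- pmin(pmax(p2, 1), c(H, W))
        mid <- (p0 + p2) / 2
        jit <- stats::rnorm(2, 0, params$curvature * diag_len / 4)
        p1 <- pmin(pmax(mid + jit, 1), c(H, W))
        thick <- sample(params$thicknessRange[1]:params$thicknessRange[2], 1)
        stroke <- rasterize_stroke(H, W, p0, p1, p2, thick)
        if (!any(stroke)) next
        if (!any(stroke & occupied)) break
        stroke <- NULL
      }
      if (is.null(stroke)) next # could not place without touching; skip
      base <- stats::runif(1, params$intensityRange[1],
                           params$intensityRange[2])
      col <- base * c(1, 0.82, 0.62) # dark brown strand
      for (ch in 1:3) {
        pl <- out[, , ch]
        pl[stroke] <- col[ch]
        out[, , ch] <- pl
      }
      union_mask <- union_mask | stroke
      occupied <- occupied | pixelValues(dilateGray(stroke * 1,
                                                    matrix(TRUE, 3, 3))) > 0
    }
  })
  structure(list(clean = RasterImage(a), corrupted = RasterImage(out),
                 truthMask = BinaryMask(union_mask), label = NA_integer_,
                 provenance = params),
            class = "SyntheticPair")
}

#' Extract a hair mask from a donor image
#'
#' Detects dark curvilinear structure in a (hairy) donor image with the
#' pipeline's own detector -- blackhat of the grayscale image under an
#' 11 x 11 cross, thresholded -- then removes connected components smaller
#' than \code{minArea} pixels as a speckle guard.
#'
#' @param donor a \code{RasterImage}.
#' @param thresh blackhat threshold (default 10).
#' @param minArea minimum component area kept, in pixels (default 20).
#' @return a \code{BinaryMask}.
#' @export
extractHairMask <- function(donor, thresh = 10, minArea = 20L) {
  g <- toGrayscale(donor)
  bh <- blackhat(g, makeCrossElement(11L))
  m <- pixelValues(thresholdBinary(bh, thresh))
  lab <- labelComponents(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minArea)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  BinaryMask(m)
}

#' Superimpose donor hair onto a clean image
#'
#' Hard replacement: the corrupted image takes the donor's values where the
#' mask is \code{TRUE} and the clean values elsewhere, so the corruption is
#' exactly localised to the mask.
#'
#' @param clean,donor \code{RasterImage}s of the same shape (resample the
#'   donor with \code{\link{resizeImage}} first if needed).
#' @param mask a \code{BinaryMask} marking the donor's hair pixels.
#' @return a \code{SyntheticPair} (see \code{\link{drawProceduralHairs}}).
#' @export
superimposeHair <- function(clean, donor, mask) {
  a <- as_rgb_array(clean); b <- as_rgb_array(donor)
  m <- as_mask_matrix(mask)
  if (!all(dim(a) == dim(b))) stop("clean and donor shapes differ")
  if (!all(dim(m) == dim(a)[1:2])) stop("mask shape differs from images")
  out <- a
  for (ch in 1:3) {
    pl <- out[, , ch]; src <- b[, , ch]
    pl[m] <- src[m]
    out[, , ch] <- pl
  }
  structure(list(clean = RasterImage(a), corrupted = RasterImage(out),
                 truthMask = BinaryMask(m), label = NA_integer_,
                 provenance = list(kind = "donor-superimposition")),
            class = "SyntheticPair")
}

# Per-class lesion appearance families: separable mean colors, distinct
# size scales. Colors are dermoscopy-plausible (browns, black, red,
# blue-gray, tan, pink, violet).
.lesion_palette <- list(
  list(color = c(121, 76, 50), axes = 0.32),  # 0 melanocytic nevus: brown
  list(color = c(45, 38, 40), axes = 0.28),   # 1 melanoma: near-black
  list(color = c(190, 60, 55), axes = 0.30),  # 2 vascular: red
  list(color = c(90, 105, 150), axes = 0.30), # 3 blue-gray
  list(color = c(185, 150, 95), axes = 0.36), # 4 benign keratosis: tan
  list(color = c(235, 150, 160), axes = 0.26),# 5 pink
  list(color = c(140, 90, 160), axes = 0.34)  # 6 violet
)

#' Generate a lesion phantom
#'
#' A skin-toned background with smooth low-frequency texture and a filled,
#' soft-edged ellipse whose color and size family is controlled by
#' \code{classId}, so the seven classes are separable by construction (a
#' nearest-centroid classifier on mean lesion color already separates
#' them). This is a synthetic stand-in for real seven-class dermoscopy
#' content.
#'
#' @param classId integer in 0..6 selecting the appearance family.
#' @param size image side length in pixels (square output).
#' @param skinTone RGB background color.
#' @param textureScale amplitude of the smooth background texture in
#'   intensity units; 0 gives a flat background.
#' @param seed integer seed.
#' @return a list with \code{image} (\code{RasterImage}) and \code{label}
#'   (the class id).
#' @export
generateLesionPhantom <- function(classId, size = 64L,
                                  skinTone = c(224, 172, 150),
                                  textureScale = 6, seed = 1L) {
  if (classId < 0 || classId > 6) stop("classId must be in 0..6")
  H <- W <- as.integer(size)
  fam <- .lesion_palette[[classId + 1L]]
  img <- with_seed(seed, {
    ax <- fam$axes * W * stats::runif(1, 0.85, 1.15)
    ay <- fam$axes * H * stats::runif(1, 0.85, 1.15)
    cx <- W / 2 + stats::runif(1, -0.05, 0.05) * W
    cy <- H / 2 + stats::runif(1, -0.05, 0.05) * H
    if (cx - ax < 1 || cx + ax > W || cy - ay < 1 || cy + ay > H)
      stop("lesion does not fit in the frame")
    lesion_col <- fam$color + stats::rnorm(3, 0, 4)
    # smooth low-frequency texture: coarse noise grid, bilinear upsampled
    tex <- if (textureScale > 0) {
      coarse <- matrix(stats::rnorm(64, 0, textureScale), 8, 8)
      g <- array(rep(clip01(coarse, -3 * textureScale, 3 * textureScale) +
                       128, 3), dim = c(8, 8, 3))
      pixelValues(resizeImage(RasterImage(clip01(g)), H, W))[, , 1] - 128
    } else matrix(0, H, W)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    rad <- sqrt(((xx - cx) / ax)^2 + ((yy - cy) / ay)^2)
    alpha <- 1 / (1 + exp((rad - 1) * 12)) # soft edge, ~2 px band
    out <- array(0, dim = c(H, W, 3))
    for (ch in 1:3)
      out[, , ch] <- (1 - alpha) * skinTone[ch] + alpha * lesion_col[ch] + tex
    RasterImage(clip01(out))
  })
  list(image = img, label = as.integer(classId))
}

#' Generate a synthetic corpus on disk
#'
#' Writes balanced seven-class phantom images under
#' \code{outDir/clean/}, their corrupted versions under
#' \code{outDir/corrupted/} (when \code{corruption != "none"}), truth masks
#' under \code{outDir/masks/} (hair corruption only), and a
#' \code{manifest.csv} with columns file, label, corruption, sigma, n_hairs,
#' seed. Regeneration with the same seed is byte-identical.
#'
#' @param nPerClass images per class (7 classes).
#' @param corruption one of \code{"hair"}, \code{"noise"}, \code{"none"}.
#' @param outDir output directory (created if missing).
#' @param seed master integer seed.
#' @param size image side length in pixels.
#' @param sigma noise scale for \code{corruption = "noise"}; \code{NULL}
#'   draws sigma uniformly from [1, 30] per image.
#' @param nHairs hairs per image for \code{corruption = "hair"}; \code{NULL}
#'   draws uniformly from 15..25 (the heavy-occlusion regime).
#' @return the manifest as a data.frame, invisibly.
#' @export
generateCorpus <- function(nPerClass, corruption = c("none", "hair", "noise"),
                           outDir, seed = 1L, size = 64L, sigma = NULL,
                           nHairs = NULL) {
  corruption <- match.arg(corruption)
  dir.create(file.path(outDir, "clean"), recursive = TRUE, showWarnings = FALSE)
  if (corruption != "none")
    dir.create(file.path(outDir, "corrupted"), showWarnings = FALSE)
  if (corruption == "hair")
    dir.create(file.path(outDir, "masks"), showWarnings = FALSE)
  n <- 7L * nPerClass
  seeds <- derive_seeds(seed, 3L * n)
  rows <- vector("list", n)
  idx <- 0L
  for (cls in 0:6) {
    for (k in seq_len(nPerClass)) {
      idx <- idx + 1L
      s_img <- seeds[idx]; s_cor <- seeds[n + idx]; s_par <- seeds[2L * n + idx]
      ph <- generateLesionPhantom(cls, size = size, seed = s_img)
      fname <- sprintf("%04d.png", idx)
      writeRaster(ph$image, file.path(outDir, "clean", fname))
      sig <- NA_real_; nh <- NA_integer_
      if (corruption == "noise") {
        sig <- if (is.null(sigma)) with_seed(s_par, stats::runif(1, 1, 30))
        else sigma
        noisy <- addGaussianNoise(ph$image, sig, seed = s_cor)
        writeRaster(noisy, file.path(outDir, "corrupted", fname))
      } else if (corruption == "hair") {
        nh <- if (is.null(nHairs)) with_seed(s_par, sample(15:25, 1))
        else as.integer(nHairs)
        pair <- drawProceduralHairs(ph$image, hairParams(nHairs = nh,
                                                         seed = s_cor))
        writeRaster(pair$corrupted, file.path(outDir, "corrupted", fname))
        writeMask(pair$truthMask, file.path(outDir, "masks", fname))
      }
      rows[[idx]] <- data.frame(file = fname, label = cls,
                                corruption = corruption, sigma = sig,
                                n_hairs = nh, seed = s_cor)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
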