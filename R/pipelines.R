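# End-to-end restoration pipelines: dehairing (blur -> grayscale -> blackhat
# -> threshold -> fast-marching inpainting) and denoising (CIELAB non-local
# means), over single images and whole corpora, with restoration-quality
# reporting.

#' Dehairing pipeline configuration
#'
#' @param blurKernel odd Gaussian kernel size (default 3).
#' @param blurSigma Gaussian sigma; derived from the kernel size when
#'   \code{NULL}.
#' @param medianKernel odd median kernel size (default 3).
#' @param seSize structuring-element side (default 11, the cross).
#' @param thresh blackhat threshold (default 10).
#' @param maxval threshold export value (default 255).
#' @param inpaintRadius Chebyshev radius eps of the inpainting neighbourhood
#'   (default 1).
#' @param inpaintSource \code{"blurred"} (default): inpaint the
#'   median-blurred image, the literal pipeline; \code{"original"}:
#'   transplant only the on-mask inpainted values into the unblurred input,
#'   which avoids softening the lesion off-mask.
#' @param maskDilate optional dilation (in pixels) of the detected mask
#'   before inpainting, for 1-px hair halos; 0 disables (default).
#' @return a list of class \code{DehairConfig}.
#' @export
dehairConfig <- function(blurKernel = 3L, blurSigma = NULL,
                         medianKernel = 3L, seSize = 11L, thresh = 10,
                         maxval = 255, inpaintRadius = 1,
                         inpaintSource = c("blurred", "original"),
                         maskDilate = 0L) {
  inpaintSource <- match.arg(inpaintSource)
  stopifnot(thresh < maxval, inpaintRadius >= 1)
  structure(list(blurKernel = odd_check(blurKernel, "blur kernel"),
                 blurSigma = blurSigma,
                 medianKernel = odd_check(medianKernel, "median kernel"),
                 seSize = odd_check(seSize, "structuring element size"),
                 thresh = thresh, maxval = maxval,
                 inpaintRadius = inpaintRadius,
                 inpaintSource = inpaintSource,
                 maskDilate = as.integer(maskDilate)),
            class = "DehairConfig")
}

#' Remove hair from a dermoscopic image
#'
#' The full dehairing pipeline: Gaussian blur, median blur, grayscale
#' conversion, blackhat under a cross structuring element, binary threshold,
#' then fast-marching inpainting of the detected mask. The mask is returned
#' alongside the restored image for auditing. On a hair-free constant image
#' the mask is empty and the output equals the blurred input.
#'
#' @param image a \code{RasterImage} (or H x W x 3 array).
#' @param cfg a \code{\link{dehairConfig}}.
#' @return a list with \code{restored} (\code{RasterImage}) and \code{mask}
#'   (\code{BinaryMask}).
#' @examples
#' ph <- generateLesionPhantom(0, size = 48, seed = 7)$image
#' pair <- drawProceduralHairs(ph, hairParams(nHairs = 8, seed = 3))
#' out <- dehairInpainted(pair$corrupted)
#' @export
dehairInpainted <- function(image, cfg = dehairConfig()) {
  img <- RasterImage(as_rgb_array(image))
  gb <- gaussianBlur(img, cfg$blurKernel, cfg$blurSigma)
  mb <- medianBlur(gb, cfg$medianKernel)
  gray <- toGrayscale(mb)
  bh <- blackhat(gray, makeCrossElement(cfg$seSize))
  mask <- thresholdBinary(bh, cfg$thresh, cfg$maxval)
  if (cfg$maskDilate > 0) {
    k <- 2L * cfg$maskDilate + 1L
    mask <- BinaryMask(pixelValues(dilateGray(pixelValues(mask) * 1,
                                              matrix(TRUE, k, k))) > 0)
  }
  if (all(pixelValues(mask))) # degenerate detection; nothing known to copy
    stop("detected mask covers the whole image; lower thresh or inspect input")
  if (!any(pixelValues(mask))) {
    restored <- if (cfg$inpaintSource == "blurred") mb else img
    return(list(restored = restored, mask = mask))
  }
  inp <- inpaintImage(mb, mask, eps = cfg$inpaintRadius)
  restored <- if (cfg$inpaintSource == "blurred") inp else {
    a <- as_rgb_array(img); b <- pixelValues(inp)
    m <- pixelValues(mask)
    for (ch in 1:3) {
      pl <- a[, , ch]; src <- b[, , ch]
      pl[m] <- src[m]
      a[, , ch] <- pl
    }
    RasterImage(a)
  }
  list(restored = restored, mask = mask)
}

#' Denoise a dermoscopic image
#'
#' Thin pipeline wrapper over \code{\link{nlMeansColored}}: CIELAB split,
#' luminance and chroma denoised separately.
#'
#' @param image a \code{RasterImage}.
#' @param params an \code{\link{nlMeansParams}}.
#' @return a denoised \code{RasterImage}.
#' @export
denoiseImage <- function(image, params = nlMeansParams()) {
  nlMeansColored(image, params)
}

#' Restoration quality metrics for one image
#'
#' @param restored,corrupted \code{RasterImage}s; \code{clean} the ground
#'   truth. All shapes must agree.
#' @param clean ground-truth \code{RasterImage}, or \code{NULL} when
#'   unavailable (MAE columns become \code{NA}).
#' @param truthMask ground-truth \code{BinaryMask} or \code{NULL};
#' @param detectedMask the pipeline's detected \code{BinaryMask} or
#'   \code{NULL}.
#' @return a one-row data.frame with columns maskArea (fraction), mae,
#'   maeCorrupted, maeOnMask and dice.
#' @export
restorationMetrics <- function(restored, corrupted, clean = NULL,
                               truthMask = NULL, detectedMask = NULL) {
  r <- as_rgb_array(restored); cpt <- as_rgb_array(corrupted)
  if (!all(dim(r) == dim(cpt))) stop("image shapes differ")
  mae <- maeC <- maeMask <- NA_real_
  if (!is.null(clean)) {
    cl <- as_rgb_array(clean)
    if (!all(dim(cl) == dim(r))) stop("image shapes differ")
    mae <- mean(abs(r - cl))
    maeC <- mean(abs(cpt - cl))
    if (!is.null(truthMask)) {
      m <- as_mask_matrix(truthMask)
      if (any(m)) {
        sel <- array(m, dim = dim(r))
        maeMask <- mean(abs(r[sel] - cl[sel]))
      }
    }
  }
  dice <- NA_real_
  maskArea <- NA_real_
  if (!is.null(detectedMask)) {
    dm <- as_mask_matrix(detectedMask)
    maskArea <- mean(dm)
    if (!is.null(truthMask)) dice <- diceCoefficient(detectedMask, truthMask)
  }
  data.frame(maskArea = maskArea, mae = mae, maeCorrupted = maeC,
             maeOnMask = maeMask, dice = dice)
}

#' Dice overlap between two masks
#'
#' \code{2 |A intersect B| / (|A| + |B|)}; defined as \code{NA} when both
#' masks are empty.
#'
#' @param a,b \code{BinaryMask}s or logical matrices of the same shape.
#' @return a scalar in [0, 1], or \code{NA}.
#' @export
diceCoefficient <- function(a, b) {
  ma <- as_mask_matrix(a); mb <- as_mask_matrix(b)
  if (!all(dim(ma) == dim(mb))) stop("mask shapes differ")
  tot <- sum(ma) + sum(mb)
  if (tot == 0) return(NA_real_)
  2 * sum(ma & mb) / tot
}

#' Process a corpus manifest through a restoration pipeline
#'
#' Reads \code{manifest.csv} as written by \code{\link{generateCorpus}},
#' restores every corrupted image (\code{mode = "dehair"} or
#' \code{"denoise"}), resizes restored images to
#' \code{resize x resize}, writes them under \code{outDir/restored/} with an
#' output manifest, and computes per-image restoration metrics wherever the
#' clean truth exists. Missing or unreadable files are recorded and skipped;
#' the run continues deterministically in manifest order.
#'
#' @param corpusDir directory containing \code{manifest.csv} and the image
#'   trees.
#' @param mode \code{"dehair"} or \code{"denoise"}.
#' @param outDir output directory.
#' @param cfg a \code{\link{dehairConfig}} (dehair mode) or
#'   \code{\link{nlMeansParams}} (denoise mode).
#' @param resize output side length in pixels; \code{NULL} keeps native
#'   resolution. Restoration always runs at native resolution first.
#' @return a list with \code{report} (per-image metrics data.frame) and
#'   \code{failures} (character vector of files that could not be
#'   processed).
#' @export
processCorpus <- function(corpusDir, mode = c("dehair", "denoise"),
                          outDir, cfg = NULL, resize = NULL) {
  mode <- match.arg(mode)
  if (is.null(cfg)) cfg <- if (mode == "dehair") dehairConfig()
  else nlMeansParams()
  man <- utils::read.csv(file.path(corpusDir, "manifest.csv"))
  dir.create(file.path(outDir, "restored"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list(); failures <- character(0)
  for (k in seq_len(nrow(man))) {
    f <- man$file[k]
    src <- file.path(corpusDir, "corrupted", f)
    if (!file.exists(src)) src <- file.path(corpusDir, "clean", f)
    res <- tryCatch({
      img <- readRaster(src)
      if (mode == "dehair") {
        out <- dehairInpainted(img, cfg)
        restored <- out$restored; dmask <- out$mask
      } else {
        restored <- denoiseImage(img, cfg); dmask <- NULL
      }
      cleanPath <- file.path(corpusDir, "clean", f)
      clean <- if (file.exists(cleanPath)) readRaster(cleanPath) else NULL
      maskPath <- file.path(corpusDir, "masks", f)
      tmask <- if (file.exists(maskPath)) readMask(maskPath) else NULL
      met <- restorationMetrics(restored, img, clean, tmask, dmask)
      if (!is.null(resize)) restored <- resizeImage(restored, resize, resize)
      writeRaster(restored, file.path(outDir, "restored", f))
      cbind(data.frame(file = f, label = man$label[k]), met)
    }, error = function(e) {
      warning("failed on ", f, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, f) else
      rows[[length(rows) + 1L]] <- res
  }
  report <- if (length(rows)) do.call(rbind, rows) else NULL
  utils::write.csv(report, file.path(outDir, "report.csv"), row.names = FALSE)
  list(report = report, failures = failures)
}
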