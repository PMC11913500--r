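test_that("PNG write/read round trip is bit-exact for u8 data", {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))

  img1 <- RasterImage(array(255, dim = c(1, 1, 3)))
  writeRaster(img1, f)
  expect_equal(pixelValues(readRaster(f)), array(255, dim = c(1, 1, 3)))

  writeRaster(array(0, dim = c(2, 2, 3)), f)
  back <- readRaster(f)
  expect_equal(dim(pixelValues(back)), c(2L, 2L, 3L))
  expect_true(all(pixelValues(back) == 0))

  a <- round(random_rgb(13, 9, seed = 11))
  writeRaster(a, f)
  expect_identical(pixelValues(readRaster(f)), a)
})

test_that("writing quantises: fractional values round and clip", {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  a <- array(128, dim = c(3, 3, 3))
  a[1, 1, ] <- 254.9 # rounds to 255
  a[2, 2, ] <- 0.4   # rounds to 0
  writeRaster(a, f)
  b <- pixelValues(readRaster(f))
  expect_equal(b[1, 1, 1], 255)
  expect_equal(b[2, 2, 1], 0)
  expect_equal(b[3, 3, 1], 128)
})

test_that("grayscale PNGs broadcast to three identical channels", {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  m <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  writeMask(m, f) # single-channel 0/1 PNG
  img <- pixelValues(readRaster(f))
  expect_equal(dim(img), c(2L, 2L, 3L))
  expect_equal(img[, , 1], img[, , 2])
  expect_equal(img[, , 1], img[, , 3])
  expect_equal(img[, , 1], m * 255)
})

test_that("missing and undecodable files raise errors", {
  expect_error(readRaster(tempfile(fileext = ".png")), "not found")
  bad <- tempfile(fileext = ".png")
  writeLines("this is not an image", bad)
  on.exit(unlink(bad))
  expect_error(readRaster(bad))
})

test_that("grayscale conversion uses Rec. 601 weights", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(pixelValues(toGrayscale(px(255, 255, 255)))[1, 1], 255)
  expect_equal(pixelValues(toGrayscale(px(0, 0, 0)))[1, 1], 0)
  expect_equal(pixelValues(toGrayscale(px(255, 0, 0)))[1, 1], 76)
  # R = G = B maps to the channel value exactly, for every level
  a <- array(rep(0:255, 3), dim = c(16, 16, 3))
  expect_equal(pixelValues(toGrayscale(a)), matrix(0:255, 16, 16))
})

test_that("CIELAB conversion agrees with the reference converter", {
  white <- pixelValues(rgbToLab(array(255, dim = c(1, 1, 3))))[1, 1, ]
  expect_equal(white[1], 100, tolerance = 1e-6)
  expect_lt(max(abs(white[2:3])), 0.5)
  black <- pixelValues(rgbToLab(array(0, dim = c(1, 1, 3))))[1, 1, ]
  expect_equal(black[1], 0, tolerance = 1e-6)

  # independent oracle: grDevices::convertColor, D65 (its sRGB curve
  # differs in the last decimals, so agreement is asserted to 0.5 Lab units)
  set.seed(42)
  rgb <- matrix(runif(300, 0, 255), ncol = 3)
  ours <- pixelValues(rgbToLab(array(rgb, dim = c(100, 1, 3))))
  ref <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  expect_lt(max(abs(matrix(ours, ncol = 3) - ref)), 0.5)

  gray <- pixelValues(rgbToLab(array(119, dim = c(1, 1, 3))))[1, 1, ]
  expect_lt(max(abs(gray[2:3])), 1e-4)
})

test_that("Lab round trip is within one intensity level for in-gamut colors", {
  a <- random_rgb(40, 25, seed = 3) # 1000 random pixels
  back <- pixelValues(labToRgb(rgbToLab(a)))
  expect_lt(max(abs(back - a)), 1)
  expect_equal(pixelValues(labToRgb(LabImage(array(c(100, 0, 0),
                                                   dim = c(1, 1, 3)))))[1, 1, ],
               c(255, 255, 255), tolerance = 1e-4)
  expect_equal(pixelValues(labToRgb(LabImage(array(0, dim = c(1, 1, 3)))))[1, 1, ],
               c(0, 0, 0), tolerance = 1e-6)
})

test_that("bilinear resize matches the closed-form sample and is convex", {
  a <- random_rgb(7, 5, seed = 9)
  expect_equal(pixelValues(resizeImage(a, 7, 5)), a)

  const <- array(77, dim = c(4, 6, 3))
  big <- pixelValues(resizeImage(const, 9, 13))
  expect_equal(big, array(77, dim = c(9, 13, 3)), tolerance = 1e-12)

  chk <- array(0, dim = c(2, 2, 3))
  chk[1, 2, ] <- 255; chk[2, 1, ] <- 255
  out <- pixelValues(resizeImage(chk, 4, 4))
  for (i in 1:4) for (j in 1:4) {
    sy <- (i - 0.5) * 2 / 4 - 0.5; sx <- (j - 0.5) * 2 / 4 - 0.5
    expect_equal(out[i, j, 1], oracle_bilinear(chk[, , 1], sy, sx))
  }

  r <- pixelValues(resizeImage(a, 11, 17))
  expect_gte(min(r), min(a) - 1e-9)
  expect_lte(max(r), max(a) + 1e-9)
  expect_error(resizeImage(a, 0, 5), "positive")
})

test_that("image classes validate their invariants", {
  expect_error(RasterImage(array(300, dim = c(2, 2, 3))), "255")
  expect_error(RasterImage(array(NA_real_, dim = c(2, 2, 3))), "finite")
  expect_error(RasterImage(array(0, dim = c(2, 2, 2))), "H x W x 3")
  expect_error(GrayImage(matrix(-5, 2, 2)), "255")
  m <- BinaryMask(matrix(c(TRUE, FALSE), 2, 2))
  expect_identical(dim(pixelValues(m)), c(2L, 2L))
  expect_output(show(m), "BinaryMask 2 x 2")
})
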