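test_that("gaussian noise: identity at sigma 0, calibrated statistics, seeded", {
  img <- RasterImage(array(128, dim = c(50, 50, 3)))
  expect_identical(pixelValues(addGaussianNoise(img, 0)), pixelValues(img))
  expect_error(addGaussianNoise(img, -1), "non-negative")

  big <- RasterImage(array(128, dim = c(183, 183, 3))) # ~1e5 px
  noisy <- addGaussianNoise(big, 15, seed = 7)
  resid <- pixelValues(noisy) - 128
  expect_lt(abs(mean(resid)), 0.15)
  expect_lt(abs(sd(resid) - 15), 0.75)

  again <- addGaussianNoise(big, 15, seed = 7)
  expect_identical(pixelValues(noisy), pixelValues(again))
  # clipping keeps the range legal even at extreme sigma
  dark <- addGaussianNoise(RasterImage(array(2, dim = c(20, 20, 3))), 30,
                           seed = 1)
  expect_gte(min(pixelValues(dark)), 0)
})

test_that("procedural hairs: localisation, counts, determinism", {
  ph <- generateLesionPhantom(2, size = 64, seed = 5)$image
  pr0 <- drawProceduralHairs(ph, hairParams(nHairs = 0, seed = 1))
  expect_identical(pixelValues(pr0$corrupted), pixelValues(ph))
  expect_false(any(pixelValues(pr0$truthMask)))

  pr <- drawProceduralHairs(ph, hairParams(nHairs = 5, thicknessRange = c(2, 2),
                                           seed = 11))
  m <- pixelValues(pr$truthMask)
  expect_true(any(m))
  # corruption exactly localised to the mask
  sel <- rep(!m, 3)
  expect_identical(pixelValues(pr$corrupted)[sel], pixelValues(ph)[sel])
  # non-touching strands: one component per hair
  expect_equal(max(labelComponents(m)), 5)
  # determinism
  pr2 <- drawProceduralHairs(ph, hairParams(nHairs = 5,
                                            thicknessRange = c(2, 2),
                                            seed = 11))
  expect_identical(pixelValues(pr$corrupted), pixelValues(pr2$corrupted))
  expect_identical(pixelValues(pr$truthMask), pixelValues(pr2$truthMask))
})

test_that("hair-mask extraction recovers the planted strands", {
  ph <- generateLesionPhantom(4, size = 64, seed = 9)$image
  # hair-free image: empty mask after the speckle guard
  empty <- extractHairMask(RasterImage(array(180, dim = c(64, 64, 3))))
  expect_false(any(pixelValues(empty)))

  pr <- drawProceduralHairs(ph, hairParams(nHairs = 10, seed = 23))
  det <- extractHairMask(pr$corrupted)
  expect_gte(diceCoefficient(det, pr$truthMask), 0.6)
  expect_lt(mean(pixelValues(det)), 1) # strictly less than the image area
})

test_that("donor superimposition is a hard masked replacement", {
  clean <- RasterImage(random_rgb(12, 12, 1))
  donor <- RasterImage(random_rgb(12, 12, 2))
  m <- matrix(FALSE, 12, 12); m[4, ] <- TRUE
  pair <- superimposeHair(clean, donor, m)
  out <- pixelValues(pair$corrupted)
  expect_identical(out[4, , ], pixelValues(donor)[4, , ])
  expect_identical(out[-4, , ], pixelValues(clean)[-4, , ])
  e <- superimposeHair(clean, donor, matrix(FALSE, 12, 12))
  expect_identical(pixelValues(e$corrupted), pixelValues(clean))
  expect_error(superimposeHair(clean, RasterImage(random_rgb(10, 10, 3)), m),
               "differ")
})

test_that("lesion phantoms are class-coloured, seeded, in-frame", {
  ph <- generateLesionPhantom(1, size = 64, seed = 3, textureScale = 0)
  expect_equal(ph$label, 1L)
  a <- pixelValues(ph$image)
  centre <- a[28:36, 28:36, ] # inside the lesion
  border <- a[1:4, 1:4, ]     # skin background
  lesion_col <- c(45, 38, 40); skin <- c(224, 172, 150)
  mc <- apply(centre, 3, mean); mb <- apply(border, 3, mean)
  expect_lt(sum((mc - lesion_col)^2), sum((mc - skin)^2))
  expect_lt(sum((mb - skin)^2), sum((mb - lesion_col)^2))
  ph2 <- generateLesionPhantom(1, size = 64, seed = 3, textureScale = 0)
  expect_identical(a, pixelValues(ph2$image))
  expect_error(generateLesionPhantom(7, size = 64), "classId")
})

test_that("mean lesion color separates the seven classes by nearest centroid", {
  n_per <- 8
  feats <- NULL; labs <- integer(0)
  for (cls in 0:6) for (k in seq_len(n_per)) {
    ph <- generateLesionPhantom(cls, size = 48, seed = 500 + cls * 100 + k)
    a <- pixelValues(ph$image)
    feats <- rbind(feats, apply(a[20:28, 20:28, ], 3, mean))
    labs <- c(labs, cls)
  }
  centroids <- t(sapply(0:6, function(cl)
    colMeans(feats[labs == cl, , drop = FALSE])))
  pred <- apply(feats, 1, function(f)
    which.min(colSums((t(centroids) - f)^2)) - 1L)
  expect_gte(mean(pred == labs), 0.95)
})

test_that("corpus generation writes a complete, reproducible tree", {
  d1 <- file.path(tempdir(), "corpus_a")
  d2 <- file.path(tempdir(), "corpus_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE))

  man <- generateCorpus(2, "none", d1, seed = 42, size = 32)
  expect_equal(nrow(man), 14)
  expect_equal(length(list.files(file.path(d1, "clean"))), 14)
  expect_false(dir.exists(file.path(d1, "masks")))

  unlink(d1, recursive = TRUE)
  man_n <- generateCorpus(1, "noise", d1, seed = 42, size = 32)
  expect_false(dir.exists(file.path(d1, "masks")))
  expect_true(all(man_n$sigma >= 1 & man_n$sigma <= 30))

  unlink(d1, recursive = TRUE)
  generateCorpus(1, "hair", d1, seed = 7, size = 48)
  generateCorpus(1, "hair", d2, seed = 7, size = 48)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
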