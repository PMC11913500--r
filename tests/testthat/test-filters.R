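test_that("gaussian kernel is normalised and centre-heavy", {
  k <- gaussianKernel(3)
  expect_equal(sum(k), 1, tolerance = 1e-9)
  expect_gt(k[2], k[1])
  expect_equal(k[1], k[3])
  expect_error(gaussianKernel(4), "odd")
})

test_that("gaussian blur matches dense 2-D convolution and preserves means", {
  k <- gaussianKernel(3)
  kern2 <- outer(k, k)
  for (seed in 1:5) {
    m <- random_gray(16, 16, seed)
    ours <- pixelValues(gaussianBlur(GrayImage(m), 3))
    expect_lt(max(abs(ours - oracle_conv2(m, kern2))), 1e-9)
  }
  # impulse response equals the kernel
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  expect_lt(max(abs(pixelValues(gaussianBlur(imp, 3)) -
                      oracle_conv2(imp, kern2))), 1e-12)
  # constant image unchanged; reflect padding preserves the mean
  cst <- matrix(42, 8, 8)
  expect_equal(pixelValues(gaussianBlur(cst, 5)), cst)
  m <- random_gray(20, 20, 77)
  expect_equal(mean(pixelValues(gaussianBlur(m, 3))), mean(m),
               tolerance = 1e-6)
  expect_error(gaussianBlur(m, 4), "odd")
})

test_that("median blur matches the brute-force median", {
  for (seed in 1:5) {
    m <- random_gray(16, 16, seed)
    expect_equal(pixelValues(medianBlur(GrayImage(m), 3)), oracle_median(m, 3))
  }
  cst <- matrix(7, 6, 6)
  expect_equal(pixelValues(medianBlur(cst, 3)), cst)
  # single salt pixel is removed
  salt <- matrix(0, 8, 8); salt[4, 5] <- 255
  expect_true(all(pixelValues(medianBlur(salt, 3)) == 0))
  # a straight step edge survives
  step <- matrix(rep(c(0, 200), each = 32), 8, 8)
  expect_equal(pixelValues(medianBlur(step, 3)), step)
})

test_that("cross element has the documented shape", {
  se3 <- pixelValues(makeCrossElement(3))
  expect_equal(sum(se3), 5)
  expect_true(all(se3[2, ]) && all(se3[, 2]))
  expect_equal(sum(pixelValues(makeCrossElement(11))), 21)
  expect_equal(sum(pixelValues(makeCrossElement(1))), 1)
  expect_error(makeCrossElement(4), "odd")
})

test_that("dilate/erode match double-loop oracles", {
  se <- pixelValues(makeCrossElement(3))
  for (seed in 1:5) {
    m <- random_gray(8, 8, seed)
    expect_equal(pixelValues(dilateGray(m, se)), oracle_morph(m, se, max))
    expect_equal(pixelValues(erodeGray(m, se)), oracle_morph(m, se, min))
  }
  cst <- matrix(9, 5, 5)
  expect_equal(pixelValues(dilateGray(cst, se)), cst)
  expect_equal(pixelValues(erodeGray(cst, se)), cst)
  # single bright pixel dilates into a plus sign
  m <- matrix(0, 7, 7); m[4, 4] <- 100
  d <- pixelValues(dilateGray(m, se))
  expect_equal(sum(d > 0), 5)
  expect_equal(d[4, 3], 100)
})

test_that("closing is extensive and idempotent; blackhat is its residue", {
  se <- pixelValues(makeCrossElement(5))
  for (seed in 1:8) {
    m <- random_gray(16, 16, seed)
    cl <- pixelValues(morphClose(m, se))
    expect_true(all(cl - m >= -1e-12))          # extensive
    expect_equal(pixelValues(morphClose(cl, se)), cl) # idempotent
    bh <- pixelValues(blackhat(m, se))
    expect_equal(bh, oracle_blackhat(m, se))
    expect_gte(min(bh), 0)
  }
  expect_true(all(pixelValues(blackhat(matrix(50, 9, 9), se)) == 0))
})

test_that("blackhat responds to a thin dark line and thresholding isolates it", {
  m <- matrix(200, 16, 16)
  m[, 8] <- 40 # 1-px dark vertical line
  se <- pixelValues(makeCrossElement(11))
  bh <- pixelValues(blackhat(GrayImage(m), se))
  expect_equal(bh, oracle_blackhat(m, se))
  expect_true(all(bh[, 8] > 100))
  mask <- pixelValues(thresholdBinary(bh, 10))
  expect_true(all(mask[, 8]))
  expect_true(mean(mask) < 0.25)
})

test_that("blackhat is translation-equivariant away from borders", {
  se <- pixelValues(makeCrossElement(3))
  base <- matrix(150, 20, 20)
  base[8:12, 9] <- 30
  shifted <- matrix(150, 20, 20)
  shifted[10:14, 11] <- 30
  a <- pixelValues(blackhat(base, se))
  b <- pixelValues(blackhat(shifted, se))
  expect_equal(a[5:15, 5:15], b[7:17, 7:17])
})

test_that("threshold uses strict inequality and validates arguments", {
  m <- matrix(c(0, 10, 10.5, 255), 2, 2)
  mask <- pixelValues(thresholdBinary(m, 10))
  expect_identical(as.vector(mask), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(!any(pixelValues(thresholdBinary(matrix(0, 3, 3), 10))))
  expect_error(thresholdBinary(m, 255, 255), "thresh")
  expect_error(thresholdBinary(m, -1), "thresh")
})

test_that("connected components: 8-connectivity labelling", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # diagonal touch: one component
  m[5, 5] <- TRUE                    # isolated: second component
  lab <- labelComponents(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1])
})
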