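test_that("relu, softmax and cross-entropy closed forms", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_true(all(relu(c(-5, -0.1)) == 0))
  x <- rnorm(10)
  expect_equal(relu(relu(x)), relu(x))

  s <- softmax(rep(0, 7))
  expect_equal(s, rep(1 / 7, 7))
  z <- c(0.3, -1, 2)
  expect_equal(softmax(z), softmax(z + 5), tolerance = 1e-12)
  expect_equal(softmax(log(1:3)), c(1, 2, 3) / 6)
  # matrix form: rows sum to 1, order preserved
  m <- matrix(rnorm(21), 3, 7)
  sm <- softmax(m)
  expect_equal(rowSums(sm), rep(1, 3), tolerance = 1e-9)
  expect_equal(apply(sm, 1, which.max), apply(m, 1, which.max))

  perfect <- diag(7)
  expect_equal(categoricalCrossEntropy(perfect, 0:6), 0, tolerance = 1e-10)
  uniform <- matrix(1 / 7, 4, 7)
  expect_equal(categoricalCrossEntropy(uniform, c(0, 3, 5, 6)), log(7))
  half <- matrix(c(0.5, 0.5, 0, 0, 0, 0, 0), 1, 7)
  expect_equal(categoricalCrossEntropy(half, 0L), log(2))
  expect_error(categoricalCrossEntropy(matrix(0.9, 2, 7), 0:1), "sum to 1")
})

test_that("accuracy counts argmax matches with deterministic tie-breaks", {
  pred <- diag(4)
  expect_equal(accuracyScore(pred, 0:3), 1)
  expect_equal(accuracyScore(pred, c(1, 0, 3, 2)), 0)
  expect_equal(accuracyScore(pred, c(0, 1, 3, 2)), 0.5)
  ties <- matrix(1, 2, 3) # all equal: argmax is class 0
  expect_equal(accuracyScore(ties, c(0, 1)), 0.5)
})

test_that("the split is a stratified, seeded partition", {
  labels <- rep(0:6, each = 10)
  sp <- splitDataset(labels, 0.8, seed = 3)
  expect_equal(length(sp$train), 56)
  expect_equal(length(sp$val), 14)
  expect_equal(sort(c(sp$train, sp$val)), seq_along(labels))
  expect_equal(length(intersect(sp$train, sp$val)), 0)
  # stratification: 8 train / 2 val in every class
  expect_true(all(table(labels[sp$train]) == 8))
  expect_identical(splitDataset(labels, 0.8, seed = 3), sp)
  expect_false(identical(splitDataset(labels, 0.8, seed = 4)$train, sp$train))
  expect_error(splitDataset(integer(0)), "class")
})

test_that("the head has the right parameter count and valid outputs", {
  bb <- identityBackbone(64)
  head <- attachHead(bb, 7, seed = 1)
  expect_equal(length(head$W) + length(head$b), 64 * 7 + 7)
  X <- matrix(rnorm(5 * 64), 5, 64)
  P <- predictHead(head, X)
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-9)
  expect_true(all(P >= 0 & P <= 1))
})

test_that("the frozen backbone yields identical features before/after training", {
  bb <- tinyCnnBackbone(seed = 2, channels = c(4L, 8L, 8L))
  img <- generateLesionPhantom(0, size = 32, seed = 1)$image
  f_before <- bb$featureFn(img)
  labels <- rep(0:6, each = 4)
  imgs <- lapply(seq_along(labels), function(i)
    generateLesionPhantom(labels[i], size = 32, seed = i)$image)
  feats <- computeFeatures(bb, imgs)
  sp <- splitDataset(labels, 0.8, seed = 1)
  invisible(trainHead(attachHead(bb, 7, seed = 1), feats, labels, sp,
                      trainConfig(epochs = 2)))
  expect_identical(bb$featureFn(img), f_before)
  expect_equal(dim(feats), c(length(labels), 8L))
})

test_that("a linearly separable toy problem is learned to high accuracy", {
  set.seed(5)
  n_per <- 40
  centers <- matrix(c(0, 0, 4, 0, 0, 4), 3, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per, centers[k, 1], 0.5), rnorm(n_per, centers[k, 2], 0.5))))
  y <- rep(0:2, each = n_per)
  bb <- identityBackbone(2)
  sp <- splitDataset(y, 0.8, seed = 2)
  fit <- trainHead(attachHead(bb, 3, seed = 2),
                   X, y, sp, trainConfig(epochs = 25, nClasses = 3, seed = 2))
  expect_gte(fit$metrics$TAcc[25], 0.95)
  expect_equal(nrow(fit$metrics), 25)
  expect_true(all(c("TAcc", "TLoss", "VAcc", "VLoss") %in%
                    colnames(fit$metrics)))
})

test_that("training is seed-deterministic and label shuffling kills skill", {
  labels <- rep(0:6, each = 8)
  imgs <- lapply(seq_along(labels), function(i)
    generateLesionPhantom(labels[i], size = 32, seed = 300 + i)$image)
  bb <- tinyCnnBackbone(seed = 3, channels = c(4L, 8L, 16L))
  feats <- computeFeatures(bb, imgs)
  sp <- splitDataset(labels, 0.8, seed = 4)
  cfg <- trainConfig(epochs = 10, seed = 4)
  f1 <- trainHead(attachHead(bb, 7, seed = 4), feats, labels, sp, cfg)
  f2 <- trainHead(attachHead(bb, 7, seed = 4), feats, labels, sp, cfg)
  expect_identical(f1$metrics, f2$metrics)

  # no-leakage control: shuffled labels give chance-level validation accuracy
  shuffled <- with(list(), {set.seed(11); sample(labels)})
  sp2 <- splitDataset(shuffled, 0.8, seed = 4)
  f3 <- trainHead(attachHead(bb, 7, seed = 4), feats, shuffled, sp2,
                  trainConfig(epochs = 25, seed = 4))
  n_val <- length(sp2$val)
  se <- sqrt((1 / 7) * (6 / 7) / n_val)
  expect_lte(f3$metrics$VAcc[25], 1 / 7 + 3 * se)
})

test_that("identical variants produce identical experiment columns", {
  labels <- rep(0:6, each = 3)
  imgs <- lapply(seq_along(labels), function(i)
    generateLesionPhantom(labels[i], size = 32, seed = 600 + i)$image)
  res <- runExperiment(list(a = imgs, b = imgs), labels,
                       backbone = tinyCnnBackbone(seed = 1,
                                                  channels = c(4L, 8L, 8L)),
                       cfg = trainConfig(epochs = 3), seeds = 1:2)
  a <- subset(res, variant == "a")[, -1]
  b <- subset(res, variant == "b")[, -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})
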