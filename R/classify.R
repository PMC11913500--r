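# Backbone-agnostic transfer-learning harness: a frozen feature extractor,
# a trainable fully connected softmax head for the seven lesion classes,
# and an Adam training loop reporting training/validation accuracy and loss
# per epoch. The reference backbone is a small fixed-random-weight
# three-block CNN so the whole harness runs offline on one CPU.

#' Rectified linear unit
#'
#' Elementwise \code{max(0, x)}; idempotent.
#'
#' @param x numeric vector, matrix or array.
#' @return same shape as \code{x}.
#' @export
relu <- function(x) pmax(x, 0)

#' Softmax over logits
#'
#' Row-wise for matrices. Computed as \code{exp(z - max z)} normalised, so
#' it is invariant to adding a constant to all logits and numerically safe.
#'
#' @param logits numeric vector, or matrix with one row per sample.
#' @return probabilities of the same shape, each (row) summing to 1.
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

# labels (0-based integers) -> one-hot matrix
one_hot <- function(labels, nClasses) {
  n <- length(labels)
  m <- matrix(0, n, nClasses)
  m[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  m
}

#' Categorical cross-entropy
#'
#' Mean over samples of \code{-sum_c truth_c * log(pred_c)}, with predicted
#' probabilities clipped to [1e-12, 1] before the log. The uniform predictor
#' over K classes scores exactly \code{log(K)}.
#'
#' @param pred matrix of predicted probabilities (rows sum to 1 within
#'   1e-6), or a vector for a single sample.
#' @param truth one-hot matrix of the same shape, or 0-based integer labels.
#' @return a non-negative scalar.
#' @export
categoricalCrossEntropy <- function(pred, truth) {
  if (!is.matrix(pred)) pred <- matrix(pred, nrow = 1)
  if (!is.matrix(truth)) truth <- one_hot(truth, ncol(pred))
  if (!all(dim(pred) == dim(truth))) stop("pred/truth shapes differ")
  if (any(abs(rowSums(pred) - 1) > 1e-6))
    stop("predicted rows must sum to 1")
  p <- pmin(pmax(pred, 1e-12), 1)
  mean(-rowSums(truth * log(p)))
}

#' Classification accuracy
#'
#' Fraction of samples whose argmax prediction matches the label; argmax
#' ties are broken by the lowest class index, deterministically.
#'
#' @param pred matrix of per-class scores or probabilities, one row per
#'   sample.
#' @param truth 0-based integer labels.
#' @return a fraction in [0, 1].
#' @export
accuracyScore <- function(pred, truth) {
  if (!is.matrix(pred)) pred <- matrix(pred, nrow = 1)
  if (nrow(pred) != length(truth)) stop("pred/truth lengths differ")
  mean(max.col(pred, ties.method = "first") - 1L == as.integer(truth))
}

#' Stratified train/validation split
#'
#' Splits sample indices into disjoint, exhaustive train and validation
#' sets, stratified by class, deterministically for a given seed. The
#' validation share plays the role of the held-out 20 percent test split.
#'
#' @param labels 0-based integer class labels.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return a list with integer index vectors \code{train} and \code{val}.
#' @export
splitDataset <- function(labels, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 1)
    stop("every class must have at least one sample")
  tr <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      if (length(idx) < 1) stop("empty class ", cl)
      ntr <- max(1L, round(fraction * length(idx)))
      tr <- c(tr, sort(sample(idx, ntr)))
    }
  })
  tr <- sort(tr)
  list(train = tr, val = setdiff(seq_along(labels), tr))
}

# zero-padded 3x3 convolution: input H x W x Cin, weights 3 x 3 x Cin x Cout
conv3x3 <- function(x, W) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  pad <- array(0, dim = c(H + 2, Wd + 2, cin))
  pad[2:(H + 1), 2:(Wd + 1), ] <- x
  out <- array(0, dim = c(H, Wd, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(0, H, Wd)
    for (ci in seq_len(cin))
      for (di in 0:2)
        for (dj in 0:2)
          acc <- acc + W[di + 1, dj + 1, ci, co] *
            pad[(1 + di):(H + di), (1 + dj):(Wd + dj), ci]
    out[, , co] <- acc
  }
  out
}

avg_pool2 <- function(x) {
  H2 <- dim(x)[1] %/% 2L; W2 <- dim(x)[2] %/% 2L; C <- dim(x)[3]
  out <- array(0, dim = c(H2, W2, C))
  for (c in seq_len(C)) {
    m <- x[seq_len(2 * H2), seq_len(2 * W2), c]
    out[, , c] <- (m[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
                     m[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
                     m[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
                     m[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]) / 4
  }
  out
}

#' Reference frozen CNN backbone
#'
#' A three-block convolutional feature extractor (3x3 conv, ReLU, 2x2
#' average pool per block; channel widths 8, 16, 32 by default) with fixed
#' He-initialised random weights drawn once from \code{seed} and never
#' trained. Features are the global average of each final channel. A frozen
#' random backbone is enough for phantoms whose classes are separable by
#' color and scale, and it keeps the harness free of any downloaded
#' pretrained weights.
#'
#' @param seed integer seed fixing the weights.
#' @param channels integer vector of the three block widths.
#' @return a \code{BackboneAdapter}: list with \code{name},
#'   \code{featureFn} (image -> numeric feature vector), \code{dim} and
#'   \code{frozen = TRUE}.
#' @export
tinyCnnBackbone <- function(seed = 42L, channels = c(8L, 16L, 32L)) {
  cin <- c(3L, channels[-length(channels)])
  weights <- with_seed(seed, lapply(seq_along(channels), function(b) {
    array(stats::rnorm(9 * cin[b] * channels[b],
                       sd = sqrt(2 / (9 * cin[b]))),
          dim = c(3, 3, cin[b], channels[b]))
  }))
  featureFn <- function(image) {
    x <- as_rgb_array(image) / 255
    for (b in seq_along(weights)) {
      x <- relu(conv3x3(x, weights[[b]]))
      x <- avg_pool2(x)
    }
    apply(x, 3, mean)
  }
  structure(list(name = "tiny-cnn-3block", featureFn = featureFn,
                 dim = channels[length(channels)], frozen = TRUE),
            class = "BackboneAdapter")
}

#' Identity backbone over precomputed feature vectors
#'
#' @param dim feature dimension.
#' @return a \code{BackboneAdapter} passing numeric vectors through.
#' @export
identityBackbone <- function(dim) {
  structure(list(name = "identity", featureFn = function(x) as.numeric(x),
                 dim = dim, frozen = TRUE),
            class = "BackboneAdapter")
}

#' Extract backbone features for a list of images
#'
#' @param backbone a \code{BackboneAdapter}.
#' @param images list of images (or of numeric vectors for the identity
#'   backbone).
#' @return numeric matrix, one row per image.
#' @export
computeFeatures <- function(backbone, images) {
  t(vapply(images, backbone$featureFn, numeric(backbone$dim)))
}

#' Training configuration
#'
#' Head-training hyperparameters: minibatch 32, 25 epochs, Adam at learning
#' rate 1e-3 (beta1 = 0.9, beta2 = 0.999, eps = 1e-8), categorical
#' cross-entropy, 80/20 stratified split, 7 classes.
#'
#' @param batchSize,epochs,learningRate,nClasses,splitFraction,seed as
#'   described.
#' @param standardize z-score features using training-set statistics before
#'   the head (conditioning aid for raw backbone features).
#' @return a list of class \code{TrainConfig}.
#' @export
trainConfig <- function(batchSize = 32L, epochs = 25L, learningRate = 1e-3,
                        nClasses = 7L, splitFraction = 0.8, seed = 1L,
                        standardize = TRUE) {
  stopifnot(batchSize >= 1, epochs >= 1, learningRate > 0,
            splitFraction > 0, splitFraction < 1)
  structure(list(batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 learningRate = learningRate, nClasses = as.integer(nClasses),
                 splitFraction = splitFraction, seed = as.integer(seed),
                 standardize = isTRUE(standardize),
                 beta1 = 0.9, beta2 = 0.999, epsAdam = 1e-8),
            class = "TrainConfig")
}

#' Attach a fully connected softmax head to a backbone
#'
#' A single dense layer mapping backbone features to \code{nClasses} logits
#' followed by softmax. For a feature dimension F the head has
#' \code{F * nClasses + nClasses} parameters. Only the head is trainable;
#' the backbone stays frozen.
#'
#' @param backbone a \code{BackboneAdapter}.
#' @param nClasses number of output classes (default 7).
#' @param seed seed for the small random initialisation of the weights.
#' @return a list of class \code{HeadModel} with elements \code{backbone},
#'   \code{W} (F x nClasses), \code{b} (length nClasses).
#' @export
attachHead <- function(backbone, nClasses = 7L, seed = 1L) {
  F <- backbone$dim
  W <- with_seed(seed, matrix(stats::rnorm(F * nClasses, sd = 0.01),
                              F, nClasses))
  structure(list(backbone = backbone, W = W, b = rep(0, nClasses),
                 nClasses = as.integer(nClasses)),
            class = "HeadModel")
}

#' Predict class probabilities from features
#'
#' @param model a \code{HeadModel}.
#' @param features numeric matrix (rows = samples) of backbone features.
#' @return matrix of class probabilities, rows summing to 1.
#' @export
predictHead <- function(model, features) {
  softmax(features %*% model$W + matrix(model$b, nrow(features),
                                        model$nClasses, byrow = TRUE))
}

#' Train the head with Adam on cross-entropy
#'
#' Seeded shuffled minibatches, Adam updates of the head weights only, and
#' per-epoch metrics on the training and validation sets: TAcc, TLoss,
#' VAcc, VLoss. Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model a \code{HeadModel} from \code{\link{attachHead}}.
#' @param features numeric matrix of backbone features (all samples).
#' @param labels 0-based integer labels.
#' @param split list with \code{train}/\code{val} indices from
#'   \code{\link{splitDataset}}.
#' @param cfg a \code{\link{trainConfig}}.
#' @return a list with \code{model} (trained) and \code{metrics} (a
#'   data.frame with one row per epoch).
#' @export
trainHead <- function(model, features, labels, split, cfg = trainConfig()) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (cfg$standardize) {
    mu <- colMeans(X[split$train, , drop = FALSE])
    sd_ <- apply(X[split$train, , drop = FALSE], 2, stats::sd)
    sd_[sd_ < 1e-8] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  }
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xva <- X[split$val, , drop = FALSE]; yva <- y[split$val]
  K <- model$nClasses
  Ttr <- one_hot(ytr, K)
  W <- model$W; b <- model$b
  mW <- vW <- matrix(0, nrow(W), ncol(W)); mb <- vb <- rep(0, K)
  stepn <- 0
  epoch_seeds <- derive_seeds(cfg$seed, cfg$epochs)
  metrics <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample(nrow(Xtr)))
    for (start in seq(1, length(ord), by = cfg$batchSize)) {
      sel <- ord[start:min(start + cfg$batchSize - 1L, length(ord))]
      Xb <- Xtr[sel, , drop = FALSE]; Tb <- Ttr[sel, , drop = FALSE]
      P <- softmax(Xb %*% W + matrix(b, length(sel), K, byrow = TRUE))
      G <- (P - Tb) / length(sel)
      gW <- t(Xb) %*% G; gb <- colSums(G)
      stepn <- stepn + 1
      mW <- cfg$beta1 * mW + (1 - cfg$beta1) * gW
      vW <- cfg$beta2 * vW + (1 - cfg$beta2) * gW^2
      mb <- cfg$beta1 * mb + (1 - cfg$beta1) * gb
      vb <- cfg$beta2 * vb + (1 - cfg$beta2) * gb^2
      mhW <- mW / (1 - cfg$beta1^stepn); vhW <- vW / (1 - cfg$beta2^stepn)
      mhb <- mb / (1 - cfg$beta1^stepn); vhb <- vb / (1 - cfg$beta2^stepn)
      W <- W - cfg$learningRate * mhW / (sqrt(vhW) + cfg$epsAdam)
      b <- b - cfg$learningRate * mhb / (sqrt(vhb) + cfg$epsAdam)
    }
    Ptr <- softmax(Xtr %*% W + matrix(b, nrow(Xtr), K, byrow = TRUE))
    Pva <- softmax(Xva %*% W + matrix(b, nrow(Xva), K, byrow = TRUE))
    tl <- categoricalCrossEntropy(Ptr, ytr)
    vl <- categoricalCrossEntropy(Pva, yva)
    if (!is.finite(tl) || !is.finite(vl))
      stop("training diverged (non-finite loss) at epoch ", ep)
    metrics[[ep]] <- data.frame(epoch = ep,
                                TAcc = accuracyScore(Ptr, ytr), TLoss = tl,
                                VAcc = accuracyScore(Pva, yva), VLoss = vl)
  }
  model$W <- W; model$b <- b
  list(model = model, metrics = do.call(rbind, metrics))
}

#' Train one model per corpus variant and compare
#'
#' The scaled-down counterpart of the study design: the same backbone,
#' head initialisation, split and minibatch schedule are applied to each
#' variant of the same corpus (e.g. clean / hair-occluded / dehaired), so
#' any difference in the metric traces is attributable to the images alone.
#' With several seeds the direction of an effect can be read off as the
#' fraction of seeds in which one variant beats another.
#'
#' @param variants named list; each element is a list of images (one per
#'   sample, shared order across variants).
#' @param labels 0-based integer labels shared by all variants.
#' @param backbone a \code{BackboneAdapter}; default
#'   \code{\link{tinyCnnBackbone}()}.
#' @param cfg a \code{\link{trainConfig}}; its seed is replaced per
#'   replicate.
#' @param seeds integer vector of replicate seeds (split + init + shuffle).
#' @return a data.frame with columns variant, seed, epoch, TAcc, TLoss,
#'   VAcc, VLoss.
#' @export
runExperiment <- function(variants, labels, backbone = tinyCnnBackbone(),
                          cfg = trainConfig(), seeds = 1:5) {
  stopifnot(length(variants) >= 1, !is.null(names(variants)))
  feats <- lapply(variants, function(imgs) computeFeatures(backbone, imgs))
  out <- list()
  for (s in seeds) {
    split <- splitDataset(labels, cfg$splitFraction, seed = s)
    for (v in names(variants)) {
      cfg_s <- cfg; cfg_s$seed <- as.integer(s)
      head <- attachHead(backbone, cfg$nClasses, seed = s)
      fit <- trainHead(head, feats[[v]], labels, split, cfg_s)
      out[[length(out) + 1L]] <- cbind(data.frame(variant = v, seed = s),
                                       fit$metrics)
    }
  }
  do.call(rbind, out)
}
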