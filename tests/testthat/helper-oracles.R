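# Independent brute-force oracles used to cross-check the fast kernels.
# Everything here is direct-definition code: double loops, dense
# convolution, exhaustive distance transforms. Shared convention with the
# implementation: symmetric reflect padding with the edge pixel included.

refl_idx <- function(i, n) {
  # 1-based symmetric reflection: 0 -> 1, n+1 -> n
  ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
}

pad_reflect <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  m[refl_idx(seq(1 - r, H + r), H), refl_idx(seq(1 - r, W + r), W)]
}

# dense 2-D convolution with an arbitrary kernel, reflect padding
oracle_conv2 <- function(m, kern2) {
  r <- (nrow(kern2) - 1) / 2
  p <- pad_reflect(m, r)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in seq_len(nrow(kern2))) for (b in seq_len(ncol(kern2)))
      acc <- acc + kern2[a, b] * p[i + a - 1, j + b - 1]
    out[i, j] <- acc
  }
  out
}

oracle_median <- function(m, k) {
  r <- (k - 1) / 2
  p <- pad_reflect(m, r)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- median(p[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

oracle_morph <- function(m, se, stat = max) {
  K <- nrow(se); r <- (K - 1) / 2
  p <- pad_reflect(m, r)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    nb <- p[i:(i + K - 1), j:(j + K - 1)]
    out[i, j] <- stat(nb[se])
  }
  out
}

oracle_blackhat <- function(m, se) {
  closed <- oracle_morph(oracle_morph(m, se, max), se, min)
  closed - m
}

# exhaustive Euclidean distance transform: distance from each TRUE pixel to
# the nearest FALSE pixel
oracle_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  known <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, H, W)
  for (idx in which(mask)) {
    i <- (idx - 1) %% H + 1; j <- (idx - 1) %/% H + 1
    out[i, j] <- sqrt(min((known[, 1] - i)^2 + (known[, 2] - j)^2))
  }
  out
}

# vectorised whole-matrix non-local means, written against the definition:
# all patch distances via explicit patch offsets, then exponential weights,
# explicit normalisation, matrix product. Independent of the C++ loop
# structure.
oracle_nlmeans <- function(v, h, tr, sr, sigma = 0, self = c("max", "one"),
                           full = FALSE) {
  self <- match.arg(self)
  H <- nrow(v); W <- ncol(v); N <- H * W
  offs <- expand.grid(di = -tr:tr, dj = -tr:tr)
  D <- matrix(0, N, N)
  for (k in seq_len(nrow(offs))) {
    sh <- v[refl_idx(seq_len(H) + offs$di[k], H),
            refl_idx(seq_len(W) + offs$dj[k], W)]
    vk <- as.vector(sh)
    D <- D + outer(vk, vk, "-")^2
  }
  D <- D / nrow(offs)
  Wt <- exp(-pmax(D - 2 * sigma^2, 0) / h^2)
  rows <- as.vector(row(v)); cols <- as.vector(col(v))
  if (!full) {
    inwin <- abs(outer(rows, rows, "-")) <= sr &
      abs(outer(cols, cols, "-")) <= sr
    Wt[!inwin] <- 0
  }
  diag(Wt) <- 0
  selfw <- if (self == "max") {
    mx <- apply(Wt, 1, max)
    ifelse(mx > 0, mx, 1)
  } else rep(1, N)
  diag(Wt) <- selfw
  Wt <- Wt / rowSums(Wt)
  matrix(Wt %*% as.vector(v), H, W)
}

# closed-form bilinear sample of a matrix at fractional (0-based) coords
oracle_bilinear <- function(m, y, x) {
  H <- nrow(m); W <- ncol(m)
  y <- min(max(y, 0), H - 1); x <- min(max(x, 0), W - 1)
  y0 <- min(floor(y), H - 1); x0 <- min(floor(x), W - 1)
  y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
  fy <- y - y0; fx <- x - x0
  (1 - fy) * (1 - fx) * m[y0 + 1, x0 + 1] + (1 - fy) * fx * m[y0 + 1, x1 + 1] +
    fy * (1 - fx) * m[y1 + 1, x0 + 1] + fy * fx * m[y1 + 1, x1 + 1]
}

random_gray <- function(H, W, seed) {
  set.seed(seed)
  matrix(runif(H * W, 0, 255), H, W)
}

random_rgb <- function(H, W, seed) {
  set.seed(seed)
  array(runif(H * W * 3, 0, 255), dim = c(H, W, 3))
}
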