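# Shared internal helpers: coercion, clipping, seeded evaluation.

# Accept RasterImage or plain H x W x 3 array; return plain array.
as_rgb_array <- function(image) {
  if (is(image, "RasterImage")) return(pixelValues(image))
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L)
    return(array(as.double(image), dim = dim(image)))
  stop("expected a RasterImage or an H x W x 3 array")
}

as_gray_matrix <- function(image) {
  if (is(image, "GrayImage")) return(pixelValues(image))
  if (is.matrix(image)) {
    m <- image; storage.mode(m) <- "double"; return(m)
  }
  stop("expected a GrayImage or a numeric matrix")
}

as_mask_matrix <- function(mask) {
  if (is(mask, "BinaryMask")) return(pixelValues(mask))
  if (is.matrix(mask)) {
    m <- mask
    if (is.numeric(m)) m <- m > 0
    storage.mode(m) <- "logical"
    return(m)
  }
  stop("expected a BinaryMask or a logical matrix")
}

as_se_matrix <- function(se) {
  if (is(se, "StructuringElement")) return(unclass(se@.Data))
  if (is.matrix(se)) {
    m <- se
    if (is.numeric(m)) m <- m != 0
    storage.mode(m) <- "logical"
    return(m)
  }
  stop("expected a StructuringElement or a logical matrix")
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

odd_check <- function(k, what) {
  if (length(k) != 1L || is.na(k) || k < 1 || k %% 2 == 0)
    stop(what, " must be a positive odd integer, got ", k)
  as.integer(k)
}

# Derive a stream of sub-seeds from a master seed, staying well below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147480000L, n))
}
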