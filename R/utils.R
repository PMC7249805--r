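# small shared helpers (internal)

# run code under a temporary RNG state; restores the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# derive per-item child seeds from a master seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1, FALSE, TRUE))
}

# Gaussian smoothing that degrades gracefully on small images: the kernel
# is capped to the image size (odd), with replicated-boundary filtering
gsmooth <- function(m, sigma) {
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  kmax <- 2L * ((min(dim(m)) - 1L) %/% 2L) + 1L
  k <- min(k, kmax)
  if (k < 3L) return(m)
  brush <- EBImage::makeBrush(k, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(m, brush, boundary = "replicate"))
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must share the same dimensions (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
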