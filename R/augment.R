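# data augmentation: lossless offline rotations and the online
# geometric/photometric pipeline applied before every training step

#' Augmentation configuration
#'
#' Ranges follow the training protocol: isotropic scaling factors from
#' `[0.8, 1.3]`, brightness shifts of magnitude `[0, 0.2]` (random sign),
#' contrast factors from `[0.75, 1.25]` about the image mean, elastic
#' deformation by a smoothed random field, and random erasing of 4x4 image
#' patches.
#'
#' @param scale_range isotropic scale factor range
#' @param brightness_range additive brightness magnitude range
#' @param contrast_range multiplicative contrast factor range
#' @param erase_count number of 4x4 erased image patches
#' @param elastic_sigma Gaussian smoothing (px) of the deformation field
#' @param elastic_alpha amplitude (px) of the deformation field
#' @return list of class `augment_config`
#' @export
augment_config <- function(scale_range = c(0.8, 1.3),
                           brightness_range = c(0, 0.2),
                           contrast_range = c(0.75, 1.25),
                           erase_count = 8L, elastic_sigma = 8,
                           elastic_alpha = 2) {
  structure(list(scale_range = scale_range,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 erase_count = as.integer(erase_count),
                 elastic_sigma = elastic_sigma, elastic_alpha = elastic_alpha),
            class = "augment_config")
}

rot90cw <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

#' Offline rotation augmentation
#'
#' Appends the 90, 180 and 270 degree rotations of every sample to the set,
#' quadrupling it. Rotations by multiples of 90 degrees permute pixels
#' without interpolation, so masks stay exact; they also turn the naturally
#' horizontal stripe artefacts into vertical ones, teaching the model to
#' ignore both orientations.
#'
#' @param samples list of samples, each with at least `image` and a mask
#'   field (`centerline` or `mask`)
#' @return list of length `4 * length(samples)`
#' @export
offline_rotations <- function(samples) {
  stopifnot(length(samples) >= 1L)
  out <- samples
  for (k in 1:3) {
    out <- c(out, lapply(samples, function(s) {
      for (f in intersect(names(s), c("image", "centerline", "mask", "body")))
        for (r in seq_len(k)) s[[f]] <- rot90cw(s[[f]])
      s
    }))
  }
  out
}

#' Random smoothed displacement field
#'
#' Gaussian-smoothed white noise scaled by `alpha`, one field per axis;
#' zero-mean in expectation with spatial correlation length set by `sigma`.
#'
#' @param shape `c(H, W)` of the field
#' @param sigma smoothing std in pixels
#' @param alpha displacement amplitude in pixels
#' @return list with `dr` and `dc` displacement matrices
#' @export
elastic_field <- function(shape, sigma, alpha) {
  stopifnot(sigma > 0)
  if (alpha == 0)
    return(list(dr = matrix(0, shape[1L], shape[2L]),
                dc = matrix(0, shape[1L], shape[2L])))
  smooth <- function() {
    z <- matrix(rnorm(prod(shape)), shape[1L], shape[2L])
    z <- gsmooth(z, sigma)
    alpha * z / max(stats::sd(z), 1e-12)
  }
  list(dr = smooth(), dc = smooth())
}

# bilinear (image) / nearest (mask) warp by a displacement field
warp_field <- function(m, field, nearest = FALSE) {
  H <- nrow(m); W <- ncol(m)
  rr <- matrix(seq_len(H), H, W) + field$dr
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) + field$dc
  rr <- pmin(pmax(rr, 1), H)
  cc <- pmin(pmax(cc, 1), W)
  if (nearest) {
    return(matrix(m[cbind(as.integer(round(rr)), as.integer(round(cc)))], H, W))
  }
  r0 <- as.vector(pmin(floor(rr), H - 1L)); c0 <- as.vector(pmin(floor(cc), W - 1L))
  fr <- as.vector(rr) - r0; fc <- as.vector(cc) - c0
  v00 <- m[cbind(r0, c0)];     v10 <- m[cbind(r0 + 1L, c0)]
  v01 <- m[cbind(r0, c0 + 1L)]; v11 <- m[cbind(r0 + 1L, c0 + 1L)]
  matrix((1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
           (1 - fr) * fc * v01 + fr * fc * v11, H, W)
}

# scale then center-crop/zero-pad back to the original canvas
scale_canvas <- function(m, s, nearest = FALSE) {
  H <- nrow(m); W <- ncol(m)
  H2 <- max(1L, as.integer(round(H * s))); W2 <- max(1L, as.integer(round(W * s)))
  if (H2 == H && W2 == W) return(m)
  z <- EBImage::resize(m, w = H2, h = W2,
                       filter = if (nearest) "none" else "bilinear")
  z <- matrix(as.numeric(z), H2, W2)
  out <- matrix(0, H, W)
  if (H2 >= H) {
    r0 <- (H2 - H) %/% 2L; c0 <- (W2 - W) %/% 2L
    out <- z[r0 + seq_len(H), c0 + seq_len(W), drop = FALSE]
  } else {
    r0 <- (H - H2) %/% 2L; c0 <- (W - W2) %/% 2L
    out[r0 + seq_len(H2), c0 + seq_len(W2)] <- z
  }
  out
}

#' Online augmentation of one training sample
#'
#' Applies, in order: random isotropic scaling (canvas-preserving), elastic
#' deformation (same field for image and mask, nearest-neighbour for the
#' mask), an additive brightness shift with random sign, a contrast scale
#' about the image mean, and erasure of `erase_count` random 4x4 image
#' patches (the mask is untouched, so the annotation still supervises
#' occluded vessels). The image is clipped back to `[0, 1]`. Uses the
#' caller's RNG stream; seed beforehand for reproducibility.
#'
#' @param image grayscale matrix in `[0, 1]`
#' @param mask binary supervision mask of the same shape
#' @param config an [augment_config()]
#' @return list with augmented `image` and `mask`
#' @export
online_augment <- function(image, mask, config = augment_config()) {
  assert_same_shape(image, mask, "image and mask")
  s <- runif(1L, config$scale_range[1L], config$scale_range[2L])
  image <- scale_canvas(image, s)
  mask <- scale_canvas(mask, s, nearest = TRUE)
  if (config$elastic_alpha > 0) {
    f <- elastic_field(dim(image), config$elastic_sigma, config$elastic_alpha)
    image <- warp_field(image, f)
    mask <- warp_field(mask, f, nearest = TRUE)
  }
  b <- runif(1L, config$brightness_range[1L], config$brightness_range[2L]) *
    sample(c(-1, 1), 1L)
  image <- image + b
  cf <- runif(1L, config$contrast_range[1L], config$contrast_range[2L])
  image <- mean(image) + cf * (image - mean(image))
  if (config$erase_count > 0L) {
    H <- nrow(image); W <- ncol(image)
    for (i in seq_len(config$erase_count)) {
      r <- sample.int(max(H - 3L, 1L), 1L)
      c <- sample.int(max(W - 3L, 1L), 1L)
      image[r:min(r + 3L, H), c:min(c + 3L, W)] <- 0
    }
  }
  list(image = clamp01(image), mask = (mask > 0.5) + 0L)
}
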