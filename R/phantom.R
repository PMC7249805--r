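# synthetic OCT-A phantom generator
#
# Emulates the appearance of OCT-A maximum-intensity projections: a tree of
# branching vessels whose cross-sectional contrast fades away from the
# centerline, unresolvable microvascular background texture, multiplicative
# speckle, and horizontally oriented stripe artefacts. Geometry uses
# continuous (row, col) coordinates with pixel centers at integers 1..size.

#' Phantom generator configuration
#'
#' @param image_size side of the square image in pixels (>= 32)
#' @param n_roots number of root branches seeded on the image border
#' @param branch_prob per-step probability that a branch spawns a child
#' @param width_range full vessel width range in pixels, `c(min, max)`
#' @param taper child/parent width ratio in (0, 1]
#' @param curvature_sigma std of the per-step heading change (radians)
#' @param contrast_range centerline peak intensity range within (0, 1]
#' @param microtexture_amp amplitude of smoothed background texture in [0, 1)
#' @param speckle_sigma std of multiplicative speckle noise
#' @param stripe_prob probability that each candidate row band is inserted
#' @param stripe_amp additive amplitude of a stripe artefact
#' @param depth_slices slice count for 3D rendering (>= 2)
#' @param seed integer RNG seed; identical configs give identical samples
#' @return an object of class `phantom_config`
#' @export
phantom_config <- function(image_size = 256L, n_roots = 4L, branch_prob = 0.02,
                           width_range = c(2, 5), taper = 0.8,
                           curvature_sigma = 0.15,
                           contrast_range = c(0.55, 0.95),
                           microtexture_amp = 0.12, speckle_sigma = 0.08,
                           stripe_prob = 0.5, stripe_amp = 0.08,
                           depth_slices = 16L, seed = 1L) {
  stopifnot(image_size >= 32, n_roots >= 0, branch_prob >= 0, branch_prob <= 1,
            length(width_range) == 2L, width_range[1L] >= 1,
            width_range[1L] <= width_range[2L], taper > 0, taper <= 1,
            curvature_sigma >= 0, all(contrast_range > 0),
            all(contrast_range <= 1), microtexture_amp >= 0,
            microtexture_amp < 1, speckle_sigma >= 0, stripe_prob >= 0,
            stripe_prob <= 1, stripe_amp >= 0, depth_slices >= 2)
  structure(list(
    image_size = as.integer(image_size), n_roots = as.integer(n_roots),
    branch_prob = branch_prob, width_range = width_range, taper = taper,
    curvature_sigma = curvature_sigma, contrast_range = contrast_range,
    microtexture_amp = microtexture_amp, speckle_sigma = speckle_sigma,
    stripe_prob = stripe_prob, stripe_amp = stripe_amp,
    depth_slices = as.integer(depth_slices), seed = as.integer(seed)
  ), class = "phantom_config")
}

# grow one branch as a bounded-curvature unit-step random walk; returns the
# vertex matrix (row, col, depth) plus spawn points for children
grow_branch <- function(start, heading, depth0, config, max_steps) {
  size <- config$image_size
  S <- config$depth_slices
  pts <- matrix(NA_real_, max_steps + 1L, 3L)
  pts[1L, ] <- c(start, depth0)
  spawns <- list()
  pos <- start
  depth <- depth0
  for (i in seq_len(max_steps)) {
    heading <- heading + rnorm(1L, 0, config$curvature_sigma)
    nxt <- pos + c(sin(heading), cos(heading))
    if (any(nxt < 1) || any(nxt > size)) {
      pts <- pts[seq_len(i), , drop = FALSE]
      return(list(pts = pts, spawns = spawns))
    }
    depth <- min(max(depth + rnorm(1L, 0, 0.08), 0), S - 1)
    pos <- nxt
    pts[i + 1L, ] <- c(pos, depth)
    if (runif(1L) < config$branch_prob)
      spawns[[length(spawns) + 1L]] <-
        list(pos = pos, heading = heading + sample(c(-1, 1), 1L) * runif(1L, 0.4, 0.9),
             depth = depth)
  }
  list(pts = pts, spawns = spawns)
}

#' Sample a random vessel tree
#'
#' Grows `n_roots` branches from border seed points by bounded-curvature
#' random walks that branch with probability `branch_prob` per step; child
#' widths taper by `taper`. Deterministic given `config$seed`.
#'
#' @param config a [phantom_config()]
#' @return object of class `vessel_tree`: a list with `branches` (each with
#'   a vertex matrix `pts` of continuous (row, col, depth) coordinates, a
#'   `width` and a `contrast`), `image_size` and `depth_slices`
#' @export
sample_vessel_tree <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  size <- config$image_size
  with_seed(config$seed, {
    branches <- list()
    queue <- list()
    for (i in seq_len(config$n_roots)) {
      side <- sample(4L, 1L)
      along <- runif(1L, 1, size)
      start <- switch(side, c(1, along), c(size, along), c(along, 1),
                      c(along, size))
      # aim inward with some spread; heading angle uses the
      # (row, col) = (sin, cos) step convention of grow_branch
      center_ang <- atan2(size / 2 - start[1L], size / 2 - start[2L])
      heading <- center_ang + rnorm(1L, 0, 0.4)
      queue[[length(queue) + 1L]] <- list(
        pos = start, heading = heading,
        depth = runif(1L, 0.2, 0.8) * (config$depth_slices - 1),
        width = runif(1L, config$width_range[1L], config$width_range[2L]),
        gen = 1L
      )
    }
    max_branches <- 64L
    while (length(queue) > 0L && length(branches) < max_branches) {
      job <- queue[[1L]]
      queue[[1L]] <- NULL
      g <- grow_branch(job$pos, job$heading, job$depth, config,
                       max_steps = 2L * size)
      if (nrow(g$pts) >= 2L)
        branches[[length(branches) + 1L]] <- list(
          pts = g$pts, width = job$width,
          contrast = runif(1L, config$contrast_range[1L],
                           config$contrast_range[2L])
        )
      for (sp in g$spawns) {
        w <- max(job$width * config$taper, 1)
        if (job$gen < 5L)
          queue[[length(queue) + 1L]] <- list(pos = sp$pos,
                                              heading = sp$heading,
                                              depth = sp$depth, width = w,
                                              gen = job$gen + 1L)
      }
    }
    structure(list(branches = branches, image_size = size,
                   depth_slices = config$depth_slices),
              class = "vessel_tree")
  })
}

# integer pixels of the digital line from p0 to p1 (Bresenham, 8-connected)
bresenham <- function(p0, p1) {
  r0 <- p0[1L]; c0 <- p0[2L]; r1 <- p1[1L]; c1 <- p1[2L]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1L
  out <- matrix(NA_integer_, n, 2L)
  err <- dr - dc
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) return(out[seq_len(i), , drop = FALSE])
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr)  { err <- err + dc; c <- c + sc }
  }
  out
}

#' Rasterize tree centerlines to a 1-px-wide binary mask
#'
#' Every branch polyline is traced as an 8-connected digital curve.
#'
#' @param tree a `vessel_tree`
#' @param image_size output mask side in pixels
#' @return 0/1 integer matrix
#' @export
rasterize_centerline <- function(tree, image_size = tree$image_size) {
  mask <- matrix(0L, image_size, image_size)
  for (b in tree$branches) {
    v <- round(b$pts[, 1:2, drop = FALSE])
    v[v < 1] <- 1L
    v[v > image_size] <- image_size
    for (i in seq_len(nrow(v) - 1L)) {
      px <- bresenham(v[i, ], v[i + 1L, ])
      mask[px] <- 1L
    }
    if (nrow(v) == 1L) mask[v] <- 1L
  }
  mask
}

# smoothed positive texture field in [0, 1]
smooth_noise_field <- function(size, sigma = 3) {
  z <- matrix(runif(size * size), size, size)
  z <- gsmooth(z, sigma)
  rng <- range(z)
  if (diff(rng) < .Machine$double.eps) return(matrix(0, size, size))
  (z - rng[1L]) / diff(rng)
}

# apply the noise model shared by 2D and per-slice 3D rendering; `rng` state
# is the caller's
apply_noise <- function(img, config) {
  size <- nrow(img)
  if (config$microtexture_amp > 0)
    img <- img + config$microtexture_amp * smooth_noise_field(size)
  if (config$speckle_sigma > 0)
    img <- img * (1 + matrix(rnorm(size^2, 0, config$speckle_sigma), size))
  if (config$stripe_prob > 0 && config$stripe_amp > 0) {
    n_bands <- max(1L, size %/% 32L)
    for (i in seq_len(n_bands)) {
      insert <- runif(1L) < config$stripe_prob
      top <- sample.int(size, 1L)
      h <- sample(2:5, 1L)
      if (insert) {
        rows <- top:min(top + h - 1L, size)
        img[rows, ] <- img[rows, ] + config$stripe_amp
      }
    }
  }
  clamp01(img)
}

#' Render a vessel tree to a 2D phantom image
#'
#' Vessel intensity peaks on the centerline and decays with a Gaussian
#' cross-profile (sigma = width/4), reproducing the fading contrast that
#' makes full-width annotation of OCT-A impractical. On top of the clean
#' rendering the noise model adds smoothed microvascular background texture,
#' multiplicative speckle, and horizontal stripe bands.
#'
#' @param tree a `vessel_tree`
#' @param config a [phantom_config()]
#' @param noise add the noise model (set `FALSE` for the clean rendering)
#' @return list with `image` (matrix in `[0,1]`) and `body` (0/1 lumen mask)
#' @export
render_image <- function(tree, config, noise = TRUE) {
  size <- config$image_size
  br <- lapply(tree$branches, function(b) sweep(b$pts, 2L, c(1, 1, 0)))  # 0-based for C++
  widths <- vapply(tree$branches, `[[`, numeric(1L), "width")
  contrasts <- vapply(tree$branches, `[[`, numeric(1L), "contrast")
  r <- cpp_render_tree(br, widths, contrasts, size, size, 0L)
  img <- r$intensity
  if (noise) img <- with_seed(config$seed + 1L, apply_noise(img, config))
  list(image = clamp01(img), body = r$body)
}

#' Render a vessel tree into a slice stack
#'
#' Each branch is drawn as a tube following its smooth per-vertex depth
#' profile. With noise disabled, the maximum intensity projection of the
#' stack equals the noise-free 2D rendering exactly, by construction.
#'
#' @inheritParams render_image
#' @return `H x W x S` numeric array
#' @export
render_volume <- function(tree, config, noise = TRUE) {
  size <- config$image_size
  S <- config$depth_slices
  br <- lapply(tree$branches, function(b) sweep(b$pts, 2L, c(1, 1, 0)))
  widths <- vapply(tree$branches, `[[`, numeric(1L), "width")
  contrasts <- vapply(tree$branches, `[[`, numeric(1L), "contrast")
  r <- cpp_render_tree(br, widths, contrasts, size, size, S)
  vol <- r$volume
  if (noise)
    vol <- with_seed(config$seed + 2L, {
      for (s in seq_len(S)) vol[, , s] <- apply_noise(vol[, , s], config)
      vol
    })
  vol
}

#' Generate one phantom sample
#'
#' @param config a [phantom_config()]
#' @param volume also render the slice stack
#' @return list of class `phantom_sample` with `image`, `centerline` (1-px
#'   binary mask), `body` (lumen mask), optional `volume`, and the `config`
#' @export
phantom_sample <- function(config, volume = FALSE) {
  tree <- sample_vessel_tree(config)
  centerline <- rasterize_centerline(tree)
  r <- render_image(tree, config)
  body <- (r$body | centerline) + 0L  # a lumen contains its centerline
  out <- list(image = r$image, centerline = centerline, body = body,
              config = config)
  if (volume) out$volume <- render_volume(tree, config)
  structure(out, class = "phantom_sample")
}

#' Generate an in-memory phantom dataset
#'
#' @param n number of samples (>= 1)
#' @param config template [phantom_config()]; per-sample seeds are derived
#'   from `seed`
#' @param seed master seed
#' @param volume also render slice stacks
#' @return list of `phantom_sample`s
#' @export
phantom_dataset <- function(n, config = phantom_config(), seed = 1L,
                            volume = FALSE) {
  stopifnot(n >= 1)
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    phantom_sample(cfg, volume = volume)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/centerline pairs as PNG plus a CSV manifest with columns
#' `id,image,mask,seed`. Deterministic for fixed `(n, config, seed)`.
#'
#' @inheritParams phantom_dataset
#' @param dir output directory (created if missing)
#' @return path of the manifest CSV, invisibly
#' @export
generate_dataset <- function(n, config = phantom_config(), seed = 1L, dir,
                             volume = FALSE) {
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  seeds <- derive_seeds(seed, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- seeds[i]
    s <- phantom_sample(cfg, volume = volume)
    id <- sprintf("phantom_%03d", i)
    img_path <- file.path(dir, paste0(id, ".png"))
    mask_path <- file.path(dir, paste0(id, "_centerline.png"))
    write_image(s$image, img_path)
    write_mask(s$centerline, mask_path)
    if (volume)
      write_stack(s$volume, file.path(dir, paste0(id, "_volume.tiff")))
    rows[[i]] <- data.frame(id = id, image = basename(img_path),
                            mask = basename(mask_path), seed = seeds[i])
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#' @param dir dataset directory containing `manifest.csv`
#' @return list of samples with `image` and `centerline`
#' @export
load_dataset <- function(dir) {
  mf <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(mf)), function(i) {
    list(image = read_image(file.path(dir, mf$image[i])),
         centerline = read_mask(file.path(dir, mf$mask[i])),
         id = mf$id[i])
  })
}
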