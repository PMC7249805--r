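test_that("tree sampling respects roots, branching and seeding", {
  expect_length(sample_vessel_tree(phantom_config(n_roots = 0L))$branches, 0L)

  cfg <- phantom_config(seed = 7L)
  expect_identical(sample_vessel_tree(cfg), sample_vessel_tree(cfg))

  # zero branching probability: branch count equals root count
  cfg0 <- phantom_config(n_roots = 4L, branch_prob = 0, image_size = 256L)
  expect_length(sample_vessel_tree(cfg0)$branches, 4L)

  # vertices stay inside the domain, children are never wider than parents
  tree <- sample_vessel_tree(phantom_config(image_size = 64L, seed = 3L,
                                            branch_prob = 0.05))
  for (b in tree$branches) {
    expect_true(all(b$pts[, 1:2] >= 1 & b$pts[, 1:2] <= 64))
    expect_gte(nrow(b$pts), 2L)
  }
  wmax <- max(vapply(tree$branches, `[[`, numeric(1L), "width"))
  expect_lte(wmax, phantom_config()$width_range[2L])
})

test_that("centerline rasterization draws 8-connected digital curves", {
  # axis-aligned segment: 10 pixels on one row
  tr <- make_tree(list(make_branch(line_pts(c(1, 1), c(1, 10)))))
  m <- rasterize_centerline(tr, 16L)
  expect_equal(sum(m), 10)
  expect_equal(sum(m[1, 1:10]), 10)

  # diagonal: 10 pixels, 8-connected single component
  trd <- make_tree(list(make_branch(line_pts(c(1, 1), c(10, 10)))))
  md <- rasterize_centerline(trd, 16L)
  expect_equal(sum(md), 10)
  expect_equal(count_components(md), 1L)

  expect_equal(sum(rasterize_centerline(empty_tree(), 16L)), 0)

  # every polyline trace is one connected pixel path
  tree <- sample_vessel_tree(phantom_config(image_size = 48L, seed = 9L,
                                            branch_prob = 0))
  for (b in tree$branches) {
    m1 <- rasterize_centerline(make_tree(list(b), 48L), 48L)
    expect_equal(count_components(m1), 1L)
  }
})

test_that("2D rendering has fading cross-profile and clean background", {
  cfg <- phantom_config(image_size = 32L, microtexture_amp = 0,
                        speckle_sigma = 0, stripe_prob = 0)
  r0 <- render_image(empty_tree(32L), cfg)
  expect_true(all(r0$image == r0$image[1, 1]))  # constant background

  # one horizontal vessel of width 4: centerline pixels are the per-column
  # maxima across the cross-section, and body is at least background
  tr <- make_tree(list(make_branch(line_pts(c(16, 4), c(16, 28)),
                                   width = 4, contrast = 0.9)), 32L)
  r <- render_image(tr, cfg)
  for (cc in 8:24) expect_equal(which.max(r$image[, cc]), 16)
  expect_true(all(r$image[r$body == 1] >= min(r$image)))
  expect_true(all(r$image >= 0 & r$image <= 1))
})

test_that("stripe artefacts produce measurable row bands", {
  cfg <- phantom_config(image_size = 64L, microtexture_amp = 0,
                        speckle_sigma = 0, stripe_prob = 1, stripe_amp = 0.2,
                        seed = 2L)
  r <- render_image(empty_tree(64L), cfg)
  row_means <- rowMeans(r$image)
  expect_gte(max(abs(row_means - mean(r$image))), cfg$stripe_amp / 2)
})

test_that("phantom samples satisfy the centerline-inside-body invariant", {
  ds <- phantom_dataset(6, phantom_config(image_size = 64L), seed = 21L)
  for (s in ds) {
    expect_true(all(s$body[s$centerline == 1] == 1))
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})

test_that("noise-free volume MIP equals the noise-free 2D rendering exactly", {
  cfg <- phantom_config(image_size = 48L, depth_slices = 12L, seed = 4L,
                        branch_prob = 0.03)
  tree <- sample_vessel_tree(cfg)
  img2d <- render_image(tree, cfg, noise = FALSE)$image
  vol <- render_volume(tree, cfg, noise = FALSE)
  expect_identical(dim(vol), c(48L, 48L, 12L))
  expect_equal(max_intensity_projection(vol), img2d, tolerance = 0)

  expect_true(all(render_volume(empty_tree(48L),
                                phantom_config(image_size = 48L),
                                noise = FALSE) == 0))
})

test_that("a constant-depth tube occupies only slices within width/2", {
  d <- 6
  w <- 3
  tr <- make_tree(list(make_branch(line_pts(c(16, 4), c(16, 28), depth = d),
                                   width = w)), 32L)
  cfg <- phantom_config(image_size = 32L, depth_slices = 16L)
  vol <- render_volume(tr, cfg, noise = FALSE)
  nz <- which(vol > 0, arr.ind = TRUE)
  expect_gt(nrow(nz), 0)
  expect_true(all(abs(nz[, 3L] - 1 - d) <= w / 2))
})

test_that("skeletonizing the clean body recovers the centerline (Quality >= 0.9)", {
  cfg <- phantom_config(image_size = 96L, seed = 13L)
  s <- phantom_sample(cfg)
  sk <- skeletonize(s$body)
  q <- delineation_metrics(sk, s$centerline, tau = 2)$quality
  expect_gte(q, 0.9)
})

test_that("dataset generation is deterministic and diverse", {
  cfg <- phantom_config(image_size = 48L)
  d1 <- file.path(tempdir(), "ds1")
  d2 <- file.path(tempdir(), "ds2")
  generate_dataset(5, cfg, seed = 3L, dir = d1)
  generate_dataset(5, cfg, seed = 3L, dir = d2)
  f1 <- sort(list.files(d1))
  expect_length(grep("\\.png$", f1), 10L)  # 5 images + 5 masks
  expect_true("manifest.csv" %in% f1)
  mf <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(nrow(mf), 5L)
  expect_identical(names(mf), c("id", "image", "mask", "seed"))
  for (f in f1)  # byte-identical across reruns with the same seed
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # derived per-sample seeds give pairwise distinct centerlines
  ds <- phantom_dataset(30, phantom_config(image_size = 48L), seed = 17L)
  keys <- vapply(ds, function(s) paste(which(s$centerline == 1), collapse = ","),
                 character(1L))
  expect_equal(anyDuplicated(keys), 0L)
  unlink(c(d1, d2), recursive = TRUE)
})
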