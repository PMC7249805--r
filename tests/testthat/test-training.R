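test_that("centerline dilation uses a 3x3 square element", {
  m <- matrix(0L, 9L, 9L); m[5L, 5L] <- 1L
  d <- dilate_centerline(m)
  expect_equal(sum(d), 9)
  expect_true(all(d[4:6, 4:6] == 1L))
  expect_equal(sum(dilate_centerline(matrix(0L, 5L, 5L))), 0)
  # extensive: input is contained in the output
  set.seed(2)
  r <- matrix(rbinom(100, 1, 0.2), 10L)
  expect_true(all(dilate_centerline(r)[r == 1L] == 1L))
})

test_that("inverse-time decay starts at 1e-4 and halves by epoch 2", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, 10, cfg), 1e-4)
  expect_equal(lr_schedule(20, 10, cfg), 5e-5)  # after 2 full epochs
  lrs <- vapply(0:100, lr_schedule, numeric(1L), steps_per_epoch = 10,
                config = cfg)
  expect_true(all(diff(lrs) <= 0))
})

test_that("stratified folds give disjoint exhaustive test sets", {
  ids <- sprintf("s%02d", 1:8)
  folds <- stratified_folds(ids, k = 4L, seed = 1L)
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(tests) == 2L))
  expect_identical(sort(unlist(tests)), sort(ids))
  expect_equal(anyDuplicated(unlist(tests)), 0L)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
    expect_identical(sort(c(f$train, f$val, f$test)), sort(ids))
  }
  expect_identical(folds, stratified_folds(ids, k = 4L, seed = 1L))

  # every stratum reaches all three sets when it has >= k members
  ids2 <- sprintf("t%02d", 1:24)
  strata <- rep(c("a", "b", "c"), each = 8L)
  folds2 <- stratified_folds(ids2, strata, k = 4L, seed = 2L)
  for (f in folds2) for (set in f)
    expect_setequal(unique(strata[match(set, ids2)]), c("a", "b", "c"))
})

test_that("early stopping fires on the 10-epoch / 1K-step rule", {
  ns <- asNamespace("octaseg")
  # improving then flat: stops only after 10 flat epochs AND >= 1000 steps
  trace <- c(0.5, 0.6, rep(0.6, 10L))
  expect_false(ns$should_stop(trace[1:11], 2000, 10L, 1000L))
  expect_true(ns$should_stop(trace, 2000, 10L, 1000L))
  expect_false(ns$should_stop(trace, 900, 10L, 1000L))  # min steps not met
  # a late improvement resets the counter
  trace2 <- c(0.5, rep(0.4, 9L), 0.7)
  expect_false(ns$should_stop(trace2, 5000, 10L, 1000L))
})

test_that("validation Quality scores oracle predictors as expected", {
  ds <- tiny_phantoms(3, size = 48L, seed = 41L)
  # an oracle emitting the dilated supervision mask scores high
  oracle <- function(img) {
    s <- Filter(function(x) identical(x$image, img), ds)[[1L]]
    dilate_centerline(s$centerline) + 0
  }
  expect_gte(validate_quality(oracle, ds, tau = 2), 0.9)
  expect_equal(validate_quality(function(img) img * 0, ds), 0)
  one <- validate_quality(oracle, ds[1L])
  expect_equal(one, validate_quality(oracle, ds[1L]))
})

test_that("the training loop runs the configured number of steps", {
  ds <- tiny_phantoms(4, size = 32L)
  cfg <- train_config(max_steps = 6L, min_steps = 6L, batch_size = 2L,
                      net = tiny_net(variant = "unet"),
                      loss = loss_config(use_topo = FALSE), augment = NULL,
                      offline_rotations = FALSE, seed = 3L)
  fit <- train_loop(ds[1:3], ds[4L], cfg)
  expect_equal(nrow(fit$history), 6L)
  expect_equal(max(fit$history$step), 6L)
  expect_true(all(is.finite(fit$history$loss)))
  # best checkpoint quality is the max of the validation history
  expect_equal(fit$best_quality, max(fit$val_history))
})

test_that("training with a fixed seed reproduces the loss trace", {
  ds <- tiny_phantoms(4, size = 32L)
  cfg <- train_config(max_steps = 4L, min_steps = 4L,
                      net = tiny_net(variant = "iunet", T_iterations = 2L),
                      loss = loss_config(use_topo = FALSE), augment = NULL,
                      offline_rotations = FALSE, seed = 11L)
  f1 <- train_loop(ds[1:3], ds[4L], cfg)
  f2 <- train_loop(ds[1:3], ds[4L], cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$val_history, f2$val_history)
})

test_that("early stopping halts a stalled run before max_steps", {
  ds <- tiny_phantoms(5, size = 32L)
  # lr 0 freezes the model, so validation never improves after epoch 1
  cfg <- train_config(lr0 = 0, max_steps = 200L, min_steps = 1L,
                      patience_epochs = 2L, batch_size = 2L,
                      net = tiny_net(variant = "unet"),
                      loss = loss_config(use_topo = FALSE), augment = NULL,
                      offline_rotations = FALSE, seed = 5L)
  fit <- train_loop(ds[1:4], ds[5L], cfg)
  expect_lt(max(fit$history$step), 200L)
  expect_equal(length(fit$val_history), 3L)  # 1 best + 2 patience epochs
})

test_that("online augmentation does not hurt held-out quality (median over seeds)", {
  ds <- tiny_phantoms(8, size = 32L, seed = 77L)
  run <- function(seed, aug) {
    cfg <- train_config(lr0 = 1e-3, max_steps = 40L, min_steps = 40L,
                        net = tiny_net(variant = "unet"),
                        loss = loss_config(use_topo = FALSE), augment = aug,
                        offline_rotations = TRUE, seed = seed)
    fit <- train_loop(ds[1:5], ds[6:8], cfg)
    validate_quality(fit$model, ds[6:8])
  }
  seeds <- c(1L, 2L, 3L)
  q_aug <- vapply(seeds, run, numeric(1L),
                  aug = augment_config(erase_count = 2L, elastic_alpha = 1))
  q_plain <- vapply(seeds, run, numeric(1L), aug = NULL)
  expect_gte(stats::median(q_aug), stats::median(q_plain) - 0.05)
})
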