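test_that("encoder widths double per block and outputs are probabilities", {
  cfg <- net_config(base_filters = 8L)
  model <- build_base(cfg, seed = 1L)
  mod <- model$modules[[1L]]
  expect_equal(nrow(mod$enc1_a$w), 8L)
  expect_equal(nrow(mod$enc2_a$w), 16L)
  expect_equal(nrow(mod$enc3_a$w), 32L)

  img <- matrix(runif(64 * 64), 64L, 64L)
  p <- forward_base(model, img)
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, forward_base(model, img))  # deterministic
})

test_that("odd-sized inputs are padded internally and cropped back", {
  model <- build_base(tiny_net(), seed = 2L)
  img <- matrix(runif(65 * 65), 65L, 65L)
  expect_identical(dim(forward_base(model, img)), c(65L, 65L))
  img2 <- matrix(runif(33 * 47), 33L, 47L)
  expect_identical(dim(forward_base(model, img2)), c(33L, 47L))
})

test_that("checkpoints reload with bit-identical forward outputs", {
  model <- build_base(tiny_net(), seed = 3L)
  img <- matrix(runif(32 * 32), 32L, 32L)
  p0 <- forward_base(model, img)
  ck <- tempfile(fileext = ".rds")
  save_model(model, ck)
  expect_identical(forward_base(load_model(ck), img), p0)
  expect_error(load_model({f <- tempfile(); saveRDS(1, f); f}),
               "not an octaseg checkpoint")
})

test_that("refinement wrappers reduce to the base network and stack correctly", {
  img <- matrix(runif(32 * 32), 32L, 32L)

  shn1 <- build_model(net_config(base_filters = 2L, variant = "shn",
                                 k_modules = 1L), seed = 4L)
  expect_identical(forward_shn(shn1, img)[[1L]], forward_base(shn1, img))

  iu <- build_model(net_config(base_filters = 2L, variant = "iunet",
                               T_iterations = 3L), seed = 4L)
  preds <- forward_iunet(iu, img)
  expect_length(preds, 3L)
  expect_identical(preds[[1L]], forward_base(iu, img))
  for (p in preds) expect_true(all(p >= 0 & p <= 1))

  shn2 <- build_model(net_config(base_filters = 2L, variant = "shn",
                                 k_modules = 2L), seed = 5L)
  expect_length(forward_shn(shn2, img), 2L)
})

test_that("weight sharing and module independence behave as designed", {
  img <- matrix(runif(32 * 32), 32L, 32L)

  # iunet: perturbing the shared weights changes every iteration's output
  iu <- build_model(net_config(base_filters = 2L, variant = "iunet",
                               T_iterations = 2L), seed = 6L)
  base <- forward_iunet(iu, img)
  iu$modules[[1L]]$out$b <- iu$modules[[1L]]$out$b + 0.1
  pert <- forward_iunet(iu, img)
  expect_false(isTRUE(all.equal(base[[1L]], pert[[1L]])))
  expect_false(isTRUE(all.equal(base[[2L]], pert[[2L]])))

  # shn: module 2's weights cannot affect module 1's output
  shn <- build_model(net_config(base_filters = 2L, variant = "shn",
                                k_modules = 2L), seed = 6L)
  o1 <- forward_shn(shn, img)
  shn$modules[[2L]]$out$b <- shn$modules[[2L]]$out$b + 0.5
  o2 <- forward_shn(shn, img)
  expect_identical(o1[[1L]], o2[[1L]])
  expect_false(isTRUE(all.equal(o1[[2L]], o2[[2L]])))
})

test_that("parameter counts follow the uniform 2-channel module interface", {
  cfg_sh <- net_config(base_filters = 8L, variant = "shn", k_modules = 4L)
  cfg_iu <- net_config(base_filters = 8L, variant = "iunet", T_iterations = 4L)
  shn <- build_model(cfg_sh, seed = 1L)
  iu <- build_model(cfg_iu, seed = 1L)
  expect_identical(count_parameters(shn), 4 * count_parameters(iu))

  # iteration count never changes the recurrent model's size
  iu2 <- build_model(net_config(base_filters = 8L, variant = "iunet",
                                T_iterations = 2L), seed = 1L)
  expect_identical(count_parameters(iu2), count_parameters(iu))

  # conv parameters are ~quadratic in width
  n8 <- count_parameters(build_base(net_config(base_filters = 8L), seed = 1L))
  n16 <- count_parameters(build_base(net_config(base_filters = 16L), seed = 1L))
  expect_gt(n16 / n8, 3.8)
  expect_lt(n16 / n8, 4.2)

  expect_equal(count_parameters(list()), 0)
})

test_that("the unrolled backward pass matches finite differences", {
  set.seed(9)
  ns <- asNamespace("octaseg")
  img <- matrix(runif(64), 8L, 8L)
  tgt <- matrix(rbinom(64, 1, 0.3), 8L, 8L)
  cfg <- net_config(base_filters = 2L, variant = "iunet", T_iterations = 2L)
  model <- build_model(cfg, seed = 10L)
  lcfg <- loss_config(use_topo = FALSE)
  r <- ns$train_backprop_sample(model$modules, cfg, img, tgt, NULL, NULL,
                                lcfg, "iunet", 2L)
  v0 <- ns$module_flatten(model$modules[[1L]])
  lossfun <- function(vec) {
    m2 <- model
    m2$modules[[1L]] <- ns$module_unflatten(model$modules[[1L]], vec)
    ls <- vapply(forward_iunet(m2, img),
                 function(p) balanced_bce(p, tgt)$l_bce, numeric(1L))
    iterative_loss(ls, "iunet")
  }
  expect_equal(r$loss, lossfun(v0), tolerance = 1e-5)
  idx <- sample(length(v0), 20L)
  h <- 1e-3
  for (i in idx) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    fd <- (lossfun(vp) - lossfun(vm)) / (2 * h)
    # single-precision forward: compare at a few-percent relative tolerance
    expect_lte(abs(fd - r$grads[[1L]][i]) / max(abs(fd), 1e-2), 0.05)
  }
})
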