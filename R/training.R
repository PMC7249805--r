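# training protocol: supervision-mask preparation, Adam with inverse-time
# learning-rate decay, epoch loop with online augmentation and intermediate
# supervision across refinement steps, Quality-based validation with early
# stopping, and stratified fold splitting

#' Training configuration
#'
#' Defaults follow the published protocol: Adam, batch size 2, initial
#' learning rate 1e-4 decayed by inverse-time scheduling with rate 0.5 per
#' epoch, up to 6000 optimizer steps, early stopping after 10 epochs
#' without validation improvement once at least 1000 steps have elapsed,
#' validation by the Quality metric at tolerance 2 after thresholding at
#' 0.5 and skeletonizing.
#'
#' @param lr0 initial learning rate
#' @param decay_rate inverse-time decay rate per epoch
#' @param batch_size images per optimizer step
#' @param max_steps maximum optimizer steps
#' @param min_steps steps that must elapse before early stopping may fire
#' @param patience_epochs epochs without improvement that trigger stopping
#' @param val_tau matching tolerance (px) of the validation Quality
#' @param binarize_threshold threshold applied before skeletonizing
#' @param net a [net_config()]
#' @param loss a [loss_config()]
#' @param augment an [augment_config()], or `NULL` to disable online
#'   augmentation
#' @param offline_rotations quadruple the training set by fixed rotations
#' @param seed master RNG seed for initialization, batching and augmentation
#' @return list of class `train_config`
#' @export
train_config <- function(lr0 = 1e-4, decay_rate = 0.5, batch_size = 2L,
                         max_steps = 6000L, min_steps = 1000L,
                         patience_epochs = 10L, val_tau = 2,
                         binarize_threshold = 0.5, net = net_config(),
                         loss = loss_config(), augment = augment_config(),
                         offline_rotations = TRUE, seed = 1L) {
  stopifnot(min_steps <= max_steps, patience_epochs >= 1)
  structure(list(lr0 = lr0, decay_rate = decay_rate,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 min_steps = as.integer(min_steps),
                 patience_epochs = as.integer(patience_epochs),
                 val_tau = val_tau, binarize_threshold = binarize_threshold,
                 net = net, loss = loss, augment = augment,
                 offline_rotations = offline_rotations,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Dilate a centerline mask to densify the supervision signal
#'
#' Morphological dilation with a `(2 * radius + 1)` square structuring
#' element; the default 1-px dilation turns the 1-px annotation into a
#' 3-px-wide supervision band.
#'
#' @param mask binary matrix
#' @param radius dilation radius in pixels
#' @return 0/1 integer matrix containing the input (dilation is extensive)
#' @export
dilate_centerline <- function(mask, radius = 1L) {
  if (radius < 1L) return((mask > 0) + 0L)
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  k <- EBImage::makeBrush(2L * radius + 1L, shape = "box")
  (as.matrix(EBImage::dilate(m, k)) > 0) + 0L
}

#' Inverse-time learning-rate schedule
#'
#' `lr = lr0 / (1 + decay_rate * floor(step / steps_per_epoch))` — the rate
#' halves after two full epochs at the default `decay_rate = 0.5`.
#'
#' @param step 0-based optimizer step
#' @param steps_per_epoch optimizer steps per epoch
#' @param config a [train_config()]
#' @return learning rate
#' @export
lr_schedule <- function(step, steps_per_epoch, config = train_config()) {
  stopifnot(step >= 0, steps_per_epoch >= 1)
  config$lr0 / (1 + config$decay_rate * (step %/% steps_per_epoch))
}

# early stopping: TRUE once `patience` epochs have passed since the best
# validation value and at least `min_steps` optimizer steps have elapsed
should_stop <- function(val_trace, steps_elapsed, patience, min_steps) {
  if (length(val_trace) < patience + 1L) return(FALSE)
  since_best <- length(val_trace) - which.max(val_trace)
  since_best >= patience && steps_elapsed >= min_steps
}

#' Stratified k-fold split with disjoint, exhaustive test sets
#'
#' Within every stratum the ids are shuffled (seeded) and dealt round-robin
#' to the k folds; fold f tests on its own share, validates on the share of
#' fold f+1 (cyclically), and trains on the rest. Test sets across folds
#' partition the dataset, and every stratum appears in train, validation
#' and test whenever it has at least k members.
#'
#' @param ids vector of sample identifiers
#' @param strata stratum label per id (e.g. pathology class)
#' @param k fold count (default 4)
#' @param seed shuffle seed
#' @return list of k folds, each with `train`, `val`, `test`; the stratum
#'   assignment is attached as attribute `strata`
#' @export
stratified_folds <- function(ids, strata = rep(1L, length(ids)), k = 4L,
                             seed = 1L) {
  stopifnot(length(ids) == length(strata), k >= 2, length(ids) >= k)
  assign_fold <- integer(length(ids))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      assign_fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    test <- ids[assign_fold == f]
    vf <- if (f == k) 1L else f + 1L
    val <- ids[assign_fold == vf]
    train <- ids[!(assign_fold %in% c(f, vf))]
    list(train = train, val = val, test = test)
  })
  attr(folds, "strata") <- stats::setNames(strata, ids)
  folds
}

#' Mean validation Quality of a model
#'
#' For each sample the final refinement-step prediction is thresholded,
#' skeletonized, and scored against the ground-truth centerline at
#' tolerance `tau`.
#'
#' @param model an `octaseg_model`, or a function `image -> probability map`
#'   (useful for oracle checks)
#' @param val_samples list of samples with `image` and `centerline`
#' @param tau matching tolerance in pixels
#' @param threshold binarization threshold
#' @return mean Quality over the validation samples
#' @export
validate_quality <- function(model, val_samples, tau = 2, threshold = 0.5) {
  stopifnot(length(val_samples) >= 1L)
  q <- vapply(val_samples, function(s) {
    p <- if (is.function(model)) model(s$image)
         else {
           preds <- predict_iterative(model, s$image)
           preds[[length(preds)]]
         }
    sk <- skeletonize(binarize(p, threshold))
    delineation_metrics(sk, s$centerline, tau)$quality
  }, numeric(1L))
  mean(q)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_update <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

# forward all refinement steps of one sample with caches, compute the
# per-step combined losses and their gradients, and backpropagate through
# the whole unrolled computation (gradients flow through the fed-back
# prediction channel). Returns flat per-module gradient vectors and the
# scalar training loss.
train_backprop_sample <- function(modules, config, image, target, extractor,
                                  target_taps, loss_cfg, variant, n_steps) {
  shared <- variant != "shn"
  fwd <- vector("list", n_steps)
  prev <- matrix(0, nrow(image), ncol(image))
  for (t in seq_len(n_steps)) {
    params <- if (shared) modules[[1L]] else modules[[t]]
    fwd[[t]] <- module_forward(params, config, image, prev, keep_cache = TRUE)
    prev <- fwd[[t]]$prob
  }
  wts <- if (variant == "iunet") iteration_weights(n_steps)
         else rep(1, n_steps)
  use_topo <- isTRUE(loss_cfg$use_topo)
  per_step <- numeric(n_steps)
  dprob <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    p <- fwd[[t]]$prob
    bce <- balanced_bce(p, target)
    g <- balanced_bce_grad(p, target)
    l_topo <- 0
    if (use_topo) {
      lg <- extractor_loss_grad(extractor, p, target_taps, loss_cfg$mu)
      l_topo <- sum(lg$terms)
      g <- g + lg$dpred
    }
    per_step[t] <- bce$l_bce + l_topo
    dprob[[t]] <- wts[t] * g
  }
  n_mod <- length(modules)
  gsum <- vector("list", n_mod)
  carry <- NULL
  for (t in rev(seq_len(n_steps))) {
    d <- dprob[[t]]
    if (!is.null(carry)) d <- d + carry
    params <- if (shared) modules[[1L]] else modules[[t]]
    bk <- module_backward(params, config, fwd[[t]]$cache, d)
    gi <- if (shared) 1L else t
    gv <- grads_flatten(params, bk$grads)
    gsum[[gi]] <- if (is.null(gsum[[gi]])) gv else gsum[[gi]] + gv
    carry <- if (t > 1L) bk$dprev else NULL
  }
  for (i in seq_len(n_mod))
    if (is.null(gsum[[i]])) gsum[[i]] <- numeric(length(module_flatten(modules[[i]])))
  list(grads = gsum, loss = iterative_loss(per_step, variant))
}

#' Train a model
#'
#' Runs the full protocol: optional offline rotation of the training set,
#' per-step minibatches with online augmentation, forward passes through
#' all refinement steps, the combined class-balanced/perceptual loss with
#' intermediate supervision (iteration-weighted for the recurrent variant,
#' summed for the hourglass cascade), Adam updates under the inverse-time
#' schedule, per-epoch validation by mean Quality, best-checkpoint
#' retention and early stopping.
#'
#' @param train_samples list of samples with `image` and `centerline`
#' @param val_samples validation samples (same structure)
#' @param config a [train_config()]
#' @param verbose print per-epoch progress
#' @return list with `model` (best-validation checkpoint), `final_model`
#'   (last state), `history` (per-step data frame: step, epoch, loss, lr)
#'   and `val_history` (per-epoch mean Quality)
#' @export
train_loop <- function(train_samples, val_samples, config = train_config(),
                       verbose = FALSE) {
  stopifnot(length(train_samples) >= 1L, length(val_samples) >= 1L)
  net <- config$net
  variant <- net$variant
  n_steps <- switch(variant, unet = 1L, iunet = net$T_iterations,
                    shn = net$k_modules)
  if (isTRUE(config$offline_rotations))
    train_samples <- offline_rotations(train_samples)
  # supervision masks: centerlines dilated by 1 px
  for (i in seq_along(train_samples))
    train_samples[[i]]$target <- dilate_centerline(train_samples[[i]]$centerline)
  extractor <- NULL
  target_taps <- NULL
  use_topo <- isTRUE(config$loss$use_topo)
  if (use_topo) {
    extractor <- make_feature_extractor(config$loss)
    if (is.null(config$augment)) {
      # fixed targets: their feature taps can be computed once
      target_taps <- lapply(train_samples, function(s)
        extractor_forward(extractor, s$target + 0)$taps)
    }
  }
  model <- build_model(net, seed = config$seed)
  n_mod <- length(model$modules)
  theta <- lapply(model$modules, module_flatten)
  opt <- lapply(theta, function(v) adam_init(length(v)))
  N <- length(train_samples)
  steps_per_epoch <- max(1L, as.integer(ceiling(N / config$batch_size)))
  history <- list()
  val_history <- numeric(0L)
  best <- list(q = -Inf, modules = model$modules)
  step <- 0L
  epoch <- 0L
  with_seed(config$seed + 1L, {
    repeat {
      epoch <- epoch + 1L
      perm <- sample.int(N)
      for (b in seq_len(steps_per_epoch)) {
        if (step >= config$max_steps) break
        idx <- perm[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, N)]
        lr <- lr_schedule(step, steps_per_epoch, config)
        gacc <- lapply(theta, function(v) numeric(length(v)))
        loss_acc <- 0
        for (i in idx) {
          s <- train_samples[[i]]
          img <- s$image
          tgt <- s$target
          ttaps <- if (use_topo) target_taps[[i]]
          if (!is.null(config$augment)) {
            a <- online_augment(img, tgt, config$augment)
            img <- a$image
            tgt <- a$mask
            ttaps <- NULL
          }
          if (use_topo && is.null(ttaps))
            ttaps <- extractor_forward(extractor, tgt + 0)$taps
          r <- train_backprop_sample(model$modules, net, img, tgt, extractor,
                                     ttaps, config$loss, variant, n_steps)
          if (!is.finite(r$loss))
            stop("training diverged: non-finite loss at step ", step)
          for (m in seq_len(n_mod)) gacc[[m]] <- gacc[[m]] + r$grads[[m]]
          loss_acc <- loss_acc + r$loss
        }
        nb <- length(idx)
        for (m in seq_len(n_mod)) {
          u <- adam_update(opt[[m]], theta[[m]], gacc[[m]] / nb, lr)
          opt[[m]] <- u$state
          theta[[m]] <- u$theta
          model$modules[[m]] <- module_unflatten(model$modules[[m]], u$theta)
        }
        step <- step + 1L
        history[[step]] <- data.frame(step = step, epoch = epoch,
                                      loss = loss_acc / nb, lr = lr)
      }
      q <- validate_quality(model, val_samples, config$val_tau,
                            config$binarize_threshold)
      val_history <- c(val_history, q)
      if (q > best$q) best <- list(q = q, modules = model$modules)
      if (verbose)
        message(sprintf("epoch %d  step %d  loss %.4f  val Quality %.4f",
                        epoch, step, history[[step]]$loss, q))
      if (step >= config$max_steps) break
      if (should_stop(val_history, step, config$patience_epochs,
                      config$min_steps)) break
    }
  })
  best_model <- structure(list(config = net, modules = best$modules),
                          class = "octaseg_model")
  list(model = best_model, final_model = model,
       history = do.call(rbind, history), val_history = val_history,
       best_quality = best$q)
}
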