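# residual U-Net base network and its iterative refinement wrappers
#
# A base module maps a 2-channel input (image, previous prediction) to a
# probability map at the input resolution. The encoder stacks residual
# blocks with 2x max pooling between them and doubling feature counts; the
# decoder mirrors it with 2x transposed convolutions and skip
# concatenations; a 1x1 convolution plus element-wise sigmoid produces the
# output. The stacked-hourglass wrapper (shn) cascades k distinct modules;
# the recurrent wrapper (iunet) applies one module T times with shared
# weights. Every refinement step — including the first, which receives an
# all-zero prediction channel — consumes the same 2-channel interface, so
# an shn with k modules has exactly k times the parameters of an iunet.

#' Network configuration
#'
#' @param in_channels input channels of each module (2: image + previous
#'   prediction)
#' @param base_filters feature maps of the first residual block (doubling at
#'   each deeper block); the published setting is 64, tests use 8
#' @param n_blocks residual blocks per encoder/decoder side (3, or 5 for
#'   the deeper ablation)
#' @param variant `"unet"`, `"shn"` or `"iunet"`
#' @param k_modules module count for `"shn"` (1..5)
#' @param T_iterations refinement iterations for `"iunet"` (1..5)
#' @return list of class `net_config`
#' @export
net_config <- function(in_channels = 2L, base_filters = 64L, n_blocks = 3L,
                       variant = c("unet", "shn", "iunet"), k_modules = 1L,
                       T_iterations = 1L) {
  variant <- match.arg(variant)
  stopifnot(n_blocks %in% c(3L, 5L), base_filters >= 1,
            k_modules %in% 1:5, T_iterations %in% 1:5)
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 n_blocks = as.integer(n_blocks), variant = variant,
                 k_modules = as.integer(k_modules),
                 T_iterations = as.integer(T_iterations)),
            class = "net_config")
}

new_conv <- function(cin, cout, k) {
  fan_in <- cin * k * k
  list(w = matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in),
       b = numeric(cout), k = as.integer(k), type = "conv")
}

new_convt <- function(cin, cout) {
  fan_in <- cin
  list(w = matrix(rnorm(cout * 4L * cin, 0, sqrt(2 / fan_in)), cout * 4L, cin),
       b = numeric(cout), type = "convt")
}

# ordered layer table of one base module
module_layout <- function(config) {
  n <- config$n_blocks
  E <- config$base_filters * 2L^(0:(n - 1L))
  layers <- list()
  add <- function(name, l) {
    l$name <- name
    layers[[name]] <<- l
  }
  cin <- config$in_channels
  for (i in seq_len(n)) {
    add(sprintf("enc%d_a", i), list(cin = cin, cout = E[i], k = 3L, what = "conv"))
    add(sprintf("enc%d_b", i), list(cin = E[i], cout = E[i], k = 3L, what = "conv"))
    add(sprintf("enc%d_p", i), list(cin = cin, cout = E[i], k = 1L, what = "conv"))
    cin <- E[i]
  }
  for (j in seq_len(n - 1L)) {
    skip <- E[n - j]
    add(sprintf("up%d", j), list(cin = cin, cout = skip, what = "convt"))
    add(sprintf("dec%d_a", j), list(cin = 2L * skip, cout = skip, k = 3L, what = "conv"))
    add(sprintf("dec%d_b", j), list(cin = skip, cout = skip, k = 3L, what = "conv"))
    add(sprintf("dec%d_p", j), list(cin = 2L * skip, cout = skip, k = 1L, what = "conv"))
    cin <- skip
  }
  add(sprintf("dec%d_a", n), list(cin = cin, cout = cin, k = 3L, what = "conv"))
  add(sprintf("dec%d_b", n), list(cin = cin, cout = cin, k = 3L, what = "conv"))
  add("out", list(cin = cin, cout = 1L, k = 1L, what = "conv"))
  layers
}

# initialize the weights of one base module (uses the current RNG stream)
init_module <- function(config) {
  lapply(module_layout(config), function(l) {
    p <- if (l$what == "convt") new_convt(l$cin, l$cout)
         else new_conv(l$cin, l$cout, l$k)
    p
  })
}

#' Build a model
#'
#' Initializes the trainable weights of the configured variant: one base
#' module for `"unet"`/`"iunet"`, `k_modules` distinct modules for `"shn"`.
#'
#' @param config a [net_config()]
#' @param seed RNG seed for weight initialization
#' @return object of class `octaseg_model` with `config` and `modules`
#' @export
build_model <- function(config = net_config(), seed = 1L) {
  n_mod <- if (config$variant == "shn") config$k_modules else 1L
  modules <- with_seed(seed, lapply(seq_len(n_mod), function(i) init_module(config)))
  structure(list(config = config, modules = modules), class = "octaseg_model")
}

#' Build a single base module (the plain residual U-Net)
#' @inheritParams build_model
#' @return `octaseg_model` with variant `"unet"`
#' @export
build_base <- function(config = net_config(), seed = 1L) {
  config$variant <- "unet"
  build_model(config, seed)
}

#' Total trainable parameter count
#' @param model an `octaseg_model` (or a bare module list)
#' @return integer scalar
#' @export
count_parameters <- function(model) {
  modules <- if (inherits(model, "octaseg_model")) model$modules else model
  sum(vapply(modules, function(m)
    sum(vapply(m, function(l) length(l$w) + length(l$b), numeric(1L))),
    numeric(1L)))
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the weights plus the full architecture metadata, so
#' reloading rebuilds a model with bit-identical forward outputs.
#'
#' @param model an `octaseg_model`
#' @param path checkpoint path (`.rds`)
#' @return `save_model` the path invisibly; `load_model` the model
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "octaseg_model"))
  saveRDS(list(format = "octaseg-checkpoint-1", config = model$config,
               modules = model$modules), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, "octaseg-checkpoint-1"))
    stop("not an octaseg checkpoint: ", path)
  structure(list(config = x$config, modules = x$modules),
            class = "octaseg_model")
}

# ---- forward / backward -----------------------------------------------------

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# reflect-pad an H x W x C array on the bottom/right to (H2, W2)
pad_reflect <- function(x, H2, W2) {
  H <- dim(x)[1L]; W <- dim(x)[2L]
  if (H == H2 && W == W2) return(x)
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(H2)]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(W2)]
  x[ri, ci, , drop = FALSE]
}

rb_forward <- function(pa, pb, pp, x, keep) {
  z1 <- cpp_conv2d_fwd(x, pa$w, pa$b, pa$k)
  h1 <- relu(z1)
  z2 <- cpp_conv2d_fwd(h1, pb$w, pb$b, pb$k)
  s <- if (is.null(pp)) x else cpp_conv2d_fwd(x, pp$w, pp$b, pp$k)
  z <- z2 + s
  y <- relu(z)
  cache <- if (keep) list(x = x, pos1 = z1 > 0, h1 = h1, pos = z > 0)
  list(y = y, cache = cache)
}

rb_backward <- function(pa, pb, pp, cache, dy) {
  dz <- dy * cache$pos
  gb <- cpp_conv2d_bwd(cache$h1, pb$w, dz, pb$k, TRUE, TRUE)
  dz1 <- gb$dx * cache$pos1
  ga <- cpp_conv2d_bwd(cache$x, pa$w, dz1, pa$k, TRUE, TRUE)
  dx <- ga$dx
  grads <- list()
  grads$a <- list(dw = ga$dw, db = ga$db)
  grads$b <- list(dw = gb$dw, db = gb$db)
  if (is.null(pp)) {
    dx <- dx + dz
  } else {
    gp <- cpp_conv2d_bwd(cache$x, pp$w, dz, pp$k, TRUE, TRUE)
    dx <- dx + gp$dx
    grads$p <- list(dw = gp$dw, db = gp$db)
  }
  list(dx = dx, grads = grads)
}

# forward pass of one module on (image, prev_pred); returns the probability
# matrix and, when keep_cache, everything needed by module_backward
module_forward <- function(params, config, image, prev_pred, keep_cache = FALSE) {
  H <- nrow(image); W <- ncol(image)
  n <- config$n_blocks
  m <- 2L^(n - 1L)
  H2 <- as.integer(ceiling(H / m) * m)
  W2 <- as.integer(ceiling(W / m) * m)
  x <- array(c(image, prev_pred), dim = c(H, W, 2L))
  x <- pad_reflect(x, H2, W2)
  caches <- list()
  enc_out <- list()
  for (i in seq_len(n)) {
    r <- rb_forward(params[[sprintf("enc%d_a", i)]],
                    params[[sprintf("enc%d_b", i)]],
                    params[[sprintf("enc%d_p", i)]], x, keep_cache)
    caches[[sprintf("enc%d", i)]] <- r$cache
    enc_out[[i]] <- r$y
    if (i < n) {
      p <- cpp_maxpool2_fwd(r$y)
      caches[[sprintf("pool%d", i)]] <- list(idx = p$idx, dims = dim(r$y))
      x <- p$y
    } else x <- r$y
  }
  for (j in seq_len(n - 1L)) {
    up <- params[[sprintf("up%d", j)]]
    u <- cpp_convt2_fwd(x, up$w, up$b)
    skip <- enc_out[[n - j]]
    caches[[sprintf("upin%d", j)]] <- if (keep_cache) list(x = x)
    xc <- array(c(u, skip), dim = c(dim(u)[1L], dim(u)[2L],
                                    dim(u)[3L] + dim(skip)[3L]))
    caches[[sprintf("cat%d", j)]] <- list(c_up = dim(u)[3L])
    r <- rb_forward(params[[sprintf("dec%d_a", j)]],
                    params[[sprintf("dec%d_b", j)]],
                    params[[sprintf("dec%d_p", j)]], xc, keep_cache)
    caches[[sprintf("dec%d", j)]] <- r$cache
    x <- r$y
  }
  r <- rb_forward(params[[sprintf("dec%d_a", n)]],
                  params[[sprintf("dec%d_b", n)]], NULL, x, keep_cache)
  caches[[sprintf("dec%d", n)]] <- r$cache
  out <- params[["out"]]
  z <- cpp_conv2d_fwd(r$y, out$w, out$b, out$k)
  prob_full <- sigmoid(z[, , 1L])
  prob <- prob_full[seq_len(H), seq_len(W)]
  if (keep_cache)
    list(prob = prob,
         cache = list(caches = caches, out_x = r$y, prob_full = prob_full,
                      H = H, W = W, H2 = H2, W2 = W2))
  else list(prob = prob)
}

# backward pass of one module given dL/dprob (H x W matrix); returns
# per-layer weight gradients and the gradient w.r.t. the 2-channel input
module_backward <- function(params, config, cache, dprob) {
  n <- config$n_blocks
  caches <- cache$caches
  dfull <- matrix(0, cache$H2, cache$W2)
  dfull[seq_len(cache$H), seq_len(cache$W)] <- dprob
  p <- cache$prob_full
  dz <- array(dfull * p * (1 - p), dim = c(cache$H2, cache$W2, 1L))
  grads <- list()
  out <- params[["out"]]
  g <- cpp_conv2d_bwd(cache$out_x, out$w, dz, out$k, TRUE, TRUE)
  grads[["out"]] <- list(dw = g$dw, db = g$db)
  dy <- g$dx
  bk <- rb_backward(params[[sprintf("dec%d_a", n)]],
                    params[[sprintf("dec%d_b", n)]], NULL,
                    caches[[sprintf("dec%d", n)]], dy)
  grads[[sprintf("dec%d_a", n)]] <- bk$grads$a
  grads[[sprintf("dec%d_b", n)]] <- bk$grads$b
  dy <- bk$dx
  denc <- vector("list", n)  # gradients flowing into encoder outputs
  for (j in rev(seq_len(n - 1L))) {
    bk <- rb_backward(params[[sprintf("dec%d_a", j)]],
                      params[[sprintf("dec%d_b", j)]],
                      params[[sprintf("dec%d_p", j)]],
                      caches[[sprintf("dec%d", j)]], dy)
    grads[[sprintf("dec%d_a", j)]] <- bk$grads$a
    grads[[sprintf("dec%d_b", j)]] <- bk$grads$b
    grads[[sprintf("dec%d_p", j)]] <- bk$grads$p
    c_up <- caches[[sprintf("cat%d", j)]]$c_up
    dcat <- bk$dx
    du <- dcat[, , seq_len(c_up), drop = FALSE]
    denc[[n - j]] <- dcat[, , -seq_len(c_up), drop = FALSE]
    up <- params[[sprintf("up%d", j)]]
    gu <- cpp_convt2_bwd(caches[[sprintf("upin%d", j)]]$x, up$w, du, TRUE, TRUE)
    grads[[sprintf("up%d", j)]] <- list(dw = gu$dw, db = gu$db)
    dy <- gu$dx
  }
  for (i in rev(seq_len(n))) {
    if (i < n) {
      d <- caches[[sprintf("pool%d", i)]]
      dy <- cpp_maxpool2_bwd(d$idx, dy, d$dims[1L], d$dims[2L], d$dims[3L])
    }
    if (!is.null(denc[[i]])) dy <- dy + denc[[i]]
    bk <- rb_backward(params[[sprintf("enc%d_a", i)]],
                      params[[sprintf("enc%d_b", i)]],
                      params[[sprintf("enc%d_p", i)]],
                      caches[[sprintf("enc%d", i)]], dy)
    grads[[sprintf("enc%d_a", i)]] <- bk$grads$a
    grads[[sprintf("enc%d_b", i)]] <- bk$grads$b
    grads[[sprintf("enc%d_p", i)]] <- bk$grads$p
    dy <- bk$dx
  }
  dinput <- dy[seq_len(cache$H), seq_len(cache$W), , drop = FALSE]
  list(grads = grads, dimage = dinput[, , 1L], dprev = dinput[, , 2L])
}

#' Single forward pass of a base module
#'
#' @param model an `octaseg_model` (its first module is used)
#' @param image grayscale matrix in `[0, 1]`
#' @param prev_pred previous prediction map of the same shape; defaults to
#'   the all-zero map used at the first refinement step
#' @return probability matrix in `[0, 1]` at the input resolution
#' @export
forward_base <- function(model, image, prev_pred = NULL) {
  if (is.null(prev_pred)) prev_pred <- matrix(0, nrow(image), ncol(image))
  assert_same_shape(image, prev_pred, "image and prev_pred")
  module_forward(model$modules[[1L]], model$config, image, prev_pred)$prob
}

#' Forward pass of a stacked-hourglass cascade
#'
#' Module 1 receives the image with a zero prediction channel; each later
#' module receives the previous module's prediction. All intermediate
#' predictions are returned (ordered, last = final).
#'
#' @param model an `octaseg_model` with variant `"shn"` (or any model whose
#'   modules should be cascaded)
#' @param image grayscale matrix in `[0, 1]`
#' @return list of probability matrices, one per module
#' @export
forward_shn <- function(model, image) {
  modules <- model$modules
  stopifnot(length(modules) >= 1L)
  prev <- matrix(0, nrow(image), ncol(image))
  preds <- vector("list", length(modules))
  for (j in seq_along(modules)) {
    prev <- module_forward(modules[[j]], model$config, image, prev)$prob
    preds[[j]] <- prev
  }
  preds
}

#' Forward pass of the recurrent refinement model
#'
#' The same weights are applied at every iteration; iteration 1 uses a zero
#' prediction channel and iteration t > 1 feeds back prediction t - 1.
#'
#' @param model an `octaseg_model`
#' @param image grayscale matrix in `[0, 1]`
#' @param T number of refinement iterations (defaults to the configured
#'   `T_iterations`)
#' @return list of `T` probability matrices (ordered, last = final)
#' @export
forward_iunet <- function(model, image, T = model$config$T_iterations) {
  stopifnot(T >= 1)
  params <- model$modules[[1L]]
  prev <- matrix(0, nrow(image), ncol(image))
  preds <- vector("list", T)
  for (t in seq_len(T)) {
    prev <- module_forward(params, model$config, image, prev)$prob
    preds[[t]] <- prev
  }
  preds
}

#' All refinement-step predictions of a model
#'
#' Dispatches on the model's variant: a plain U-Net yields one prediction,
#' an shn one per module, an iunet one per iteration.
#'
#' @inheritParams forward_iunet
#' @return list of probability matrices (ordered, last = final)
#' @export
predict_iterative <- function(model, image) {
  switch(model$config$variant,
    unet = list(forward_base(model, image)),
    shn = forward_shn(model, image),
    iunet = forward_iunet(model, image)
  )
}

# ---- flat parameter vector helpers (used by the optimizer) ------------------

module_flatten <- function(params) {
  unlist(lapply(params, function(l) c(as.numeric(l$w), as.numeric(l$b))),
         use.names = FALSE)
}

module_unflatten <- function(params, vec) {
  i <- 0L
  for (nm in names(params)) {
    nw <- length(params[[nm]]$w)
    params[[nm]]$w[] <- vec[i + seq_len(nw)]
    i <- i + nw
    nb <- length(params[[nm]]$b)
    params[[nm]]$b[] <- vec[i + seq_len(nb)]
    i <- i + nb
  }
  params
}

grads_flatten <- function(params, grads) {
  unlist(lapply(names(params), function(nm) {
    g <- grads[[nm]]
    c(as.numeric(g$dw), as.numeric(g$db))
  }), use.names = FALSE)
}
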