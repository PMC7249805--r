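# loss functions: class-balanced cross-entropy, feature-space perceptual
# ("topological") loss, their combination, and the iteration weighting used
# for intermediate supervision of refinement models

BCE_EPS <- 1e-7

#' Loss configuration
#'
#' @param mu per-layer weighing factors of the perceptual loss, one per
#'   feature tap; defaults `1e-2, 1e-3, 1e-4` for the three taps
#' @param extractor_kind `"seeded-random"` (frozen random filters in the
#'   VGG19 layout, usable offline) or `"vgg19-imagenet"` (published
#'   pretrained weights; requires them to be available locally)
#' @param use_topo include the perceptual term in the combined loss
#' @param extractor_seed seed for the random frozen filters
#' @return list of class `loss_config`
#' @export
loss_config <- function(mu = c(1e-2, 1e-3, 1e-4),
                        extractor_kind = c("seeded-random", "vgg19-imagenet"),
                        use_topo = TRUE, extractor_seed = 771L) {
  stopifnot(all(mu >= 0), length(mu) >= 1L)
  structure(list(mu = mu, extractor_kind = match.arg(extractor_kind),
                 use_topo = use_topo, extractor_seed = extractor_seed),
            class = "loss_config")
}

#' Class-balanced binary cross-entropy
#'
#' \deqn{L = -\beta \sum_{i \in Y_+} \log p_i - (1-\beta) \sum_{i \in Y_-} \log(1 - p_i)}
#' with \eqn{Y_+} the vessel pixels and \eqn{\beta = |Y_-|/|Y|}, so the rare
#' vessel class receives the large weight. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]`. An all-background target makes the positive sum empty
#' and the negative weight zero; the loss is 0 and flagged degenerate.
#'
#' @param pred probability map in `[0, 1]`
#' @param target binary supervision mask of the same shape
#' @return list with `l_bce`, `beta`, `n_pos`, `n_neg`, `degenerate`
#' @export
balanced_bce <- function(pred, target) {
  assert_same_shape(pred, target, "pred and target")
  t <- target > 0
  n_pos <- sum(t)
  n_neg <- length(t) - n_pos
  beta <- n_neg / (n_pos + n_neg)
  p <- pmin(pmax(pred, BCE_EPS), 1 - BCE_EPS)
  l <- -beta * sum(log(p[t])) - (1 - beta) * sum(log(1 - p[!t]))
  list(l_bce = l, beta = beta, n_pos = n_pos, n_neg = n_neg,
       degenerate = n_pos == 0L)
}

# analytic gradient of balanced_bce w.r.t. pred (zero where clamped)
balanced_bce_grad <- function(pred, target) {
  t <- target > 0
  n <- length(t)
  beta <- sum(!t) / n
  inside <- pred > BCE_EPS & pred < 1 - BCE_EPS
  p <- pmin(pmax(pred, BCE_EPS), 1 - BCE_EPS)
  g <- ifelse(t, -beta / p, (1 - beta) / (1 - p))
  g * inside
}

# ---- feature extractor ------------------------------------------------------

# conv layout of VGG19 up to the third feature tap; `tap` marks the
# post-ReLU activations that enter the perceptual loss
EXTRACTOR_LAYOUT <- list(
  list(name = "conv1_1", cin = 3L,   cout = 64L,  tap = FALSE),
  list(name = "conv1_2", cin = 64L,  cout = 64L,  tap = TRUE),
  list(name = "pool1"),
  list(name = "conv2_1", cin = 64L,  cout = 128L, tap = FALSE),
  list(name = "conv2_2", cin = 128L, cout = 128L, tap = TRUE),
  list(name = "pool2"),
  list(name = "conv3_1", cin = 128L, cout = 256L, tap = FALSE),
  list(name = "conv3_2", cin = 256L, cout = 256L, tap = FALSE),
  list(name = "conv3_3", cin = 256L, cout = 256L, tap = FALSE),
  list(name = "conv3_4", cin = 256L, cout = 256L, tap = TRUE)
)

#' Build the frozen feature extractor for the perceptual loss
#'
#' The perceptual loss compares feature maps of the prediction and of the
#' ground truth extracted at the post-ReLU activations of `conv1_2`,
#' `conv2_2` and `conv3_4` of a VGG19-shaped network (channel widths 64,
#' 128, 256 at scales 1, 1/2, 1/4). Kind `"seeded-random"` freezes
#' He-initialized random filters from a fixed seed, giving a deterministic
#' extractor that needs no downloaded weights; random frozen features are a
#' recognised basis for perceptual distances. Kind `"vgg19-imagenet"`
#' requires the published pretrained weights, which this package does not
#' bundle.
#'
#' @param config a [loss_config()]
#' @return object of class `feature_extractor`
#' @export
make_feature_extractor <- function(config = loss_config()) {
  if (config$extractor_kind == "vgg19-imagenet")
    stop("pretrained VGG19 weights are not bundled and no download is ",
         "attempted; use extractor_kind = \"seeded-random\" instead")
  convs <- Filter(function(l) startsWith(l$name, "conv"), EXTRACTOR_LAYOUT)
  params <- with_seed(config$extractor_seed, {
    lapply(convs, function(l) {
      fan_in <- l$cin * 9L
      list(w = matrix(rnorm(l$cout * fan_in, 0, sqrt(2 / fan_in)),
                      l$cout, fan_in),
           b = numeric(l$cout))
    })
  })
  structure(list(kind = config$extractor_kind,
                 conv_names = vapply(convs, `[[`, character(1L), "name"),
                 w = lapply(params, `[[`, "w"),
                 b = lapply(params, `[[`, "b")),
            class = "feature_extractor")
}

# forward pass through the extractor; x is an H x W map in [0, 1] which is
# replicated to the 3 input channels. Returns the three tap activations.
extractor_forward <- function(extractor, x) {
  H <- nrow(x); W <- ncol(x)
  if (H %% 4L != 0L || W %% 4L != 0L)
    stop("extractor input sides must be multiples of 4")
  r <- cpp_extractor_run(x, extractor$w, extractor$b, numeric(3L), NULL,
                         TRUE, FALSE)
  list(taps = r$taps)
}

# fused forward + backward: per-tap perceptual terms and the gradient of
# their sum w.r.t. the input map
extractor_loss_grad <- function(extractor, pred, target_taps, mu) {
  cpp_extractor_run(pred, extractor$w, extractor$b, mu, target_taps,
                    FALSE, TRUE)
}

#' Perceptual (topological) loss
#'
#' \deqn{L_{topo} = \sum_n \frac{\mu_n}{W_n H_n C_n} \sum_c \lVert F_n^c(pred) - F_n^c(target) \rVert_2^2}
#' summed over the extractor's feature taps, with the target fed through the
#' same frozen extractor as a float image.
#'
#' @param pred probability map in `[0, 1]`
#' @param target supervision mask as a float image of the same shape
#' @param extractor a [make_feature_extractor()] result
#' @param mu per-tap weighing factors
#' @return list with `l_topo_per_layer` and their sum `l_topo`
#' @export
perceptual_loss <- function(pred, target, extractor,
                            mu = c(1e-2, 1e-3, 1e-4)) {
  assert_same_shape(pred, target, "pred and target")
  fp <- extractor_forward(extractor, pred)$taps
  ft <- extractor_forward(extractor, target)$taps
  per <- perceptual_terms(fp, ft, mu)
  list(l_topo_per_layer = per, l_topo = sum(per))
}

perceptual_terms <- function(fp, ft, mu) {
  vapply(seq_along(fp), function(n) {
    d <- fp[[n]] - ft[[n]]
    mu[n] / length(d) * sum(d * d)
  }, numeric(1L))
}

#' Combined loss
#'
#' `l_comb = l_bce + sum(l_topo_per_layer)`; the relative weight of the two
#' terms is carried entirely by the per-layer factors `mu`.
#'
#' @inheritParams perceptual_loss
#' @param config a [loss_config()]
#' @param extractor optional prebuilt extractor (built on the fly otherwise)
#' @return list of class `loss_breakdown` with `beta`, `n_pos`, `n_neg`,
#'   `l_bce`, `l_topo_per_layer`, `l_comb`
#' @export
combined_loss <- function(pred, target, config = loss_config(),
                          extractor = NULL) {
  bce <- balanced_bce(pred, target)
  topo <- if (isTRUE(config$use_topo)) {
    if (is.null(extractor)) extractor <- make_feature_extractor(config)
    perceptual_loss(pred, target, extractor, config$mu)
  } else list(l_topo_per_layer = numeric(0L), l_topo = 0)
  structure(list(beta = bce$beta, n_pos = bce$n_pos, n_neg = bce$n_neg,
                 l_bce = bce$l_bce, l_topo_per_layer = topo$l_topo_per_layer,
                 l_comb = bce$l_bce + topo$l_topo,
                 degenerate = bce$degenerate),
            class = "loss_breakdown")
}

#' Iteration weights for the recurrent refinement loss
#'
#' `w_t = 2t / (T (T + 1))`: strictly increasing in `t` and summing to 1,
#' which pushes the recurrent model toward coarse-to-fine refinement while
#' keeping the overall loss scale independent of `T`.
#'
#' @param T number of refinement iterations (>= 1)
#' @return numeric vector of `T` weights
#' @export
iteration_weights <- function(T) {
  stopifnot(T >= 1)
  2 * seq_len(T) / (T * (T + 1))
}

#' Aggregate per-step losses across refinement steps
#'
#' The recurrent model (`"iunet"`) weighs the per-iteration combined losses
#' by [iteration_weights()]; the stacked-hourglass model (`"shn"`) sums its
#' per-module losses unweighted.
#'
#' @param per_step_losses numeric vector of per-step `l_comb` values
#' @param variant `"iunet"` or `"shn"` (a plain `"unet"` must have length 1)
#' @return scalar total loss
#' @export
iterative_loss <- function(per_step_losses, variant = c("iunet", "shn", "unet")) {
  variant <- match.arg(variant)
  T <- length(per_step_losses)
  stopifnot(T >= 1)
  switch(variant,
    iunet = sum(iteration_weights(T) * per_step_losses),
    shn = sum(per_step_losses),
    unet = {
      stopifnot(T == 1L)
      per_step_losses
    }
  )
}
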