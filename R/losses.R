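#' Contrastive and adversarial loss configuration
#'
#' @param tau softmax temperature (dimensionless, `> 0`); default 0.07.
#' @param lambda_x weight of the patch-contrastive loss on the source
#'   (CBCT) domain; default 1.
#' @param lambda_y weight of the identity patch-contrastive loss on the
#'   target (CT) domain; default 1.
#' @param n_patches locations sampled per tap layer per image (the other
#'   `n_patches - 1` locations of the same layer act as internal negatives).
#' @return a `LossConfig`.
#' @export
loss_config <- function(tau = 0.07, lambda_x = 1, lambda_y = 1,
                        n_patches = 64L) {
  if (tau <= 0) stop("tau must be > 0")
  if (lambda_x < 0 || lambda_y < 0) stop("lambda weights must be >= 0")
  if (n_patches < 2) stop("n_patches must be >= 2 so negatives exist")
  structure(list(tau = tau, lambda_x = lambda_x, lambda_y = lambda_y,
                 n_patches = as.integer(n_patches)),
            class = "LossConfig")
}

#' Patch-wise noise-contrastive loss for one query
#'
#' `-log[ exp(v.v+ / tau) / (exp(v.v+ / tau) + sum_n exp(v.v-_n / tau)) ]`,
#' the (N+1)-way softmax cross-entropy selecting the positive among N
#' negatives, computed with a log-sum-exp guard.  Under uniform logits the
#' value is `log(N + 1)`.
#'
#' @param query numeric vector `v` (unit norm).
#' @param positive numeric vector `v+` of the same length.
#' @param negatives matrix `[N, K]` of negative vectors, `N >= 1`.
#' @param tau temperature, `> 0`.
#' @return scalar loss (strictly positive).
#' @export
patch_nce_loss <- function(query, positive, negatives, tau = 0.07) {
  if (tau <= 0) stop("tau must be > 0")
  if (is.vector(negatives)) negatives <- matrix(negatives, nrow = 1)
  if (nrow(negatives) < 1) stop("at least one negative is required")
  logits <- c(sum(query * positive), as.vector(negatives %*% query)) / tau
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  lse - logits[1]
}

## fused InfoNCE over S queries with internal negatives: queries Zh[i, ]
## (features of the translated image), positives Z[i, ], negatives Z[j != i].
## Returns mean loss and gradients wrt both feature matrices.
nce_loss_grad <- function(Z, Zh, tau) {
  S <- nrow(Z)
  M <- (Zh %*% t(Z)) / tau            # logits, labels on the diagonal
  mx <- apply(M, 1, max)
  P <- exp(M - mx)
  P <- P / rowSums(P)
  loss <- -mean(log(pmax(diag(P), 1e-300)))
  dM <- P
  diag(dM) <- diag(dM) - 1
  dM <- dM / (S * tau)
  list(loss = loss, dZh = dM %*% Z, dZ = t(dM) %*% Zh)
}

#' Multi-layer patch-contrastive loss between an image and its translation
#'
#' For each image: translate it, sample `n_patches` locations per tap layer
#' (the same locations on input and output so positives correspond
#' spatially), project both feature sets, and average the per-location
#' contrastive loss over locations and layers; finally average over images.
#' Negatives are internal: for location `s`, the other `S - 1` sampled
#' locations of the same layer.  Applied to target-domain images this is the
#' identity contrastive term.
#'
#' @param model a `ClgGenerator`.
#' @param images list of 2D `ImageGrid`s (or a single one).
#' @param loss_config a [loss_config()].
#' @param seed optional seed for location sampling.
#' @return scalar loss.
#' @export
multilayer_patchnce <- function(model, images, loss_config = loss_config(),
                                seed = NULL) {
  if (is_image_grid(images)) images <- list(images)
  if (length(images) < 1) stop("at least one image required")
  if (!is.null(seed)) set.seed(seed)
  total <- 0
  for (img in images) {
    p <- pad_for_net(normalize_hu(img$values, model$spec$hu_window))
    locs <- sample_tap_locations(model, dim(p$x), loss_config$n_patches)
    fx <- encode_and_project(img, model, locs, loss_config)
    yhat <- translate(img, model)
    fy <- encode_and_project(yhat, model, locs, loss_config)
    acc <- 0
    for (key in names(locs)) {
      r <- nce_loss_grad(fx$layers[[key]], fy$layers[[key]], loss_config$tau)
      acc <- acc + r$loss
    }
    total <- total + acc / length(locs)
  }
  total / length(images)
}

#' Adversarial (GAN) value function
#'
#' `E[log D(y)] + E[log(1 - D(G(x)))]` in the probability convention.
#' Discriminator outputs outside (0, 1) are clamped to
#' `[1e-7, 1 - 1e-7]` with a warning (numerical guard).  The discriminator
#' ascends this value; the generator descends its second term (the
#' implementation trains G with the standard non-saturating surrogate).
#'
#' @param discriminator_outputs_real probabilities `D(y)` on real targets.
#' @param discriminator_outputs_fake probabilities `D(G(x))` on translations.
#' @return scalar value (`<= 0`, supremum 0 for a perfect discriminator).
#' @export
gan_loss <- function(discriminator_outputs_real, discriminator_outputs_fake) {
  r <- as.numeric(discriminator_outputs_real)
  f <- as.numeric(discriminator_outputs_fake)
  eps <- 1e-7
  if (any(r <= 0 | r >= 1) || any(f <= 0 | f >= 1)) {
    warning("discriminator outputs outside (0, 1); clamping")
    r <- pmin(pmax(r, eps), 1 - eps)
    f <- pmin(pmax(f, eps), 1 - eps)
  }
  mean(log(r)) + mean(log(1 - f))
}

## ---- discriminator --------------------------------------------------------

## small PatchGAN classifier; forward returns logits.  No normalization
## layers: per-image patch statistics (mean shifts from shading, variance
## shrink from contrast compression) are exactly the real-vs-fake cues at
## this scale, and instance norm would cancel them.
build_discriminator <- function(base_channels = 8L, seed = 1L) {
  nc <- as.integer(base_channels)
  layers <- list(
    layer_conv(1L, nc, 4L, 2L), layer_act("lrelu"),
    layer_conv(nc, 2L * nc, 4L, 2L), layer_act("lrelu"),
    layer_conv(2L * nc, 1L, 4L, 1L))
  net <- nn_sequential(layers)
  set.seed(seed)
  structure(list(net = net, params = nn_init_params(net)),
            class = "ClgDiscriminator")
}

disc_prob <- function(disc, x) {
  logits <- nn_forward(disc$net, disc$params, x)$y
  1 / (1 + exp(-logits))
}

#' Total CLG objective with component breakdown
#'
#' `L = L_GAN(G, D, X, Y) + lambda_x L_PatchNCE(G, H, X) +
#' lambda_y L_PatchNCE(G, H, Y)` evaluated (no gradients) on one batch.
#' With both lambdas zero the total equals the GAN term exactly.
#'
#' @param model a `ClgGenerator`.
#' @param disc a discriminator from [build_discriminator()].
#' @param x_batch,y_batch lists of source/target `ImageGrid`s.
#' @param loss_config a [loss_config()].
#' @param seed optional seed for patch sampling.
#' @return list with `total`, `gan`, `nce_x`, `nce_y`.
#' @export
total_loss <- function(model, disc, x_batch, y_batch,
                       loss_config = loss_config(), seed = NULL) {
  if (is_image_grid(x_batch)) x_batch <- list(x_batch)
  if (is_image_grid(y_batch)) y_batch <- list(y_batch)
  if (!is.null(seed)) set.seed(seed)
  w <- model$spec$hu_window
  pr_real <- unlist(lapply(y_batch, function(y)
    as.vector(disc_prob(disc, pad_for_net(normalize_hu(y$values, w))$x))))
  pr_fake <- unlist(lapply(x_batch, function(x) {
    yh <- translate(x, model)
    as.vector(disc_prob(disc, pad_for_net(normalize_hu(yh$values, w))$x))
  }))
  gan <- gan_loss(pr_real, pr_fake)
  nce_x <- if (loss_config$lambda_x > 0)
    multilayer_patchnce(model, x_batch, loss_config) else 0
  nce_y <- if (loss_config$lambda_y > 0)
    multilayer_patchnce(model, y_batch, loss_config) else 0
  list(total = gan + loss_config$lambda_x * nce_x + loss_config$lambda_y * nce_y,
       gan = gan, nce_x = nce_x, nce_y = nce_y)
}
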