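#' Training configuration for the CLG model
#'
#' Defaults follow the published protocol: Adam at learning rate 2e-4,
#' batch size one, 200 epochs with the learning rate held constant for the
#' first 50 epochs and then decayed linearly to zero by the final epoch.
#' Desk-scale experiments override `epochs`/`warm_epochs` downward.
#'
#' @param lr initial learning rate.
#' @param beta1,beta2 Adam moment coefficients.
#' @param epochs total training epochs (`>= 1`).
#' @param warm_epochs epochs at constant learning rate before linear decay.
#' @param batch_size images per update (the protocol uses 1).
#' @param seed integer seed controlling initialization, shuffling and patch
#'   sampling.
#' @param checkpoint_dir optional directory for periodic checkpoints.
#' @param checkpoint_every checkpoint period in epochs.
#' @return a `TrainConfig`.
#' @export
train_config <- function(lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         epochs = 200L, warm_epochs = 50L, batch_size = 1L,
                         seed = 1L, checkpoint_dir = NULL,
                         checkpoint_every = 50L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (lr <= 0) stop("learning rate must be > 0")
  if (warm_epochs > epochs) stop("warm_epochs cannot exceed epochs")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs),
                 warm_epochs = as.integer(warm_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch
#'
#' Constant at `lr` through `warm_epochs`, then linear to 0 at `epochs`.
#'
#' @param epoch 1-based epoch index.
#' @param config a [train_config()].
#' @return scalar learning rate.
#' @export
lr_schedule <- function(epoch, config) {
  if (epoch <= config$warm_epochs || config$epochs == config$warm_epochs)
    return(config$lr)
  config$lr * max(0, (config$epochs - epoch) /
                     (config$epochs - config$warm_epochs))
}

softplus <- function(z) log1p(exp(-abs(z))) + pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

## discriminator update on one (x, y) pair of padded normalized arrays;
## returns new disc/state and the Eq-3 value function for logging
clg_step_d <- function(model, disc, dstate, x, y, lr, tc) {
  fake <- gen_forward(model, x)$y
  fr <- nn_forward(disc$net, disc$params, y)
  ff <- nn_forward(disc$net, disc$params, fake)
  sr <- fr$y; sf <- ff$y
  nr <- length(sr); nf <- length(sf)
  d_loss <- mean(softplus(-sr)) + mean(softplus(sf))
  g_r <- nn_backward(disc$net, disc$params, fr$caches, -sigmoid(-sr) / nr)
  g_f <- nn_backward(disc$net, disc$params, ff$caches, sigmoid(sf) / nf)
  grads <- grads_add(g_r$grads, g_f$grads)
  st <- adam_step(disc$params, grads, dstate, lr, tc$beta1, tc$beta2)
  disc$params <- st$params
  # Eq-3 value in the probability convention, for the log
  gan_value <- mean(log(pmax(sigmoid(sr), 1e-12))) +
    mean(log(pmax(1 - sigmoid(sf), 1e-12)))
  list(disc = disc, dstate = st$state, d_loss = d_loss, gan_value = gan_value)
}

## patch-contrastive loss + grads for one full-generator pass:
## given taps of the source pass and an encoder pass on the translation,
## returns loss, tap gradients for both passes, and head gradients
nce_branch <- function(model, taps_src, fw_tr, locs, lc) {
  L <- length(locs)
  tapg_src <- list(); tapg_tr <- list(); headg <- list()
  loss <- 0
  for (key in names(locs)) {
    act_x <- taps_src[[key]]
    act_y <- fw_tr$taps[[key]]
    loc <- locs[[key]]
    Xv <- extract_at(act_x, loc)
    Yv <- extract_at(act_y, loc)
    hx <- head_forward(model$heads[[key]], Xv)
    hy <- head_forward(model$heads[[key]], Yv)
    r <- nce_loss_grad(hx$z, hy$z, lc$tau)
    loss <- loss + r$loss / L
    bx <- head_backward(model$heads[[key]], hx$cache, r$dZ / L)
    by <- head_backward(model$heads[[key]], hy$cache, r$dZh / L)
    headg[[key]] <- grads_add(bx$grads, by$grads)
    tapg_src[[key]] <- scatter_at(dim(act_x), loc, bx$dX)
    tapg_tr[[key]] <- scatter_at(dim(act_y), loc, by$dX)
  }
  list(loss = loss, tapg_src = tapg_src, tapg_tr = tapg_tr, headg = headg)
}

scatter_at <- function(d, loc, dX) {
  out <- matrix(0, d[1] * d[2], d[3])
  lin <- loc[, 1] + (loc[, 2] - 1) * d[1]
  out[lin, ] <- dX
  array(out, d)
}

## generator + head update on one (x, y) pair; returns new model/state and
## the loss components
clg_step_g <- function(model, disc, gstate, hstate, x, y, lr, lc, tc) {
  taps <- model$taps
  # --- source branch: GAN + lambda_x NCE
  fw_x <- gen_forward(model, x, taps = taps)
  yhat <- fw_x$y
  fw_yh <- nn_forward(model$net, model$params, yhat, upto = model$enc_end,
                      taps = taps)
  locs <- sample_tap_locations(model, dim(x), lc$n_patches)
  nx <- nce_branch(model, fw_x$taps, fw_yh, locs, lc)

  fd <- nn_forward(disc$net, disc$params, yhat)
  s <- fd$y
  g_gan <- mean(softplus(-s))               # non-saturating surrogate
  rd <- nn_backward(disc$net, disc$params, fd$caches, -sigmoid(-s) / length(s))
  dyhat <- rd$dx

  head_grads <- grads_scale(nx$headg, lc$lambda_x)
  r_yh <- nn_backward(model$net, model$params, fw_yh$caches,
                      array(0, dim(fw_yh$y)), from = model$enc_end,
                      tap_grads = grads_scale(nx$tapg_tr, lc$lambda_x))
  dyhat <- dyhat + r_yh$dx
  r_gx <- nn_backward(model$net, model$params, fw_x$caches, dyhat,
                      tap_grads = grads_scale(nx$tapg_src, lc$lambda_x))
  g_grads <- grads_add(r_yh$grads, r_gx$grads)

  # --- identity branch on the target domain: lambda_y NCE
  nce_y_val <- 0
  if (lc$lambda_y > 0) {
    fw_y <- gen_forward(model, y, taps = taps)
    fw_yhy <- nn_forward(model$net, model$params, fw_y$y,
                         upto = model$enc_end, taps = taps)
    locs_y <- sample_tap_locations(model, dim(y), lc$n_patches)
    ny <- nce_branch(model, fw_y$taps, fw_yhy, locs_y, lc)
    nce_y_val <- ny$loss
    head_grads <- grads_add(head_grads, grads_scale(ny$headg, lc$lambda_y))
    r_yhy <- nn_backward(model$net, model$params, fw_yhy$caches,
                         array(0, dim(fw_yhy$y)), from = model$enc_end,
                         tap_grads = grads_scale(ny$tapg_tr, lc$lambda_y))
    r_gy <- nn_backward(model$net, model$params, fw_y$caches, r_yhy$dx,
                        tap_grads = grads_scale(ny$tapg_src, lc$lambda_y))
    g_grads <- grads_add(g_grads, grads_add(r_yhy$grads, r_gy$grads))
  }

  stg <- adam_step(model$params, g_grads, gstate, lr, tc$beta1, tc$beta2)
  model$params <- stg$params
  sth <- adam_step(model$heads, head_grads, hstate, lr, tc$beta1, tc$beta2)
  model$heads <- sth$params
  list(model = model, gstate = stg$state, hstate = sth$state,
       g_gan = g_gan, nce_x = nx$loss, nce_y = nce_y_val)
}

#' Train the contrastive translation (CLG) model
#'
#' Unpaired training: per step one source (CBCT-like) and one target
#' (CT-like) slice are drawn, the discriminator is updated, then the
#' generator and projection heads are updated on the combined objective
#' (adversarial term plus weighted patch-contrastive terms on both
#' domains).  Learning follows [lr_schedule()].  Aborts on a non-finite
#' loss, retaining the last checkpoint when checkpointing is enabled.
#'
#' @param x_images list of source-domain 2D `ImageGrid`s (CBCT-like).
#' @param y_images list of target-domain 2D `ImageGrid`s (CT-like).
#' @param generator_spec a [generator_spec()].
#' @param loss_config a [loss_config()].
#' @param train_config a [train_config()].
#' @param verbose print per-epoch summaries.
#' @return list with `model` (a `ClgGenerator`), `disc`, and `log`: a
#'   data.frame with columns `epoch`, `L_GAN`, `L_NCE_X`, `L_NCE_Y`, `LR`.
#' @export
train_clg <- function(x_images, y_images, generator_spec = generator_spec(),
                      loss_config = loss_config(),
                      train_config = train_config(), verbose = FALSE) {
  if (length(x_images) < 1 || length(y_images) < 1)
    stop("both image sets must be nonempty")
  tc <- train_config; lc <- loss_config
  model <- build_generator(generator_spec, seed = tc$seed)
  disc <- build_discriminator(generator_spec$base_channels, seed = tc$seed + 1L)
  set.seed(tc$seed)
  w <- generator_spec$hu_window
  xs <- lapply(x_images, function(g) pad_for_net(normalize_hu(g$values, w))$x)
  ys <- lapply(y_images, function(g) pad_for_net(normalize_hu(g$values, w))$x)
  gstate <- adam_state(model$params)
  hstate <- adam_state(model$heads)
  dstate <- adam_state(disc$params)
  log_rows <- vector("list", tc$epochs)
  ckpt_path <- NULL
  for (epoch in seq_len(tc$epochs)) {
    lr <- lr_schedule(epoch, tc)
    order_x <- sample.int(length(xs))
    acc <- c(gan = 0, nce_x = 0, nce_y = 0)
    for (ix in order_x) {
      iy <- sample.int(length(ys), 1)
      sd_ <- clg_step_d(model, disc, dstate, xs[[ix]], ys[[iy]], lr, tc)
      disc <- sd_$disc; dstate <- sd_$dstate
      sg <- clg_step_g(model, disc, gstate, hstate, xs[[ix]], ys[[iy]],
                       lr, lc, tc)
      model <- sg$model; gstate <- sg$gstate; hstate <- sg$hstate
      if (!all(is.finite(c(sd_$d_loss, sg$g_gan, sg$nce_x, sg$nce_y))))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             if (!is.null(ckpt_path)) paste0("; last checkpoint: ", ckpt_path))
      acc <- acc + c(sd_$gan_value, sg$nce_x, sg$nce_y)
    }
    acc <- acc / length(xs)
    log_rows[[epoch]] <- data.frame(epoch = epoch, L_GAN = acc[["gan"]],
                                    L_NCE_X = acc[["nce_x"]],
                                    L_NCE_Y = acc[["nce_y"]], LR = lr)
    if (verbose)
      message(sprintf("epoch %d: L_GAN=%.3f L_NCE_X=%.3f L_NCE_Y=%.3f lr=%.2e",
                      epoch, acc[["gan"]], acc[["nce_x"]], acc[["nce_y"]], lr))
    if (!is.null(tc$checkpoint_dir) &&
        (epoch %% tc$checkpoint_every == 0 || epoch == tc$epochs)) {
      dir.create(tc$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      ckpt_path <- file.path(tc$checkpoint_dir,
                             sprintf("clg_epoch%03d.rds", epoch))
      saveRDS(list(model = model, disc = disc, epoch = epoch), ckpt_path)
    }
  }
  list(model = model, disc = disc, log = do.call(rbind, log_rows))
}
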