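#' Generator architecture description
#'
#' A ResNet-style one-way generator: an encoder (7x7 stem plus two strided
#' 3x3 stages), a stack of residual blocks, and a mirrored decoder
#' (upsample + 3x3 convolutions) with a tanh output head, operating on
#' single-channel 2D slices normalized to [-1, 1].  The declared tap layers
#' are the encoder stages whose features feed the patch-contrastive loss;
#' tap 0 is the raw input image.
#'
#' @param base_channels channel width of the stem; stages use 1x, 2x, 4x.
#' @param n_res number of residual blocks at the bottleneck.
#' @param hu_window intensity window (HU) mapped linearly to [-1, 1];
#'   values outside are clamped before the network sees them.  In residual
#'   mode the predicted correction is applied in HU, so out-of-window
#'   intensities pass through unclamped.
#' @param residual_output if `TRUE` (default) the network predicts a
#'   correction added to its input (`sCT = CBCT + r`), so an untrained
#'   generator is already the identity and training only has to learn the
#'   artifact correction; this is what makes desk-scale training feasible
#'   and further biases the model toward anatomy preservation.  `FALSE`
#'   gives the classic direct-synthesis head with a tanh output.
#' @return a `GeneratorSpec`.
#' @export
generator_spec <- function(base_channels = 8L, n_res = 2L,
                           hu_window = c(-1000, 200),
                           residual_output = TRUE) {
  stopifnot(base_channels >= 1, n_res >= 0, hu_window[2] > hu_window[1])
  nc <- as.integer(base_channels)
  structure(list(base_channels = nc, n_res = as.integer(n_res),
                 hu_window = as.numeric(hu_window),
                 residual_output = isTRUE(residual_output)),
            class = "GeneratorSpec")
}

## layer list + structural indices for a spec
gen_architecture <- function(spec) {
  nc <- spec$base_channels
  layers <- list(
    layer_conv(1L, nc, 7L, 1L), layer_instancenorm(nc), layer_act("relu"),
    layer_conv(nc, 2L * nc, 3L, 2L), layer_instancenorm(2L * nc), layer_act("relu"),
    layer_conv(2L * nc, 4L * nc, 3L, 2L), layer_instancenorm(4L * nc), layer_act("relu"))
  for (i in seq_len(spec$n_res)) layers <- c(layers, list(layer_resblock(4L * nc)))
  enc_end <- length(layers)
  dec <- list(
    layer_upsample2(), layer_conv(4L * nc, 2L * nc, 3L, 1L),
    layer_instancenorm(2L * nc), layer_act("relu"),
    layer_upsample2(), layer_conv(2L * nc, nc, 3L, 1L),
    layer_instancenorm(nc), layer_act("relu"),
    # small-gain output head: with the residual skip the generator starts
    # close to the identity mapping
    layer_conv(nc, 1L, 7L, 1L, init_gain = 0.1))
  if (!spec$residual_output) dec <- c(dec, list(layer_act("tanh")))
  layers <- c(layers, dec)
  list(net = nn_sequential(layers), enc_end = enc_end,
       taps = c(0L, 3L, 6L, 9L),                 # input + three encoder stages
       tap_channels = c(1L, nc, 2L * nc, 4L * nc))
}

#' Build an initialized CLG generator model
#'
#' Bundles the generator network, its parameters, and one two-layer MLP
#' projection head per tap layer (width `K`, ReLU between, output
#' L2-normalized to the unit sphere).
#'
#' @param spec a [generator_spec()].
#' @param K projection-head output dimension.
#' @param seed RNG seed for weight initialization.
#' @return a `ClgGenerator` model object.
#' @export
build_generator <- function(spec = generator_spec(), K = 256L, seed = 1L) {
  arch <- gen_architecture(spec)
  set.seed(seed)
  params <- nn_init_params(arch$net)
  heads <- lapply(arch$tap_channels, head_init, K = as.integer(K))
  names(heads) <- as.character(arch$taps)
  structure(list(spec = spec, net = arch$net, params = params,
                 enc_end = arch$enc_end, taps = arch$taps,
                 tap_channels = arch$tap_channels, heads = heads,
                 K = as.integer(K)),
            class = "ClgGenerator")
}

## full generator forward on a padded normalized slice; applies the global
## residual skip when the spec asks for it.  The returned caches describe the
## network body only: with the skip, d(net_out) = d(y), so backward calls
## are unchanged.
gen_forward <- function(model, x, taps = integer(0)) {
  fw <- nn_forward(model$net, model$params, x, taps = taps)
  if (model$spec$residual_output) fw$y <- fw$y + x
  fw
}

## intensity window <-> [-1, 1]
normalize_hu <- function(values, window) {
  v <- pmin(pmax(values, window[1]), window[2])
  2 * (v - window[1]) / (window[2] - window[1]) - 1
}

denormalize_hu <- function(values, window) {
  (values + 1) / 2 * (window[2] - window[1]) + window[1]
}

## pad a [H, W] slice to multiples of 4 by edge replication; returns padded
## [H', W', 1] array and the original size
pad_for_net <- function(slice) {
  d <- dim(slice)
  H2 <- 4 * ceiling(d[1] / 4); W2 <- 4 * ceiling(d[2] / 4)
  out <- slice[c(seq_len(d[1]), rep(d[1], H2 - d[1])),
               c(seq_len(d[2]), rep(d[2], W2 - d[2])), drop = FALSE]
  list(x = array(out, c(H2, W2, 1L)), size = d)
}

#' Translate a CBCT-like image into a synthetic CT
#'
#' Normalizes intensities to [-1, 1] over the model's HU window, runs the
#' generator, and maps back to HU.  Grid geometry (shape, spacing, origin)
#' is preserved exactly; 3D volumes are translated slice-by-slice along the
#' third axis.
#'
#' @param image an `ImageGrid`.
#' @param model a `ClgGenerator` from [build_generator()] or [train_clg()].
#' @return translated `ImageGrid` on the same grid.
#' @export
translate <- function(image, model) {
  stopifnot(is_image_grid(image), inherits(model, "ClgGenerator"))
  w <- model$spec$hu_window
  run_slice <- function(slice) {
    p <- pad_for_net(normalize_hu(slice, w))
    y <- gen_forward(model, p$x)$y
    # inverse of the input windowing: the sCT lives inside the HU window,
    # so out-of-window artifact excursions in the CBCT are clipped even
    # before the learned correction acts
    denormalize_hu(array(y[seq_len(p$size[1]), seq_len(p$size[2]), 1],
                         p$size), w)
  }
  if (image$ndim == 2) {
    out <- run_slice(image$values)
  } else {
    out <- array(0, dim(image$values))
    for (k in seq_len(dim(image$values)[3]))
      out[, , k] <- run_slice(image$values[, , k])
  }
  image_grid(out, spacing = image$spacing, origin = image$origin)
}

## extract [S, C] feature vectors at 1-based (row, col) locations
extract_at <- function(act, loc) {
  d <- dim(act)
  lin <- loc[, 1] + (loc[, 2] - 1) * d[1]
  matrix(act, d[1] * d[2], d[3])[lin, , drop = FALSE]
}

## sample S locations per tap (without replacement), given the padded input
## size; returns a named list of [S, 2] matrices
sample_tap_locations <- function(model, input_size, n_patches) {
  H <- input_size[1]; W <- input_size[2]
  locs <- list()
  for (i in seq_along(model$taps)) {
    t <- model$taps[i]
    f <- if (t <= 3) 1L else if (t <= 6) 2L else 4L   # downsampling factor
    h <- ceiling(H / f); w_ <- ceiling(W / f)
    S <- min(n_patches, h * w_)
    lin <- sample.int(h * w_, S)
    locs[[as.character(t)]] <- cbind((lin - 1) %% h + 1, (lin - 1) %/% h + 1)
  }
  locs
}

#' FeatureStack: projected, unit-normalized encoder features
#'
#' Runs the generator encoder on an image, reads the activations of the tap
#' layers at the requested spatial locations, and projects each vector
#' through the corresponding MLP head onto the unit sphere.
#'
#' @param image an `ImageGrid` (2D).
#' @param model a `ClgGenerator`.
#' @param sample_locations named list (by tap index) of 1-based `[S, 2]`
#'   location matrices, as produced internally; `NULL` samples
#'   `loss_config$n_patches` locations per tap using the current RNG state.
#' @param loss_config a [loss_config()].
#' @return a `FeatureStack`: list with `layers` (named list of `[S, K]`
#'   unit-row matrices), `locations`, and `source`.
#' @export
encode_and_project <- function(image, model, sample_locations = NULL,
                               loss_config = loss_config()) {
  stopifnot(inherits(model, "ClgGenerator"))
  p <- pad_for_net(normalize_hu(image$values, model$spec$hu_window))
  if (is.null(sample_locations))
    sample_locations <- sample_tap_locations(model, dim(p$x), loss_config$n_patches)
  fw <- nn_forward(model$net, model$params, p$x, upto = model$enc_end,
                   taps = model$taps)
  layers <- list()
  for (key in names(sample_locations)) {
    act <- fw$taps[[key]]
    if (is.null(act)) stop("tap layer ", key, " not available")
    loc <- sample_locations[[key]]
    d <- dim(act)
    if (any(loc[, 1] < 1 | loc[, 1] > d[1] | loc[, 2] < 1 | loc[, 2] > d[2]))
      stop("sample location outside layer ", key, " extent (",
           d[1], " x ", d[2], ")")
    X <- extract_at(act, loc)
    layers[[key]] <- head_forward(model$heads[[key]], X)$z
  }
  structure(list(layers = layers, locations = sample_locations,
                 source = "image"), class = "FeatureStack")
}
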