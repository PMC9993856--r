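#' Configuration for the digital breast-slice phantom
#'
#' The phantom emulates an axial planning-CT slice after breast-conserving
#' surgery: an elliptical body with a subcutaneous fat rim, a heart-like disk,
#' and two nested target structures (a large breast target, CTV2, containing
#' a small low-contrast tumour-bed target, CTV1).  Intensities are on an
#' HU-like scale (air -1000, soft tissue 0-100) with a smooth within-tissue
#' texture so registration has gradients to work with.
#'
#' Geometry parameters are physical (mm), centred coordinates: the body is
#' centred on the grid.  All radii are checked for nesting (CTV1 inside CTV2
#' inside body).
#'
#' @param shape integer voxel counts, length 2 (2D slice, the default
#'   working mode) .
#' @param spacing mm per voxel, length 2.
#' @param body_radii,body_center ellipse half-axes and centre offset (mm).
#' @param fat_thickness thickness of the subcutaneous fat rim (mm).
#' @param heart_center,heart_radius heart disk centre offset and radius (mm).
#' @param ctv2_center,ctv2_radius breast target (CTV2) centre and radius (mm).
#' @param ctv1_center,ctv1_radius tumour-bed target (CTV1) centre and radius
#'   (mm); must fit inside CTV2.
#' @param hu named intensity levels (air, fat, soft, heart, ctv2, ctv1).
#' @param texture_amplitude amplitude (HU) of the smooth within-tissue
#'   texture; `texture_smoothness_mm` its correlation length.
#' @param seed integer RNG seed; the phantom is a pure function of its config.
#' @return a `PhantomConfig` list.
#' @export
phantom_config <- function(shape = c(128L, 128L),
                           spacing = c(1, 1),
                           body_radii = c(55, 44),
                           body_center = c(0, 0),
                           fat_thickness = 7,
                           heart_center = c(22, -12),
                           heart_radius = 15,
                           ctv2_center = c(-22, 12),
                           ctv2_radius = 17,
                           ctv1_center = c(-25, 15),
                           ctv1_radius = 8,
                           hu = c(air = -1000, fat = -90, soft = 30,
                                  heart = 45, ctv2 = 40, ctv1 = 55),
                           texture_amplitude = 12,
                           texture_smoothness_mm = 8,
                           seed = 1L) {
  cfg <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
              body_radii = body_radii, body_center = body_center,
              fat_thickness = fat_thickness,
              heart_center = heart_center, heart_radius = heart_radius,
              ctv2_center = ctv2_center, ctv2_radius = ctv2_radius,
              ctv1_center = ctv1_center, ctv1_radius = ctv1_radius,
              hu = hu, texture_amplitude = texture_amplitude,
              texture_smoothness_mm = texture_smoothness_mm,
              seed = as.integer(seed))
  class(cfg) <- "PhantomConfig"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$shape) != 2) stop("phantom generator is 2D; shape must have length 2")
  if (any(cfg$spacing <= 0)) stop("spacing must be positive")
  if (any(!is.finite(unlist(cfg$hu)))) stop("intensity levels must be finite")
  # nesting: CTV1 ball inside CTV2 ball inside the body ellipse
  d12 <- sqrt(sum((cfg$ctv1_center - cfg$ctv2_center)^2))
  if (d12 + cfg$ctv1_radius > cfg$ctv2_radius)
    stop("configuration error: CTV1 does not fit inside CTV2")
  # conservative body check against the smaller half-axis
  d2b <- sqrt(sum((cfg$ctv2_center - cfg$body_center)^2))
  if (d2b + cfg$ctv2_radius > min(cfg$body_radii))
    stop("configuration error: CTV2 does not fit inside the body")
  dhb <- sqrt(sum((cfg$heart_center - cfg$body_center)^2))
  if (dhb + cfg$heart_radius > min(cfg$body_radii))
    stop("configuration error: heart does not fit inside the body")
  invisible(cfg)
}

## physical coordinates of every voxel, centred on the grid midpoint (mm)
centred_coords <- function(shape, spacing) {
  idx <- voxel_index_matrix(shape)
  ctr <- (shape - 1) / 2
  sweep(sweep(idx, 2, ctr), 2, spacing, `*`)
}

#' Generate a planning-CT-like phantom slice with nested target contours
#'
#' @param config a [phantom_config()].
#' @return list with `image` (`ImageGrid`) and `structures` (`StructureSet`
#'   with masks `body`, `Heart`, `CTV2`, `CTV1`).
#' @export
generate_phantom <- function(config = phantom_config()) {
  validate_phantom_config(config)
  shape <- config$shape
  xy <- centred_coords(shape, config$spacing)

  ell <- function(center, radii) {
    r <- sweep(xy, 2, center)
    matrix((r[, 1] / radii[1])^2 + (r[, 2] / radii[2])^2 <= 1, shape[1], shape[2])
  }
  disk <- function(center, radius) ell(center, c(radius, radius))

  body <- ell(config$body_center, config$body_radii)
  inner <- ell(config$body_center, config$body_radii - config$fat_thickness)
  fat <- body & !inner
  heart <- disk(config$heart_center, config$heart_radius)
  ctv2 <- disk(config$ctv2_center, config$ctv2_radius)
  ctv1 <- disk(config$ctv1_center, config$ctv1_radius)

  hu <- config$hu
  img <- array(hu[["air"]], shape)
  img[body] <- hu[["soft"]]
  img[fat] <- hu[["fat"]]
  img[heart] <- hu[["heart"]]
  img[ctv2] <- hu[["ctv2"]]
  img[ctv1] <- hu[["ctv1"]]

  if (config$texture_amplitude > 0) {
    rng <- local_rng(config$seed)
    noise <- array(rng$rnorm(prod(shape)), shape)
    sm <- gaussian_blur(noise, config$texture_smoothness_mm / config$spacing)
    sm <- sm / max(stats::sd(sm), 1e-12)
    img[body] <- img[body] + config$texture_amplitude * sm[body]
  }

  grid <- image_grid(img, spacing = config$spacing)
  masks <- list(body = body * 1, Heart = heart * 1,
                CTV2 = ctv2 * 1, CTV1 = ctv1 * 1)
  masks <- lapply(masks, function(m) array(m, shape))
  list(image = grid, structures = structure_set(masks, grid))
}

## Seeded RNG that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  run <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (!is.null(env$state)) assign(".Random.seed", env$state, envir = globalenv())
    else set.seed(seed)
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    out
  }
  list(rnorm = function(...) run(stats::rnorm, ...),
       runif = function(...) run(stats::runif, ...),
       sample_int = function(...) run(sample.int, ...))
}

#' Sample a smooth, boundary-zero random displacement field
#'
#' Draws white noise per component, smooths it with an isotropic Gaussian of
#' physical width `smoothness_mm`, tapers it to zero at the domain boundary
#' with a cosine window, and rescales so the maximum displacement magnitude
#' equals `amplitude_mm`.  For amplitudes well below the smoothness scale the
#' resulting map `Id + u` is diffeomorphic (positive Jacobian determinant);
#' the function checks the Jacobian by finite differences and emits a warning
#' (never silently) if folding is detected.
#'
#' @param grid_shape voxel counts (length 2 or 3).
#' @param spacing mm per voxel.
#' @param amplitude_mm maximum displacement magnitude (mm), `>= 0`.
#' @param smoothness_mm Gaussian correlation length (mm), `> 0`.
#' @param seed integer seed.
#' @return a `DisplacementField` (see [displacement_field()]).
#' @export
sample_smooth_deformation <- function(grid_shape, spacing = rep(1, length(grid_shape)),
                                      amplitude_mm = 3, smoothness_mm = 20,
                                      seed = 1L) {
  if (amplitude_mm < 0) stop("amplitude_mm must be >= 0")
  if (smoothness_mm <= 0) stop("smoothness_mm must be > 0")
  nd <- length(grid_shape)
  u <- array(0, c(grid_shape, nd))
  if (amplitude_mm > 0) {
    rng <- local_rng(seed)
    taper <- array(1, grid_shape)
    idxm <- voxel_index_matrix(grid_shape)
    w <- rep(1, nrow(idxm))
    for (ax in seq_len(nd)) {
      t <- idxm[, ax] / (grid_shape[ax] - 1)       # 0..1 across the axis
      w <- w * (0.5 - 0.5 * cos(2 * pi * t))^0.5   # zero at both ends
    }
    taper <- array(w, grid_shape)
    comps <- vector("list", nd)
    for (ax in seq_len(nd)) {
      z <- array(rng$rnorm(prod(grid_shape)), grid_shape)
      z <- gaussian_blur(z, smoothness_mm / spacing)
      comps[[ax]] <- z * taper
    }
    mag <- sqrt(Reduce(`+`, lapply(comps, function(c) c^2)))
    scale <- amplitude_mm / max(max(mag), 1e-12)
    for (ax in seq_len(nd)) {
      idx <- c(rep(list(quote(expr = )), nd), list(ax))
      u <- do.call(`[<-`, c(list(u), idx, list(value = comps[[ax]] * scale)))
    }
  }
  dvf <- displacement_field(u, spacing)
  jmin <- min(jacobian_determinant(dvf))
  if (jmin <= 0)
    warning("sampled deformation folds (min Jacobian determinant = ",
            signif(jmin, 3), "); reduce amplitude_mm or increase smoothness_mm")
  dvf
}

#' Configuration of the CBCT-style degradation
#'
#' Models the defect classes of clinical CBCT relative to planning CT: a
#' low-frequency shading/scatter bias field, reduced soft-tissue contrast,
#' sparse streak artifacts, and additive noise.  The all-zero configuration
#' (with `contrast_compression = 1`) is the identity degradation.
#'
#' @param shading_amplitude peak amplitude of the additive low-frequency bias
#'   field (HU).
#' @param noise_sigma standard deviation of additive Gaussian noise (HU).
#' @param streak_count number of oriented streak lines.
#' @param streak_amplitude peak streak intensity (HU).
#' @param contrast_compression factor in (0, 1] scaling soft-tissue contrast
#'   about the in-body mean (1 = no compression).
#' @param shading_smoothness_mm correlation length of the bias field (mm).
#' @param seed integer seed.
#' @return an `ArtifactConfig` list.
#' @export
artifact_config <- function(shading_amplitude = 60,
                            noise_sigma = 25,
                            streak_count = 8L,
                            streak_amplitude = 40,
                            contrast_compression = 0.65,
                            shading_smoothness_mm = 40,
                            seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (contrast_compression <= 0 || contrast_compression > 1)
    stop("contrast_compression must lie in (0, 1]")
  structure(list(shading_amplitude = shading_amplitude,
                 noise_sigma = noise_sigma,
                 streak_count = as.integer(streak_count),
                 streak_amplitude = streak_amplitude,
                 contrast_compression = contrast_compression,
                 shading_smoothness_mm = shading_smoothness_mm,
                 seed = as.integer(seed)),
            class = "ArtifactConfig")
}

#' Degrade a CT-like image into a CBCT-like image
#'
#' Applies, in order: contrast compression about the soft-tissue (above
#' -300 HU) mean, the additive shading bias field, streaks, and Gaussian
#' noise.  The grid geometry is untouched and any structure masks drawn on
#' the input remain valid on the output.
#'
#' @param image an `ImageGrid`.
#' @param config an [artifact_config()].
#' @return degraded `ImageGrid` on the same grid.
#' @export
degrade_to_cbct <- function(image, config = artifact_config()) {
  stopifnot(is_image_grid(image))
  shape <- dim(image$values)
  out <- image$values
  rng <- local_rng(config$seed)

  if (config$contrast_compression < 1) {
    soft <- out > -300                       # body tissue, not air
    if (any(soft)) {
      m <- mean(out[soft])
      out[soft] <- m + config$contrast_compression * (out[soft] - m)
    }
  }
  if (config$shading_amplitude != 0) {
    z <- array(rng$rnorm(prod(shape)), shape)
    z <- gaussian_blur(z, config$shading_smoothness_mm / image$spacing)
    z <- z / max(abs(z))
    out <- out + config$shading_amplitude * z
  }
  if (config$streak_count > 0 && config$streak_amplitude != 0) {
    xy <- centred_coords(shape, image$spacing)
    ang <- rng$runif(config$streak_count, 0, pi)
    off <- rng$runif(config$streak_count, -0.35, 0.35) *
      min(shape * image$spacing)
    wid <- rng$runif(config$streak_count, 0.6, 1.6)    # mm
    amp <- rng$runif(config$streak_count, 0.3, 1) * config$streak_amplitude *
      sign(rng$runif(config$streak_count) - 0.5)
    streaks <- numeric(nrow(xy))
    for (s in seq_len(config$streak_count)) {
      dist <- xy[, 1] * sin(ang[s]) - xy[, 2] * cos(ang[s]) - off[s]
      streaks <- streaks + amp[s] * exp(-(dist / wid[s])^2 / 2)
    }
    out <- out + array(streaks, shape)
  }
  if (config$noise_sigma > 0)
    out <- out + array(rng$rnorm(prod(shape), sd = config$noise_sigma), shape)

  image_grid(out, spacing = image$spacing, origin = image$origin)
}

#' Stack 2D phantom slices into a 3D volume
#'
#' Convenience helper for exercising the 3D code paths: repeats a 2D slice
#' generator across `n_slices` with per-slice seeds and stacks the result
#' with the given through-plane spacing (default mirrors the clinical
#' 0.977 x 0.977 x 5 mm acquisition aspect ratio, here 1 x 1 x 5 mm).
#'
#' @param config base [phantom_config()].
#' @param n_slices number of slices.
#' @param slice_spacing through-plane spacing (mm).
#' @return list with `image` (3D `ImageGrid`) and `structures`.
#' @export
stack_phantom_3d <- function(config = phantom_config(), n_slices = 5L,
                             slice_spacing = 5) {
  slices <- lapply(seq_len(n_slices), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    generate_phantom(cfg)
  })
  shape3 <- c(config$shape, n_slices)
  vol <- array(0, shape3)
  masks <- lapply(slices[[1]]$structures$names, function(nm) array(0, shape3))
  names(masks) <- slices[[1]]$structures$names
  for (k in seq_len(n_slices)) {
    vol[, , k] <- slices[[k]]$image$values
    for (nm in names(masks)) masks[[nm]][, , k] <- slices[[k]]$structures$masks[[nm]]
  }
  grid <- image_grid(vol, spacing = c(config$spacing, slice_spacing))
  list(image = grid, structures = structure_set(masks, grid))
}
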