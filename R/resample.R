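#' Resample an image onto another image's grid
#'
#' Every voxel of `target` is sampled from `image` at its physical position
#' (`origin + index * spacing`).  Use `"nearest"` for label maps so binary
#' masks stay binary.  Samples falling outside `image`'s domain take `fill`
#' (default: the minimum input intensity, the CT air convention).
#'
#' @param image source `ImageGrid`.
#' @param target `ImageGrid` providing the output geometry (values unused).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill out-of-domain fill value.
#' @return `ImageGrid` with `target`'s shape, spacing and origin.
#' @export
resample_to_grid <- function(image, target,
                             interpolation = c("linear", "nearest"),
                             fill = min(image$values)) {
  interpolation <- match.arg(interpolation)
  if (image$ndim != target$ndim) stop("image and target rank differ")
  shape <- dim(target$values)
  idx <- voxel_index_matrix(shape)
  coords <- idx
  for (ax in seq_len(target$ndim)) {
    phys <- target$origin[ax] + idx[, ax] * target$spacing[ax]
    coords[, ax] <- (phys - image$origin[ax]) / image$spacing[ax]
  }
  vals <- interp_at(image$values, coords, method = interpolation,
                    oob = "fill", fill = fill)
  image_grid(array(vals, shape), spacing = target$spacing,
             origin = target$origin)
}

#' Rigid transform (rotation + translation)
#'
#' 2D: one in-plane angle.  3D: one angle about the third axis (the
#' through-plane axis, matching axial acquisition geometry) plus a 3D
#' translation.  Maps physical points as `T(x) = R (x - c) + c + t`.
#'
#' @param rotation angle in radians.
#' @param translation per-axis offset (mm).
#' @param center rotation centre (mm).
#' @return a `RigidTransform`.
#' @export
rigid_transform <- function(rotation = 0, translation = rep(0, 2),
                            center = rep(0, length(translation))) {
  stopifnot(is.finite(rotation), all(is.finite(translation)))
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "RigidTransform")
}

rigid_apply_points <- function(tf, pts) {
  nd <- ncol(pts)
  ca <- cos(tf$rotation); sa <- sin(tf$rotation)
  out <- sweep(pts, 2, tf$center)
  x <- out[, 1] * ca - out[, 2] * sa
  y <- out[, 1] * sa + out[, 2] * ca
  out[, 1] <- x; out[, 2] <- y
  out <- sweep(out, 2, tf$center + tf$translation, `+`)
  out
}

## resample `moving` onto `fixed`'s grid under rigid transform tf:
## output(x) = moving(T(x))
resample_rigid <- function(moving, fixed, tf,
                           interpolation = "linear",
                           fill = min(moving$values)) {
  shape <- dim(fixed$values)
  idx <- voxel_index_matrix(shape)
  phys <- sweep(sweep(idx, 2, fixed$spacing, `*`), 2, fixed$origin, `+`)
  src <- rigid_apply_points(tf, phys)
  coords <- sweep(sweep(src, 2, moving$origin), 2, moving$spacing, `/`)
  vals <- interp_at(moving$values, coords, method = interpolation,
                    oob = "fill", fill = fill)
  image_grid(array(vals, shape), spacing = fixed$spacing,
             origin = fixed$origin)
}

## mean squared difference on a subsampled voxel lattice
rigid_msd <- function(moving, fixed, tf, stride = 2L, fill) {
  shape <- dim(fixed$values)
  nd <- length(shape)
  sub <- lapply(shape, function(n) seq(1, n, by = stride))
  idx <- as.matrix(expand.grid(lapply(sub, function(s) s - 1),
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(idx) <- NULL
  phys <- sweep(sweep(idx, 2, fixed$spacing, `*`), 2, fixed$origin, `+`)
  src <- rigid_apply_points(tf, phys)
  coords <- sweep(sweep(src, 2, moving$origin), 2, moving$spacing, `/`)
  vals <- interp_at(moving$values, coords, method = "linear",
                    oob = "fill", fill = fill)
  fvals <- do.call(`[`, c(list(fixed$values), sub))
  mean((vals - as.vector(fvals))^2)
}

#' Rigidly align a moving image to a fixed image
#'
#' Minimizes the mean squared intensity difference over rotation and
#' translation: a multi-start grid search over integer-voxel translations
#' (and a coarse angle sweep) followed by Nelder-Mead refinement.  Returns
#' the moving image resampled onto the fixed grid and the recovered
#' transform.  Emits a convergence warning with diagnostics when the
#' optimized objective fails to improve on the identity (e.g.
#' non-overlapping fields of view).
#'
#' @param moving,fixed `ImageGrid`s of equal rank.
#' @param max_translation_vox half-width of the translation search grid
#'   (voxels of the fixed image).
#' @param max_rotation maximum |angle| searched (radians).
#' @param stride voxel subsampling stride for the objective.
#' @param fill out-of-domain fill value.
#' @return list with `image` (resampled `ImageGrid`), `transform`
#'   (`RigidTransform`), and `msd` (final objective).
#' @export
rigid_align <- function(moving, fixed, max_translation_vox = 10,
                        max_rotation = 10 * pi / 180, stride = 2L,
                        fill = min(moving$values)) {
  if (moving$ndim != fixed$ndim) stop("image ranks differ")
  nd <- fixed$ndim
  center <- fixed$origin + (dim(fixed$values) - 1) / 2 * fixed$spacing
  obj <- function(par) {
    tf <- rigid_transform(par[1], par[1 + seq_len(nd)], center)
    rigid_msd(moving, fixed, tf, stride = stride, fill = fill)
  }
  id_msd <- obj(rep(0, nd + 1))

  # multi-start: translation grid (step 2 voxels) x coarse angles
  steps <- seq(-max_translation_vox, max_translation_vox, by = 2)
  angles <- seq(-max_rotation, max_rotation, length.out = 5)
  best <- list(par = rep(0, nd + 1), val = id_msd)
  for (a in angles) {
    for (tx in steps * fixed$spacing[1]) {
      for (ty in steps * fixed$spacing[2]) {
        par <- c(a, tx, ty, if (nd == 3) 0)
        v <- obj(par)
        if (v < best$val) best <- list(par = par, val = v)
      }
    }
  }
  opt <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  if (opt$value > best$val) opt <- list(par = best$par, value = best$val)
  if (opt$value >= id_msd && id_msd > 0)
    warning("rigid_align did not improve on the identity transform ",
            "(MSD ", signif(opt$value, 4), " vs ", signif(id_msd, 4),
            "); fields of view may not overlap")
  tf <- rigid_transform(opt$par[1], opt$par[1 + seq_len(nd)], center)
  list(image = resample_rigid(moving, fixed, tf, fill = fill),
       transform = tf, msd = opt$value)
}
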