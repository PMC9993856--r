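#' Displacement and velocity fields
#'
#' A `DisplacementField` stores the per-voxel displacement `u` (mm, physical
#' axes) of the transform `phi = Id + u`; a `VelocityField` stores a
#' stationary velocity `v` whose Lie-group exponential generates a
#' diffeomorphic displacement.  Both are arrays of shape `c(grid_shape,
#' ndim)` on an `ImageGrid` geometry.
#'
#' @param u,v numeric array `c(grid_shape, ndim)` (mm).
#' @param spacing per-axis voxel size (mm).
#' @param origin physical coordinate of voxel 0 (mm).
#' @return object of class `DisplacementField` / `VelocityField`.
#' @export
displacement_field <- function(u, spacing, origin = rep(0, length(spacing))) {
  field_obj(u, spacing, origin, "DisplacementField")
}

#' @rdname displacement_field
#' @export
velocity_field <- function(v, spacing, origin = rep(0, length(spacing))) {
  field_obj(v, spacing, origin, "VelocityField")
}

field_obj <- function(a, spacing, origin, cls) {
  d <- dim(a)
  nd <- length(d) - 1L
  if (d[length(d)] != nd)
    stop(cls, ": array must have shape c(grid_shape, ndim)")
  if (any(!is.finite(a))) stop(cls, ": values must be finite")
  structure(list(values = a, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), ndim = nd,
                 shape = d[seq_len(nd)]),
            class = cls)
}

zero_displacement <- function(shape, spacing, origin = rep(0, length(spacing))) {
  displacement_field(array(0, c(shape, length(shape))), spacing, origin)
}

## extract component ax as a plain array
field_component <- function(f, ax) {
  nd <- f$ndim
  idx <- c(rep(list(quote(expr = )), nd), list(ax))
  array(do.call(`[`, c(list(f$values), idx)), f$shape)
}

set_field_component <- function(f, ax, values) {
  nd <- f$ndim
  idx <- c(rep(list(quote(expr = )), nd), list(ax))
  f$values <- do.call(`[<-`, c(list(f$values), idx, list(value = values)))
  f
}

## ---- differential operators ----------------------------------------------

## central-difference gradient of a scalar array, spacing-aware (per mm);
## one-sided at the array edges.
grad_scalar <- function(x, spacing) {
  d <- dim(x)
  nd <- length(d)
  out <- vector("list", nd)
  for (ax in seq_len(nd)) {
    fwd <- shift_slab(x, ax, 1)   # x[i+1]
    bwd <- shift_slab(x, ax, -1)  # x[i-1]
    den <- (fwd$weight + bwd$weight) * spacing[ax]
    num <- fwd$values - bwd$values
    # one-sided at edges: fwd or bwd value is zero-padded there, so add x back
    num <- num + (1 - fwd$weight) * x - (1 - bwd$weight) * x
    out[[ax]] <- num / den
  }
  out
}

#' Jacobian determinant of the transform Id + u
#'
#' Finite-difference (central, one-sided at edges) determinant of
#' `grad(phi)` with `phi = Id + u`, evaluated at every voxel.  Positive
#' everywhere iff the discrete map is locally orientation-preserving.
#'
#' @param dvf a `DisplacementField`.
#' @return array of determinants, one per voxel.
#' @export
jacobian_determinant <- function(dvf) {
  nd <- dvf$ndim
  sp <- dvf$spacing
  J <- vector("list", nd)          # J[[i]][[j]] = d phi_i / d x_j
  for (i in seq_len(nd)) {
    gi <- grad_scalar(field_component(dvf, i), sp)
    for (j in seq_len(nd)) gi[[j]] <- gi[[j]] + (i == j)  # + Id
    J[[i]] <- gi
  }
  if (nd == 2) {
    J[[1]][[1]] * J[[2]][[2]] - J[[1]][[2]] * J[[2]][[1]]
  } else {
    J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
  }
}

## ---- warping --------------------------------------------------------------

#' Warp an image by a displacement field
#'
#' `output(x) = input(x + u(x))`: pull-back sampling at physical positions,
#' spacing-aware, with clamp-to-edge boundary handling.  Use
#' `interpolation = "nearest"` for label maps (binary masks stay binary).
#'
#' @param image an `ImageGrid`.
#' @param dvf a `DisplacementField` on the same grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return warped `ImageGrid`.
#' @export
warp_image <- function(image, dvf, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!identical(dim(image$values), as.integer(dvf$shape)) &&
      !identical(dim(image$values), dvf$shape))
    stop("image and displacement field grids do not match")
  shape <- dim(image$values)
  nd <- length(shape)
  idx <- voxel_index_matrix(shape)
  coords <- idx
  for (ax in seq_len(nd))
    coords[, ax] <- idx[, ax] +
      as.vector(field_component(dvf, ax)) / image$spacing[ax]
  vals <- interp_at(image$values, coords, method = interpolation, oob = "clamp")
  image_grid(array(vals, shape), spacing = image$spacing, origin = image$origin)
}

warp_mask <- function(mask, dvf, spacing) {
  g <- image_grid(mask, spacing = spacing)
  warp_image(g, dvf, interpolation = "nearest")$values
}

#' Warp every structure in a set with one displacement field
#'
#' Nearest-neighbour sampling keeps masks binary.
#'
#' @param structures a `StructureSet`.
#' @param dvf a `DisplacementField` on the same grid.
#' @return a warped `StructureSet`.
#' @export
warp_structures <- function(structures, dvf) {
  masks <- lapply(structures$masks, warp_mask, dvf = dvf,
                  spacing = structures$spacing)
  ref <- image_grid(masks[[1]], spacing = structures$spacing,
                    origin = structures$origin)
  structure_set(masks, ref)
}

## compose displacements: (u2 after u1)(x) = u1(x + u2(x)) + u2(x)
## i.e. (Id+u1) o (Id+u2) = Id + u2 + u1 o (Id+u2)
compose_displacements <- function(u1, u2) {
  nd <- u1$ndim
  shape <- u1$shape
  idx <- voxel_index_matrix(shape)
  coords <- idx
  for (ax in seq_len(nd))
    coords[, ax] <- idx[, ax] +
      as.vector(field_component(u2, ax)) / u1$spacing[ax]
  out <- u2$values
  for (ax in seq_len(nd)) {
    s <- interp_at(field_component(u1, ax), coords, method = "linear",
                   oob = "clamp")
    out <- inc_component(out, ax, array(s, shape), nd)
  }
  displacement_field(out, u1$spacing, u1$origin)
}

inc_component <- function(a, ax, add, nd) {
  idx <- c(rep(list(quote(expr = )), nd), list(ax))
  cur <- do.call(`[`, c(list(a), idx))
  do.call(`[<-`, c(list(a), idx, list(value = cur + as.vector(add))))
}

#' Exponential of a stationary velocity field by scaling and squaring
#'
#' Scales `v` by `2^-k`, treats the result as a small displacement, and
#' self-composes `k` times; converges to the flow of the stationary ODE
#' `dx/dt = v(x)` as `k` grows.  Composition uses spacing-aware linear
#' interpolation with clamp-to-edge boundaries.
#'
#' @param v a `VelocityField` (mm).
#' @param squaring_steps number of squarings `k >= 0`.
#' @return a `DisplacementField` for `exp(v)`.
#' @export
exp_velocity <- function(v, squaring_steps = 6L) {
  if (squaring_steps < 0) stop("squaring_steps must be >= 0")
  u <- displacement_field(v$values / 2^squaring_steps, v$spacing, v$origin)
  for (i in seq_len(squaring_steps)) u <- compose_displacements(u, u)
  u
}

## ---- demons energy and updates -------------------------------------------

#' Registration energy: SSD plus displacement smoothness
#'
#' `E = sum((I_m(phi) - I_f)^2) + lambda * sum(|grad u|^2)`, with the
#' regularizer taken on the displacement `u = phi - Id` using spacing-aware
#' finite differences, so the identity transform scores zero penalty.
#'
#' @param moving,fixed `ImageGrid`s on the same grid.
#' @param displacement a `DisplacementField`.
#' @param lambda regularization weight (`>= 0`).
#' @return scalar energy.
#' @export
demons_energy <- function(moving, fixed, displacement, lambda = 1) {
  stop_if_grid_mismatch(moving, fixed)
  warped <- warp_image(moving, displacement, "linear")
  ssd <- sum((warped$values - fixed$values)^2)
  reg <- 0
  if (lambda > 0) {
    for (i in seq_len(displacement$ndim)) {
      g <- grad_scalar(field_component(displacement, i), displacement$spacing)
      reg <- reg + sum(Reduce(`+`, lapply(g, function(x) x^2)))
    }
  }
  ssd + lambda * reg
}

#' One demons force step
#'
#' Classic intensity-driven demons force at the current transform: with
#' `w = I_m(phi)` and `diff = I_f - w`,
#' `force = diff * grad(w) / (|grad w|^2 + diff^2 / xi^2)` where `xi` is the
#' mean voxel size (the standard normalization making the step well-scaled
#' in mm).  The force is magnitude-capped at `config$step_bound_mm` and
#' smoothed with the fluid kernel `sigma_fluid_mm`.
#'
#' @param moving,fixed `ImageGrid`s.
#' @param current_displacement `DisplacementField` (the current `phi - Id`).
#' @param config a [demons_config()].
#' @return a `VelocityField` increment (mm).
#' @export
demons_update <- function(moving, fixed, current_displacement, config = demons_config()) {
  stop_if_grid_mismatch(moving, fixed)
  sp <- moving$spacing
  nd <- moving$ndim
  warped <- warp_image(moving, current_displacement, "linear")
  diff <- fixed$values - warped$values
  g <- grad_scalar(warped$values, sp)
  g2 <- Reduce(`+`, lapply(g, function(x) x^2))
  xi2 <- mean(sp)^2
  den <- g2 + diff^2 / xi2
  den[den < 1e-9] <- Inf
  comps <- lapply(g, function(gx) diff * gx / den)
  mag <- sqrt(Reduce(`+`, lapply(comps, function(x) x^2)))
  cap <- pmin(1, config$step_bound_mm / pmax(mag, 1e-12))
  arr <- array(0, c(dim(diff), nd))
  for (ax in seq_len(nd)) {
    c_ax <- comps[[ax]] * cap
    if (config$sigma_fluid_mm > 0)
      c_ax <- gaussian_blur(c_ax, config$sigma_fluid_mm / sp)
    arr <- inc_component(arr, ax, c_ax, nd)
  }
  velocity_field(arr, sp, moving$origin)
}

#' Demons registration configuration
#'
#' Defaults: regularization reported diagnostically with `lambda = 1`
#' (smoothing kernels, not an explicit lambda gradient, perform the
#' regularization, as is standard for demons), fluid smoothing 2 mm,
#' diffusion smoothing 1 mm, 3 multiresolution levels, 50 iterations per
#' level, 6 scaling-and-squaring steps, 2 mm step bound, and energy-descent
#' step checking enabled.
#'
#' @param lambda smoothness weight in the reported energy (diagnostic).
#' @param sigma_fluid_mm Gaussian width applied to each force increment (mm).
#' @param sigma_diffusion_mm Gaussian width applied to the accumulated
#'   velocity after each update (mm).
#' @param iterations iterations per resolution level.
#' @param levels number of multiresolution levels (coarsest first).
#' @param squaring_steps scaling-and-squaring steps for the exponential.
#' @param step_bound_mm cap on the per-iteration force magnitude (mm).
#' @param tol relative energy-decrease tolerance for early stopping.
#' @param line_check if `TRUE`, an update that increases the energy is
#'   rejected (the trace of accepted energies is then non-increasing).
#' @return a `DemonsConfig` list.
#' @export
demons_config <- function(lambda = 1, sigma_fluid_mm = 2, sigma_diffusion_mm = 1,
                          iterations = 50L, levels = 3L, squaring_steps = 6L,
                          step_bound_mm = 2, tol = 1e-5, line_check = TRUE) {
  if (lambda < 0 || sigma_fluid_mm < 0 || sigma_diffusion_mm < 0)
    stop("lambda and smoothing widths must be >= 0")
  if (iterations < 1 || levels < 1 || squaring_steps < 0)
    stop("invalid iteration/level/squaring configuration")
  structure(list(lambda = lambda, sigma_fluid_mm = sigma_fluid_mm,
                 sigma_diffusion_mm = sigma_diffusion_mm,
                 iterations = as.integer(iterations), levels = as.integer(levels),
                 squaring_steps = as.integer(squaring_steps),
                 step_bound_mm = step_bound_mm, tol = tol,
                 line_check = isTRUE(line_check)),
            class = "DemonsConfig")
}

## downsample an image by 2 per axis (block mean), spacing doubles
downsample2 <- function(image) {
  d <- dim(image$values)
  nd <- length(d)
  keep <- lapply(d, function(n) seq(1, n - n %% 2))
  x <- do.call(`[`, c(list(image$values), keep, list(drop = FALSE)))
  d2 <- floor(d / 2)
  if (nd == 2) {
    x <- (x[seq(1, 2 * d2[1], 2), , drop = FALSE] +
          x[seq(2, 2 * d2[1], 2), , drop = FALSE]) / 2
    x <- (x[, seq(1, 2 * d2[2], 2), drop = FALSE] +
          x[, seq(2, 2 * d2[2], 2), drop = FALSE]) / 2
  } else {
    x <- (x[seq(1, 2 * d2[1], 2), , , drop = FALSE] +
          x[seq(2, 2 * d2[1], 2), , , drop = FALSE]) / 2
    x <- (x[, seq(1, 2 * d2[2], 2), , drop = FALSE] +
          x[, seq(2, 2 * d2[2], 2), , drop = FALSE]) / 2
    x <- (x[, , seq(1, 2 * d2[3], 2), drop = FALSE] +
          x[, , seq(2, 2 * d2[3], 2), drop = FALSE]) / 2
  }
  image_grid(array(x, d2), spacing = image$spacing * 2, origin = image$origin)
}

## resample a velocity field onto a finer shape (values stay in mm)
upsample_velocity <- function(v, target_shape, target_spacing) {
  nd <- v$ndim
  idx <- voxel_index_matrix(target_shape)
  coords <- idx
  for (ax in seq_len(nd))
    coords[, ax] <- idx[, ax] * target_spacing[ax] / v$spacing[ax]
  out <- array(0, c(target_shape, nd))
  for (ax in seq_len(nd)) {
    s <- interp_at(field_component(v, ax), coords, "linear", oob = "clamp")
    out <- inc_component(out, ax, array(s, target_shape), nd)
  }
  velocity_field(out, target_spacing, v$origin)
}

## zero the outermost voxel ring of every component
zero_boundary <- function(f) {
  nd <- f$ndim
  for (ax in seq_len(nd)) {
    for (edge in c(1, f$shape[ax])) {
      idx <- c(rep(list(quote(expr = )), nd), list(quote(expr = )))
      idx[[ax]] <- edge
      f$values <- do.call(`[<-`, c(list(f$values), idx, list(value = 0)))
    }
  }
  f
}

#' Log-domain diffeomorphic demons registration
#'
#' Iterates, per multiresolution level: compute the demons force at the
#' current transform, accumulate it into the stationary velocity `V`
#' (first-order log-domain composition `V <- V + v`, a
#' Baker-Campbell-Hausdorff truncation valid for small updates), smooth `V`
#' with the diffusion kernel, zero it on the boundary ring, and exponentiate
#' by scaling-and-squaring to obtain the displacement.  An update that
#' increases the energy is rejected when `line_check` is on, so the accepted
#' energy trace is non-increasing.  The exponential parameterization keeps
#' the displacement diffeomorphic (positive Jacobian determinant) at all
#' times.
#'
#' @param fixed,moving `ImageGrid`s on the same grid.
#' @param config a [demons_config()].
#' @return list with `dvf` (a `DisplacementField`), `velocity` (the final
#'   `VelocityField`), and `diagnostics`: a data.frame with columns `level`,
#'   `iteration`, `energy`, `ssd`, `accepted`.
#' @export
register_diffeodemons <- function(fixed, moving, config = demons_config()) {
  stop_if_grid_mismatch(fixed, moving)
  # build pyramid, coarsest last in construction order
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(config$levels - 1)) {
    if (any(floor(dim(pyr_f[[l]]$values) / 2) < 8)) break
    pyr_f[[l + 1]] <- downsample2(pyr_f[[l]])
    pyr_m[[l + 1]] <- downsample2(pyr_m[[l]])
  }
  nlev <- length(pyr_f)
  V <- NULL
  trace <- list()
  for (lev in seq(nlev, 1)) {
    f <- pyr_f[[lev]]; m <- pyr_m[[lev]]
    shape <- dim(f$values)
    if (is.null(V)) {
      V <- velocity_field(array(0, c(shape, f$ndim)), f$spacing, f$origin)
    } else {
      V <- upsample_velocity(V, shape, f$spacing)
      V <- zero_boundary(V)
    }
    u <- exp_velocity(V, config$squaring_steps)
    e_prev <- demons_energy(m, f, u, config$lambda)
    step_scale <- 1
    rejects <- 0L
    for (it in seq_len(config$iterations)) {
      v_inc <- demons_update(m, f, u, config)
      V_try <- velocity_field(V$values + step_scale * v_inc$values,
                              V$spacing, V$origin)
      V_try$values <- apply_diffusion(V_try, config)
      V_try <- zero_boundary(V_try)
      u_try <- exp_velocity(V_try, config$squaring_steps)
      e_try <- demons_energy(m, f, u_try, config$lambda)
      if (!is.finite(e_try))
        stop("registration diverged (non-finite energy) at level ", lev,
             ", iteration ", it)
      accepted <- !config$line_check || e_try <= e_prev
      improve <- NA_real_
      if (accepted) {
        V <- V_try; u <- u_try
        improve <- (e_prev - e_try) / max(e_prev, 1e-12)
        e_prev <- e_try
        rejects <- 0L
      } else {
        step_scale <- step_scale / 2  # back off and retry with a smaller step
        rejects <- rejects + 1L
      }
      ssd <- demons_energy(m, f, u, 0)
      trace[[length(trace) + 1]] <- data.frame(
        level = lev, iteration = it, energy = e_prev, ssd = ssd,
        accepted = accepted)
      if (accepted && improve < config$tol) break
      if (rejects >= 3L) break
    }
  }
  diag <- do.call(rbind, trace)
  list(dvf = exp_velocity(V, config$squaring_steps), velocity = V,
       diagnostics = diag)
}

apply_diffusion <- function(V, config) {
  if (config$sigma_diffusion_mm <= 0) return(V$values)
  out <- V$values
  for (ax in seq_len(V$ndim)) {
    sm <- gaussian_blur(field_component(V, ax), config$sigma_diffusion_mm / V$spacing)
    out <- inc_component(out, ax, sm - field_component(V, ax), V$ndim)
  }
  out
}
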