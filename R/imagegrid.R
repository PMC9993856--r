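#' Scalar image on a regular grid
#'
#' `ImageGrid` is the common currency of every stage of the pipeline: a 2D or
#' 3D scalar array together with its physical geometry.  Voxel indices are
#' 0-based in the physical convention: the centre of voxel `(i, j, ...)` sits
#' at `origin + index * spacing` (mm).  Internally values are stored as a
#' plain R array (1-based subscripts as usual).
#'
#' @param values numeric array (2D or 3D) of intensities, HU-like units.
#' @param spacing numeric vector, one strictly positive entry per axis (mm).
#' @param origin numeric vector, physical coordinate of voxel `(0, 0[, 0])`
#'   (mm).  Defaults to the zero vector.
#' @return an object of class `ImageGrid` with fields `values`, `spacing`,
#'   `origin`, `ndim`.
#' @export
image_grid <- function(values, spacing = rep(1, length(dim(values))),
                       origin = rep(0, length(dim(values)))) {
  if (is.null(dim(values))) stop("`values` must be a 2D or 3D array")
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("ImageGrid supports 2 or 3 dimensions, got ", nd)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != nd || length(origin) != nd)
    stop("spacing/origin length must match array rank (", nd, ")")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive and finite")
  if (any(!is.finite(values))) stop("image values must be finite")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin,
                 ndim = nd), class = "ImageGrid")
}

#' @export
print.ImageGrid <- function(x, ...) {
  cat("ImageGrid ", paste(dim(x$values), collapse = " x "),
      " | spacing (mm): ", paste(signif(x$spacing, 4), collapse = ", "),
      " | origin (mm): ", paste(signif(x$origin, 4), collapse = ", "),
      " | range: [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

is_image_grid <- function(x) inherits(x, "ImageGrid")

#' Test whether two images share a grid geometry
#'
#' @param a,b `ImageGrid` objects.
#' @param tol tolerance on spacing/origin (mm).
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "images") {
  if (!same_geometry(a, b))
    stop(what, " must share shape, spacing and origin", call. = FALSE)
  invisible(TRUE)
}

#' Named set of binary masks on a shared grid
#'
#' A `StructureSet` holds contoured structures (e.g. CTV1, CTV2, Heart) as
#' binary arrays on one `ImageGrid` geometry, preserving a declared order.
#'
#' @param masks named list of arrays with values in `{0, 1}`.
#' @param grid the parent `ImageGrid` (geometry reference only).
#' @return object of class `StructureSet` with fields `masks`, `names`,
#'   `spacing`, `origin`.
#' @export
structure_set <- function(masks, grid) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("all masks must be named")
  shp <- dim(grid$values)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), shp))
      stop("mask '", nm, "' does not match the parent grid shape")
    u <- unique(as.vector(m))
    if (!all(u %in% c(0, 1)))
      stop("mask '", nm, "' has values outside {0, 1}")
    storage.mode(masks[[nm]]) <- "double"
  }
  structure(list(masks = masks, names = names(masks),
                 spacing = grid$spacing, origin = grid$origin),
            class = "StructureSet")
}

#' @export
print.StructureSet <- function(x, ...) {
  cat("StructureSet:", paste(x$names, collapse = ", "), "\n")
  for (nm in x$names)
    cat("  ", nm, ": ", sum(x$masks[[nm]]), " voxels\n", sep = "")
  invisible(x)
}

## ---- interpolation --------------------------------------------------------
## Shared sampler used by resampling, warping and the velocity-field
## exponential.  `coords` are 0-based continuous voxel coordinates, one row
## per sample point.  Out-of-domain behaviour: "clamp" (clamp-to-edge) or a
## constant fill value.

interp_at <- function(values, coords, method = c("linear", "nearest"),
                      oob = c("clamp", "fill"), fill = 0) {
  method <- match.arg(method)
  oob <- match.arg(oob)
  d <- dim(values)
  nd <- length(d)
  n <- nrow(coords)
  if (ncol(coords) != nd) stop("coords rank mismatch")

  outside <- rep(FALSE, n)
  if (oob == "fill") {
    for (ax in seq_len(nd))
      outside <- outside | coords[, ax] < 0 | coords[, ax] > d[ax] - 1
  }
  # clamp (also keeps fill-mode arithmetic in range)
  for (ax in seq_len(nd))
    coords[, ax] <- pmin(pmax(coords[, ax], 0), d[ax] - 1)

  if (method == "nearest") {
    idx <- round(coords[, 1]) + 1
    if (nd >= 2) idx <- idx + round(coords[, 2]) * d[1]
    if (nd == 3) idx <- idx + round(coords[, 3]) * d[1] * d[2]
    out <- values[idx]
  } else {
    lo <- floor(coords)
    fr <- coords - lo
    for (ax in seq_len(nd)) {      # keep lo+1 inside the array
      hit <- lo[, ax] >= d[ax] - 1
      lo[hit, ax] <- d[ax] - 2
      fr[hit, ax] <- 1
      if (d[ax] == 1) { lo[, ax] <- 0; fr[, ax] <- 0 }
    }
    if (nd == 2) {
      i0 <- lo[, 1] + 1; j0 <- lo[, 2]
      s1 <- d[1]
      v00 <- values[i0 + j0 * s1];       v10 <- values[i0 + 1 + j0 * s1]
      v01 <- values[i0 + (j0 + 1) * s1]; v11 <- values[i0 + 1 + (j0 + 1) * s1]
      fx <- fr[, 1]; fy <- fr[, 2]
      out <- (v00 * (1 - fx) + v10 * fx) * (1 - fy) +
             (v01 * (1 - fx) + v11 * fx) * fy
    } else {
      i0 <- lo[, 1] + 1; j0 <- lo[, 2]; k0 <- lo[, 3]
      s1 <- d[1]; s2 <- d[1] * d[2]
      fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
      out <- 0
      for (dz in 0:1) {
        wz <- if (dz == 0) 1 - fz else fz
        base <- (k0 + dz) * s2
        v00 <- values[i0 + j0 * s1 + base]
        v10 <- values[i0 + 1 + j0 * s1 + base]
        v01 <- values[i0 + (j0 + 1) * s1 + base]
        v11 <- values[i0 + 1 + (j0 + 1) * s1 + base]
        out <- out + wz * ((v00 * (1 - fx) + v10 * fx) * (1 - fy) +
                           (v01 * (1 - fx) + v11 * fx) * fy)
      }
    }
  }
  if (oob == "fill" && any(outside)) out[outside] <- fill
  out
}

## 0-based voxel index grid as an n-by-ndim matrix (column-major order,
## matching as.vector() on the value array).
voxel_index_matrix <- function(shape) {
  nd <- length(shape)
  args <- lapply(shape, function(k) seq_len(k) - 1)
  g <- as.matrix(expand.grid(args, KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  g
}

## Separable Gaussian blur of a 2D/3D array; sigma given per-axis in voxels.
## Edge handling: renormalized (truncated) kernel, i.e. zero-flux-ish.
gaussian_blur <- function(x, sigma_vox) {
  d <- dim(x)
  nd <- length(d)
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, nd)
  for (ax in seq_len(nd)) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, d)
    norm <- array(0, d)
    for (t in -r:r) {
      wt <- w[t + r + 1]
      src <- shift_slab(x, ax, t)
      acc <- acc + wt * src$values
      norm <- norm + wt * src$weight
    }
    x <- acc / norm
  }
  x
}

## Shift an array along one axis by t voxels (zero-padded), returning both the
## shifted values and a 0/1 validity weight for kernel renormalization.
shift_slab <- function(x, ax, t) {
  d <- dim(x)
  nd <- length(d)
  out <- array(0, d)
  w <- array(0, d)
  n <- d[ax]
  if (abs(t) >= n) return(list(values = out, weight = w))
  src <- if (t >= 0) (1 + t):n else 1:(n + t)
  dst <- if (t >= 0) 1:(n - t) else (1 - t):n
  idx_src <- rep(list(quote(expr = )), nd)
  idx_dst <- idx_src
  idx_src[[ax]] <- src
  idx_dst[[ax]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(value = do.call(`[`, c(list(x), idx_src)))))
  w <- do.call(`[<-`, c(list(w), idx_dst, list(value = 1)))
  list(values = out, weight = w)
}
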