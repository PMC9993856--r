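#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`.  Two empty masks are defined as perfectly
#' agreeing (DSC 1, with a warning); exactly one empty mask gives 0.
#'
#' @param a,b binary arrays of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  check_mask_pair(a, b)
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) {
    warning("both masks empty; DSC defined as 1")
    return(1)
  }
  if (na == 0 || nb == 0) return(0)
  2 * sum(a * b) / (na + nb)
}

check_mask_pair <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a shape")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("masks must be binary")
  invisible(TRUE)
}

## border voxels: mask voxels with at least one face-neighbour outside the
## mask; the array boundary counts as background.  Returns an n x ndim matrix
## of physical coordinates (mm).
border_coords <- function(mask, spacing) {
  d <- dim(mask)
  nd <- length(d)
  interior <- array(TRUE, d)
  for (ax in seq_len(nd)) {
    fwd <- shift_slab(mask, ax, 1)   # neighbour at i+1 (array edge -> 0)
    bwd <- shift_slab(mask, ax, -1)
    interior <- interior & (fwd$values == 1) & (bwd$values == 1)
  }
  border <- (mask == 1) & !interior
  idx <- which(border)
  coords <- arrayInd(idx, d) - 1
  sweep(coords, 2, spacing, `*`)
}

#' Directed surface-distance multisets between two masks
#'
#' For every border voxel of `a` (a mask voxel with at least one face
#' neighbour outside the mask; the array edge counts as outside) the
#' Euclidean distance in mm, spacing-aware, to the nearest border voxel of
#' `b`, and vice versa.
#'
#' @param a,b binary arrays of the same shape, both nonempty.
#' @param spacing per-axis voxel size (mm).
#' @return list with numeric vectors `a_to_b` and `b_to_a`.
#' @export
surface_distances <- function(a, b, spacing = rep(1, length(dim(a)))) {
  check_mask_pair(a, b)
  if (sum(a) == 0 || sum(b) == 0)
    stop("surface_distances requires nonempty masks")
  if (any(spacing <= 0)) stop("spacing must be positive")
  pa <- border_coords(a, spacing)
  pb <- border_coords(b, spacing)
  list(a_to_b = nearest_dists(pa, pb), b_to_a = nearest_dists(pb, pa))
}

## min distance from each row of p to the rows of q, chunked to bound
## memory; per-axis explicit differences (not the expanded a^2+b^2-2ab
## form, which loses ~1e-7 absolute accuracy to cancellation)
nearest_dists <- function(p, q, chunk = 2048L) {
  n <- nrow(p)
  out <- numeric(n)
  for (s in seq(1, n, chunk)) {
    e <- min(s + chunk - 1, n)
    pp <- p[s:e, , drop = FALSE]
    d2 <- 0
    for (ax in seq_len(ncol(p)))
      d2 <- d2 + outer(pp[, ax], q[, ax], `-`)^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

pooled_surface_distances <- function(a, b, spacing) {
  sd <- surface_distances(a, b, spacing)
  c(sd$a_to_b, sd$b_to_a)
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The 95th percentile, by linear interpolation on the sorted values
#' (quantile type 7), of the pooled symmetric surface-distance multiset.
#' Undefined (`NA`) if either mask is empty.
#'
#' @inheritParams surface_distances
#' @return scalar mm, or `NA_real_` for an empty mask.
#' @export
hd95 <- function(a, b, spacing = rep(1, length(dim(a)))) {
  check_mask_pair(a, b)
  if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
  unname(stats::quantile(pooled_surface_distances(a, b, spacing), 0.95,
                         type = 7))
}

#' Average surface distance (mm)
#'
#' Mean of the pooled symmetric surface-distance multiset.  Undefined (`NA`)
#' if either mask is empty.
#'
#' @inheritParams surface_distances
#' @return scalar mm, or `NA_real_` for an empty mask.
#' @export
asd <- function(a, b, spacing = rep(1, length(dim(a)))) {
  check_mask_pair(a, b)
  if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
  mean(pooled_surface_distances(a, b, spacing))
}

#' Per-structure overlap and surface metrics for one case
#'
#' Computes DSC, HD95 and ASD for every structure present in both sets;
#' structures missing on one side are recorded with `NA` metrics and a
#' warning and excluded from aggregates.
#'
#' @param predicted,reference `StructureSet`s on the same geometry.
#' @param spacing optional spacing override (mm); defaults to the sets'.
#' @return a `MetricsReport` data.frame with columns `structure`, `DSC`,
#'   `HD95_mm`, `ASD_mm`.
#' @export
evaluate_structures <- function(predicted, reference, spacing = NULL) {
  if (is.null(spacing)) spacing <- reference$spacing
  all_names <- union(reference$names, predicted$names)
  rows <- lapply(all_names, function(nm) {
    if (!(nm %in% predicted$names) || !(nm %in% reference$names)) {
      warning("structure '", nm, "' missing on one side; excluded")
      return(data.frame(structure = nm, DSC = NA_real_, HD95_mm = NA_real_,
                        ASD_mm = NA_real_))
    }
    p <- predicted$masks[[nm]]
    r <- reference$masks[[nm]]
    d <- dsc(p, r)
    if (sum(p) == 0 || sum(r) == 0) {
      h <- NA_real_; s <- NA_real_
    } else {
      pooled <- pooled_surface_distances(p, r, spacing)
      h <- unname(stats::quantile(pooled, 0.95, type = 7))
      s <- mean(pooled)
    }
    data.frame(structure = nm, DSC = d, HD95_mm = h, ASD_mm = s)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("MetricsReport", class(out))
  out
}

#' Aggregate per-case metric reports into a cohort summary
#'
#' Mean and SD across cases per structure, plus an `Average` row holding the
#' mean/SD of the per-case across-structure means (one value per case, then
#' aggregated — cohort SD is over cases, never voxels).
#'
#' @param reports list of `MetricsReport` data.frames (one per case).
#' @return data.frame with columns `structure`, `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(reports) {
  stopifnot(length(reports) >= 1)
  long <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- as.data.frame(reports[[i]])
    r$case <- i
    r
  }))
  metrics <- c("DSC", "HD95_mm", "ASD_mm")
  rows <- list()
  for (st in unique(long$structure)) {
    sub <- long[long$structure == st, ]
    for (m in metrics) {
      v <- sub[[m]][!is.na(sub[[m]])]
      rows[[length(rows) + 1]] <- data.frame(
        structure = st, metric = m,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n = length(v))
    }
  }
  # per-case mean over structures, then cohort mean/SD
  for (m in metrics) {
    per_case <- tapply(long[[m]], long$case, function(v) mean(v, na.rm = TRUE))
    per_case <- per_case[!is.na(per_case)]
    rows[[length(rows) + 1]] <- data.frame(
      structure = "Average", metric = m,
      mean = if (length(per_case)) mean(per_case) else NA_real_,
      sd = if (length(per_case) > 1) stats::sd(per_case) else NA_real_,
      n = length(per_case))
  }
  do.call(rbind, rows)
}
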