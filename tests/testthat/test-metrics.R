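# Independent oracle used throughout: border voxels found by an explicit
# neighbour loop, distances by exhaustive pairwise search.
oracle_border <- function(mask, spacing) {
  d <- dim(mask)
  nd <- length(d)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nd == 2 && is.null(dim(idx))) idx <- matrix(idx, ncol = 2)
  on_border <- apply(idx, 1, function(p) {
    for (ax in seq_len(nd)) {
      for (dlt in c(-1, 1)) {
        q <- p; q[ax] <- q[ax] + dlt
        if (any(q < 1) || any(q > d)) return(TRUE)    # array edge = outside
        if (mask[matrix(q, 1)] == 0) return(TRUE)
      }
    }
    FALSE
  })
  sweep(idx[on_border, , drop = FALSE] - 1, 2, spacing, `*`)
}

oracle_pooled <- function(a, b, spacing) {
  pa <- oracle_border(a, spacing)
  pb <- oracle_border(b, spacing)
  dmat <- as.matrix(stats::dist(rbind(pa, pb)))
  ab <- dmat[seq_len(nrow(pa)), nrow(pa) + seq_len(nrow(pb)), drop = FALSE]
  c(apply(ab, 1, min), apply(ab, 2, min))
}

test_that("dsc: identity, disjoint, half-overlap, empty-mask conventions", {
  a <- array(0, c(20, 20)); a[5:14, 5:14] <- 1          # 10x10 square
  b <- array(0, c(20, 20)); b[5:14, 10:19] <- 1         # overlap 10x5
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, b), 0.5)                          # 2*50 / 200
  d <- array(0, c(20, 20)); d[1:2, 1:2] <- 1
  expect_equal(dsc(a, d), 0)
  e <- array(0, c(20, 20))
  expect_warning(expect_equal(dsc(e, e), 1), "empty")
  expect_equal(dsc(a, e), 0)
  expect_error(dsc(a, array(0, c(5, 5))), "shape")
  expect_error(dsc(a * 2, a), "binary")
})

test_that("surface distances: single-voxel pairs, anisotropic spacing", {
  m1 <- array(0, c(12, 12)); m1[2, 3] <- 1
  m2 <- array(0, c(12, 12)); m2[9, 3] <- 1              # 7 voxels apart
  sd2 <- surface_distances(m1, m2, c(2, 2))
  expect_equal(sd2$a_to_b, 14)
  expect_equal(sd2$b_to_a, 14)

  a3 <- array(0, c(6, 6, 4)); a3[3, 3, 2] <- 1
  b3 <- array(0, c(6, 6, 4)); b3[3, 3, 3] <- 1          # one slice apart
  sd3 <- surface_distances(a3, b3, c(1, 1, 5))
  expect_equal(sd3$a_to_b, 5)
  expect_equal(asd(a3, b3, c(1, 1, 5)), 5)
  expect_equal(hd95(a3, b3, c(1, 1, 5)), 5)
  expect_error(surface_distances(a3, array(0, c(6, 6, 4))), "nonempty")
})

test_that("metrics agree exactly with the exhaustive pairwise oracle", {
  cases <- list(
    list(a = random_blob(c(18, 18), 1), b = random_blob(c(18, 18), 2),
         sp = c(1, 1)),
    list(a = random_blob(c(14, 14), 3), b = random_blob(c(14, 14), 4),
         sp = c(0.7, 1.3)),
    list(a = random_blob(c(12, 12, 10), 5), b = random_blob(c(12, 12, 10), 6),
         sp = c(1, 1, 5)),
    list(a = random_blob(c(10, 10, 8), 7), b = random_blob(c(10, 10, 8), 8),
         sp = c(0.977, 0.977, 5)))
  for (cs in cases) {
    pooled <- oracle_pooled(cs$a, cs$b, cs$sp)
    expect_equal(hd95(cs$a, cs$b, cs$sp),
                 unname(stats::quantile(pooled, 0.95, type = 7)),
                 tolerance = 1e-12)
    expect_equal(asd(cs$a, cs$b, cs$sp), mean(pooled), tolerance = 1e-12)
    # symmetry
    expect_equal(hd95(cs$a, cs$b, cs$sp), hd95(cs$b, cs$a, cs$sp))
    expect_equal(asd(cs$a, cs$b, cs$sp), asd(cs$b, cs$a, cs$sp))
    expect_equal(dsc(cs$a, cs$b), dsc(cs$b, cs$a))
    # bounds: hd95 and asd never exceed the max pooled distance
    expect_lte(hd95(cs$a, cs$b, cs$sp), max(pooled))
    expect_lte(asd(cs$a, cs$b, cs$sp), max(pooled))
  }
})

test_that("hd95 percentile rule on an explicit multiset", {
  # two parallel 25-voxel segments; 5 voxels of one displaced sideways
  a <- array(0, c(40, 30)); a[6:30, 10] <- 1
  b <- array(0, c(40, 30)); b[6:30, 10] <- 1
  b[11:15, 10] <- 0; b[11:15, 20] <- 1      # 5 voxels moved 10 mm away
  pooled <- oracle_pooled(a, b, c(1, 1))
  expect_equal(hd95(a, b, c(1, 1)),
               unname(stats::quantile(pooled, 0.95, type = 7)),
               tolerance = 1e-12)
  expect_identical(hd95(a, array(0, c(40, 30)), c(1, 1)), NA_real_)
  expect_identical(asd(a, array(0, c(40, 30)), c(1, 1)), NA_real_)
})

test_that("ASD is monotone as a square translates away (convex shapes)", {
  base <- array(0, c(40, 40)); base[16:25, 16:25] <- 1
  prev <- -Inf
  for (shift in 0:6) {
    moved <- array(0, c(40, 40)); moved[16:25 + shift, 16:25] <- 1
    cur <- asd(base, moved, c(1, 1))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("evaluate_structures and cohort aggregation", {
  ph <- generate_phantom(micro_phantom_config())
  rep0 <- evaluate_structures(ph$structures, ph$structures)
  expect_s3_class(rep0, "MetricsReport")
  expect_equal(rep0$DSC, rep(1, 4))
  expect_equal(rep0$HD95_mm, rep(0, 4))
  expect_equal(rep0$ASD_mm, rep(0, 4))

  # missing structure: warned and excluded
  partial <- structure_set(ph$structures$masks[c("body", "Heart", "CTV2")],
                           ph$image)
  expect_warning(rep1 <- evaluate_structures(partial, ph$structures),
                 "missing")
  expect_true(is.na(rep1[rep1$structure == "CTV1", "DSC"]))
  expect_equal(rep1[rep1$structure == "CTV2", "DSC"], 1)

  # cohort SD is over per-case values (aggregation oracle)
  reports <- lapply(1:4, function(i) {
    r <- rep0
    r$DSC <- r$DSC - i / 100
    r
  })
  agg <- aggregate_metrics(reports)
  ctv1_dsc <- agg[agg$structure == "CTV1" & agg$metric == "DSC", ]
  expect_equal(ctv1_dsc$mean, mean(1 - (1:4) / 100))
  expect_equal(ctv1_dsc$sd, stats::sd(1 - (1:4) / 100))
  avg <- agg[agg$structure == "Average" & agg$metric == "DSC", ]
  per_case_means <- sapply(reports, function(r) mean(r$DSC))
  expect_equal(avg$mean, mean(per_case_means))
  expect_equal(avg$sd, stats::sd(per_case_means))
})
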