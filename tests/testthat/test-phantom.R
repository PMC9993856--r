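test_that("generate_phantom is deterministic and respects nesting", {
  cfg <- phantom_config(seed = 3L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$structures$masks, b$structures$masks)

  for (seed in c(1L, 7L, 42L)) {
    ph <- generate_phantom(phantom_config(seed = seed))
    m <- ph$structures$masks
    expect_equal(sum(m$CTV1 * (1 - m$CTV2)), 0)      # CTV1 inside CTV2
    expect_equal(sum(m$CTV2 * (1 - m$body)), 0)      # CTV2 inside body
    expect_equal(sum(m$Heart * (1 - m$body)), 0)
    expect_true(all(unlist(m) %in% c(0, 1)))
  }
})

test_that("heart mask voxel count matches the analytic disk area", {
  cfg <- phantom_config(shape = c(160L, 160L), spacing = c(1, 1),
                        heart_radius = 15)
  ph <- generate_phantom(cfg)
  analytic <- pi * 15^2                       # 2D disk, 1 mm voxels
  count <- sum(ph$structures$masks$Heart)
  expect_lt(abs(count - analytic) / analytic, 0.10)
})

test_that("impossible structure nesting is a configuration error", {
  expect_error(phantom_config(ctv1_radius = 30), "CTV1")
  expect_error(phantom_config(ctv2_center = c(-50, 30)), "CTV2")
  expect_error(phantom_config(spacing = c(0, 1)), "spacing")
})

test_that("sample_smooth_deformation: zero amplitude, determinism, bounds", {
  z <- sample_smooth_deformation(c(32, 32), c(1, 1), amplitude_mm = 0)
  expect_true(all(z$values == 0))

  a <- sample_smooth_deformation(c(48, 48), c(1, 1), 3, 20, seed = 5)
  b <- sample_smooth_deformation(c(48, 48), c(1, 1), 3, 20, seed = 5)
  expect_identical(a$values, b$values)

  mag <- sqrt(a$values[, , 1]^2 + a$values[, , 2]^2)
  expect_lte(max(mag), 3 + 1e-9)
  # boundary-zero convention
  expect_equal(max(abs(a$values[1, , ])), 0)
  expect_equal(max(abs(a$values[48, , ])), 0)
  expect_equal(max(abs(a$values[, 1, ])), 0)
  expect_error(sample_smooth_deformation(c(8, 8), amplitude_mm = -1))
  expect_error(sample_smooth_deformation(c(8, 8), smoothness_mm = 0))
})

test_that("default-amplitude deformations are diffeomorphic (independent Jacobian scan)", {
  # independent oracle: central/one-sided finite differences written here,
  # not the package's jacobian_determinant
  fd_jac_min <- function(u, spacing) {
    d <- dim(u)[1:2]
    phi1 <- outer(0:(d[1] - 1) * spacing[1], rep(1, d[2])) + u[, , 1]
    phi2 <- outer(rep(1, d[1]), 0:(d[2] - 1) * spacing[2]) + u[, , 2]
    gr <- function(f, ax) {
      if (ax == 1) {
        g <- (rbind(f[-1, ], f[d[1], ]) - rbind(f[1, ], f[-d[1], ]))
        den <- matrix(2, d[1], d[2]); den[1, ] <- 1; den[d[1], ] <- 1
      } else {
        g <- (cbind(f[, -1], f[, d[2]]) - cbind(f[, 1], f[, -d[2]]))
        den <- matrix(2, d[1], d[2]); den[, 1] <- 1; den[, d[2]] <- 1
      }
      g / (den * spacing[ax])
    }
    J <- gr(phi1, 1) * gr(phi2, 2) - gr(phi1, 2) * gr(phi2, 1)
    min(J)
  }
  for (seed in 1:5) {
    u <- sample_smooth_deformation(c(64, 64), c(2, 2), 3, 20, seed = seed)
    expect_gt(fd_jac_min(u$values, c(2, 2)), 0)
    expect_equal(min(jacobian_determinant(u)),
                 fd_jac_min(u$values, c(2, 2)), tolerance = 1e-10)
  }
  # folding amplitudes warn rather than fail silently
  expect_warning(sample_smooth_deformation(c(32, 32), c(1, 1), 40, 4, seed = 1),
                 "folds")
})

test_that("degrade_to_cbct: identity config, noise level, shading bound", {
  ph <- generate_phantom(phantom_config(seed = 2L))
  none <- artifact_config(shading_amplitude = 0, noise_sigma = 0,
                          streak_count = 0, contrast_compression = 1)
  out <- degrade_to_cbct(ph$image, none)
  expect_identical(out$values, ph$image$values)

  s <- 25
  noise_only <- artifact_config(shading_amplitude = 0, noise_sigma = s,
                                streak_count = 0, contrast_compression = 1,
                                seed = 9L)
  noised <- degrade_to_cbct(ph$image, noise_only)
  expect_gte(length(noised$values), 1e4)
  expect_lt(abs(stats::sd(noised$values - ph$image$values) - s) / s, 0.05)

  a <- 60
  shade_only <- artifact_config(shading_amplitude = a, noise_sigma = 0,
                                streak_count = 0, contrast_compression = 1,
                                seed = 4L)
  shaded <- degrade_to_cbct(ph$image, shade_only)
  expect_lte(max(abs(shaded$values - ph$image$values)), a + 1e-9)
  expect_gt(mean(abs(shaded$values - ph$image$values)), 0)

  # geometry and masks untouched; determinism
  expect_true(same_geometry(noised, ph$image))
  again <- degrade_to_cbct(ph$image, noise_only)
  expect_identical(noised$values, again$values)

  expect_error(artifact_config(noise_sigma = -1))
  expect_error(artifact_config(contrast_compression = 0))
})

test_that("stack_phantom_3d assembles slices with through-plane spacing", {
  v <- stack_phantom_3d(micro_phantom_config(), n_slices = 3L,
                        slice_spacing = 5)
  expect_equal(dim(v$image$values), c(64, 64, 3))
  expect_equal(v$image$spacing, c(2, 2, 5))
  expect_equal(dim(v$structures$masks$CTV1), c(64, 64, 3))
})
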