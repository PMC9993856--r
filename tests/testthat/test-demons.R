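test_that("demons_energy: identity zero, SSD oracle, quadratic scaling", {
  ph <- generate_phantom(micro_phantom_config())
  u0 <- sctdir:::zero_displacement(dim(ph$image$values), ph$image$spacing)
  expect_equal(demons_energy(ph$image, ph$image, u0, lambda = 1), 0)

  other <- generate_phantom(phantom_config(shape = c(64L, 64L),
                                           spacing = c(2, 2), seed = 9L))
  # u = 0: energy is the plain SSD (brute-force voxel sum oracle)
  e <- demons_energy(other$image, ph$image, u0, lambda = 5)
  ssd <- sum((other$image$values - ph$image$values)^2)
  expect_equal(e, ssd, tolerance = 1e-12)

  # doubling a constant offset quadruples the energy at lambda = 0
  off1 <- image_grid(ph$image$values + 10, ph$image$spacing)
  off2 <- image_grid(ph$image$values + 20, ph$image$spacing)
  e1 <- demons_energy(off1, ph$image, u0, lambda = 0)
  e2 <- demons_energy(off2, ph$image, u0, lambda = 0)
  expect_equal(e2 / e1, 4, tolerance = 1e-12)

  # lambda = 0 ignores the displacement's roughness
  u_rough <- sctdir:::zero_displacement(dim(ph$image$values), ph$image$spacing)
  expect_equal(demons_energy(off1, ph$image, u_rough, 0), e1)
  expect_error(demons_energy(ph$image, generate_phantom(phantom_config())$image,
                             u0), "share")
})

test_that("exp_velocity: zero field, constant translation flow", {
  sp <- c(1.5, 1.5)
  v0 <- velocity_field(array(0, c(24, 24, 2)), sp)
  expect_true(all(exp_velocity(v0, 6)$values == 0))

  # spatially constant velocity: interior displacement equals the constant
  vc <- velocity_field(array(rep(c(2, -1.5), each = 24 * 24), c(24, 24, 2)), sp)
  u <- exp_velocity(vc, 6)
  inner <- u$values[8:17, 8:17, ]
  expect_close(inner[, , 1], 2, 1e-6)
  expect_close(inner[, , 2], -1.5, 1e-6)
})

test_that("exp_velocity matches a dense Euler flow integrator on linear fields", {
  # v(x) = A (x - x0), analytic flow x(1) = x0 + e^A (x - x0); oracle is
  # forward-Euler integration of the ODE with 1e4 substeps
  sp <- c(1, 1)
  n <- 32
  A <- matrix(c(-0.06, 0.08, -0.05, 0.04), 2, 2)
  x0 <- c(15.5, 15.5)
  idx <- sctdir:::voxel_index_matrix(c(n, n))
  vvals <- t(A %*% t(sweep(idx, 2, x0)))
  v <- velocity_field(array(c(vvals[, 1], vvals[, 2]), c(n, n, 2)), sp)

  euler_flow <- function(pts, nsub = 1e4) {
    h <- 1 / nsub
    for (i in seq_len(nsub)) pts <- pts + h * t(A %*% t(sweep(pts, 2, x0)))
    pts
  }
  interior <- idx[, 1] >= 8 & idx[, 1] <= 23 & idx[, 2] >= 8 & idx[, 2] <= 23
  expected_u <- euler_flow(idx[interior, , drop = FALSE]) -
    idx[interior, , drop = FALSE]

  errs <- vapply(c(2L, 4L, 8L), function(k) {
    u <- exp_velocity(v, k)
    got <- cbind(as.vector(u$values[, , 1])[interior],
                 as.vector(u$values[, , 2])[interior])
    max(abs(got - expected_u))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))   # error non-increasing in k
  expect_lt(errs[3], 0.05)                # <= 0.05 voxel at 8 steps
})

test_that("demons_update: converged case, step cap, descent direction", {
  ph <- generate_phantom(micro_phantom_config())
  u0 <- sctdir:::zero_displacement(dim(ph$image$values), ph$image$spacing)
  cfg <- demons_config()
  inc <- demons_update(ph$image, ph$image, u0, cfg)
  expect_equal(max(abs(inc$values)), 0)

  # mismatched images: increment bounded and a small step along it
  # decreases the SSD (finite-difference descent oracle)
  dv <- sample_smooth_deformation(dim(ph$image$values), ph$image$spacing,
                                  3, 20, seed = 2)
  fixed <- warp_image(ph$image, dv)
  inc2 <- demons_update(ph$image, fixed, u0, cfg)
  mag <- sqrt(inc2$values[, , 1]^2 + inc2$values[, , 2]^2)
  expect_lte(max(mag), cfg$step_bound_mm + 1e-9)
  e0 <- demons_energy(ph$image, fixed, u0, 0)
  for (epsl in c(0.05, 0.1)) {
    u_eps <- displacement_field(epsl * inc2$values, ph$image$spacing)
    expect_lt(demons_energy(ph$image, fixed, u_eps, 0), e0)
  }
})

test_that("self-registration returns a near-identity transform", {
  ph <- generate_phantom(micro_phantom_config())
  reg <- register_diffeodemons(ph$image, ph$image,
                               demons_config(iterations = 10L, levels = 2L))
  expect_lt(max(abs(reg$dvf$values)) / min(ph$image$spacing), 0.1)
})

test_that("registration recovers a known smooth deformation", {
  ph <- generate_phantom(micro_phantom_config())
  dv <- sample_smooth_deformation(dim(ph$image$values), ph$image$spacing,
                                  3, 20, seed = 4)
  fixed <- warp_image(ph$image, dv)
  reg <- register_diffeodemons(fixed, ph$image, micro_demons_config())
  ssd0 <- sum((ph$image$values - fixed$values)^2)
  ssd1 <- sum((warp_image(ph$image, reg$dvf)$values - fixed$values)^2)
  expect_lt(ssd1 / ssd0, 0.10)
  body <- ph$structures$masks$body == 1
  err <- sqrt((reg$dvf$values[, , 1] - dv$values[, , 1])^2 +
              (reg$dvf$values[, , 2] - dv$values[, , 2])^2)
  expect_lt(mean(err[body]), min(ph$image$spacing))   # <= 1 voxel
  expect_gt(min(jacobian_determinant(reg$dvf)), 0)
  # accepted-step energies are non-increasing (line check on)
  acc <- reg$diagnostics[reg$diagnostics$accepted, ]
  for (lev in unique(acc$level))
    expect_true(all(diff(acc$energy[acc$level == lev]) <= 1e-9))
})

test_that("warp_image: identity, exact one-voxel shift on a ramp, label safety", {
  sp <- c(2, 2)
  ramp <- image_grid(outer(0:31, rep(1, 32)) * 5, sp)
  u0 <- sctdir:::zero_displacement(c(32, 32), sp)
  expect_equal(warp_image(ramp, u0)$values, ramp$values)

  # constant +1 voxel (= +2 mm) shift along axis 1: interior rows shift
  shift <- displacement_field(
    array(rep(c(2, 0), each = 32 * 32), c(32, 32, 2)), sp)
  w <- warp_image(ramp, shift, "linear")
  expect_equal(w$values[1:31, ], ramp$values[2:32, ], tolerance = 1e-12)

  mask <- array(0, c(32, 32)); mask[10:20, 10:20] <- 1
  mg <- image_grid(mask, sp)
  wm <- warp_image(mg, shift, "nearest")
  expect_true(all(wm$values %in% c(0, 1)))
  expect_equal(wm$values[9:19, 10:20], mask[10:20, 10:20])
  expect_error(warp_image(ramp, sctdir:::zero_displacement(c(16, 16), sp)),
               "match")
})

test_that("warp_structures propagates all masks with nearest sampling", {
  ph <- generate_phantom(micro_phantom_config())
  dv <- sample_smooth_deformation(dim(ph$image$values), ph$image$spacing,
                                  3, 20, seed = 6)
  ws <- warp_structures(ph$structures, dv)
  expect_identical(ws$names, ph$structures$names)
  for (nm in ws$names) expect_true(all(ws$masks[[nm]] %in% c(0, 1)))
  # nesting is preserved under a shared diffeomorphic warp
  expect_equal(sum(ws$masks$CTV1 * (1 - ws$masks$CTV2)), 0)
})
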