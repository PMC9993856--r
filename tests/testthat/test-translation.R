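test_that("patch_nce_loss matches its closed forms", {
  # uniform logits: loss = log(N + 1)
  v <- c(1, 0)
  for (N in c(1, 4, 15)) {
    negs <- matrix(rep(v, N), N, 2, byrow = TRUE)   # all dot products equal
    expect_equal(patch_nce_loss(v, v, negs, tau = 0.07), log(N + 1),
                 tolerance = 1e-12)
  }
  # orthogonal negative at tau = 0.07 (value ~6.2e-7; tolerance covers the
  # log1p-vs-log(1+x) rounding difference between the two forms)
  expect_equal(patch_nce_loss(c(1, 0), c(1, 0), matrix(c(0, 1), 1), 0.07),
               log(1 + exp(-1 / 0.07)), tolerance = 1e-6)
  expect_error(patch_nce_loss(v, v, matrix(v, 1), tau = 0), "tau")
})

test_that("patch_nce_loss agrees with direct softmax cross-entropy on random vectors", {
  set.seed(11)
  for (rep in 1:20) {
    K <- sample(2:8, 1); N <- sample(1:6, 1)
    unit <- function(x) x / sqrt(sum(x^2))
    v <- unit(stats::rnorm(K)); vp <- unit(stats::rnorm(K))
    vn <- t(apply(matrix(stats::rnorm(N * K), N, K), 1, unit))
    # independent oracle: literal softmax cross-entropy, no LSE guard
    logits <- c(sum(v * vp), vn %*% v) / 0.07
    expected <- -log(exp(logits[1]) / sum(exp(logits)))
    expect_equal(patch_nce_loss(v, vp, vn, 0.07), expected, tolerance = 1e-6)
  }
  # numerical stability at the logit extremes |v.v'|/tau ~ 14.3
  expect_true(is.finite(patch_nce_loss(c(1, 0), c(1, 0),
                                       matrix(c(-1, 0), 1), 0.07)))
})

test_that("loss defaults match the training protocol", {
  lc <- loss_config()
  expect_equal(lc$tau, 0.07)
  expect_equal(lc$lambda_x, 1)
  expect_equal(lc$lambda_y, 1)
  expect_error(loss_config(n_patches = 1), "negatives")
})

test_that("fused NCE reduces to log(S) for identical features and is permutation invariant", {
  S <- 8; K <- 5
  z <- rep(1, K) / sqrt(K)
  Z <- matrix(z, S, K, byrow = TRUE)
  r <- sctdir:::nce_loss_grad(Z, Z, 0.07)
  expect_equal(r$loss, log(S), tolerance = 1e-10)

  set.seed(3)
  Z <- matrix(stats::rnorm(S * K), S, K); Z <- Z / sqrt(rowSums(Z^2))
  Zh <- matrix(stats::rnorm(S * K), S, K); Zh <- Zh / sqrt(rowSums(Zh^2))
  base <- sctdir:::nce_loss_grad(Z, Zh, 0.07)$loss
  perm <- sample(S)
  expect_equal(sctdir:::nce_loss_grad(Z[perm, ], Zh[perm, ], 0.07)$loss,
               base, tolerance = 1e-12)
})

test_that("encode_and_project yields unit vectors, deterministically, with expected counts", {
  model <- build_generator(generator_spec(base_channels = 4L, n_res = 1L),
                           K = 16L, seed = 5L)
  ph <- generate_phantom(micro_phantom_config())
  set.seed(1)
  fs <- encode_and_project(ph$image, model,
                           loss_config = loss_config(n_patches = 8L))
  expect_s3_class(fs, "FeatureStack")
  expect_length(fs$layers, 4)                      # L = 4 tap layers
  for (z in fs$layers) {
    expect_equal(nrow(z), 8)                       # S_l = 8 each
    expect_equal(rowSums(z^2), rep(1, 8), tolerance = 1e-5)
  }
  fs2 <- encode_and_project(ph$image, model, fs$locations)
  expect_identical(fs$layers, fs2$layers)          # fixed weights + locations

  bad <- fs$locations
  bad[["9"]][1, ] <- c(999, 1)
  expect_error(encode_and_project(ph$image, model, bad), "extent")
})

test_that("gan_loss closed forms, monotonicity, and clamping", {
  expect_equal(gan_loss(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  expect_gt(gan_loss(1 - 1e-9, 1e-9), -1e-6)       # perfect discriminator -> 0-
  expect_lte(gan_loss(1 - 1e-9, 1e-9), 0)
  # monotone increasing in D(real) at fixed D(fake)
  dr <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(dr, function(p) gan_loss(p, 0.3), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_warning(gan_loss(1.2, 0.5), "clamping")
})

test_that("total_loss degenerates to the GAN term and is finite at initialization", {
  spec <- generator_spec(base_channels = 4L, n_res = 1L)
  model <- build_generator(spec, K = 16L, seed = 2L)
  disc <- sctdir:::build_discriminator(4L, seed = 3L)
  ph <- generate_phantom(micro_phantom_config())
  cb <- degrade_to_cbct(ph$image)
  lc0 <- loss_config(lambda_x = 0, lambda_y = 0)
  r0 <- total_loss(model, disc, cb, ph$image, lc0, seed = 1)
  expect_identical(r0$total, r0$gan)
  r1 <- total_loss(model, disc, cb, ph$image, loss_config(), seed = 1)
  expect_true(all(is.finite(unlist(r1))))
  expect_equal(r1$total, r1$gan + r1$nce_x + r1$nce_y, tolerance = 1e-12)
})

test_that("translate conserves geometry and stacks slice-wise in 3D", {
  model <- build_generator(generator_spec(base_channels = 4L, n_res = 1L),
                           K = 16L, seed = 4L)
  v3 <- stack_phantom_3d(micro_phantom_config(), n_slices = 3L)
  out3 <- translate(v3$image, model)
  expect_equal(dim(out3$values), dim(v3$image$values))
  expect_equal(out3$spacing, v3$image$spacing)
  expect_true(all(is.finite(out3$values)))
  # slice-wise composition
  for (k in 1:3) {
    sl <- image_grid(v3$image$values[, , k], spacing = v3$image$spacing[1:2])
    expect_equal(out3$values[, , k], translate(sl, model)$values,
                 tolerance = 1e-12)
  }
  # determinism at fixed weights
  expect_identical(translate(v3$image, model)$values, out3$values)
})

test_that("learning-rate schedule: constant 2e-4 through epoch 50, linear to 0 at 200", {
  tc <- train_config()
  expect_equal(tc$epochs, 200L)
  expect_equal(tc$warm_epochs, 50L)
  expect_equal(lr_schedule(1, tc), 2e-4)
  expect_equal(lr_schedule(50, tc), 2e-4)
  expect_equal(lr_schedule(125, tc), 2e-4 * 75 / 150)
  expect_equal(lr_schedule(200, tc), 0)
  lrs <- vapply(50:200, lr_schedule, numeric(1), config = tc)
  expect_equal(diff(lrs), rep(-2e-4 / 150, 150), tolerance = 1e-9)
})

test_that("micro training run completes with finite logged losses", {
  set.seed(99)
  mk <- function(s) image_grid(array(stats::rnorm(64, sd = 100), c(8, 8)),
                               spacing = c(2, 2))
  fit <- train_clg(lapply(1:2, mk), lapply(3:4, mk),
                   generator_spec(base_channels = 2L, n_res = 1L),
                   loss_config(n_patches = 4L),
                   train_config(epochs = 2L, warm_epochs = 1L, seed = 1L))
  expect_equal(nrow(fit$log), 2)
  expect_true(all(is.finite(as.matrix(fit$log))))
  expect_named(fit$log, c("epoch", "L_GAN", "L_NCE_X", "L_NCE_Y", "LR"))
  expect_error(train_clg(list(), list(mk(1))), "nonempty")
})
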