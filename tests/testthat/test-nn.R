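# Finite-difference verification of the hand-derived backpropagation.  The
# oracle is central differencing of the forward pass; every layer type used
# by the generator and discriminator is covered through one composite net.

`%||%` <- function(a, b) if (is.null(a)) b else a

fd_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, numeric(1))
}

test_that("layer gradients match finite differences", {
  set.seed(42)
  net <- sctdir:::nn_sequential(list(
    sctdir:::layer_conv(2, 3, 3, 1), sctdir:::layer_instancenorm(3),
    sctdir:::layer_act("relu"), sctdir:::layer_conv(3, 2, 4, 2),
    sctdir:::layer_act("lrelu"), sctdir:::layer_resblock(2),
    sctdir:::layer_upsample2(), sctdir:::layer_conv(2, 1, 7, 1),
    sctdir:::layer_act("tanh")))
  params <- sctdir:::nn_init_params(net)
  x <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 2))
  fw <- sctdir:::nn_forward(net, params, x)
  R <- array(stats::rnorm(length(fw$y)), dim(fw$y))
  bw <- sctdir:::nn_backward(net, params, fw$caches, R)

  for (li in c(1, 2, 4, 8)) {
    nm <- if (!is.null(params[[li]]$W)) "W" else "g"
    v <- params[[li]][[nm]]
    idx <- sample(length(v), min(5, length(v)))
    fd <- fd_grad(function(vv) {
      p <- params; p[[li]][[nm]] <- array(vv, dim(v) %||% length(v))
      sum(sctdir:::nn_forward(net, p, x)$y * R)
    }, v, idx)
    expect_equal(bw$grads[[li]][[nm]][idx], fd, tolerance = 1e-5)
  }
  # residual block inner conv
  v <- params[[6]][[1]]$W
  idx <- sample(length(v), 5)
  fd <- fd_grad(function(vv) {
    p <- params; p[[6]][[1]]$W <- array(vv, dim(v))
    sum(sctdir:::nn_forward(net, p, x)$y * R)
  }, v, idx)
  expect_equal(bw$grads[[6]][[1]]$W[idx], fd, tolerance = 1e-5)
  # input gradient
  idx <- sample(length(x), 6)
  fd <- fd_grad(function(xx) sum(sctdir:::nn_forward(net, params,
                                                     array(xx, dim(x)))$y * R),
                x, idx)
  expect_equal(unname(bw$dx[idx]), fd, tolerance = 1e-5)
})

test_that("projection head and fused NCE gradients match finite differences", {
  set.seed(7)
  hp <- sctdir:::head_init(4, 6)
  X <- matrix(stats::rnorm(12 * 4), 12, 4)
  hf <- sctdir:::head_forward(hp, X)
  expect_equal(rowSums(hf$z^2), rep(1, 12), tolerance = 1e-9)
  R <- matrix(stats::rnorm(12 * 6), 12, 6)
  hb <- sctdir:::head_backward(hp, hf$cache, R)
  idx <- sample(length(hp$W1), 5)
  fd <- fd_grad(function(v) {
    p <- hp; p$W1 <- array(v, dim(hp$W1))
    sum(sctdir:::head_forward(p, X)$z * R)
  }, hp$W1, idx)
  expect_equal(hb$grads$W1[idx], fd, tolerance = 1e-5)

  S <- 6; K <- 4
  Z <- matrix(stats::rnorm(S * K), S, K); Z <- Z / sqrt(rowSums(Z^2))
  Zh <- matrix(stats::rnorm(S * K), S, K); Zh <- Zh / sqrt(rowSums(Zh^2))
  r <- sctdir:::nce_loss_grad(Z, Zh, 0.2)
  idx <- sample(length(Z), 6)
  fd <- fd_grad(function(v) sctdir:::nce_loss_grad(matrix(v, S, K), Zh,
                                                   0.2)$loss, Z, idx)
  expect_equal(r$dZ[idx], fd, tolerance = 1e-6)
  fd2 <- fd_grad(function(v) sctdir:::nce_loss_grad(Z, matrix(v, S, K),
                                                    0.2)$loss, Zh, idx)
  expect_equal(r$dZh[idx], fd2, tolerance = 1e-6)
})

test_that("Adam decreases a quadratic and handles nested parameter lists", {
  params <- list(list(W = matrix(2, 2, 2), b = c(1, -1)), list())
  st <- sctdir:::adam_state(params)
  loss <- function(p) sum(p[[1]]$W^2) + sum(p[[1]]$b^2)
  l0 <- loss(params)
  for (i in 1:50) {
    g <- list(list(W = 2 * params[[1]]$W, b = 2 * params[[1]]$b), list())
    r <- sctdir:::adam_step(params, g, st, lr = 0.1)
    params <- r$params; st <- r$state
  }
  expect_lt(loss(params), l0 / 10)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
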