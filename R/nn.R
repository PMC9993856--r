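## Minimal dense/convolutional network machinery with hand-derived
## backpropagation.  No deep-learning framework ships with this R stack, so
## the contrastive translation model runs on these primitives: im2col
## convolutions backed by BLAS matrix products, instance normalization,
## nearest-neighbour upsampling, residual blocks, and Adam.
##
## Conventions: feature maps are arrays [H, W, C]; batch size is one (the
## training protocol uses batch 1).  Layers are stateless descriptions; a
## `forward(params, x)` returns list(y, cache) and
## `backward(params, cache, dy)` returns list(dx, grads), so one layer can
## be applied to several inputs per step (needed because the encoder runs on
## both the input and the translated output).

## He/Kaiming initialization keeps activation scale ~O(1) through
## conv+ReLU stacks even at the small channel counts used here (a fixed
## small SD would shrink activations several-fold per layer and stall
## adversarial training)
nn_he_init <- function(n, fan_in, gain = 1) {
  stats::rnorm(n, sd = gain * sqrt(2 / fan_in))
}

## im2col gather-index cache, keyed by (H, W, cin, k, stride); one integer
## index vector per configuration turns patch extraction into a single
## vectorized subscript operation
.conv_idx_cache <- new.env(parent = emptyenv())

conv_geometry <- function(H, W_, cin, k, stride) {
  key <- paste(H, W_, cin, k, stride, sep = "x")
  g <- .conv_idx_cache[[key]]
  if (!is.null(g)) return(g)
  p <- (k - 1L) %/% 2L
  Ho <- as.integer(ceiling(H / stride)); Wo <- as.integer(ceiling(W_ / stride))
  # left pad p; right pad whatever the last patch needs (even kernels need
  # one extra on the right)
  prH <- max(0L, (Ho - 1L) * stride + k - H - p)
  prW <- max(0L, (Wo - 1L) * stride + k - W_ - p)
  Hp <- H + p + prH; Wp <- W_ + p + prW
  ri <- seq_len(Ho) * stride - stride + 1L
  ci <- seq_len(Wo) * stride - stride + 1L
  b0 <- as.integer(outer(ri, (ci - 1L) * Hp, `+`))      # HoWo base positions
  n <- Ho * Wo
  kk <- k * k
  idx <- integer(n * kk * cin)
  # column layout: (p - 1) * cin + c, p = di + (dj - 1) * k
  for (c_ in seq_len(cin)) {
    coff <- (c_ - 1L) * Hp * Wp
    for (dj in seq_len(k)) for (di in seq_len(k)) {
      p_ <- di + (dj - 1L) * k
      col_j <- (p_ - 1L) * cin + c_
      idx[((col_j - 1L) * n + 1L):(col_j * n)] <-
        b0 + (di - 1L) + (dj - 1L) * Hp + coff
    }
  }
  g <- list(p = p, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, idx = idx, n = n)
  .conv_idx_cache[[key]] <- g
  g
}

## ---- convolution ----------------------------------------------------------

## same-padding conv: output H_out = ceiling(H / stride); weight rows are
## ordered channel-fastest to match the gather-index layout
layer_conv <- function(cin, cout, k = 3L, stride = 1L, init_gain = 1) {
  kk <- k * k
  list(
    type = "conv", cin = cin, cout = cout, k = k, stride = stride,
    init = function() list(
      W = array(nn_he_init(kk * cin * cout, kk * cin, init_gain),
                c(kk * cin, cout)),
      b = numeric(cout)),
    forward = function(params, x) {
      d <- dim(x)
      g <- conv_geometry(d[1], d[2], cin, k, stride)
      xp <- array(0, c(g$Hp, g$Wp, cin))
      xp[g$p + seq_len(d[1]), g$p + seq_len(d[2]), ] <- x
      colm <- xp[g$idx]
      dim(colm) <- c(g$n, kk * cin)
      y <- colm %*% params$W
      y <- y + rep(params$b, each = g$n)
      dim(y) <- c(g$Ho, g$Wo, cout)
      list(y = y, cache = list(colm = colm, dimin = d, g = g))
    },
    backward = function(params, cache, dy) {
      g <- cache$g
      dym <- dy
      dim(dym) <- c(g$n, cout)
      dW <- crossprod(cache$colm, dym)
      db <- .colSums(dym, g$n, cout)
      dcol <- dym %*% t(params$W)
      dxp <- numeric(g$Hp * g$Wp * cin)
      ncolblk <- g$n * cin
      for (p_ in seq_len(kk)) {
        rng <- ((p_ - 1L) * ncolblk + 1L):(p_ * ncolblk)
        ip <- g$idx[rng]
        dxp[ip] <- dxp[ip] + dcol[rng]
      }
      dim(dxp) <- c(g$Hp, g$Wp, cin)
      dx <- dxp[g$p + seq_len(cache$dimin[1]),
                g$p + seq_len(cache$dimin[2]), , drop = FALSE]
      dim(dx) <- cache$dimin
      list(dx = dx, grads = list(W = dW, b = db))
    })
}

## ---- instance normalization ----------------------------------------------

layer_instancenorm <- function(ch, eps = 1e-5) {
  list(
    type = "instancenorm", ch = ch,
    init = function() list(g = rep(1, ch), b = numeric(ch)),
    forward = function(params, x) {
      d <- dim(x)
      n <- d[1] * d[2]
      mu <- .colMeans(x, n, ch)
      xc <- x - rep(mu, each = n)
      v <- .colMeans(xc * xc, n, ch)
      istd <- 1 / sqrt(v + eps)
      xhat <- xc * rep(istd, each = n)
      y <- xhat * rep(params$g, each = n) + rep(params$b, each = n)
      dim(y) <- d
      list(y = y, cache = list(xhat = xhat, istd = istd, d = d))
    },
    backward = function(params, cache, dy) {
      d <- cache$d
      n <- d[1] * d[2]
      xhat <- cache$xhat
      dg <- .colSums(dy * xhat, n, ch)
      db <- .colSums(dy, n, ch)
      dxhat <- dy * rep(params$g, each = n)
      m1 <- .colMeans(dxhat, n, ch)
      m2 <- .colMeans(dxhat * xhat, n, ch)
      dx <- (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n)) *
        rep(cache$istd, each = n)
      dim(dx) <- d
      list(dx = dx, grads = list(g = dg, b = db))
    })
}

## ---- pointwise activations ------------------------------------------------

layer_act <- function(kind = c("relu", "lrelu", "tanh"), slope = 0.2) {
  kind <- match.arg(kind)
  list(
    type = kind,
    init = function() list(),
    forward = function(params, x) {
      y <- switch(kind,
        relu = pmax(x, 0),
        lrelu = pmax(x, 0) + slope * pmin(x, 0),
        tanh = tanh(x))
      list(y = y, cache = list(x = x, y = y))
    },
    backward = function(params, cache, dy) {
      dx <- switch(kind,
        relu = dy * (cache$x > 0),
        lrelu = dy * (slope + (1 - slope) * (cache$x > 0)),
        tanh = dy * (1 - cache$y^2))
      list(dx = dx, grads = list())
    })
}

## ---- nearest-neighbour 2x upsampling --------------------------------------

layer_upsample2 <- function() {
  list(
    type = "upsample2",
    init = function() list(),
    forward = function(params, x) {
      d <- dim(x)
      y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
             drop = FALSE]
      list(y = array(y, c(2 * d[1], 2 * d[2], d[3])), cache = list(d = d))
    },
    backward = function(params, cache, dy) {
      d <- cache$d
      odd <- seq(1, 2 * d[1], 2); evn <- odd + 1
      dx <- dy[odd, , , drop = FALSE] + dy[evn, , , drop = FALSE]
      oddc <- seq(1, 2 * d[2], 2); evnc <- oddc + 1
      dx <- dx[, oddc, , drop = FALSE] + dx[, evnc, , drop = FALSE]
      list(dx = array(dx, d), grads = list())
    })
}

## ---- residual block -------------------------------------------------------

## conv3-IN-ReLU-conv3-IN with identity skip
layer_resblock <- function(ch) {
  inner <- list(layer_conv(ch, ch, 3L, 1L), layer_instancenorm(ch),
                layer_act("relu"), layer_conv(ch, ch, 3L, 1L),
                layer_instancenorm(ch))
  list(
    type = "resblock", inner = inner,
    init = function() lapply(inner, function(l) l$init()),
    forward = function(params, x) {
      caches <- vector("list", length(inner))
      h <- x
      for (i in seq_along(inner)) {
        r <- inner[[i]]$forward(params[[i]], h)
        h <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x + h, cache = caches)
    },
    backward = function(params, cache, dy) {
      grads <- vector("list", length(inner))
      dh <- dy
      for (i in rev(seq_along(inner))) {
        r <- inner[[i]]$backward(params[[i]], cache[[i]], dh)
        dh <- r$dx
        grads[[i]] <- r$grads
      }
      list(dx = dy + dh, grads = grads)
    })
}

## ---- sequential network ---------------------------------------------------

nn_sequential <- function(layers) {
  list(layers = layers)
}

nn_init_params <- function(net) lapply(net$layers, function(l) l$init())

## forward through layers 1..upto; records activations AFTER the layer
## indices named in `taps` (tap index 0 = the raw input)
nn_forward <- function(net, params, x, upto = length(net$layers),
                       taps = integer(0)) {
  caches <- vector("list", upto)
  tap_acts <- list()
  if (0 %in% taps) tap_acts[["0"]] <- x
  h <- x
  for (i in seq_len(upto)) {
    r <- net$layers[[i]]$forward(params[[i]], h)
    h <- r$y
    caches[[i]] <- r$cache
    if (i %in% taps) tap_acts[[as.character(i)]] <- h
  }
  list(y = h, caches = caches, taps = tap_acts)
}

## backward from layer `from` down to layer 1; `dy` is the gradient at the
## output of layer `from`; `tap_grads` (named by layer index as character)
## are added to the gradient flowing past that layer's output.  A tap grad
## at "0" is returned as part of dx.
nn_backward <- function(net, params, caches, dy, from = length(net$layers),
                        tap_grads = list()) {
  grads <- vector("list", length(params))
  dh <- dy
  for (i in seq(from, 1)) {
    key <- as.character(i)
    if (!is.null(tap_grads[[key]])) dh <- dh + tap_grads[[key]]
    r <- net$layers[[i]]$backward(params[[i]], caches[[i]], dh)
    dh <- r$dx
    grads[[i]] <- r$grads
  }
  if (!is.null(tap_grads[["0"]])) dh <- dh + tap_grads[["0"]]
  list(dx = dh, grads = grads)
}

## elementwise-add two gradient pytrees (nested lists of arrays)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) {
      r <- grads_add(a[[i]], b[[i]])
      if (is.null(r)) out[i] <- list(NULL) else out[[i]] <- r
    }
    return(out)
  }
  a + b
}

grads_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, grads_scale, s = s))
  a * s
}

grads_zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, grads_zero_like))
  p * 0
}

## ---- Adam -----------------------------------------------------------------

adam_state <- function(params) {
  list(m = grads_zero_like(params), v = grads_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    if (length(p) == 0) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

## ---- MLP projection head --------------------------------------------------

## two dense layers (Cin -> K -> K) with ReLU between; output L2-normalized
head_init <- function(cin, K) {
  # biases start slightly off zero so an all-zero feature vector (a fully
  # dead-ReLU location in the encoder) still projects to a well-defined
  # unit vector instead of 0/0
  list(W1 = array(stats::rnorm(cin * K, sd = sqrt(2 / cin)), c(cin, K)),
       b1 = stats::rnorm(K, sd = 0.01),
       W2 = array(stats::rnorm(K * K, sd = sqrt(2 / K)), c(K, K)),
       b2 = stats::rnorm(K, sd = 0.01))
}

head_forward <- function(params, X) {       # X: [S, Cin]
  h1 <- sweep(X %*% params$W1, 2, params$b1, `+`)
  a1 <- pmax(h1, 0)
  h2 <- sweep(a1 %*% params$W2, 2, params$b2, `+`)
  nrm <- sqrt(rowSums(h2^2)) + 1e-12
  z <- h2 / nrm
  list(z = z, cache = list(X = X, h1 = h1, a1 = a1, h2 = h2, nrm = nrm, z = z))
}

head_backward <- function(params, cache, dz) {
  # through normalization: dh2 = (dz - z * rowSums(z*dz)) / nrm
  z <- cache$z
  dh2 <- (dz - z * rowSums(z * dz)) / cache$nrm
  dW2 <- crossprod(cache$a1, dh2)
  db2 <- colSums(dh2)
  da1 <- dh2 %*% t(params$W2)
  dh1 <- da1 * (cache$h1 > 0)
  dW1 <- crossprod(cache$X, dh1)
  db1 <- colSums(dh1)
  dX <- dh1 %*% t(params$W1)
  list(dX = dX, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}
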