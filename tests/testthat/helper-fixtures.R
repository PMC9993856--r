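# Shared desk-scale fixtures.  Everything is generated in code; expensive
# objects (the trained micro generator) are built once per test run and
# memoized.

.fixture_cache <- new.env(parent = emptyenv())

# the desk-scale phantom world: 64x64 slices at 2 mm (128 mm field of view)
micro_phantom_config <- function() phantom_config(shape = c(64L, 64L),
                                                  spacing = c(2, 2))

micro_deformation <- function() list(amplitude_mm = 3, smoothness_mm = 20)

# one synthetic fraction: clean CT ground truth + degraded CBCT
micro_case <- function(seed) {
  make_phantom_case(micro_phantom_config(), artifact_config(),
                    micro_deformation(), seed = seed)
}

micro_training_sets <- function(seed, n = 40L) {
  cfg <- experiment_config(phantom = micro_phantom_config(),
                           deformation = micro_deformation(),
                           n_train_slices = n, seed = seed)
  sctdir:::cohort_training_images(cfg)
}

# reduced-epoch training protocol for per-seed improvement checks; at a few
# hundred steps the linear-decay tail of the full protocol is unused, so the
# LR is held constant (scaled-down schedule)
micro_train_config <- function(seed, epochs = 4L) {
  train_config(epochs = epochs, warm_epochs = epochs, seed = as.integer(seed))
}

train_micro_model <- function(seed, n = 40L, epochs = 4L) {
  tr <- micro_training_sets(seed, n)
  train_clg(tr$x, tr$y, generator_spec(), loss_config(),
            micro_train_config(seed, epochs))
}

# memoized cohort generator shared by the pipeline-level tests: the
# longer-trained model used for the two-arm experiment
cached_micro_model <- function() {
  if (is.null(.fixture_cache$model))
    .fixture_cache$model <- train_micro_model(seed = 101L, epochs = 24L)$model
  .fixture_cache$model
}

# fast demons settings for 64^2 cohort tests
micro_demons_config <- function() demons_config(iterations = 30L, levels = 2L)

mae <- function(a, b) mean(abs(a$values - b$values))

# smooth random binary mask for metric oracle tests
random_blob <- function(shape, seed) {
  set.seed(seed)
  z <- array(stats::rnorm(prod(shape)), shape)
  z <- sctdir:::gaussian_blur(z, rep(2, length(shape)))
  m <- (z > stats::quantile(z, 0.7)) * 1
  if (sum(m) == 0) m[ceiling(shape / 2)] <- 1
  array(m, shape)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
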