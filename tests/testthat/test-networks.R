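# Architecture builders, autoencoder primitives, training behaviour,
# and the Jaya hyperparameter search.

# Structural walker independent of the builders: recount convolutions
# and check kernels/strides from the raw layer descriptors.
walk_convs <- function(spec, sections, role = "main") {
  Filter(function(ly) ly$kind == "conv" && ly$section %in% sections &&
           ly$role == role, spec$layers)
}

test_that("modified ResNet-50 satisfies the architecture contract", {
  spec <- build_modified_resnet50(c(224L, 224L, 3L), 4L, 1)
  sm <- network_summary(spec)
  expect_equal(unname(sm$tap_widths["gap"]), 1024L)
  for (blk in c("added1", "added2", "added3")) {
    convs <- walk_convs(spec, blk)
    expect_length(convs, 4L)
    expect_true(all(vapply(convs, `[[`, 0L, "stride") == 1L))
    kernels <- unname(vapply(convs, function(l) l$kernel[1], 0L))
    expect_equal(kernels, c(1L, 3L, 1L, 3L))
  }
  # one extra 3x3 stride-1 conv after the first appended block
  extra <- walk_convs(spec, "extra_conv")
  expect_length(extra, 1L)
  expect_equal(extra[[1]]$kernel, c(3L, 3L))
  expect_equal(extra[[1]]$stride, 1L)
  # backbone: stem + 3*(3+4+6+3) bottleneck convs
  backbone <- walk_convs(spec, c("stem", paste0("stage", 1:4)))
  expect_length(backbone, 1L + 3L * 16L)
  # every conv is followed by batch normalization
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  conv_pos <- which(kinds == "conv")
  expect_true(all(kinds[conv_pos + 1L] == "batchnorm"))
})

test_that("gap width scales with the channel multiplier", {
  expect_equal(unname(network_summary(
    build_modified_resnet50(c(64L, 64L, 3L), 4L, 0.25))$tap_widths["gap"]),
    256L)
  expect_equal(unname(network_summary(
    build_modified_resnet50(c(32L, 32L, 1L), 4L, 0.125))$tap_widths["gap"]),
    128L)
  expect_error(build_modified_resnet50(c(16L, 16L, 1L)), "at least 32")
})

test_that("parameter count is monotone in the width scale", {
  counts <- vapply(c(0.125, 0.25, 0.5, 1), function(ws) {
    network_summary(build_modified_resnet50(c(64L, 64L, 1L), 4L,
                                            ws))$n_parameters
  }, 0)
  expect_true(all(diff(counts) > 0))
})

test_that("stacked autoencoder has 5+5 convolutions and the published tap width", {
  spec <- build_stacked_autoencoder()
  sm <- network_summary(spec)
  expect_equal(unname(sm$tap_widths["decoder_conv_last"]), 1236L)
  expect_length(walk_convs(spec, "encoder"), 5L)
  expect_length(walk_convs(spec, "decoder"), 5L)
  # reconstruction output has the input's shape
  last <- sm$layers$out_shape[nrow(sm$layers)]
  expect_equal(last, "224x224x3")
  # dense bottlenecks 100 then 50
  widths <- vapply(Filter(function(l) l$kind == "dense" &&
                            grepl("^code", l$name), spec$layers),
                   `[[`, 0L, "units")
  expect_equal(widths, c(100L, 50L), ignore_attr = TRUE)
  expect_error(build_stacked_autoencoder(c(100L, 100L, 1L)),
               "multiples of 32")
})

test_that("autoencoder layer map matches hand arithmetic", {
  expect_equal(sae_layer_forward(c(2, -1), diag(2), c(0, 0), "linear"),
               c(2, -1))
  expect_equal(sae_layer_forward(c(1, -1), matrix(c(1, 1), 1), 0.5,
                                 "sigmoid"),
               1 / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(sae_layer_forward(c(1, 2), matrix(c(-1, -2, -3, -4), 2),
                                 c(0, 0), "relu"), c(0, 0))
  expect_error(sae_layer_forward(c(1, 2, 3), diag(2), c(0, 0)),
               "shape mismatch")
})

test_that("reconstruction loss matches its definition and scaling law", {
  expect_equal(sae_loss(matrix(2), matrix(0)), 2)
  x <- matrix(rnorm(12), 3)
  expect_equal(sae_loss(x, x), 0)
  r <- matrix(rnorm(12), 3)
  # brute-force elementwise oracle
  oracle <- sum((x - r)^2) / (2 * nrow(x))
  expect_equal(sae_loss(x, r), oracle, tolerance = 1e-12)
  # doubling every residual entry quadruples the loss
  expect_equal(sae_loss(x, x + 2 * (r - x)), 4 * sae_loss(x, r),
               tolerance = 1e-12)
  # regularizers add exactly their closed forms
  w <- list(matrix(1:4, 2))
  hm <- c(0.2, 0.4)
  rho <- 0.15
  kl <- sum(rho * log(rho / hm) + (1 - rho) * log((1 - rho) / (1 - hm)))
  expect_equal(sae_loss(x, r, weights = w, hidden_mean = hm,
                        l2_weight = 0.01, sparsity_reg = 2),
               oracle + 0.01 * 30 + 2 * kl, tolerance = 1e-12)
  expect_error(sae_loss(matrix(1, 2, 2), matrix(1, 2, 3)), "shape")
})

test_that("CNN training descends, learns above chance, and is seed-deterministic", {
  fx <- cnn_fixture()
  h <- fx$model$history
  expect_equal(nrow(h), 12L)
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_gt(h$accuracy[nrow(h)], h$accuracy[1])
  # hold-out accuracy well above the 0.25 chance level
  probs <- predict_network(fx$model,
                           fx$data$images[, , , fx$test_idx, drop = FALSE])
  acc <- mean(max.col(probs) - 1L == fx$data$labels[fx$test_idx])
  expect_gt(acc, 0.6)
  # determinism: two short runs with one seed coincide exactly
  ds <- sub_images(fx$data, c(1:8, 41:48, 81:88, 121:128))
  spec <- build_modified_resnet50(c(32L, 32L, 1L), 4L, 0.125)
  cfg <- train_config(optimizer = "adam", max_epochs = 1L,
                      minibatch = 16L, learning_rate = 0.003)
  m1 <- train_network(spec, ds, cfg, seed = 9)
  m2 <- train_network(spec, ds, cfg, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("autoencoder training reduces reconstruction loss", {
  fx <- sae_fixture()
  h <- fx$model$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_true(all(is.finite(h$loss)))
})

test_that("Jaya search recovers a known optimum and respects its budget", {
  hits <- vapply(1:10, function(s) {
    sp <- hyperparam_space(
      list(lr = param_continuous(1e-4, 1e-2, log = TRUE)),
      population = 6L, iterations = 20L)
    r <- tune_hyperparameters_jaya(sp, function(cfg) {
      -(log10(cfg$lr) + 3)^2
    }, seed = s)
    r$config$lr > 5e-4 && r$config$lr < 2e-3
  }, NA)
  expect_gte(sum(hits), 8L)

  evals <- 0L
  sp2 <- hyperparam_space(list(a = param_continuous(0, 1)),
                          population = 2L, iterations = 1L)
  r2 <- tune_hyperparameters_jaya(sp2, function(cfg) {
    evals <<- evals + 1L
    -abs(cfg$a - 0.3)
  }, seed = 1)
  expect_equal(evals, 4L)
  expect_equal(r2$n_evaluations, 4L)
  expect_error(
    tune_hyperparameters_jaya(sp2, function(cfg) NaN, seed = 1),
    "non-finite")
})
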