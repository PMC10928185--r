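# Grad-CAM weights, maps, and whole-image explanations.

test_that("channel weights are gradient-grid means", {
  expect_equal(gradcam_weights(matrix(1:4, 2, 2)), 2.5)
  g <- array(0, c(3, 3, 4))
  expect_equal(gradcam_weights(g), rep(0, 4))
  set.seed(1)
  g2 <- array(rnorm(18), c(3, 3, 2))
  expect_equal(gradcam_weights(5 * g2), 5 * gradcam_weights(g2))
})

test_that("the map is the rectified weighted activation sum", {
  a1 <- rbind(c(1, 0), c(0, 0)); a2 <- rbind(c(0, 0), c(0, 1))
  hm <- gradcam_map(array(c(a1, a2), c(2, 2, 2)), c(2, -3))
  expect_equal(hm$map, rbind(c(2, 0), c(0, 0)))
  neg <- gradcam_map(array(-abs(rnorm(4)), c(2, 2, 1)), 1)
  expect_equal(neg$map, matrix(0, 2, 2))
  zero <- gradcam_map(array(rnorm(8), c(2, 2, 2)), c(0, 0))
  expect_equal(zero$map, matrix(0, 2, 2))
  expect_error(gradcam_map(array(0, c(2, 2, 2)), 1), "shape mismatch")
})

test_that("weights and maps agree with a scalar-loop oracle", {
  set.seed(2)
  for (i in 1:10) {
    K <- sample(1:3, 1)
    grads <- array(rnorm(16 * K), c(4, 4, K))
    acts <- array(rnorm(16 * K), c(4, 4, K))
    # brute-force oracle
    w_o <- numeric(K); m_o <- matrix(0, 4, 4)
    for (k in 1:K) {
      s <- 0
      for (ii in 1:4) for (jj in 1:4) s <- s + grads[ii, jj, k]
      w_o[k] <- s / 16
    }
    for (ii in 1:4) for (jj in 1:4) {
      v <- 0
      for (k in 1:K) v <- v + w_o[k] * acts[ii, jj, k]
      m_o[ii, jj] <- max(v, 0)
    }
    expect_equal(gradcam_weights(grads), w_o, tolerance = 1e-12)
    expect_equal(gradcam_map(acts, w_o)$map, m_o, tolerance = 1e-12)
  }
})

test_that("explanations localize on the brain mask and expose the score", {
  fx <- cnn_fixture()
  i <- fx$test_idx[1]
  hm <- explain_image(fx$model, fx$data$images[, , , i])
  # raw map has the tap's spatial shape; display copy the input's
  expect_equal(dim(hm$map), c(1L, 1L))
  expect_true(all(hm$map >= 0))
  expect_equal(dim(hm$upsampled), c(32L, 32L))
  expect_true(is.finite(hm$score))
  # a shallower spatial tap gives a richer map; heat concentrates on
  # the elliptical support where all class signal lives
  hm2 <- explain_image(fx$model, fx$data$images[, , , i],
                       class_index = fx$data$labels[i],
                       layer = "stage2_b1_relu")
  expect_equal(dim(hm2$upsampled), c(32L, 32L))
  inside <- sum(hm2$upsampled[fx$data$mask])
  outside <- sum(hm2$upsampled[!fx$data$mask])
  expect_gt(inside, outside)
})

test_that("degenerate networks yield zero maps and bad requests fail", {
  fx <- cnn_fixture()
  dead <- fx$model
  dead$params$fc$w <- dead$params$fc$w * 0
  dead$params$fc$b <- dead$params$fc$b * 0
  hm <- explain_image(dead, fx$data$images[, , , 1], class_index = 0L,
                      layer = "stage2_b1_relu")
  expect_equal(max(abs(hm$map)), 0)
  expect_error(explain_image(fx$model, fx$data$images[, , , 1],
                             class_index = 9L), "out of range")
  expect_error(explain_image(fx$model, fx$data$images[, , , 1],
                             layer = "gap"), "not a convolutional")
  expect_error(explain_image(fx$model, fx$data$images[, , , 1],
                             layer = "nope"), "unknown layer")
})
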