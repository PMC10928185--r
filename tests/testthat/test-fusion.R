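# Parallel-pooling fusion operator.

test_that("mean padding appends the running mean and nothing else", {
  expect_equal(mean_pad(c(1, 3), 3), c(1, 3, 2))
  v <- rnorm(10)
  expect_identical(mean_pad(v, 10), v)
  expect_equal(mean_pad(5, 3), c(5, 5, 5))
  expect_error(mean_pad(1:4, 2), "shorter")
})

test_that("pooling reproduces worked examples and the published widths", {
  expect_length(pool1d(stats::rnorm(1024)), 512L)
  expect_length(pool1d(stats::rnorm(1236)), 618L)
  expect_equal(pool1d(c(1, 3, 2, 5)), c(3, 5))
  expect_equal(pool1d(c(1, 3, 2), fusion_config(mode = "mean")), c(2, 2))
  expect_error(pool1d(c(1, 2, 3), fusion_config(pad_policy = "none")),
               "align")
})

# independent oracle: explicit windowing after explicit mean padding
pool_oracle <- function(v, window, stride, mode) {
  while (length(v) < window ||
         (length(v) - window) %% stride != 0) v <- c(v, mean(v))
  starts <- seq(1, length(v) - window + 1, by = stride)
  vapply(starts, function(s) {
    w <- v[s:(s + window - 1)]
    if (mode == "max") max(w) else mean(w)
  }, 0)
}

test_that("pooling matches the brute-force windowing oracle on widths 1..64", {
  set.seed(1)
  for (w in 1:64) {
    v <- rnorm(w)
    for (mode in c("max", "mean")) {
      got <- pool1d(v, fusion_config(mode = mode))
      expect_equal(got, pool_oracle(v, 2, 2, mode))
      expect_length(got, ceiling(w / 2))
    }
  }
  # non-default geometry
  v <- rnorm(17)
  cfg <- fusion_config(window = 3, stride = 2, mode = "mean")
  expect_equal(pool1d(v, cfg), pool_oracle(v, 3, 2, "mean"))
})

test_that("max pooling dominates mean pooling elementwise", {
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(sample(4:40, 1))
    expect_true(all(pool1d(v, fusion_config(mode = "max")) >=
                      pool1d(v, fusion_config(mode = "mean")) - 1e-12))
  }
})

test_that("fusion concatenates pooled halves in order with tagged names", {
  set.seed(3)
  fv1 <- matrix(rnorm(5 * 1024), 5)
  fv2 <- matrix(rnorm(5 * 1236), 5)
  fused <- fuse_features(fv1, fv2)
  expect_equal(ncol(fused), 1130L)
  expect_equal(nrow(fused), 5L)
  expect_identical(grep("^fv1_", colnames(fused)), 1:512)
  expect_identical(grep("^fv2_", colnames(fused)), 513:1130)
  # each row pooled independently and identically to pool1d
  expect_equal(unname(fused[3, 1:512]), pool1d(fv1[3, ]))
  expect_equal(unname(fused[3, 513:1130]), pool1d(fv2[3, ]))
})

test_that("fusion handles degenerate and symmetric inputs", {
  set.seed(4)
  fv1 <- matrix(rnorm(4 * 10), 4)
  empty <- matrix(numeric(0), 4, 0)
  expect_equal(unname(fuse_features(fv1, empty)),
               unname(fuse_features(fv1, empty)))
  expect_equal(ncol(fuse_features(fv1, empty)), 5L)
  self <- fuse_features(fv1, fv1)
  expect_equal(unname(self[, 1:5]), unname(self[, 6:10]))
  expect_error(fuse_features(fv1, matrix(0, 3, 4)), "same number")
})

test_that("fused width follows ceil(w1/2) + ceil(w2/2) for arbitrary widths", {
  set.seed(5)
  for (i in 1:15) {
    w1 <- sample(1:64, 1); w2 <- sample(1:64, 1)
    fused <- fuse_features(matrix(rnorm(3 * w1), 3),
                           matrix(rnorm(3 * w2), 3))
    expect_equal(ncol(fused), ceiling(w1 / 2) + ceiling(w2 / 2))
  }
})
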