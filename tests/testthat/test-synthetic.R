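# Synthetic generators and the slice-accounting rule.

test_that("feature generator obeys its shape, balance, and tagging contract", {
  fd <- make_feature_dataset(200, 4, 5, 5, 40, 3, seed = 7)
  expect_equal(dim(fd$x), c(200L, 50L))
  expect_true(all(is.finite(fd$x)))
  counts <- table(fd$y)
  expect_length(counts, 4L)
  expect_lte(max(counts) - min(counts), 1L)
  expect_identical(fd$info$informative, 1:5)
  expect_identical(grep("^inf_", colnames(fd$x)), 1:5)
  expect_identical(grep("^noise_", colnames(fd$x)), 11:50)
})

test_that("generators are bitwise deterministic in the seed", {
  a <- make_feature_dataset(100, 4, 3, 2, 5, 2, seed = 7)
  b <- make_feature_dataset(100, 4, 3, 2, 5, 2, seed = 7)
  expect_identical(a, b)
  c2 <- make_feature_dataset(100, 4, 3, 2, 5, 2, seed = 8)
  expect_false(identical(a$x, c2$x))
  i1 <- make_modality_images(3, 32, 32, seed = 11)
  i2 <- make_modality_images(3, 32, 32, seed = 11)
  expect_identical(i1$images, i2$images)
})

test_that("generator rejects degenerate requests", {
  expect_error(make_feature_dataset(200, 4, n_informative = 0),
               "n_informative")
  expect_error(make_feature_dataset(5, 4), "n_samples")
  expect_error(make_modality_images(0), "n_per_class")
  expect_error(make_modality_images(2, height = 8), "height")
})

test_that("modality images are bounded, balanced, and class-distinct", {
  ds <- make_modality_images(10, 32, 32, seed = 2)
  expect_equal(dim(ds$images), c(32L, 32L, 1L, 40L))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  expect_equal(as.integer(table(ds$labels)), rep(10L, 4L))
  means <- lapply(0:3, function(k) {
    apply(ds$images[, , 1, ds$labels == k, drop = FALSE], c(1, 2), mean)
  })
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gt(sqrt(sum((means[[i]] - means[[j]])^2)), 0.5)
  }
})

test_that("no-signal features give chance-level ELM accuracy", {
  accs <- vapply(1:20, function(s) {
    fd <- make_feature_dataset(120, 4, 5, 0, 10, class_sep = 0, seed = s)
    elm_fitness(fd$x, fd$y, rep(TRUE, 15), seed = s, train_ratio = 0.5)
  }, 0)
  # 20 independent runs, 60 held-out samples each: the mean sits within
  # a few standard errors of 1/K
  expect_lt(abs(mean(accs) - 0.25), 0.05)
})

test_that("ELM accuracy is non-decreasing in the class separation", {
  mean_acc <- vapply(c(0, 1, 3), function(sep) {
    mean(vapply(1:10, function(s) {
      fd <- make_feature_dataset(160, 4, 5, 0, 10, sep, seed = s)
      elm_fitness(fd$x, fd$y, rep(TRUE, 15), seed = s, train_ratio = 0.5)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_acc) >= 0))
})

test_that("slice accounting matches brute-force enumeration", {
  plan <- plan_slice_selection(10, 1, 155, 4)
  expect_equal(plan$per_class, 1550L)
  expect_equal(plan$total, 6200L)
  # enumeration oracle over (patient, slice, modality) tuples
  tuples <- expand.grid(patient = 1:10, slice = 1:155, modality = 1:4)
  expect_equal(plan$total, nrow(tuples))
  expect_equal(plan$per_class, sum(tuples$modality == 1))
  single <- plan_slice_selection(1, 40, 114, 1)
  expect_equal(single$per_class, 75L)
  expect_error(plan_slice_selection(5, 50, 40), "inverted")
})

test_that("feature tables and image datasets round-trip through disk", {
  dir <- withr::local_tempdir()
  fd <- make_feature_dataset(30, 3, 2, 1, 2, 2, seed = 5)
  p <- file.path(dir, "feat.csv")
  write_feature_csv(fd$x, fd$y, p)
  back <- read_feature_csv(p)
  expect_equal(back$x, fd$x, tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(back$y, fd$y)
  expect_identical(colnames(back$x), colnames(fd$x))

  ds <- make_modality_images(2, 16, 16, seed = 9)
  idir <- file.path(dir, "imgs")
  write_image_dataset(ds, idir)
  back2 <- read_image_dataset(idir)
  expect_identical(back2$labels, ds$labels)
  # 8-bit PNG quantization
  expect_lt(max(abs(back2$images - ds$images)), 1 / 255 + 1e-9)
})
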