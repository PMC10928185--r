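# Classifier presets, the confusion metric suite, and the evaluation
# protocol.

test_that("presets map to their defined layouts and reject unknowns", {
  expect_equal(make_classifier_preset("narrow")$hidden_layout, 10L)
  expect_equal(make_classifier_preset("medium")$hidden_layout, 25L)
  expect_equal(make_classifier_preset("wide")$hidden_layout, 100L)
  expect_equal(make_classifier_preset("bilayered")$hidden_layout,
               c(10L, 10L))
  expect_equal(make_classifier_preset("trilayered")$hidden_layout,
               c(10L, 10L, 10L))
  expect_error(make_classifier_preset("mlp7"), "unknown")
})

test_that("metrics reproduce the binary worked example", {
  conf <- rbind(c(9, 1), c(2, 8))
  rep <- compute_metrics(conf)
  expect_equal(rep$per_class$sensitivity[1], 90)
  expect_equal(rep$per_class$precision[1], 900 / 11, tolerance = 1e-9)
  expect_equal(rep$per_class$fnr[1], 10)
  expect_equal(rep$accuracy, 85)
})

test_that("perfect and degenerate confusions behave as defined", {
  rep <- compute_metrics(diag(c(5L, 7L, 9L)))
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$fnr, 0)
  expect_equal(rep$sensitivity, 100)
  expect_error(compute_metrics(matrix(0L, 2, 2)), "zero total")
  expect_error(compute_metrics(matrix(1L, 2, 3)), "square")
})

test_that("FNR complements sensitivity per class", {
  set.seed(7)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    conf <- matrix(rpois(K * K, 4), K)
    conf[1, 1] <- conf[1, 1] + 1  # non-zero total
    rep <- compute_metrics(conf)
    ok <- !is.na(rep$per_class$sensitivity)
    expect_equal(rep$per_class$fnr[ok], 100 - rep$per_class$sensitivity[ok])
  }
})

test_that("metrics agree with a per-pair counting oracle", {
  set.seed(8)
  for (i in 1:300) {
    K <- sample(2:5, 1); n <- sample(20:60, 1)
    truth <- sample(0:(K - 1), n, replace = TRUE)
    pred <- sample(0:(K - 1), n, replace = TRUE)
    conf <- neurofusion:::confusion_from(truth, pred, K)
    rep <- compute_metrics(conf)
    # brute-force counts
    for (k in 0:(K - 1)) {
      tp <- sum(truth == k & pred == k)
      fn <- sum(truth == k & pred != k)
      fp <- sum(truth != k & pred == k)
      expect_equal(rep$per_class$tp[k + 1], tp)
      expect_equal(rep$per_class$fn[k + 1], fn)
      expect_equal(rep$per_class$fp[k + 1], fp)
      expect_equal(rep$per_class$tn[k + 1], n - tp - fn - fp)
    }
    expect_equal(rep$accuracy, 100 * mean(truth == pred))
  }
})

test_that("metrics are invariant to simultaneous class permutation", {
  set.seed(9)
  conf <- matrix(rpois(16, 6), 4)
  perm <- sample(4)
  a <- compute_metrics(conf)
  b <- compute_metrics(conf[perm, perm])
  expect_equal(sort(a$per_class$sensitivity), sort(b$per_class$sensitivity))
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$precision, b$precision)
})

test_that("rank-based AUC hits its closed-form anchors and matches pROC", {
  y <- c(0L, 0L, 1L, 1L, 1L)
  perfect <- cbind(c(.9, .8, .1, .2, .3), c(.1, .2, .9, .8, .7))
  expect_equal(neurofusion:::auc_macro_ovr(perfect, y), 1.0)
  constant <- matrix(0.5, 5, 2)
  expect_equal(neurofusion:::auc_macro_ovr(constant, y), 0.5)
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:10) {
    yy <- sample(0:1, 40, replace = TRUE)
    if (length(unique(yy)) < 2) next
    sc <- cbind(rnorm(40), rnorm(40))
    ours <- neurofusion:::auc_macro_ovr(sc, yy)
    ref <- mean(c(
      as.numeric(pROC::auc(pROC::roc(yy == 0, sc[, 1], quiet = TRUE,
                                     direction = "<"))),
      as.numeric(pROC::auc(pROC::roc(yy == 1, sc[, 2], quiet = TRUE,
                                     direction = "<")))))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("wide preset masters well-separated features", {
  fd <- make_feature_dataset(200, 4, 5, 0, 5, 6, seed = 2)
  rep <- evaluate_classifier(fd$x, fd$y, make_classifier_preset("wide"),
                             list(holdout = 0.5), seed = 2)
  expect_gte(rep$accuracy, 95)
  expect_gte(rep$auc, 0.99)
  expect_equal(sum(rep$confusion), 100)
})

test_that("label shuffles drive the MLP to chance", {
  fd <- make_feature_dataset(120, 4, 5, 0, 10, 3, seed = 1)
  accs <- vapply(1:20, function(s) {
    y_sh <- neurofusion:::with_seed(s, sample(fd$y))
    evaluate_classifier(fd$x, y_sh,
                        make_classifier_preset("narrow",
                                               max_iterations = 80L),
                        list(holdout = 0.5), seed = s)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 25), 5)
})

test_that("k-fold and leave-one-out protocols return valid reports", {
  fd <- make_feature_dataset(60, 3, 4, 0, 2, 4, seed = 5)
  rep <- evaluate_classifier(fd$x, fd$y,
                             make_classifier_preset("medium",
                                                    max_iterations = 80L),
                             list(k_folds = 5), seed = 5)
  expect_equal(sum(rep$confusion), 60)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 100)
  loo <- make_feature_dataset(12, 2, 3, 0, 0, 4, seed = 3)
  rl <- evaluate_classifier(loo$x, loo$y,
                            make_classifier_preset("narrow",
                                                   max_iterations = 60L),
                            list(k_folds = 12), seed = 3)
  expect_equal(sum(rl$confusion), 12)
  expect_true(is.finite(rl$accuracy))
})
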