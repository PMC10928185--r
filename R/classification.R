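# Final classifiers: the five neural-network presets, the confusion
# metric suite, and the holdout / k-fold evaluation protocol.

#' Classifier presets
#'
#' Maps the five preset names to concrete multilayer-perceptron
#' layouts following the MATLAB Classification Learner conventions the
#' names come from: narrow [10], medium [25], wide [100], bi-layered
#' [10, 10], tri-layered [10, 10, 10]; ReLU hidden units and a softmax
#' output in every case.
#'
#' @param name One of `"narrow"`, `"medium"`, `"wide"`, `"bilayered"`,
#'   `"trilayered"`.
#' @param max_iterations Training iterations for the fitted MLP.
#' @param seed Integer seed stored with the spec.
#' @return A list of class `classifier_spec`.
#' @export
make_classifier_preset <- function(name, max_iterations = 200L,
                                   seed = 1L) {
  layouts <- list(narrow = 10L, medium = 25L, wide = 100L,
                  bilayered = c(10L, 10L), trilayered = c(10L, 10L, 10L))
  if (!name %in% names(layouts)) {
    stop("unknown classifier preset: ", name)
  }
  structure(list(name = name, hidden_layout = layouts[[name]],
                 activation = "relu",
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# Dense MLP trained by Adam on softmax cross-entropy. Features are
# standardized with training-set statistics.
mlp_fit <- function(x, y, n_classes, hidden_layout, max_iterations = 200L,
                    learning_rate = 0.01, seed = 1L) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd); sdv[sdv < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  widths <- c(ncol(x), hidden_layout, n_classes)
  L <- length(widths) - 1L
  with_seed(seed, {
    ws <- lapply(seq_len(L), function(i) {
      matrix(stats::rnorm(widths[i] * widths[i + 1],
                          sd = sqrt(2 / widths[i])),
             widths[i], widths[i + 1])
    })
    bs <- lapply(seq_len(L), function(i) numeric(widths[i + 1]))
  })
  y1h <- one_hot(y, n_classes)
  m_w <- lapply(ws, function(w) w * 0); v_w <- m_w
  m_b <- lapply(bs, function(b) b * 0); v_b <- m_b
  n <- nrow(xs)
  for (t in seq_len(max_iterations)) {
    acts <- vector("list", L + 1L); acts[[1]] <- xs
    for (i in seq_len(L)) {
      z <- sweep(acts[[i]] %*% ws[[i]], 2, bs[[i]], "+")
      acts[[i + 1]] <- if (i < L) pmax(z, 0) else z
    }
    probs <- softmax_rows(acts[[L + 1]])
    delta <- (probs - y1h) / n
    for (i in seq.int(L, 1L)) {
      dw <- crossprod(acts[[i]], delta)
      db <- colSums(delta)
      if (i > 1L) {
        delta <- tcrossprod(delta, ws[[i]]) * (acts[[i]] > 0)
      }
      m_w[[i]] <- 0.9 * m_w[[i]] + 0.1 * dw
      v_w[[i]] <- 0.999 * v_w[[i]] + 0.001 * dw^2
      ws[[i]] <- ws[[i]] - learning_rate *
        (m_w[[i]] / (1 - 0.9^t)) / (sqrt(v_w[[i]] / (1 - 0.999^t)) + 1e-8)
      m_b[[i]] <- 0.9 * m_b[[i]] + 0.1 * db
      v_b[[i]] <- 0.999 * v_b[[i]] + 0.001 * db^2
      bs[[i]] <- bs[[i]] - learning_rate *
        (m_b[[i]] / (1 - 0.9^t)) / (sqrt(v_b[[i]] / (1 - 0.999^t)) + 1e-8)
    }
  }
  structure(list(ws = ws, bs = bs, mu = mu, sd = sdv,
                 n_classes = n_classes), class = "mlp_model")
}

mlp_predict <- function(model, newx) {
  a <- sweep(sweep(as.matrix(newx), 2, model$mu), 2, model$sd, "/")
  L <- length(model$ws)
  for (i in seq_len(L)) {
    z <- sweep(a %*% model$ws[[i]], 2, model$bs[[i]], "+")
    a <- if (i < L) pmax(z, 0) else z
  }
  probs <- softmax_rows(a)
  list(class = max.col(probs, ties.method = "first") - 1L, probs = probs)
}

#' Confusion-matrix metric suite
#'
#' From a K x K confusion matrix (rows = truth, columns = predicted)
#' computes, per class, TP on the diagonal, FN as the remaining row
#' sum, FP as the remaining column sum, TN as the rest; then
#' sensitivity TP/(TP+FN), precision TP/(TP+FP), false-negative rate
#' FN/(TP+FN) = 100% - sensitivity, and overall accuracy as the
#' diagonal share. Macro values are unweighted class means; all rates
#' are reported as percentages.
#'
#' @param confusion Non-negative integer K x K matrix with a positive
#'   total.
#' @return A list of class `metrics_report` with `confusion`,
#'   `per_class` (data frame), `accuracy`, `sensitivity`, `fnr`,
#'   `precision` (macro, percent), and `auc` (`NA`: the area under the
#'   curve needs class scores and is filled by
#'   [evaluate_classifier()]).
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || nrow(confusion) < 1) {
    stop("confusion matrix must be square and non-empty")
  }
  if (any(confusion < 0)) stop("negative confusion counts")
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix (zero total)")
  K <- nrow(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  prec <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  fnr <- ifelse(tp + fn > 0, 100 * fn / (tp + fn), NA_real_)
  per_class <- data.frame(class = seq_len(K) - 1L, tp = tp, fn = fn,
                          fp = fp, tn = tn, sensitivity = sens,
                          fnr = fnr, precision = prec)
  structure(list(
    confusion = confusion, per_class = per_class,
    accuracy = 100 * sum(tp) / total,
    sensitivity = mean(sens, na.rm = TRUE),
    fnr = mean(fnr, na.rm = TRUE),
    precision = mean(prec, na.rm = TRUE),
    auc = NA_real_, wall_time_s = NA_real_
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> accuracy %.2f%% | sensitivity %.2f%% | FNR %.2f%% | precision %.2f%% | AUC %s\n",
    x$accuracy, x$sensitivity, x$fnr, x$precision,
    if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

# Macro one-vs-rest AUC from class scores, by the rank (Mann-Whitney)
# statistic with midranks for ties.
auc_macro_ovr <- function(scores, labels) {
  K <- ncol(scores)
  aucs <- vapply(seq_len(K), function(k) {
    pos <- labels == (k - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, k])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
  mean(aucs, na.rm = TRUE)
}

confusion_from <- function(truth, pred, K) {
  tab <- table(factor(truth, levels = 0:(K - 1L)),
               factor(pred, levels = 0:(K - 1L)))
  matrix(as.integer(tab), K, K)
}

#' Train and evaluate a preset classifier
#'
#' Trains the preset MLP on features and evaluates it under the chosen
#' protocol: a seeded stratified holdout (default 50:50, the headline
#' protocol) or stratified k-fold cross-validation (k = 10 by
#' default), in which case metrics are averaged over folds and
#' confusions summed. AUC is the macro one-vs-rest area computed from
#' the predicted class scores.
#'
#' @param features Feature matrix (n x d).
#' @param labels Integer labels 0..K-1.
#' @param spec A [make_classifier_preset()] spec.
#' @param protocol `list(holdout = ratio)` or `list(k_folds = k)`.
#' @param seed Integer seed for splits and weight initialization.
#' @return A `metrics_report` with `auc` and `wall_time_s` filled.
#' @export
evaluate_classifier <- function(features, labels, spec,
                                protocol = list(holdout = 0.5),
                                seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  K <- max(labels) + 1L
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(protocol$holdout)) {
    tr <- stratified_train_indices(labels, protocol$holdout,
                                   substream_seed(seed, 21L))
    te <- setdiff(seq_len(nrow(features)), tr)
    model <- mlp_fit(features[tr, , drop = FALSE], labels[tr], K,
                     spec$hidden_layout, spec$max_iterations,
                     seed = substream_seed(seed, 22L))
    pred <- mlp_predict(model, features[te, , drop = FALSE])
    rep <- compute_metrics(confusion_from(labels[te], pred$class, K))
    rep$auc <- auc_macro_ovr(pred$probs, labels[te])
  } else if (!is.null(protocol$k_folds)) {
    k <- protocol$k_folds
    ids <- stratified_fold_ids(labels, k, substream_seed(seed, 21L))
    fold_reports <- list()
    conf <- matrix(0L, K, K)
    for (f in seq_len(k)) {
      te <- which(ids == f); tr <- which(ids != f)
      if (length(te) == 0) next
      model <- mlp_fit(features[tr, , drop = FALSE], labels[tr], K,
                       spec$hidden_layout, spec$max_iterations,
                       seed = substream_seed(seed, 22L + f))
      pred <- mlp_predict(model, features[te, , drop = FALSE])
      cf <- confusion_from(labels[te], pred$class, K)
      conf <- conf + cf
      fr <- compute_metrics(cf)
      fr$auc <- auc_macro_ovr(pred$probs, labels[te])
      fold_reports[[f]] <- fr
    }
    fold_reports <- Filter(Negate(is.null), fold_reports)
    rep <- compute_metrics(conf)
    for (field in c("accuracy", "sensitivity", "fnr", "precision", "auc")) {
      rep[[field]] <- mean(vapply(fold_reports, `[[`, 0, field),
                           na.rm = TRUE)
    }
  } else {
    stop("protocol must specify holdout or k_folds")
  }
  rep$wall_time_s <- proc.time()[["elapsed"]] - t0
  rep
}
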