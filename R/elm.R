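# Extreme learning machine: a single hidden layer of fixed random
# Gaussian projections with sigmoid activation; output weights solved
# in closed form by ridge-regularized least squares on one-hot targets.

#' Fit an extreme learning machine
#'
#' @param x Feature matrix (n x d).
#' @param y Integer labels 0..K-1.
#' @param n_classes Number of classes K.
#' @param hidden Hidden-layer width.
#' @param ridge Ridge regularization added to the normal equations for
#'   conditioning.
#' @param seed Integer seed for the random hidden projection.
#' @return A list of class `elm_model`.
#' @export
elm_train <- function(x, y, n_classes = length(unique(y)), hidden = 100L,
                      ridge = 1e-6, seed = 1L) {
  x <- as.matrix(x)
  d <- ncol(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd); sdv[sdv < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  with_seed(seed, {
    w <- matrix(stats::rnorm(d * hidden), d, hidden) / sqrt(d)
    b <- stats::runif(hidden, -1, 1)
  })
  h <- sigmoid(sweep(xs %*% w, 2, b, "+"))
  ty <- one_hot(y, n_classes)
  beta <- solve(crossprod(h) + diag(ridge, hidden), crossprod(h, ty))
  structure(list(w = w, b = b, beta = beta, mu = mu, sd = sdv,
                 n_classes = n_classes),
            class = "elm_model")
}

#' @rdname elm_train
#' @param model A fitted `elm_model`.
#' @param newx Feature matrix to score.
#' @return `elm_predict` returns a list with `class` (0-based labels)
#'   and `scores` (n x K).
#' @export
elm_predict <- function(model, newx) {
  xs <- sweep(sweep(as.matrix(newx), 2, model$mu), 2, model$sd, "/")
  h <- sigmoid(sweep(xs %*% model$w, 2, model$b, "+"))
  scores <- h %*% model$beta
  list(class = max.col(scores, ties.method = "first") - 1L,
       scores = scores)
}

#' ELM hold-out accuracy of a feature subset
#'
#' The wrapper fitness: masks the feature columns, makes a seeded
#' stratified 70:30 split, fits an ELM on the training portion, and
#' returns hold-out accuracy. Fully deterministic given the seed.
#'
#' @param features Feature matrix (n x d).
#' @param labels Integer labels 0..K-1 (at least two classes present).
#' @param mask Logical (or 0/1) vector of length d selecting >= 1
#'   column.
#' @param hidden Hidden-layer width.
#' @param seed Integer seed controlling both the split and the random
#'   projection.
#' @param ridge Ridge regularization constant.
#' @param train_ratio Training fraction of the stratified split.
#' @return Hold-out accuracy in [0, 1].
#' @export
elm_fitness <- function(features, labels, mask, hidden = 100L, seed = 1L,
                        ridge = 1e-6, train_ratio = 0.7) {
  mask <- as.logical(mask)
  if (length(mask) != ncol(features)) stop("mask length != feature count")
  if (!any(mask)) stop("mask selects no columns")
  if (length(unique(labels)) < 2) stop("need at least two classes")
  x <- features[, mask, drop = FALSE]
  K <- max(labels) + 1L
  tr <- stratified_train_indices(labels, train_ratio,
                                 substream_seed(seed, 101L))
  te <- setdiff(seq_len(nrow(x)), tr)
  model <- elm_train(x[tr, , drop = FALSE], labels[tr], K, hidden,
                     ridge, substream_seed(seed, 102L))
  pred <- elm_predict(model, x[te, , drop = FALSE])
  mean(pred$class == labels[te])
}
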