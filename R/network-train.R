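# Parameter initialization, forward/backward passes over the layer
# DAG, SGDM/Adam optimizers, and the training drivers for the two
# architectures.

#' Training configuration
#'
#' Bundles the optimizer settings used to train either network. The
#' defaults mirror the study configuration: stochastic gradient descent
#' with momentum, 100 epochs, minibatch 256, initial learning rate
#' 0.001, 10 folds and a 50:50 train/test split; the autoencoder stack
#' constants default to L2 weight penalties 0.004/0.002, sparsity
#' regularization 4 and sparsity proportions 0.15/0.10 for the two
#' dense bottleneck stacks, each pretrained for 5 epochs.
#'
#' @param optimizer `"sgdm"` or `"adam"`.
#' @param max_epochs,minibatch,learning_rate,momentum Optimization
#'   settings; momentum applies to sgdm only.
#' @param l2_weight L2 weight-decay coefficient for joint training.
#' @param sparsity_reg,sparsity_prop Sparsity (KL) penalty weight and
#'   target mean activation for autoencoder bottlenecks.
#' @param folds,split_ratio Evaluation protocol defaults carried with
#'   the config.
#' @param stack_epochs,stack_l2,stack_sparsity_prop Greedy pretraining
#'   settings per bottleneck stack.
#' @return A list of class `train_config`.
#' @export
train_config <- function(optimizer = c("sgdm", "adam"), max_epochs = 100L,
                         minibatch = 256L, learning_rate = 0.001,
                         momentum = 0.9, l2_weight = 0,
                         sparsity_reg = 4, sparsity_prop = 0.15,
                         folds = 10L, split_ratio = 0.5,
                         stack_epochs = 5L, stack_l2 = c(0.004, 0.002),
                         stack_sparsity_prop = c(0.15, 0.10)) {
  optimizer <- match.arg(optimizer)
  stopifnot(max_epochs >= 1, minibatch >= 2, learning_rate > 0,
            momentum >= 0, momentum <= 1, l2_weight >= 0,
            sparsity_reg >= 0, sparsity_prop > 0, sparsity_prop < 1,
            folds >= 2, split_ratio > 0, split_ratio < 1)
  structure(list(optimizer = optimizer, max_epochs = as.integer(max_epochs),
                 minibatch = as.integer(minibatch),
                 learning_rate = learning_rate, momentum = momentum,
                 l2_weight = l2_weight, sparsity_reg = sparsity_reg,
                 sparsity_prop = sparsity_prop, folds = as.integer(folds),
                 split_ratio = split_ratio,
                 stack_epochs = as.integer(stack_epochs),
                 stack_l2 = stack_l2,
                 stack_sparsity_prop = stack_sparsity_prop),
            class = "train_config")
}

init_params <- function(spec, seed) {
  shapes <- infer_shapes(spec)
  params <- list(); bn_state <- list()
  with_seed(seed, {
    prev <- ".input"
    for (ly in spec$layers) {
      ins <- ly$input %||% prev
      s <- shapes[[ins[1]]]
      if (ly$kind == "conv") {
        fan_in <- prod(ly$kernel) * s[3]
        w <- array(stats::rnorm(prod(ly$kernel) * s[3] * ly$out_channels,
                                sd = sqrt(2 / fan_in)),
                   c(ly$kernel[1], ly$kernel[2], s[3], ly$out_channels))
        params[[ly$name]] <- list(w = w, b = numeric(ly$out_channels))
      } else if (ly$kind == "dense") {
        w <- matrix(stats::rnorm(s[1] * ly$units, sd = sqrt(2 / s[1])),
                    s[1], ly$units)
        params[[ly$name]] <- list(w = w, b = numeric(ly$units))
      } else if (ly$kind == "batchnorm") {
        params[[ly$name]] <- list(gamma = rep(1, s[3]), beta = rep(0, s[3]))
        bn_state[[ly$name]] <- list(running_mean = rep(0, s[3]),
                                    running_var = rep(1, s[3]))
      }
      prev <- ly$name
    }
  })
  list(params = params, bn_state = bn_state)
}

# Forward pass. Returns per-layer outputs, caches for backward, and the
# (possibly updated) batch-norm state.
forward_network <- function(spec, params, bn_state, x, train = FALSE,
                            upto = NULL) {
  outs <- list(.input = x); caches <- list()
  prev <- ".input"
  for (ly in spec$layers) {
    ins <- ly$input %||% prev
    xin <- outs[[ins[1]]]
    nm <- ly$name
    if (ly$kind == "conv") {
      r <- conv_forward(xin, params[[nm]]$w, params[[nm]]$b,
                        ly$stride, ly$pad)
      outs[[nm]] <- r$out; caches[[nm]] <- r$cache
    } else if (ly$kind == "batchnorm") {
      r <- bn_forward(xin, params[[nm]]$gamma, params[[nm]]$beta,
                      bn_state[[nm]], train)
      outs[[nm]] <- r$out; caches[[nm]] <- r$cache
      bn_state[[nm]] <- r$state
    } else if (ly$kind == "relu") {
      outs[[nm]] <- pmax(xin, 0); caches[[nm]] <- NULL
    } else if (ly$kind == "sigmoid") {
      outs[[nm]] <- 1 / (1 + exp(-xin))
    } else if (ly$kind == "add") {
      outs[[nm]] <- xin + outs[[ins[2]]]
    } else if (ly$kind == "maxpool") {
      r <- maxpool_forward(xin, ly$kernel[1], ly$stride, ly$pad)
      outs[[nm]] <- r$out; caches[[nm]] <- r$cache
    } else if (ly$kind == "gap") {
      r <- gap_forward(xin)
      outs[[nm]] <- r$out; caches[[nm]] <- r$cache
    } else if (ly$kind == "flatten") {
      d <- dim(xin)
      outs[[nm]] <- t(matrix(xin, prod(d[1:3]), d[4]))
      caches[[nm]] <- d
    } else if (ly$kind == "dense") {
      r <- dense_forward(xin, params[[nm]]$w, params[[nm]]$b)
      outs[[nm]] <- r$out; caches[[nm]] <- r$cache
    } else if (ly$kind == "softmax") {
      outs[[nm]] <- softmax_rows(xin)
    } else if (ly$kind == "upsample") {
      r <- upsample_forward(xin)
      outs[[nm]] <- r$out; caches[[nm]] <- r$cache
    } else if (ly$kind == "reshape") {
      ts <- ly$target_shape
      outs[[nm]] <- array(t(xin), c(ts[1], ts[2], ts[3], nrow(xin)))
      caches[[nm]] <- c(ts, nrow(xin))
    } else {
      stop("unknown layer kind: ", ly$kind)
    }
    prev <- nm
    if (!is.null(upto) && nm == upto) break
  }
  list(outs = outs, caches = caches, bn_state = bn_state)
}

# Backward pass seeded with gradient `dseed` at layer `seed_layer`.
# Returns parameter gradients and (optionally) activation gradients at
# requested layers.
backward_network <- function(spec, params, outs, caches, seed_layer,
                             dseed, want_activation_grads = character()) {
  nms <- names(spec$layers)
  seed_pos <- match(seed_layer, nms)
  if (is.na(seed_pos)) stop("unknown seed layer: ", seed_layer)
  grad_acc <- list(); pgrads <- list()
  grad_acc[[seed_layer]] <- dseed
  add_grad <- function(nm, g) {
    grad_acc[[nm]] <<- if (is.null(grad_acc[[nm]])) g else grad_acc[[nm]] + g
  }
  for (i in seq.int(seed_pos, 1L)) {
    ly <- spec$layers[[i]]
    nm <- ly$name
    g <- grad_acc[[nm]]
    if (is.null(g)) next
    ins <- ly$input %||% (if (i > 1L) nms[i - 1L] else ".input")
    if (ly$kind == "conv") {
      r <- conv_backward(g, params[[nm]]$w, ly$stride, ly$pad, caches[[nm]])
      pgrads[[nm]] <- list(w = r$dw, b = r$db)
      add_grad(ins[1], r$dx)
    } else if (ly$kind == "batchnorm") {
      r <- bn_backward(g, params[[nm]]$gamma, caches[[nm]])
      pgrads[[nm]] <- list(gamma = r$dgamma, beta = r$dbeta)
      add_grad(ins[1], r$dx)
    } else if (ly$kind == "relu") {
      add_grad(ins[1], g * (outs[[nm]] > 0))
    } else if (ly$kind == "sigmoid") {
      s <- outs[[nm]]
      add_grad(ins[1], g * s * (1 - s))
    } else if (ly$kind == "add") {
      add_grad(ins[1], g); add_grad(ins[2], g)
    } else if (ly$kind == "maxpool") {
      add_grad(ins[1], maxpool_backward(g, caches[[nm]]))
    } else if (ly$kind == "gap") {
      add_grad(ins[1], gap_backward(g, caches[[nm]]))
    } else if (ly$kind == "flatten") {
      d <- caches[[nm]]
      add_grad(ins[1], array(t(g), d))
    } else if (ly$kind == "dense") {
      r <- dense_backward(g, params[[nm]]$w, caches[[nm]])
      pgrads[[nm]] <- list(w = r$dw, b = r$db)
      add_grad(ins[1], r$dx)
    } else if (ly$kind == "upsample") {
      add_grad(ins[1], upsample_backward(g, caches[[nm]]))
    } else if (ly$kind == "reshape") {
      d <- caches[[nm]]
      add_grad(ins[1], t(matrix(g, prod(d[1:3]), d[4])))
    } else if (ly$kind == "softmax") {
      stop("backward through softmax is not used; seed at the logits")
    }
    if (!(nm %in% want_activation_grads)) grad_acc[[nm]] <- NULL
  }
  list(param_grads = pgrads,
       activation_grads = grad_acc[want_activation_grads])
}

new_opt_state <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

opt_step <- function(params, grads, state, cfg, t) {
  lr <- cfg$learning_rate
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      if (cfg$optimizer == "sgdm") {
        v <- cfg$momentum * state$v[[nm]][[pn]] + g
        state$v[[nm]][[pn]] <- v
        params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * v
      } else {
        m <- 0.9 * state$m[[nm]][[pn]] + 0.1 * g
        v <- 0.999 * state$v[[nm]][[pn]] + 0.001 * g^2
        state$m[[nm]][[pn]] <- m; state$v[[nm]][[pn]] <- v
        mh <- m / (1 - 0.9^t); vh <- v / (1 - 0.999^t)
        params[[nm]][[pn]] <- params[[nm]][[pn]] -
          lr * mh / (sqrt(vh) + 1e-8)
      }
    }
  }
  list(params = params, state = state)
}

# Add L2 weight-decay gradients (weights only, never biases or BN).
add_l2_grads <- function(pgrads, params, spec, l2) {
  if (l2 == 0) return(pgrads)
  for (nm in names(pgrads)) {
    if (spec$layers[[nm]]$kind %in% c("conv", "dense")) {
      pgrads[[nm]]$w <- pgrads[[nm]]$w + 2 * l2 * params[[nm]]$w
    }
  }
  pgrads
}

#' Forward map of one autoencoder layer
#'
#' Applies `act(weights %*% input + bias)`: the encoding map of a
#' layer, or — with the decoder's weights and activation — its decoding
#' map.
#'
#' @param input Numeric vector.
#' @param weights Weight matrix (output x input).
#' @param bias Bias vector (length = output width).
#' @param activation `"linear"`, `"sigmoid"`, or `"relu"`.
#' @return The activated output vector.
#' @export
sae_layer_forward <- function(input, weights, bias,
                              activation = c("linear", "sigmoid", "relu")) {
  activation <- match.arg(activation)
  if (ncol(weights) != length(input) || nrow(weights) != length(bias)) {
    stop("shape mismatch between input, weights, and bias")
  }
  z <- as.numeric(weights %*% input + bias)
  switch(activation, linear = z, sigmoid = sigmoid(z), relu = relu(z))
}

#' Autoencoder reconstruction loss
#'
#' Computes the autoencoder objective: half the mean (per sample)
#' squared reconstruction error, `(1 / (2N)) * ||I - dOUT||^2` with `N`
#' the batch size, plus an L2 penalty on the supplied weights and a
#' KL-divergence sparsity penalty pulling the mean hidden activation
#' toward `sparsity_prop`. With both regularizers at zero it is exactly
#' the plain reconstruction term.
#'
#' @param inputs,reconstructions Equal-shaped numeric arrays; rows (or
#'   the last array dimension) index the N samples.
#' @param weights Optional list of weight arrays entering the L2 term.
#' @param hidden_mean Optional vector of mean hidden-unit activations
#'   (in (0,1)) entering the sparsity term.
#' @param l2_weight,sparsity_reg,sparsity_prop Regularization constants.
#' @return Non-negative scalar loss.
#' @export
sae_loss <- function(inputs, reconstructions, weights = NULL,
                     hidden_mean = NULL, l2_weight = 0, sparsity_reg = 0,
                     sparsity_prop = 0.15) {
  if (!identical(dim(inputs) %||% length(inputs),
                 dim(reconstructions) %||% length(reconstructions))) {
    stop("inputs and reconstructions must have identical shape")
  }
  n <- if (is.matrix(inputs)) nrow(inputs)
       else if (is.array(inputs)) dim(inputs)[length(dim(inputs))]
       else 1L
  loss <- sum((inputs - reconstructions)^2) / (2 * n)
  if (l2_weight > 0 && !is.null(weights)) {
    loss <- loss + l2_weight * sum(vapply(weights,
                                          function(w) sum(w^2), 0))
  }
  if (sparsity_reg > 0 && !is.null(hidden_mean)) {
    rho <- sparsity_prop; rh <- pmin(pmax(hidden_mean, 1e-8), 1 - 1e-8)
    loss <- loss + sparsity_reg *
      sum(rho * log(rho / rh) + (1 - rho) * log((1 - rho) / (1 - rh)))
  }
  loss
}

# Greedy pretraining of one dense sparse-autoencoder stack: sigmoid
# hidden layer, linear decoder, trained by Adam on the composite loss.
pretrain_dense_stack <- function(z, hidden, l2, sparsity_reg,
                                 sparsity_prop, epochs, lr, seed) {
  n <- nrow(z); d <- ncol(z)
  with_seed(seed, {
    w1 <- matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden)
    b1 <- numeric(hidden)
    w2 <- matrix(stats::rnorm(hidden * d, sd = sqrt(2 / hidden)), hidden, d)
    b2 <- numeric(d)
  })
  ms <- list(w1 = w1 * 0, b1 = b1 * 0, w2 = w2 * 0, b2 = b2 * 0)
  vs <- ms
  steps <- max(20L, epochs * 20L)
  for (t in seq_len(steps)) {
    h <- sigmoid(sweep(z %*% w1, 2, b1, "+"))
    recon <- sweep(h %*% w2, 2, b2, "+")
    rho_hat <- pmin(pmax(colMeans(h), 1e-8), 1 - 1e-8)
    dr <- (recon - z) / n
    dw2 <- crossprod(h, dr) + 2 * l2 * w2
    db2 <- colSums(dr)
    dh <- tcrossprod(dr, w2)
    dkl <- sparsity_reg *
      (-sparsity_prop / rho_hat + (1 - sparsity_prop) / (1 - rho_hat)) / n
    dz1 <- (sweep(dh, 2, dkl, "+")) * h * (1 - h)
    dw1 <- crossprod(z, dz1) + 2 * l2 * w1
    db1 <- colSums(dz1)
    gs <- list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2)
    ps <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
    for (pn in names(gs)) {
      ms[[pn]] <- 0.9 * ms[[pn]] + 0.1 * gs[[pn]]
      vs[[pn]] <- 0.999 * vs[[pn]] + 0.001 * gs[[pn]]^2
      ps[[pn]] <- ps[[pn]] - lr * (ms[[pn]] / (1 - 0.9^t)) /
        (sqrt(vs[[pn]] / (1 - 0.999^t)) + 1e-8)
    }
    w1 <- ps$w1; b1 <- ps$b1; w2 <- ps$w2; b2 <- ps$b2
  }
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
       code = sigmoid(sweep(z %*% w1, 2, b1, "+")))
}

#' Train a network
#'
#' Dispatches on the specification type. The ResNet variant is trained
#' by minimizing softmax cross-entropy with the configured optimizer.
#' The stacked autoencoder is trained greedily first — each dense
#' bottleneck stack is pretrained as a sparse autoencoder (sigmoid
#' hidden units, KL sparsity penalty, per-stack L2 constants) on the
#' codes of the previous stage — and then fine-tuned jointly on the
#' reconstruction objective. Training history is recorded per epoch and
#' a non-finite loss aborts with a diagnostic.
#'
#' @param spec A `network_spec`.
#' @param data An `image_dataset` (images + labels; labels are ignored
#'   for the autoencoder).
#' @param cfg A [train_config()].
#' @param seed Integer seed; identical seeds give identical training
#'   trajectories.
#' @return A list of class `trained_network` with `spec`, `params`,
#'   `bn_state`, `history`, `config`, `seed`.
#' @export
train_network <- function(spec, data, cfg = train_config(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  x <- data$images
  n <- dim(x)[4]
  if (n < 2) stop("need at least 2 samples")
  ini <- init_params(spec, substream_seed(seed, 1L))
  params <- ini$params; bn_state <- ini$bn_state
  if (spec$type == "resnet_classifier") {
    y <- data$labels
    if (min(table(y)) < 2) stop("need >= 2 samples per class")
    res <- train_classifier_loop(spec, params, bn_state, x, y, cfg, seed)
  } else if (spec$type == "stacked_autoencoder") {
    res <- train_autoencoder_loop(spec, params, bn_state, x, cfg, seed)
  } else {
    stop("unknown network type: ", spec$type)
  }
  structure(list(spec = spec, params = res$params,
                 bn_state = res$bn_state, history = res$history,
                 config = cfg, seed = seed),
            class = "trained_network")
}

train_classifier_loop <- function(spec, params, bn_state, x, y, cfg, seed) {
  n <- dim(x)[4]
  K <- spec$n_classes
  y1h <- one_hot(y, K)
  state <- list(v = new_opt_state(params), m = new_opt_state(params))
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  t <- 0L
  with_seed(substream_seed(seed, 2L), {
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = cfg$minibatch)) {
        idx <- ord[start:min(start + cfg$minibatch - 1L, n)]
        if (length(idx) < 2L) next  # batch norm needs >= 2 samples
        xb <- x[, , , idx, drop = FALSE]
        fw <- forward_network(spec, params, bn_state, xb, train = TRUE,
                              upto = "fc")
        bn_state <- fw$bn_state
        logits <- fw$outs$fc
        probs <- softmax_rows(logits)
        pt <- probs[cbind(seq_along(idx), y[idx] + 1L)]
        loss <- -mean(log(pmax(pt, 1e-12)))
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", ep)
        }
        ep_loss <- ep_loss + loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(probs) == y[idx] + 1L)
        dlogits <- (probs - y1h[idx, , drop = FALSE]) / length(idx)
        bw <- backward_network(spec, params, fw$outs, fw$caches, "fc",
                               dlogits)
        pg <- add_l2_grads(bw$param_grads, params, spec, cfg$l2_weight)
        t <- t + 1L
        upd <- opt_step(params, pg, state, cfg, t)
        params <- upd$params; state <- upd$state
      }
      history <- rbind(history, data.frame(
        epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n))
    }
  })
  list(params = params, bn_state = bn_state, history = history)
}

train_autoencoder_loop <- function(spec, params, bn_state, x, cfg, seed) {
  n <- dim(x)[4]
  # Greedy phase: pretrain the dense bottleneck stacks on the flattened
  # encoder codes.
  enc_out <- forward_network(spec, params, bn_state, x, train = FALSE,
                             upto = "enc_flatten")
  z <- enc_out$outs$enc_flatten
  stack_names <- grep("^code[0-9]+_dense$", names(spec$layers),
                      value = TRUE)
  dec_names <- rev(grep("^decode[0-9]+_dense$", names(spec$layers),
                        value = TRUE))
  for (i in seq_along(stack_names)) {
    l2_i <- cfg$stack_l2[min(i, length(cfg$stack_l2))]
    sp_i <- cfg$stack_sparsity_prop[min(i, length(cfg$stack_sparsity_prop))]
    pt <- pretrain_dense_stack(z, spec$layers[[stack_names[i]]]$units,
                               l2_i, cfg$sparsity_reg, sp_i,
                               cfg$stack_epochs, 0.005,
                               substream_seed(seed, 10L + i))
    params[[stack_names[i]]] <- list(w = pt$w1, b = pt$b1)
    params[[dec_names[i]]] <- list(w = pt$w2, b = pt$b2)
    z <- pt$code
  }
  # Joint fine-tuning on the reconstruction objective.
  state <- list(v = new_opt_state(params), m = new_opt_state(params))
  history <- data.frame(epoch = integer(), loss = numeric())
  t <- 0L
  last <- names(spec$layers)[length(spec$layers)]
  with_seed(substream_seed(seed, 3L), {
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      for (start in seq(1, n, by = cfg$minibatch)) {
        idx <- ord[start:min(start + cfg$minibatch - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        fw <- forward_network(spec, params, bn_state, xb, train = TRUE)
        bn_state <- fw$bn_state
        recon <- fw$outs[[last]]
        loss <- sum((xb - recon)^2) / (2 * length(idx))
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", ep)
        }
        ep_loss <- ep_loss + loss * length(idx)
        drecon <- (recon - xb) / length(idx)
        # seed backward through the output sigmoid
        s <- recon
        dsig <- drecon * s * (1 - s)
        bw <- backward_network(spec, params, fw$outs, fw$caches,
                               "recon_conv", dsig)
        pg <- add_l2_grads(bw$param_grads, params, spec, cfg$l2_weight)
        t <- t + 1L
        upd <- opt_step(params, pg, state, cfg, t)
        params <- upd$params; state <- upd$state
      }
      history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n))
    }
  })
  list(params = params, bn_state = bn_state, history = history)
}

#' Predict class probabilities from a trained classifier network
#'
#' @param model A `trained_network` of the ResNet variant.
#' @param images H x W x C x N array.
#' @param batch Evaluation minibatch size.
#' @return N x K matrix of softmax probabilities.
#' @export
predict_network <- function(model, images, batch = 32L) {
  n <- dim(images)[4]
  out <- NULL
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- forward_network(model$spec, model$params, model$bn_state,
                          images[, , , idx, drop = FALSE], train = FALSE)
    out <- rbind(out, fw$outs$softmax)
  }
  out
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf("<trained_network: %s> %d epochs, final loss %.4f\n",
              x$spec$type, nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}
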