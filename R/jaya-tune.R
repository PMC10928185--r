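# Jaya-driven hyperparameter initialization: candidates live in the
# unit hypercube, move toward the best and away from the worst
# configuration, and are decoded per dimension.

#' Describe a hyperparameter search space
#'
#' @param params Named list of dimensions, each created by
#'   [param_continuous()] or [param_choice()].
#' @param population,iterations Search budget (population >= 2,
#'   iterations >= 1).
#' @return A list of class `hyperparam_space`.
#' @export
hyperparam_space <- function(params, population = 6L, iterations = 10L) {
  stopifnot(length(params) >= 1, population >= 2, iterations >= 1)
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    stop("every dimension must be named")
  }
  structure(list(params = params, population = as.integer(population),
                 iterations = as.integer(iterations)),
            class = "hyperparam_space")
}

#' @rdname hyperparam_space
#' @param lo,hi Ordered bounds of a continuous dimension.
#' @param log Interpolate on the log scale (for scale parameters such
#'   as learning rates).
#' @export
param_continuous <- function(lo, hi, log = FALSE) {
  stopifnot(lo < hi, !log || lo > 0)
  list(type = "continuous", lo = lo, hi = hi, log = log)
}

#' @rdname hyperparam_space
#' @param values Non-empty choice set of a categorical/integer
#'   dimension.
#' @export
param_choice <- function(values) {
  stopifnot(length(values) >= 1)
  list(type = "choice", values = values)
}

#' Default search space for the CNN training configuration
#'
#' Brackets the study's training configuration: optimizer in
#' {sgdm, adam}, learning rate log-uniform on [1e-4, 1e-2], momentum on
#' [0.8, 0.99], minibatch in {32, 64, 128, 256}.
#'
#' @param population,iterations Search budget.
#' @export
default_resnet_space <- function(population = 6L, iterations = 10L) {
  hyperparam_space(list(
    optimizer = param_choice(c("sgdm", "adam")),
    learning_rate = param_continuous(1e-4, 1e-2, log = TRUE),
    momentum = param_continuous(0.8, 0.99),
    minibatch = param_choice(c(32L, 64L, 128L, 256L))
  ), population = population, iterations = iterations)
}

decode_position <- function(space, u) {
  cfg <- list()
  for (i in seq_along(space$params)) {
    p <- space$params[[i]]
    cfg[[names(space$params)[i]]] <- if (p$type == "continuous") {
      if (p$log) exp(log(p$lo) + u[i] * (log(p$hi) - log(p$lo)))
      else p$lo + u[i] * (p$hi - p$lo)
    } else {
      k <- length(p$values)
      p$values[[min(k, 1L + floor(u[i] * k))]]
    }
  }
  cfg
}

#' Tune hyperparameters with the Jaya update
#'
#' Maintains a population of candidate configurations encoded in
#' [0,1] per dimension, scores each decoded configuration with
#' `eval_fn` (higher is better), and updates every candidate toward the
#' population's best and away from its worst configuration, accepting a
#' move only when it improves the score.
#'
#' @param space A [hyperparam_space()].
#' @param eval_fn Function taking a decoded configuration (named list)
#'   and returning a finite scalar score to maximize.
#' @param seed Integer seed.
#' @return List with `config` (best decoded configuration), `score`,
#'   `trace` (best score per iteration, including the initial
#'   population), and `n_evaluations`.
#' @export
tune_hyperparameters_jaya <- function(space, eval_fn, seed = 1L) {
  stopifnot(inherits(space, "hyperparam_space"))
  d <- length(space$params); pop <- space$population
  evals <- 0L
  score_of <- function(u) {
    s <- eval_fn(decode_position(space, u))
    evals <<- evals + 1L
    if (!is.finite(s)) stop("eval_fn returned a non-finite score")
    s
  }
  with_seed(seed, {
    U <- matrix(stats::runif(pop * d), pop, d)
    fit <- apply(U, 1, score_of)
    trace <- max(fit)
    for (it in seq_len(space$iterations)) {
      best <- U[which.max(fit), ]; worst <- U[which.min(fit), ]
      for (m in seq_len(pop)) {
        prop <- jaya_update(U[m, ], best, worst,
                            stats::runif(d), stats::runif(d))
        s <- score_of(prop)
        if (s > fit[m]) { U[m, ] <- prop; fit[m] <- s }
      }
      trace <- c(trace, max(fit))
    }
    b <- which.max(fit)
    list(config = decode_position(space, U[b, ]), score = fit[b],
         trace = trace, n_evaluations = evals)
  })
}
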