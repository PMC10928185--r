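# Hybrid wrapper feature selection: a Grey Wolf Optimization phase in
# which candidate masks (wolves) move toward the three best solutions,
# followed by a Jaya refinement phase that moves candidates toward the
# best and away from the worst solution with greedy acceptance.

#' Grey wolf coefficient vectors
#'
#' Computes the encircling coefficients from the decaying control
#' scalar `g` and two uniform random vectors: `M = 2 g h1 - g`
#' (componentwise in `[-g, g]`) and `B = 2 h2` (in `[0, 2]`).
#'
#' @param g Control scalar in [0, 2], decaying linearly over
#'   iterations.
#' @param h1,h2 Uniform random vectors in [0, 1].
#' @return List with vectors `M` and `B`.
#' @export
gwo_coefficients <- function(g, h1, h2) {
  stopifnot(g >= 0, g <= 2, length(h1) == length(h2))
  list(M = 2 * g * h1 - g, B = 2 * h2)
}

#' Grey wolf position update
#'
#' Moves one wolf toward the three pack leaders: for each leader
#' `Z_l`, the encircling distance is `L_l = |B_l * Z_l - Z|` and the
#' pulled position is `Z_l - M_l * L_l`; the new position is the mean
#' of the three pulled positions, clipped to the unit hypercube.
#'
#' @param z Current position vector in [0,1]^d.
#' @param z_alpha,z_beta,z_delta Leader positions (best three).
#' @param g Control scalar in [0, 2].
#' @param draws Optional list of three `list(h1=, h2=)` random draws
#'   (one per leader); fresh uniforms are drawn when omitted.
#' @return The updated position, clipped to [0, 1].
#' @export
gwo_update_position <- function(z, z_alpha, z_beta, z_delta, g,
                                draws = NULL) {
  d <- length(z)
  leaders <- list(z_alpha, z_beta, z_delta)
  if (any(vapply(leaders, length, 0L) != d)) {
    stop("dimension mismatch between wolf and leaders")
  }
  if (is.null(draws)) {
    draws <- lapply(1:3, function(i) list(h1 = stats::runif(d),
                                          h2 = stats::runif(d)))
  }
  pulled <- vapply(1:3, function(i) {
    co <- gwo_coefficients(g, draws[[i]]$h1, draws[[i]]$h2)
    l <- abs(co$B * leaders[[i]] - z)
    leaders[[i]] - co$M * l
  }, numeric(d))
  clip01(rowMeans(matrix(pulled, nrow = d)))
}

#' Jaya position update
#'
#' Moves a candidate toward the best and away from the worst solution:
#' `X' = X + r1 (X_best - |X|) - r2 (X_worst - |X|)`, clipped to the
#' unit hypercube.
#'
#' @param x Candidate position vector.
#' @param x_best,x_worst Best and worst positions in the population.
#' @param r1,r2 Uniform random vectors in [0, 1].
#' @return The updated position, clipped to [0, 1].
#' @export
jaya_update <- function(x, x_best, x_worst, r1 = stats::runif(length(x)),
                        r2 = stats::runif(length(x))) {
  if (length(x_best) != length(x) || length(x_worst) != length(x) ||
      length(r1) != length(x) || length(r2) != length(x)) {
    stop("dimension mismatch in jaya update")
  }
  clip01(x + r1 * (x_best - abs(x)) - r2 * (x_worst - abs(x)))
}

binarize_position <- function(z, threshold = 0.5) {
  mask <- z > threshold
  if (!any(mask)) mask[which.max(z)] <- TRUE  # guarantee >= 1 column
  mask
}

# Default wrapper fitness: binarize the position and score the masked
# columns with the ELM hold-out accuracy; memoized on the mask.
make_mask_fitness <- function(features, labels, hidden, ridge, seed,
                              threshold = 0.5) {
  cache <- new.env(parent = emptyenv())
  function(z) {
    mask <- binarize_position(z, threshold)
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- elm_fitness(features, labels, mask, hidden = hidden,
                     seed = seed, ridge = ridge)
    cache[[key]] <- f
    f
  }
}

#' Grey Wolf Optimization phase
#'
#' Runs the GWO search over positions in the unit hypercube. The
#' default fitness binarizes each wolf at threshold 0.5 and scores the
#' selected feature columns with ELM hold-out accuracy; a custom
#' `fitness_fn` (taking the continuous position, returning a finite
#' score to maximize) replaces it, in which case `features`/`labels`
#' may be `NULL`. The control scalar decays linearly from 2 to 0
#' across iterations.
#'
#' @param features Feature matrix (n x d), or `NULL` with a custom
#'   fitness.
#' @param labels Integer labels 0..K-1, or `NULL`.
#' @param population Pack size (>= 3, defaults to the study's 50).
#' @param iterations GWO iterations (defaults to the study's 200).
#' @param fitness_fn Optional custom fitness on positions.
#' @param seed Integer seed.
#' @param dim Search dimension; defaults to `ncol(features)`.
#' @param hidden,ridge ELM settings for the default fitness.
#' @return A list of class `wolf_pack`: `positions`, `fitness`,
#'   `leaders` (indices of alpha/beta/delta), `best_position`,
#'   `best_fitness`, `trace` (best-so-far per iteration, the first
#'   entry being the initial population), `g_final`.
#' @export
gwo_select <- function(features = NULL, labels = NULL, population = 50L,
                       iterations = 200L, fitness_fn = NULL, seed = 1L,
                       dim = if (!is.null(features)) ncol(features) else NULL,
                       hidden = 100L, ridge = 1e-6) {
  if (population < 3) stop("population must be >= 3 (alpha/beta/delta)")
  if (is.null(dim) || dim < 2) stop("need at least 2 search dimensions")
  if (is.null(fitness_fn)) {
    if (is.null(features) || is.null(labels)) {
      stop("features and labels are required for the default fitness")
    }
    fitness_fn <- make_mask_fitness(features, labels, hidden, ridge,
                                    substream_seed(seed, 7L))
  }
  with_seed(substream_seed(seed, 8L), {
    z <- matrix(stats::runif(population * dim), population, dim)
    fit <- apply(z, 1, fitness_fn)
    if (any(!is.finite(fit))) stop("non-finite fitness")
    best_i <- which.max(fit)
    best_position <- z[best_i, ]; best_fitness <- fit[best_i]
    trace <- best_fitness
    for (m in seq_len(max(iterations, 0L))) {
      g <- 2 * (1 - m / iterations)
      ord <- order(fit, decreasing = TRUE)  # ties: lower index wins
      lead <- ord[1:3]
      za <- z[lead[1], ]; zb <- z[lead[2], ]; zd <- z[lead[3], ]
      for (i in seq_len(population)) {
        z[i, ] <- gwo_update_position(z[i, ], za, zb, zd, g)
      }
      fit <- apply(z, 1, fitness_fn)
      if (any(!is.finite(fit))) stop("non-finite fitness")
      if (max(fit) > best_fitness) {
        best_i <- which.max(fit)
        best_fitness <- fit[best_i]; best_position <- z[best_i, ]
      }
      trace <- c(trace, best_fitness)
    }
    structure(list(positions = z, fitness = fit,
                   leaders = order(fit, decreasing = TRUE)[1:3],
                   best_position = best_position,
                   best_fitness = best_fitness, trace = trace,
                   g_final = if (iterations > 0) 0 else 2,
                   seed = seed),
              class = "wolf_pack")
  })
}

#' Selection budget and settings
#'
#' Defaults are the study's: 50 wolves, 200 GWO iterations, 100 Jaya
#' refinement iterations; ELM hidden width 100 and ridge 1e-6 for the
#' fitness; binarization threshold 0.5.
#'
#' @param population,gwo_iterations,jaya_iterations Search budget.
#' @param hidden,ridge ELM fitness settings.
#' @param threshold Position binarization threshold.
#' @export
selection_config <- function(population = 50L, gwo_iterations = 200L,
                             jaya_iterations = 100L, hidden = 100L,
                             ridge = 1e-6, threshold = 0.5) {
  stopifnot(population >= 3, gwo_iterations >= 0, jaya_iterations >= 0)
  structure(list(population = as.integer(population),
                 gwo_iterations = as.integer(gwo_iterations),
                 jaya_iterations = as.integer(jaya_iterations),
                 hidden = as.integer(hidden), ridge = ridge,
                 threshold = threshold),
            class = "selection_config")
}

#' Hybrid Grey Wolf + Jaya feature selection
#'
#' Phase 1 runs [gwo_select()]. Phase 2 refines the final pack for
#' `jaya_iterations` rounds: each candidate is moved toward the current
#' best and away from the current worst position with [jaya_update()],
#' re-scored, and accepted only on improvement, so the best-so-far
#' trace is non-decreasing. The best-ever position is binarized at the
#' threshold into the final feature mask (falling back to the single
#' largest component if the threshold selects nothing).
#'
#' @param features Feature matrix (n x d, d >= 2).
#' @param labels Integer labels 0..K-1.
#' @param config A [selection_config()].
#' @param seed Integer seed.
#' @return A list of class `selection_result`: `mask` (logical, named
#'   by feature columns when available), `n_selected`, `fitness_trace`
#'   (GWO then Jaya best-so-far), `best_position`, `best_fitness`,
#'   `phase_boundary` (index of the last GWO trace entry), `seed`.
#' @export
select_features <- function(features, labels, config = selection_config(),
                            seed = 1L) {
  features <- as.matrix(features)
  d <- ncol(features)
  if (d < 2) stop("need at least 2 features")
  fitness_fn <- make_mask_fitness(features, labels, config$hidden,
                                  config$ridge, substream_seed(seed, 7L),
                                  config$threshold)
  pack <- gwo_select(features, labels, population = config$population,
                     iterations = config$gwo_iterations,
                     fitness_fn = fitness_fn, seed = seed, dim = d)
  z <- pack$positions; fit <- pack$fitness
  best_position <- pack$best_position
  best_fitness <- pack$best_fitness
  trace <- pack$trace
  with_seed(substream_seed(seed, 9L), {
    for (j in seq_len(config$jaya_iterations)) {
      xb <- z[which.max(fit), ]; xw <- z[which.min(fit), ]
      for (i in seq_len(nrow(z))) {
        prop <- jaya_update(z[i, ], xb, xw)
        f <- fitness_fn(prop)
        if (f > fit[i]) { z[i, ] <- prop; fit[i] <- f }
      }
      if (max(fit) > best_fitness) {
        best_fitness <- max(fit)
        best_position <- z[which.max(fit), ]
      }
      trace <- c(trace, best_fitness)
    }
  })
  mask <- binarize_position(best_position, config$threshold)
  names(mask) <- colnames(features)
  structure(list(mask = mask, n_selected = sum(mask),
                 fitness_trace = trace, best_position = best_position,
                 best_fitness = best_fitness,
                 phase_boundary = length(pack$trace), seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d/%d features selected; best fitness %.4f\n",
    x$n_selected, length(x$mask), x$best_fitness))
  invisible(x)
}
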