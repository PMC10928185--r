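# Grey Wolf + Jaya wrapper feature selection with ELM fitness.

test_that("encircling coefficients stay in their defined ranges", {
  set.seed(1)
  for (i in 1:50) {
    g <- runif(1, 0, 2)
    co <- gwo_coefficients(g, runif(6), runif(6))
    expect_true(all(co$M >= -g - 1e-12 & co$M <= g + 1e-12))
    expect_true(all(co$B >= 0 & co$B <= 2))
  }
})

test_that("wolf update reproduces hand-evaluated encircling arithmetic", {
  # scalar case: M = 0.5, B = 1 for all three leaders
  draws <- rep(list(list(h1 = 0.75, h2 = 0.5)), 3)
  got <- gwo_update_position(0.2, 0.8, 0.6, 0.4, g = 1, draws = draws)
  expect_equal(got, 0.4, tolerance = 1e-12)
  # g = 0 makes M vanish: result is the leader centroid
  draws0 <- rep(list(list(h1 = runif(3), h2 = rep(0.5, 3))), 3)
  za <- c(0.9, 0.1, 0.5); zb <- c(0.3, 0.3, 0.3); zd <- c(0.6, 0.9, 0.1)
  got0 <- gwo_update_position(c(0.2, 0.2, 0.2), za, zb, zd, g = 0,
                              draws = draws0)
  expect_equal(got0, (za + zb + zd) / 3, tolerance = 1e-12)
  # converged pack with B = 1 is a fixed point
  z <- c(0.4, 0.7)
  draws1 <- rep(list(list(h1 = runif(2), h2 = rep(0.5, 2))), 3)
  expect_equal(gwo_update_position(z, z, z, z, g = 1.3, draws = draws1),
               z, tolerance = 1e-12)
  expect_error(gwo_update_position(c(0.1, 0.2), 0.5, 0.5, 0.5, 1),
               "dimension mismatch")
})

test_that("jaya update matches its closed form and fixed points", {
  expect_equal(jaya_update(0.5, 1, 0, r1 = 0.5, r2 = 0.5), 1.0)
  x <- c(0.2, 0.6, 0.9)
  expect_equal(jaya_update(x, x, x, runif(3), runif(3)), x)
  expect_equal(jaya_update(x, c(1, 1, 1), c(0, 0, 0),
                           rep(0, 3), rep(0, 3)), x)
  expect_error(jaya_update(c(0.1, 0.2), c(1, 1, 1), c(0, 0, 0)),
               "dimension mismatch")
  # results are always clipped to the unit interval
  expect_true(all(jaya_update(c(0.9, 0.1), c(1, 1), c(0, 0),
                              c(1, 1), c(1, 1)) <= 1))
})

test_that("ELM separates well-separated blobs and stays at chance on shuffles", {
  fd <- make_feature_dataset(200, 2, 5, 0, 0, 6, seed = 1)
  expect_equal(elm_fitness(fd$x, fd$y, rep(TRUE, 5), seed = 1), 1.0)
  accs <- vapply(1:20, function(s) {
    fd2 <- make_feature_dataset(120, 4, 5, 0, 5, 3, seed = s)
    y_sh <- neurofusion:::with_seed(s, sample(fd2$y))
    elm_fitness(fd2$x, y_sh, rep(TRUE, 10), seed = s)
  }, 0)
  expect_lt(abs(mean(accs) - 0.25), 0.05)
  # an informative mask beats an all-noise mask
  fd3 <- std_selection_data(2)
  fit_inf <- elm_fitness(fd3$x, fd3$y, seq_len(50) %in% 1:5, seed = 2)
  fit_noise <- elm_fitness(fd3$x, fd3$y, seq_len(50) %in% 46:50, seed = 2)
  expect_gt(fit_inf, fit_noise)
  expect_error(elm_fitness(fd3$x, fd3$y, rep(FALSE, 50)), "no columns")
  expect_error(elm_fitness(fd3$x, rep(0L, 300), rep(TRUE, 50)),
               "two classes")
})

test_that("ELM fitness is deterministic in its seed", {
  fd <- std_selection_data(3)
  m <- seq_len(50) %in% c(1:5, 20:25)
  expect_identical(elm_fitness(fd$x, fd$y, m, seed = 11),
                   elm_fitness(fd$x, fd$y, m, seed = 11))
})

test_that("GWO recovers the optimum of a 5-D sphere in most seeds", {
  hits <- vapply(1:10, function(s) {
    pk <- gwo_select(population = 20L, iterations = 50L, seed = s,
                     dim = 5L, fitness_fn = function(z) -sum((z - 0.5)^2))
    all(abs(pk$best_position - 0.5) < 0.1)
  }, NA)
  expect_gte(sum(hits), 8L)
})

test_that("zero iterations return the best of the initial pack", {
  fit_fn <- function(z) -sum((z - 0.2)^2)
  pk <- gwo_select(population = 10L, iterations = 0L, seed = 4, dim = 3L,
                   fitness_fn = fit_fn)
  expect_length(pk$trace, 1L)
  expect_equal(pk$best_fitness, max(pk$fitness))
  expect_equal(pk$best_fitness, fit_fn(pk$best_position))
  expect_error(gwo_select(population = 2L, iterations = 1L, dim = 3L,
                          fitness_fn = fit_fn), "population")
})

test_that("default budgets echo the published configuration", {
  cfg <- selection_config()
  expect_equal(cfg$population, 50L)
  expect_equal(cfg$gwo_iterations, 200L)
  expect_equal(cfg$jaya_iterations, 100L)
})

test_that("selector recovers planted informative columns and beats random masks", {
  rec <- integer(10); beat <- logical(10)
  for (s in 1:10) {
    fd <- std_selection_data(s)
    sel <- select_features(fd$x, fd$y, reduced_selection_config(),
                           seed = s)
    rec[s] <- sum(sel$mask[fd$info$informative])
    rnd <- neurofusion:::with_seed(1000 + s,
                                   sample(50, sel$n_selected))
    f_rand <- elm_fitness(fd$x, fd$y, seq_len(50) %in% rnd,
                          seed = neurofusion:::substream_seed(s, 7L))
    beat[s] <- sel$best_fitness >= f_rand
    expect_false(is.unsorted(sel$fitness_trace))
    expect_gte(sel$n_selected, 1L)
  }
  expect_gte(median(rec), 4)
  expect_gte(sum(beat), 8L)
})

test_that("on tiny problems the mask reaches the top decile of all masks", {
  quantiles <- vapply(1:6, function(s) {
    fd <- make_feature_dataset(80, 2, 2, 1, 1, 3, seed = s)
    d <- ncol(fd$x)
    sel <- select_features(fd$x, fd$y,
                           selection_config(population = 6L,
                                            gwo_iterations = 10L,
                                            jaya_iterations = 5L,
                                            hidden = 30L), seed = s)
    fit_seed <- neurofusion:::substream_seed(s, 7L)
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d))[-1, ])
    fits <- apply(masks, 1, function(mk) {
      elm_fitness(fd$x, fd$y, as.logical(mk), hidden = 30L,
                  seed = fit_seed)
    })
    mean(fits <= sel$best_fitness)
  }, 0)
  expect_gte(median(quantiles), 0.9)
})

test_that("a perfectly predictive lone column is always kept", {
  fd <- make_feature_dataset(60, 2, 1, 0, 1, 8, seed = 4)
  sel <- select_features(fd$x, fd$y,
                         selection_config(population = 5L,
                                          gwo_iterations = 8L,
                                          jaya_iterations = 4L,
                                          hidden = 20L), seed = 4)
  expect_true(sel$mask[1])
  # brute force over the 3 non-empty masks confirms column 1 is optimal
  fit_seed <- neurofusion:::substream_seed(4L, 7L)
  fits <- vapply(list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE)),
                 function(m) elm_fitness(fd$x, fd$y, m, hidden = 20L,
                                         seed = fit_seed), 0)
  expect_gte(sel$best_fitness, max(fits) - 1e-12)
})
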