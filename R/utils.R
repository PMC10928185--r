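# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

clip01 <- function(x) pmin(pmax(x, 0), 1)

# One-hot encode 0-based integer labels into an n x K {0,1} matrix.
one_hot <- function(y, n_classes) {
  stopifnot(all(y >= 0), all(y < n_classes))
  m <- matrix(0, length(y), n_classes)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

# Derive a reproducible sub-seed from a root seed and a stage offset.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483629) + 1L
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Seeded stratified holdout: returns indices of the training portion.
# Each class contributes round(ratio * n_class) members (at least 1,
# never the whole class when the class has >= 2 members).
stratified_train_indices <- function(labels, ratio, seed) {
  stopifnot(ratio > 0, ratio < 1)
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      n_tr <- round(ratio * length(ix))
      n_tr <- max(1L, min(length(ix) - 1L, n_tr))
      if (length(ix) == 1L) return(ix)  # degenerate: lone member trains
      sample(ix, n_tr)
    }), use.names = FALSE)
    sort(idx)
  })
}

# Seeded stratified k-fold assignment: fold id (1..k) per sample.
stratified_fold_ids <- function(labels, k, seed) {
  ids <- integer(length(labels))
  with_seed(seed, {
    for (ix in split(seq_along(labels), labels)) {
      ids[sample(ix)] <- rep_len(seq_len(k), length(ix))
    }
  })
  ids
}

`%||%` <- function(a, b) if (is.null(a)) b else a
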