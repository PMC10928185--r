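# Parallel-pooling feature fusion: each extractor's feature vector is
# pooled independently along its length and the pooled halves are
# concatenated, extractor 1 first.

#' Fusion configuration
#'
#' Defaults reproduce the published fused dimensions: a length-2
#' window with stride 2 halves each vector (1024 -> 512, 1236 -> 618),
#' and max pooling preserves salient activations. Vectors whose length
#' does not align with the window/stride grid are first mean-padded.
#'
#' @param window Pooling window length (>= 1).
#' @param stride Pooling stride (>= 1).
#' @param mode `"max"` or `"mean"`.
#' @param pad_policy `"mean_pad_to_even"` pads a vector with its own
#'   mean up to the next stride-aligned length; `"none"` refuses
#'   misaligned input lengths.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(window = 2L, stride = 2L,
                          mode = c("max", "mean"),
                          pad_policy = c("mean_pad_to_even", "none")) {
  mode <- match.arg(mode)
  pad_policy <- match.arg(pad_policy)
  stopifnot(window >= 1, stride >= 1)
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 mode = mode, pad_policy = pad_policy),
            class = "fusion_config")
}

#' Mean padding
#'
#' Extends a vector to `target_len` by appending its own arithmetic
#' mean; original entries are unchanged.
#'
#' @param v Numeric vector.
#' @param target_len Target length (>= `length(v)`).
#' @return The padded vector.
#' @examples
#' mean_pad(c(1, 3), 3)  # 1 3 2
#' @export
mean_pad <- function(v, target_len) {
  if (target_len < length(v)) stop("target_len is shorter than the vector")
  c(v, rep(mean(v), target_len - length(v)))
}

padded_length <- function(l, cfg) {
  if (l >= cfg$window && (l - cfg$window) %% cfg$stride == 0L) return(l)
  lp <- max(l, cfg$window)
  lp + (cfg$stride - (lp - cfg$window) %% cfg$stride) %% cfg$stride
}

#' One-dimensional feature pooling
#'
#' Slides a window of length `cfg$window` with stride `cfg$stride`
#' along the vector, emitting the window maximum or mean. Under the
#' mean-padding policy a misaligned vector is first extended with its
#' own mean to the next valid length, so the default window-2/stride-2
#' configuration always halves the length (rounding up).
#'
#' @param v Numeric vector (length >= 1).
#' @param cfg A [fusion_config()].
#' @return The pooled vector of length
#'   `(padded_length - window) / stride + 1`.
#' @examples
#' length(pool1d(rnorm(1024)))  # 512
#' pool1d(c(1, 3, 2, 5))        # 3 5
#' @export
pool1d <- function(v, cfg = fusion_config()) {
  stopifnot(length(v) >= 1)
  if (cfg$pad_policy == "mean_pad_to_even") {
    v <- mean_pad(v, padded_length(length(v), cfg))
  } else if (length(v) < cfg$window ||
             (length(v) - cfg$window) %% cfg$stride != 0L) {
    stop("vector length does not align with window/stride (pad_policy = none)")
  }
  starts <- seq.int(1L, length(v) - cfg$window + 1L, by = cfg$stride)
  win <- vapply(starts, function(s) {
    w <- v[s:(s + cfg$window - 1L)]
    if (cfg$mode == "max") max(w) else mean(w)
  }, 0)
  win
}

# Pool every row of a matrix with shared windows (vectorized pool1d).
pool_rows <- function(m, cfg) {
  l <- ncol(m)
  lp <- if (cfg$pad_policy == "mean_pad_to_even") padded_length(l, cfg) else l
  if (lp != l) {
    if (cfg$pad_policy == "none") {
      stop("feature width does not align with window/stride")
    }
    m <- cbind(m, matrix(rowMeans(m), nrow(m), lp - l))
  }
  starts <- seq.int(1L, lp - cfg$window + 1L, by = cfg$stride)
  out <- matrix(0, nrow(m), length(starts))
  for (j in seq_along(starts)) {
    w <- m[, starts[j]:(starts[j] + cfg$window - 1L), drop = FALSE]
    out[, j] <- if (cfg$mode == "max") do.call(pmax, asplit(w, 2))
                else rowMeans(w)
  }
  out
}

#' Fuse two feature matrices by parallel pooling
#'
#' Pools each row of both matrices independently with [pool1d()]'s
#' windows and concatenates the pooled rows, first extractor first.
#' With the default configuration and the study widths 1024 and 1236
#' the fused width is 512 + 618 = 1130.
#'
#' @param fv1,fv2 Feature matrices with equal row counts and matching
#'   sample order. `fv2` may have zero columns, in which case the
#'   result is the pooled `fv1`.
#' @param cfg A [fusion_config()].
#' @return The fused feature matrix; column names carry `fv1_` / `fv2_`
#'   source tags.
#' @export
fuse_features <- function(fv1, fv2, cfg = fusion_config()) {
  fv1 <- as.matrix(fv1); fv2 <- as.matrix(fv2)
  if (nrow(fv1) != nrow(fv2)) {
    stop("fv1 and fv2 must have the same number of samples")
  }
  p1 <- if (ncol(fv1) > 0) pool_rows(fv1, cfg) else fv1
  p2 <- if (ncol(fv2) > 0) pool_rows(fv2, cfg) else fv2
  out <- cbind(p1, p2)
  colnames(out) <- c(
    if (ncol(p1) > 0) sprintf("fv1_p%04d", seq_len(ncol(p1))),
    if (ncol(p2) > 0) sprintf("fv2_p%04d", seq_len(ncol(p2)))
  )
  out
}
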