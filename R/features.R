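# Deep-feature extraction from named network taps.

#' Extract deep features from a named tap
#'
#' Runs the dataset through the trained network in evaluation mode and
#' collects the activations of the named tap, one row per sample in
#' dataset order. A flat tap (such as the ResNet `"gap"` layer) is
#' returned as-is; a spatial (convolutional) tap is reduced by the
#' tap's pooling plan — adaptive average pooling over the spatial
#' dimensions followed by flattening — so the feature width is
#' independent of the input resolution. With the default
#' architectures, `"gap"` yields 1024 columns and `"decoder_conv_last"`
#' 1236.
#'
#' @param model A `trained_network`.
#' @param data An `image_dataset` (or H x W x C x N array).
#' @param tap Name of a tap in `model$spec$named_taps`.
#' @param batch Evaluation minibatch size.
#' @return An N x width feature matrix with tagged column names.
#' @export
extract_features <- function(model, data, tap, batch = 32L) {
  spec <- model$spec
  if (!tap %in% names(spec$named_taps)) {
    stop("unknown tap: ", tap, " (available: ",
         paste(names(spec$named_taps), collapse = ", "), ")")
  }
  tp <- spec$named_taps[[tap]]
  x <- if (is.list(data)) data$images else data
  if (!identical(dim(x)[1:3], as.integer(spec$input_shape))) {
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match the network input ",
         paste(spec$input_shape, collapse = "x"))
  }
  n <- dim(x)[4]
  rows <- vector("list", ceiling(n / batch))
  bi <- 0L
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- forward_network(spec, model$params, model$bn_state,
                          x[, , , idx, drop = FALSE], train = FALSE,
                          upto = tp$layer)
    out <- fw$outs[[tp$layer]]
    if (!is.matrix(out)) {
      g <- tp$pool %||% c(1L, 1L)
      pooled <- adaptive_avgpool(out, g[1])
      d <- dim(pooled)
      out <- t(matrix(pooled, prod(d[1:3]), d[4]))
    }
    bi <- bi + 1L
    rows[[bi]] <- out
  }
  fm <- do.call(rbind, rows)
  if (any(!is.finite(fm))) stop("non-finite activations at tap ", tap)
  colnames(fm) <- sprintf("%s_%04d", tap, seq_len(ncol(fm)))
  fm
}
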