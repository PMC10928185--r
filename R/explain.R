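# Grad-CAM class-activation maps for the trained CNN: feature maps of
# a convolutional tap are weighted by the spatial mean of the class
# score's gradients and combined under a ReLU.

as_map_array <- function(x) {
  if (is.list(x)) {
    x <- array(unlist(x), c(dim(x[[1]]), length(x)))
  }
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected K grids of equal shape")
  x
}

#' Grad-CAM channel weights
#'
#' Computes one weight per feature map as the global average of the
#' class-score gradient over that map: `a_k = (1/N) sum_ij dy/dA_k[i,j]`
#' with `N` the number of spatial positions.
#'
#' @param gradients K gradient grids: an H' x W' x K array (or list of
#'   K matrices).
#' @return Numeric vector of K weights.
#' @examples
#' gradcam_weights(matrix(1:4, 2, 2))  # 2.5
#' @export
gradcam_weights <- function(gradients) {
  g <- as_map_array(gradients)
  if (prod(dim(g)[1:2]) == 0) stop("empty gradient grids")
  apply(g, 3, mean)
}

#' Grad-CAM activation map
#'
#' Combines the K activation grids with the channel weights and clamps
#' at zero: `M = ReLU(sum_k a_k A_k)`. Optionally upsamples the raw map
#' bilinearly to a display resolution and min-max normalizes only that
#' copy.
#'
#' @param activations K activation grids (H' x W' x K array or list).
#' @param weights Numeric vector of K channel weights.
#' @param upsample_to Optional `c(H, W)` display resolution.
#' @param class_index,score Optional class bookkeeping carried in the
#'   result.
#' @return A list of class `gradcam_heatmap` with the raw `map`
#'   (non-negative H' x W'), `upsampled` ([0,1] H x W or `NULL`),
#'   `class_index`, `score`.
#' @export
gradcam_map <- function(activations, weights, upsample_to = NULL,
                        class_index = NA_integer_, score = NA_real_) {
  a <- as_map_array(activations)
  if (dim(a)[3] != length(weights)) {
    stop("shape mismatch: ", dim(a)[3], " maps vs ", length(weights),
         " weights")
  }
  m <- matrix(0, dim(a)[1], dim(a)[2])
  for (k in seq_along(weights)) m <- m + weights[k] * a[, , k]
  m <- pmax(m, 0)
  up <- NULL
  if (!is.null(upsample_to)) {
    up <- bilinear_resize(m, upsample_to[1], upsample_to[2])
    rng <- range(up)
    up <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else up * 0
  }
  structure(list(map = m, upsampled = up,
                 class_index = class_index, score = score),
            class = "gradcam_heatmap")
}

#' Explain a prediction with Grad-CAM
#'
#' Runs the image through the trained network, takes the gradient of
#' the chosen class's pre-softmax score with respect to the tap
#' layer's activations, and composes [gradcam_weights()] and
#' [gradcam_map()]. The default tap is the last convolution of the
#' third appended residual block — the deepest convolutional
#' activation before global average pooling.
#'
#' @param model A `trained_network` (ResNet variant).
#' @param image H x W x C array (or H x W matrix for grayscale).
#' @param class_index 0-based class to explain; defaults to the
#'   predicted class.
#' @param layer Name of a convolutional activation layer in the spec;
#'   the default is the output of the third appended residual block.
#' @return A `gradcam_heatmap` whose raw map has the tap's spatial
#'   shape and whose `upsampled` copy has the input resolution;
#'   `score` is the class's pre-softmax score.
#' @export
explain_image <- function(model, image, class_index = NULL,
                          layer = "added3_relu") {
  spec <- model$spec
  if (!layer %in% names(spec$layers)) stop("unknown layer: ", layer)
  shapes <- infer_shapes(spec)
  if (length(shapes[[layer]]) != 3L) {
    stop("layer ", layer, " is not a convolutional (spatial) tap")
  }
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  x <- array(image, c(dim(image), 1L))
  fw <- forward_network(spec, model$params, model$bn_state, x,
                        train = FALSE, upto = "fc")
  logits <- fw$outs$fc
  if (is.null(class_index)) class_index <- which.max(logits[1, ]) - 1L
  if (class_index < 0 || class_index >= spec$n_classes) {
    stop("class index out of range")
  }
  dseed <- matrix(0, 1, spec$n_classes)
  dseed[1, class_index + 1L] <- 1
  bw <- backward_network(spec, model$params, fw$outs, fw$caches, "fc",
                         dseed, want_activation_grads = layer)
  grads <- bw$activation_grads[[layer]][, , , 1, drop = FALSE]
  dim(grads) <- dim(grads)[1:3]
  acts <- fw$outs[[layer]][, , , 1, drop = FALSE]
  dim(acts) <- dim(acts)[1:3]
  w <- gradcam_weights(grads)
  gradcam_map(acts, w, upsample_to = dim(image)[1:2],
              class_index = class_index,
              score = logits[1, class_index + 1L])
}
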