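# Declarative network specifications. A spec is an ordered list of
# layer descriptors forming a DAG (each layer names its input layers;
# NULL means "previous layer"), plus named feature taps. Builders below
# construct the two extractor architectures; shape inference walks the
# descriptor list so tap widths and dense sizes are derived, never
# hard-coded.

layer_desc <- function(name, kind, input = NULL, section = "body",
                       role = "main", ...) {
  c(list(name = name, kind = kind, input = input, section = section,
         role = role), list(...))
}

new_network_spec <- function(layers, named_taps, input_shape, n_classes,
                             width_scale, type) {
  names(layers) <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(names(layers))) stop("duplicate layer names")
  structure(list(layers = layers, named_taps = named_taps,
                 input_shape = input_shape, n_classes = n_classes,
                 width_scale = width_scale, type = type),
            class = "network_spec")
}

# Walk the layer list computing output shapes: c(H, W, C) for spatial
# layers, c(d) for flat layers.
infer_shapes <- function(spec) {
  shapes <- list(.input = spec$input_shape)
  prev <- ".input"
  for (ly in spec$layers) {
    ins <- ly$input %||% prev
    s <- shapes[[ins[1]]]
    if (is.null(s)) stop("unknown input layer: ", ins[1])
    out <- switch(ly$kind,
      conv = {
        ho <- conv_out_len(s[1], ly$kernel[1], ly$stride, ly$pad)
        wo <- conv_out_len(s[2], ly$kernel[2], ly$stride, ly$pad)
        if (ho < 1 || wo < 1) stop("input too small at layer ", ly$name)
        c(ho, wo, ly$out_channels)
      },
      batchnorm = s,
      relu = s,
      sigmoid = s,
      add = {
        s2 <- shapes[[ins[2]]]
        if (!identical(s, s2)) {
          stop("shape mismatch at residual add ", ly$name)
        }
        s
      },
      maxpool = {
        c(conv_out_len(s[1], ly$kernel[1], ly$stride, ly$pad),
          conv_out_len(s[2], ly$kernel[2], ly$stride, ly$pad), s[3])
      },
      gap = s[3],
      flatten = prod(s),
      dense = ly$units,
      softmax = s,
      upsample = c(s[1] * 2L, s[2] * 2L, s[3]),
      reshape = ly$target_shape,
      stop("unknown layer kind: ", ly$kind)
    )
    shapes[[ly$name]] <- out
    prev <- ly$name
  }
  shapes
}

#' Summarize a network specification
#'
#' Walks the layer graph and reports, per architectural section, the
#' convolutional layers (kernel, stride, channels, role), the inferred
#' output shapes, tap widths, and the trainable parameter count.
#'
#' @param spec A `network_spec`.
#' @return A list with `layers` (data frame), `tap_widths` (named
#'   integer vector), and `n_parameters`.
#' @export
network_summary <- function(spec) {
  shapes <- infer_shapes(spec)
  rows <- lapply(spec$layers, function(ly) {
    s <- shapes[[ly$name]]
    data.frame(
      name = ly$name, kind = ly$kind, section = ly$section,
      role = ly$role,
      kernel = if (!is.null(ly$kernel)) paste(ly$kernel, collapse = "x") else "",
      stride = if (!is.null(ly$stride)) ly$stride else NA_integer_,
      out_shape = paste(s, collapse = "x"),
      stringsAsFactors = FALSE
    )
  })
  taps <- vapply(names(spec$named_taps), function(tp) {
    tap <- spec$named_taps[[tp]]
    s <- shapes[[tap$layer]]
    if (length(s) == 1L) as.integer(s)
    else as.integer(s[3] * prod(tap$pool %||% c(1L, 1L)))
  }, integer(1))
  list(layers = do.call(rbind, rows), tap_widths = taps,
       n_parameters = count_parameters(spec))
}

count_parameters <- function(spec) {
  shapes <- infer_shapes(spec)
  prev <- ".input"; total <- 0
  for (ly in spec$layers) {
    ins <- ly$input %||% prev
    s <- shapes[[ins[1]]]
    total <- total + switch(ly$kind,
      conv = prod(ly$kernel) * s[3] * ly$out_channels + ly$out_channels,
      batchnorm = 2 * s[3],
      dense = s[1] * ly$units + ly$units,
      0
    )
    prev <- ly$name
  }
  total
}

#' @export
print.network_spec <- function(x, ...) {
  sm <- network_summary(x)
  cat(sprintf("<network_spec: %s>\n", x$type))
  cat(sprintf("  input %s, %d layers, %s parameters\n",
              paste(x$input_shape, collapse = "x"), length(x$layers),
              format(round(sm$n_parameters), big.mark = ",")))
  for (tp in names(sm$tap_widths)) {
    cat(sprintf("  tap '%s': %d features\n", tp, sm$tap_widths[tp]))
  }
  invisible(x)
}

scale_ch <- function(ch, width_scale) max(1L, as.integer(round(ch * width_scale)))

# Emit conv + BN + ReLU descriptor triplet.
conv_bn_relu <- function(layers, prefix, k, stride, pad, out_ch, section,
                         role = "main", input = NULL, bn = TRUE,
                         act = "relu") {
  layers <- c(layers, list(layer_desc(paste0(prefix, "_conv"), "conv",
    input = input, section = section, role = role,
    kernel = c(k, k), stride = stride, pad = pad, out_channels = out_ch)))
  if (bn) {
    layers <- c(layers, list(layer_desc(paste0(prefix, "_bn"), "batchnorm",
                                        section = section, role = role)))
  }
  if (!is.null(act)) {
    layers <- c(layers, list(layer_desc(paste0(prefix, "_", act), act,
                                        section = section, role = role)))
  }
  layers
}

# Standard bottleneck residual block (1x1, 3x3, 1x1) with projection
# shortcut when the shape changes.
bottleneck_block <- function(layers, prefix, in_name, in_ch, mid_ch,
                             out_ch, stride, section) {
  layers <- conv_bn_relu(layers, paste0(prefix, "_a"), 1L, stride, 0L,
                         mid_ch, section, input = in_name)
  layers <- conv_bn_relu(layers, paste0(prefix, "_b"), 3L, 1L, 1L,
                         mid_ch, section)
  layers <- conv_bn_relu(layers, paste0(prefix, "_c"), 1L, 1L, 0L,
                         out_ch, section, act = NULL)
  main_out <- paste0(prefix, "_c_bn")
  if (in_ch != out_ch || stride != 1L) {
    layers <- conv_bn_relu(layers, paste0(prefix, "_proj"), 1L, stride, 0L,
                           out_ch, section, role = "projection",
                           input = in_name, act = NULL)
    skip_out <- paste0(prefix, "_proj_bn")
  } else {
    skip_out <- in_name
  }
  layers <- c(layers, list(
    layer_desc(paste0(prefix, "_add"), "add",
               input = c(main_out, skip_out), section = section),
    layer_desc(paste0(prefix, "_relu"), "relu", section = section)
  ))
  layers
}

# Appended residual block: four stride-1 convolutions alternating 1x1
# and 3x3 kernels, BN + ReLU after each, identity skip with a 1x1
# projection when the channel count changes.
appended_block <- function(layers, prefix, in_name, in_ch, out_ch,
                           section) {
  half <- max(1L, out_ch %/% 2L)
  layers <- conv_bn_relu(layers, paste0(prefix, "_a"), 1L, 1L, 0L, half,
                         section, input = in_name)
  layers <- conv_bn_relu(layers, paste0(prefix, "_b"), 3L, 1L, 1L, half,
                         section)
  layers <- conv_bn_relu(layers, paste0(prefix, "_c"), 1L, 1L, 0L, out_ch,
                         section)
  layers <- conv_bn_relu(layers, paste0(prefix, "_d"), 3L, 1L, 1L, out_ch,
                         section, act = NULL)
  main_out <- paste0(prefix, "_d_bn")
  if (in_ch != out_ch) {
    layers <- conv_bn_relu(layers, paste0(prefix, "_proj"), 1L, 1L, 0L,
                           out_ch, section, role = "projection",
                           input = in_name, act = NULL)
    skip_out <- paste0(prefix, "_proj_bn")
  } else {
    skip_out <- in_name
  }
  c(layers, list(
    layer_desc(paste0(prefix, "_add"), "add",
               input = c(main_out, skip_out), section = section),
    layer_desc(paste0(prefix, "_relu"), "relu", section = section)
  ))
}

#' Build the modified ResNet-50 specification
#'
#' Constructs the ResNet-50 backbone (7x7 stride-2 stem with max
#' pooling, four bottleneck stages of 3/4/6/3 blocks) followed by the
#' three appended residual blocks - each four stride-1 convolutions
#' alternating 1x1 and 3x3 kernels with an identity skip (1x1
#' projection where channels change) - one extra 3x3 stride-1
#' convolution after the first appended block, batch normalization and
#' ReLU after every convolution, a global-average-pooling tap named
#' `"gap"`, and a fully connected softmax head.
#'
#' The appended blocks taper the channel plan from the backbone's 2048
#' down to 1024 (times `width_scale`), so the `"gap"` tap emits
#' `1024 * width_scale` features; at the default scale that is the
#' 1024-wide deep-feature vector fed to fusion.
#'
#' @param input_shape Integer vector `c(H, W, C)`; H, W >= 32.
#' @param n_classes Number of output classes.
#' @param width_scale Positive multiplier applied to every channel
#'   count; fractional scales give desk-size networks for testing.
#' @return A `network_spec`.
#' @export
build_modified_resnet50 <- function(input_shape = c(224L, 224L, 3L),
                                    n_classes = 4L, width_scale = 1) {
  stopifnot(length(input_shape) == 3L, width_scale > 0, n_classes >= 2)
  if (input_shape[1] < 32 || input_shape[2] < 32) {
    stop("input must be at least 32x32 for the downsampling plan")
  }
  s <- function(ch) scale_ch(ch, width_scale)
  layers <- list()
  layers <- conv_bn_relu(layers, "stem", 7L, 2L, 3L, s(64), "stem",
                         input = ".input")
  layers <- c(layers, list(layer_desc("stem_pool", "maxpool",
    section = "stem", kernel = c(3L, 3L), stride = 2L, pad = 1L)))

  stage_plan <- list(
    list(section = "stage1", blocks = 3L, mid = 64, out = 256, stride = 1L),
    list(section = "stage2", blocks = 4L, mid = 128, out = 512, stride = 2L),
    list(section = "stage3", blocks = 6L, mid = 256, out = 1024, stride = 2L),
    list(section = "stage4", blocks = 3L, mid = 512, out = 2048, stride = 2L)
  )
  in_name <- "stem_pool"; in_ch <- s(64)
  for (st in stage_plan) {
    for (b in seq_len(st$blocks)) {
      prefix <- paste0(st$section, "_b", b)
      stride <- if (b == 1L) st$stride else 1L
      layers <- bottleneck_block(layers, prefix, in_name, in_ch,
                                 s(st$mid), s(st$out), stride, st$section)
      in_name <- paste0(prefix, "_relu"); in_ch <- s(st$out)
    }
  }

  # Three appended residual blocks tapering 2048 -> 1536 -> 1280 -> 1024,
  # with one extra 3x3 stride-1 convolution after the first block.
  added_out <- c(1536, 1280, 1024)
  for (a in 1:3) {
    prefix <- paste0("added", a)
    layers <- appended_block(layers, prefix, in_name, in_ch,
                             s(added_out[a]), prefix)
    in_name <- paste0(prefix, "_relu"); in_ch <- s(added_out[a])
    if (a == 1L) {
      layers <- conv_bn_relu(layers, "extra", 3L, 1L, 1L, in_ch,
                             "extra_conv", input = in_name)
      in_name <- "extra_relu"
    }
  }

  layers <- c(layers, list(
    layer_desc("gap", "gap", input = in_name, section = "head"),
    layer_desc("fc", "dense", section = "head", units = n_classes),
    layer_desc("softmax", "softmax", section = "head")
  ))
  new_network_spec(layers,
                   named_taps = list(gap = list(layer = "gap", pool = NULL)),
                   input_shape = as.integer(input_shape),
                   n_classes = as.integer(n_classes),
                   width_scale = width_scale, type = "resnet_classifier")
}

#' Build the stacked convolutional autoencoder specification
#'
#' The encoder is five stride-2 3x3 convolutions (ReLU); the flattened
#' code passes through stacked dense sigmoid bottlenecks (default
#' widths 100 and 50), is decoded through the mirrored dense layers,
#' and the decoder is five upsampling 3x3 convolutions (nearest 2x
#' upsampling followed by a stride-1 convolution, ReLU). The final
#' decoder convolution carries `feature_dim / 4` channels and hosts the
#' feature tap `"decoder_conv_last"`: its output is adaptively
#' average-pooled to a 2x2 grid and flattened, giving exactly
#' `feature_dim` features (default 1236). A 1x1 output-projection
#' convolution (sigmoid) maps that layer to the reconstruction, which
#' has the input's shape.
#'
#' @param input_shape Integer vector `c(H, W, C)`; H and W must be
#'   multiples of 32 so the five 2x down/up-sampling stages mirror.
#' @param bottlenecks Dense bottleneck widths, outermost first.
#' @param feature_dim Width of the `"decoder_conv_last"` tap; must be
#'   divisible by 4 (channels x 2x2 pooling grid) unless it is small
#'   enough to use a 1x1 grid.
#' @return A `network_spec`.
#' @export
build_stacked_autoencoder <- function(input_shape = c(224L, 224L, 3L),
                                      bottlenecks = c(100L, 50L),
                                      feature_dim = 1236L) {
  stopifnot(length(input_shape) == 3L, length(bottlenecks) >= 1,
            feature_dim >= 1)
  if (input_shape[1] %% 32 != 0 || input_shape[2] %% 32 != 0) {
    stop("input height and width must be multiples of 32")
  }
  if (feature_dim %% 4L == 0L) {
    tap_pool <- c(2L, 2L); tap_ch <- as.integer(feature_dim) %/% 4L
  } else {
    tap_pool <- c(1L, 1L); tap_ch <- as.integer(feature_dim)
  }
  if (min(input_shape[1:2]) < max(tap_pool)) {
    stop("feature_dim unreachable: no valid pooling plan for this input")
  }
  enc_ch <- c(16L, 32L, 64L, 64L, 64L)
  dec_ch <- c(64L, 64L, 32L, 16L, tap_ch)
  layers <- list()
  in_name <- ".input"
  for (i in 1:5) {
    prefix <- paste0("enc", i)
    layers <- conv_bn_relu(layers, prefix, 3L, 2L, 1L, enc_ch[i],
                           "encoder", input = in_name, bn = FALSE)
    in_name <- paste0(prefix, "_relu")
  }
  h5 <- input_shape[1] %/% 32L; w5 <- input_shape[2] %/% 32L
  flat <- h5 * w5 * enc_ch[5]
  layers <- c(layers, list(layer_desc("enc_flatten", "flatten",
                                      section = "bottleneck")))
  for (i in seq_along(bottlenecks)) {
    layers <- c(layers, list(
      layer_desc(paste0("code", i, "_dense"), "dense",
                 section = "bottleneck", units = as.integer(bottlenecks[i])),
      layer_desc(paste0("code", i, "_sigmoid"), "sigmoid",
                 section = "bottleneck")
    ))
  }
  widths_up <- c(rev(bottlenecks[-length(bottlenecks)]), flat)
  for (i in seq_along(widths_up)) {
    last <- i == length(widths_up)
    layers <- c(layers, list(
      layer_desc(paste0("decode", i, "_dense"), "dense",
                 section = "bottleneck", units = as.integer(widths_up[i])),
      layer_desc(paste0("decode", i, if (last) "_relu" else "_sigmoid"),
                 if (last) "relu" else "sigmoid", section = "bottleneck")
    ))
  }
  layers <- c(layers, list(layer_desc("dec_reshape", "reshape",
    section = "bottleneck", target_shape = c(h5, w5, enc_ch[5]))))
  in_name <- "dec_reshape"
  for (i in 1:5) {
    prefix <- paste0("dec", i)
    layers <- c(layers, list(layer_desc(paste0(prefix, "_up"), "upsample",
                                        input = in_name,
                                        section = "decoder")))
    layers <- conv_bn_relu(layers, prefix, 3L, 1L, 1L, dec_ch[i],
                           "decoder", bn = FALSE)
    in_name <- paste0(prefix, "_relu")
  }
  layers <- c(layers, list(
    layer_desc("recon_conv", "conv", section = "output", role = "output",
               kernel = c(1L, 1L), stride = 1L, pad = 0L,
               out_channels = as.integer(input_shape[3])),
    layer_desc("recon_sigmoid", "sigmoid", section = "output",
               role = "output")
  ))
  new_network_spec(layers,
    named_taps = list(decoder_conv_last = list(layer = "dec5_relu",
                                               pool = tap_pool)),
    input_shape = as.integer(input_shape), n_classes = NA_integer_,
    width_scale = 1, type = "stacked_autoencoder")
}
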