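# Synthetic fixtures: seeded generators for feature tables and
# modality-like image sets, plus the dataset slice-accounting rule.

#' Generate a class-conditional Gaussian feature table
#'
#' Builds a labelled feature matrix that emulates the structure deep
#' feature selection has to cope with: a block of informative columns
#' whose class-conditional means are separated, a block of redundant
#' columns that are noisy linear combinations of the informative ones,
#' and a block of pure-noise columns that carry no class signal.
#'
#' Informative column means sit at `+/- class_sep / 2` according to a
#' seeded, per-column non-constant sign pattern over the classes, with
#' unit-variance Gaussian noise, so the between-class mean separation in
#' every informative column is `class_sep` standard deviations.
#'
#' @param n_samples Number of rows (>= 2 * n_classes); class sizes are
#'   balanced to within one sample.
#' @param n_classes Number of classes K (>= 2); labels are 0..K-1.
#' @param n_informative,n_redundant,n_noise Column counts per block
#'   (`n_informative >= 1`, others >= 0).
#' @param class_sep Between-class mean separation of informative
#'   columns, in units of the within-class standard deviation. 0 gives
#'   a no-signal null dataset.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `feature_dataset` with elements `x` (matrix
#'   with tagged column names `inf_*`, `red_*`, `noise_*`), `y`
#'   (integer labels 0..K-1), `class_names`, and `info` (the column
#'   indices of each block).
#' @export
make_feature_dataset <- function(n_samples, n_classes = 4L,
                                 n_informative = 5L, n_redundant = 5L,
                                 n_noise = 40L, class_sep = 3,
                                 seed = 1L) {
  stopifnot(n_informative >= 1, n_redundant >= 0, n_noise >= 0,
            n_classes >= 2, class_sep >= 0)
  if (n_samples < 2 * n_classes) {
    stop("n_samples must be at least 2 * n_classes for stratification")
  }
  K <- as.integer(n_classes)
  d_inf <- as.integer(n_informative)
  d_red <- as.integer(n_redundant)
  d_noi <- as.integer(n_noise)

  # Balanced labels: counts differ by at most one.
  y <- sort(rep_len(0:(K - 1L), n_samples))

  with_seed(seed, {
    # Per-column sign pattern over classes, rejected if constant so
    # every informative column genuinely carries class signal.
    signs <- matrix(0, K, d_inf)
    for (j in seq_len(d_inf)) {
      repeat {
        s <- sample(c(-1, 1), K, replace = TRUE)
        if (length(unique(s)) > 1L) break
      }
      signs[, j] <- s
    }
    centroids <- signs * class_sep / 2

    x_inf <- centroids[y + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n_samples * d_inf), n_samples, d_inf)

    x_red <- NULL
    if (d_red > 0) {
      # Redundant columns are degraded substitutes: a random linear
      # combination of the informative block plus unit-variance noise,
      # so they correlate with the class signal but carry visibly less
      # of it than the informative columns they mix.
      mix <- matrix(stats::rnorm(d_inf * d_red), d_inf, d_red) /
        sqrt(d_inf)
      x_red <- x_inf %*% mix +
        matrix(stats::rnorm(n_samples * d_red), n_samples, d_red)
    }
    x_noi <- NULL
    if (d_noi > 0) {
      x_noi <- matrix(stats::rnorm(n_samples * d_noi), n_samples, d_noi)
    }

    x <- cbind(x_inf, x_red, x_noi)
    colnames(x) <- c(
      sprintf("inf_%02d", seq_len(d_inf)),
      if (d_red > 0) sprintf("red_%02d", seq_len(d_red)),
      if (d_noi > 0) sprintf("noise_%02d", seq_len(d_noi))
    )
    structure(list(
      x = x, y = y,
      class_names = paste0("class", 0:(K - 1L)),
      info = list(
        informative = seq_len(d_inf),
        redundant = if (d_red > 0) d_inf + seq_len(d_red) else integer(),
        noise = if (d_noi > 0) d_inf + d_red + seq_len(d_noi) else integer()
      )
    ), class = "feature_dataset")
  })
}

#' Generate a four-modality synthetic image set
#'
#' Emulates 2-D brain-MRI slices of the four structural modalities as
#' grayscale images on an elliptical brain-like mask. Each class is
#' distinguished by a controllable texture signature: a class-specific
#' sinusoidal grating (distinct spatial frequency and orientation) and
#' a class-specific radial intensity profile, plus seeded pixel noise.
#' The signal is strong enough that a small CNN can exceed chance.
#'
#' @param n_per_class Images per class (>= 1).
#' @param height,width Image dimensions in pixels (>= 16).
#' @param seed Integer seed; identical seeds give identical output.
#' @param noise_sd Pixel noise standard deviation (intensity units).
#' @return A list of class `image_dataset` with `images` (H x W x 1 x N
#'   array of intensities in [0,1]), `labels` (0..3), `class_names`
#'   (the four MRI modalities), `mask` (the elliptical support), and
#'   `metadata` (per-image class, index, seed).
#' @export
make_modality_images <- function(n_per_class, height = 64L, width = 64L,
                                 seed = 1L, noise_sd = 0.04) {
  stopifnot(n_per_class >= 1, height >= 16, width >= 16)
  class_names <- c("flair", "t1", "t1ce", "t2")
  K <- 4L
  n <- n_per_class * K
  labels <- rep(0:(K - 1L), each = n_per_class)

  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  # Elliptical brain-like support covering most of the frame.
  r2 <- ((yy - cy) / (0.44 * height))^2 + ((xx - cx) / (0.47 * width))^2
  mask <- r2 <= 1
  rr <- sqrt(pmin(r2, 1))

  freqs <- c(3, 6, 10, 16)              # cycles across the frame
  thetas <- c(0, 45, 90, 135) * pi / 180
  radial_pow <- c(0.5, 1, 2, 4)         # radial brightness falloff

  images <- array(0, c(height, width, 1L, n))
  with_seed(seed, {
    for (i in seq_len(n)) {
      k <- labels[i] + 1L
      u <- (xx / width) * cos(thetas[k]) + (yy / height) * sin(thetas[k])
      phase <- stats::runif(1, 0, 2 * pi)
      grating <- sin(2 * pi * freqs[k] * u + phase)
      profile <- (1 - rr)^radial_pow[k]
      img <- 0.15 + 0.35 * profile + 0.25 * (grating + 1) / 2 +
        stats::rnorm(height * width, sd = noise_sd)
      img <- img * mask
      images[, , 1L, i] <- clip01(img)
    }
  })
  structure(list(
    images = images, labels = labels, class_names = class_names,
    mask = mask,
    metadata = data.frame(index = seq_len(n),
                          class = class_names[labels + 1L],
                          seed = seed)
  ), class = "image_dataset")
}

#' Plan the per-patient axial slice selection
#'
#' Applies the dataset accounting rule used for multi-modal MRI
#' volumes: an inclusive range of axial slices is kept from every
#' patient's volume, for each modality, and the per-class and total
#' image counts follow by multiplication.
#'
#' @param n_patients Number of patients (>= 1).
#' @param slice_lo,slice_hi Inclusive 1-based slice range.
#' @param n_modalities Number of modalities / classes (>= 1).
#' @return A list of class `slice_plan` with `per_class`, `total`,
#'   `slice_range`, `n_patients`, `n_modalities`.
#' @examples
#' plan_slice_selection(369, 40, 114, 4)  # 27,675 per class; 110,700 total
#' @export
plan_slice_selection <- function(n_patients, slice_lo = 40L,
                                 slice_hi = 114L, n_modalities = 4L) {
  stopifnot(n_patients >= 1, n_modalities >= 1, slice_lo >= 1)
  if (slice_lo > slice_hi) stop("inverted slice range")
  n_slices <- slice_hi - slice_lo + 1L
  per_class <- as.integer(n_patients) * as.integer(n_slices)
  structure(list(
    per_class = per_class,
    total = per_class * as.integer(n_modalities),
    slice_range = c(as.integer(slice_lo), as.integer(slice_hi)),
    n_patients = as.integer(n_patients),
    n_modalities = as.integer(n_modalities)
  ), class = "slice_plan")
}

#' @export
print.slice_plan <- function(x, ...) {
  cat(sprintf(
    "Slice plan: %d patients x slices %d-%d x %d modalities\n  per class: %s\n  total:     %s\n",
    x$n_patients, x$slice_range[1], x$slice_range[2], x$n_modalities,
    format(x$per_class, big.mark = ","), format(x$total, big.mark = ",")
  ))
  invisible(x)
}

#' Write and read labelled feature tables as CSV
#'
#' The delimited interchange format for feature matrices: one row per
#' sample, one column per feature (header row kept), plus a final
#' integer `label` column with 0-based class codes.
#'
#' @param x Feature matrix with column names.
#' @param y Integer label vector (0-based).
#' @param path Output file path.
#' @return `write_feature_csv` returns `path` invisibly;
#'   `read_feature_csv` returns a list with `x` and `y`.
#' @export
write_feature_csv <- function(x, y, path) {
  stopifnot(nrow(x) == length(y))
  df <- as.data.frame(x)
  df$label <- as.integer(y)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("label" %in% names(df))
  y <- as.integer(df$label)
  x <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  list(x = x, y = y)
}

#' Write and read an image dataset as per-class PNG directories
#'
#' Images are written as 8-bit grayscale PNG files under one
#' subdirectory per class, alongside a JSON manifest recording the
#' layout, labels, and provenance.
#'
#' @param ds An `image_dataset` (see [make_modality_images()]).
#' @param dir Output directory (created if missing).
#' @return `write_image_dataset` returns `dir` invisibly;
#'   `read_image_dataset` returns an `image_dataset` (intensities
#'   quantized to 8 bits by the PNG round trip).
#' @export
write_image_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(ds$images)[4]
  files <- character(n)
  for (i in seq_len(n)) {
    cls <- ds$class_names[ds$labels[i] + 1L]
    sub <- file.path(dir, cls)
    dir.create(sub, showWarnings = FALSE)
    files[i] <- file.path(cls, sprintf("img_%05d.png", i))
    png::writePNG(ds$images[, , 1L, i], file.path(dir, files[i]))
  }
  manifest <- list(
    class_names = ds$class_names,
    labels = ds$labels,
    files = files,
    height = dim(ds$images)[1], width = dim(ds$images)[2]
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_image_dataset
#' @export
read_image_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  n <- length(manifest$files)
  images <- array(0, c(manifest$height, manifest$width, 1L, n))
  for (i in seq_len(n)) {
    img <- png::readPNG(file.path(dir, manifest$files[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    images[, , 1L, i] <- img
  }
  structure(list(
    images = images, labels = as.integer(manifest$labels),
    class_names = manifest$class_names, mask = NULL,
    metadata = data.frame(index = seq_len(n),
                          class = manifest$class_names[manifest$labels + 1L])
  ), class = "image_dataset")
}

#' Extract axial slices from NIfTI volumes into the PNG layout
#'
#' Real-data adapter: reads one NIfTI volume per (patient, modality),
#' keeps the inclusive axial slice range, min-max scales each slice to
#' [0,1] (volume intensity calibration is scanner-specific, so each
#' slice is normalized independently), and writes the per-class PNG
#' directory layout used by [read_image_dataset()]. Requires the RNifti
#' package and user-supplied files; it downloads nothing.
#'
#' @param files Named character vector: one NIfTI path per modality;
#'   names are used as class directories.
#' @param out_dir Output directory.
#' @param slice_lo,slice_hi Inclusive 1-based axial slice range.
#' @return The output directory, invisibly.
#' @export
nifti_to_image_dir <- function(files, out_dir, slice_lo = 40L,
                               slice_hi = 114L) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the NIfTI adapter requires the RNifti package")
  }
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    stop("`files` must be named by modality")
  }
  if (slice_lo > slice_hi) stop("inverted slice range")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  class_names <- names(files)
  labels <- integer(0); out_files <- character(0)
  for (k in seq_along(files)) {
    vol <- RNifti::readNifti(files[[k]])
    stopifnot(length(dim(vol)) >= 3L, slice_hi <= dim(vol)[3])
    sub <- file.path(out_dir, class_names[k])
    dir.create(sub, showWarnings = FALSE)
    for (s in slice_lo:slice_hi) {
      sl <- vol[, , s]
      rng <- range(sl)
      sl <- if (diff(rng) > 0) (sl - rng[1]) / diff(rng) else sl * 0
      f <- file.path(class_names[k], sprintf("slice_%03d.png", s))
      png::writePNG(sl, file.path(out_dir, f))
      out_files <- c(out_files, f)
      labels <- c(labels, k - 1L)
    }
  }
  manifest <- list(class_names = class_names, labels = labels,
                   files = out_files,
                   height = dim(vol)[1], width = dim(vol)[2])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
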