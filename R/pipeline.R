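# End-to-end pipeline: simulate -> train -> extract -> fuse -> select
# -> classify -> explain -> compare, from one declarative config with
# a single root seed feeding named substreams per stage.

#' Pipeline configuration
#'
#' @param seed Root seed; every stage derives a named substream from
#'   it.
#' @param out_dir Optional artifact directory (created if missing);
#'   `NULL` keeps everything in memory.
#' @param data Input description. `list(mode = "images", n_per_class,
#'   height, width)` simulates a four-modality image set;
#'   `list(mode = "features", n_samples, n_informative, n_redundant,
#'   n_noise, class_sep)` simulates a feature table (training and
#'   extraction are skipped); `list(mode = "files", features_csv =
#'   path)` loads a precomputed table.
#' @param stages Named logical toggles: train, extract, fuse, select,
#'   classify, explain, ttest.
#' @param network CNN/SAE settings: `width_scale`, `sae_feature_dim`,
#'   `epochs`, `minibatch`, `learning_rate`, `optimizer`.
#' @param fusion A [fusion_config()].
#' @param selection A [selection_config()].
#' @param classifiers Preset names to evaluate.
#' @param protocol Evaluation protocol for [evaluate_classifier()].
#' @param alpha Significance level for the stage comparison.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            data = list(mode = "images", n_per_class = 12L,
                                        height = 32L, width = 32L),
                            stages = list(train = TRUE, extract = TRUE,
                                          fuse = TRUE, select = TRUE,
                                          classify = TRUE, explain = TRUE,
                                          ttest = TRUE),
                            network = list(width_scale = 0.125,
                                           sae_feature_dim = 64L,
                                           epochs = 3L, minibatch = 16L,
                                           learning_rate = 0.002,
                                           optimizer = "adam"),
                            fusion = fusion_config(),
                            selection = selection_config(),
                            classifiers = c("narrow", "medium", "wide",
                                            "bilayered", "trilayered"),
                            protocol = list(holdout = 0.5),
                            alpha = 0.05) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, data = data,
                 stages = stages, network = network, fusion = fusion,
                 selection = selection, classifiers = classifiers,
                 protocol = protocol, alpha = alpha),
            class = "pipeline_config")
}

#' Bundled demo configuration
#'
#' A reduced-budget, fully synthetic configuration that exercises every
#' stage in a few minutes on one CPU: 48 images (12 per modality) at
#' 32 x 32, width scale 1/8, a 64-wide autoencoder tap, and a selector
#' budget of 8 wolves with 10 + 6 iterations.
#'
#' @param seed Root seed.
#' @param out_dir Optional artifact directory.
#' @export
demo_pipeline_config <- function(seed = 1L, out_dir = NULL) {
  pipeline_config(
    seed = seed, out_dir = out_dir,
    selection = selection_config(population = 8L, gwo_iterations = 10L,
                                 jaya_iterations = 6L, hidden = 50L)
  )
}

pipeline_log <- function(state, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  state$log <- c(state$log, line)
  message(line)
  state
}

metrics_to_list <- function(rep) {
  list(confusion = unname(rep$confusion), accuracy = rep$accuracy,
       sensitivity = rep$sensitivity, fnr = rep$fnr,
       precision = rep$precision, auc = rep$auc,
       wall_time_s = rep$wall_time_s)
}

#' Run the pipeline
#'
#' Executes the enabled stages in order on synthetic or user data,
#' returning a consolidated report (dimensions, selection mask,
#' metrics per classifier preset and stage, the paired-t stage
#' comparison) and writing per-stage artifacts plus a JSON report and
#' a text log when `out_dir` is set. Identical config and seed give an
#' identical report.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  st <- list(log = character())
  seed <- cfg$seed
  on_stage <- function(nm) isTRUE(cfg$stages[[nm]])
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  report <- list(seed = seed, dims = list(), stages_run = character())
  feature_sets <- list()
  labels <- NULL
  images <- NULL
  resnet <- NULL

  # --- simulate / load -------------------------------------------------
  mode <- cfg$data$mode %||% "images"
  if (mode == "images") {
    st <- pipeline_log(st, "simulate: %d images per modality at %dx%d",
                       cfg$data$n_per_class, cfg$data$height,
                       cfg$data$width)
    images <- make_modality_images(cfg$data$n_per_class, cfg$data$height,
                                   cfg$data$width,
                                   seed = substream_seed(seed, 31L))
    labels <- images$labels
  } else if (mode == "features") {
    p <- cfg$data
    st <- pipeline_log(st, "simulate: %d x %d feature table",
                       p$n_samples,
                       p$n_informative + p$n_redundant + p$n_noise)
    fd <- make_feature_dataset(p$n_samples, p$n_classes %||% 4L,
                               p$n_informative, p$n_redundant, p$n_noise,
                               p$class_sep %||% 3,
                               seed = substream_seed(seed, 31L))
    feature_sets$features <- fd$x
    labels <- fd$y
  } else if (mode == "files") {
    st <- pipeline_log(st, "load: %s", cfg$data$features_csv)
    fd <- read_feature_csv(cfg$data$features_csv)
    feature_sets$features <- fd$x
    labels <- fd$y
  } else {
    stop("unknown data mode: ", mode)
  }
  report$stages_run <- c(report$stages_run, "simulate")

  # --- train + extract (image mode only) -------------------------------
  if (mode == "images" && on_stage("train")) {
    nw <- cfg$network
    tc <- train_config(optimizer = nw$optimizer %||% "adam",
                       max_epochs = nw$epochs %||% 3L,
                       minibatch = nw$minibatch %||% 16L,
                       learning_rate = nw$learning_rate %||% 0.002)
    shape <- dim(images$images)[1:3]
    st <- pipeline_log(st, "train: modified ResNet-50 (width scale %.3g)",
                       nw$width_scale)
    rspec <- build_modified_resnet50(shape, n_classes = 4L,
                                     width_scale = nw$width_scale)
    resnet <- train_network(rspec, images, tc,
                            seed = substream_seed(seed, 32L))
    st <- pipeline_log(st, "train: stacked autoencoder (tap width %d)",
                       nw$sae_feature_dim)
    sspec <- build_stacked_autoencoder(shape,
                                       feature_dim = nw$sae_feature_dim)
    sae <- train_network(sspec, images, tc,
                         seed = substream_seed(seed, 33L))
    report$stages_run <- c(report$stages_run, "train")

    if (on_stage("extract")) {
      fv1 <- extract_features(resnet, images, "gap")
      fv2 <- extract_features(sae, images, "decoder_conv_last")
      feature_sets$resnet <- fv1
      feature_sets$sae <- fv2
      report$dims$fv1 <- ncol(fv1); report$dims$fv2 <- ncol(fv2)
      st <- pipeline_log(st, "extract: fv1 %d features, fv2 %d features",
                         ncol(fv1), ncol(fv2))
      report$stages_run <- c(report$stages_run, "extract")
    }

    if (on_stage("explain")) {
      picks <- vapply(0:3, function(k) which(labels == k)[1], 0L)
      heatmaps <- lapply(picks, function(i) {
        explain_image(resnet, images$images[, , , i])
      })
      report$explain <- lapply(seq_along(heatmaps), function(j) {
        hm <- heatmaps[[j]]
        list(image = picks[j], class_index = hm$class_index,
             score = hm$score, map_shape = dim(hm$map))
      })
      if (!is.null(cfg$out_dir)) {
        for (j in seq_along(heatmaps)) {
          png::writePNG(heatmaps[[j]]$upsampled,
                        file.path(cfg$out_dir,
                                  sprintf("gradcam_%d.png", picks[j])))
        }
      }
      st <- pipeline_log(st, "explain: %d Grad-CAM maps", length(heatmaps))
      report$stages_run <- c(report$stages_run, "explain")
    }
  }

  # --- fuse ------------------------------------------------------------
  if (on_stage("fuse") && !is.null(feature_sets$resnet) &&
      !is.null(feature_sets$sae)) {
    fused <- fuse_features(feature_sets$resnet, feature_sets$sae,
                           cfg$fusion)
    feature_sets$fused <- fused
    report$dims$fused <- ncol(fused)
    st <- pipeline_log(st, "fuse: %d + %d -> %d features",
                       ncol(feature_sets$resnet), ncol(feature_sets$sae),
                       ncol(fused))
    report$stages_run <- c(report$stages_run, "fuse")
  }

  # --- select ----------------------------------------------------------
  sel_input <- feature_sets$fused %||% feature_sets$features
  if (on_stage("select") && !is.null(sel_input)) {
    sel <- select_features(sel_input, labels, cfg$selection,
                           seed = substream_seed(seed, 34L))
    feature_sets$selected <- sel_input[, sel$mask, drop = FALSE]
    report$dims$selected <- sel$n_selected
    report$selection <- list(
      n_selected = sel$n_selected, best_fitness = sel$best_fitness,
      mask = unname(sel$mask),
      feature_names = names(sel$mask) %||% character()
    )
    st <- pipeline_log(st, "select: %d/%d features, fitness %.4f",
                       sel$n_selected, ncol(sel_input), sel$best_fitness)
    if (!is.null(cfg$out_dir)) {
      jsonlite::write_json(
        list(mask = as.integer(sel$mask),
             feature_names = names(sel$mask) %||% character(),
             n_selected = sel$n_selected, seed = seed),
        file.path(cfg$out_dir, "mask.json"), auto_unbox = TRUE,
        digits = NA)
      utils::write.csv(
        data.frame(iteration = seq_along(sel$fitness_trace) - 1L,
                   best_fitness = sel$fitness_trace),
        file.path(cfg$out_dir, "fitness_trace.csv"), row.names = FALSE)
    }
    report$stages_run <- c(report$stages_run, "select")
  }

  # --- classify --------------------------------------------------------
  if (on_stage("classify")) {
    report$metrics <- list()
    for (set_name in names(feature_sets)) {
      report$metrics[[set_name]] <- list()
      for (preset in cfg$classifiers) {
        spec <- make_classifier_preset(preset)
        rep <- evaluate_classifier(feature_sets[[set_name]], labels,
                                   spec, cfg$protocol,
                                   seed = substream_seed(seed, 35L))
        report$metrics[[set_name]][[preset]] <- metrics_to_list(rep)
      }
      accs <- vapply(report$metrics[[set_name]], `[[`, 0, "accuracy")
      st <- pipeline_log(st, "classify [%s]: best %.1f%% (%s)", set_name,
                         max(accs), names(accs)[which.max(accs)])
    }
    report$stages_run <- c(report$stages_run, "classify")
  }

  # --- paired-t stage comparison --------------------------------------
  if (on_stage("ttest") && !is.null(report$metrics) &&
      length(report$metrics) >= 2) {
    acc_tab <- sapply(report$metrics, function(stage) {
      vapply(stage, `[[`, 0, "accuracy")
    })
    mean_acc <- rowMeans(acc_tab)
    best <- names(mean_acc)[which.max(mean_acc)]
    worst <- names(mean_acc)[which.min(mean_acc)]
    tt <- tryCatch(
      paired_difference_test(acc_tab[best, ], acc_tab[worst, ],
                             cfg$alpha),
      error = function(e) NULL)
    report$ttest <- if (is.null(tt)) {
      list(best = best, worst = worst,
           note = "statistic undefined (all paired differences equal)")
    } else {
      list(best = best, worst = worst, differences = tt$differences,
           mean = tt$mean, sd = tt$sd, t_selection = tt$t_selection,
           df = tt$df, critical = tt$critical,
           within_interval = tt$within_interval,
           decision = tt$decision_text)
    }
    st <- pipeline_log(st, "ttest: %s vs %s", best, worst)
    report$stages_run <- c(report$stages_run, "ttest")
  }

  # --- artifacts -------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    for (set_name in names(feature_sets)) {
      write_feature_csv(feature_sets[[set_name]], labels,
                        file.path(cfg$out_dir,
                                  paste0("features_", set_name, ".csv")))
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(st$log, file.path(cfg$out_dir, "pipeline.log"))
  }
  report$log <- st$log
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages:", paste(x$stages_run, collapse = " -> "),
      "\n")
  if (length(x$dims)) {
    cat("  dims:", paste(names(x$dims), unlist(x$dims), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}
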