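# Shared fixtures, built lazily once per test session. The trained
# networks are deliberately small (32 x 32 grayscale, width scale 1/8)
# so the whole suite stays desk-scale.

.fixtures <- new.env(parent = emptyenv())

sub_images <- function(ds, idx) {
  structure(list(images = ds$images[, , , idx, drop = FALSE],
                 labels = ds$labels[idx], class_names = ds$class_names,
                 mask = ds$mask, metadata = ds$metadata[idx, ]),
            class = "image_dataset")
}

# 160 synthetic modality images with a 75:25 split and a CNN trained on
# the training portion.
cnn_fixture <- function() {
  if (!is.null(.fixtures$cnn)) return(.fixtures$cnn)
  ds <- make_modality_images(40, 32, 32, seed = 3)
  tr <- neurofusion:::stratified_train_indices(ds$labels, 0.75, 42)
  te <- setdiff(seq_along(ds$labels), tr)
  spec <- build_modified_resnet50(c(32L, 32L, 1L), 4L, 0.125)
  cfg <- train_config(optimizer = "adam", max_epochs = 12L,
                      minibatch = 20L, learning_rate = 0.003)
  model <- train_network(spec, sub_images(ds, tr), cfg, seed = 5)
  .fixtures$cnn <- list(data = ds, train_idx = tr, test_idx = te,
                        model = model)
  .fixtures$cnn
}

# Stacked autoencoder trained on a smaller image subset.
sae_fixture <- function() {
  if (!is.null(.fixtures$sae)) return(.fixtures$sae)
  ds <- make_modality_images(12, 32, 32, seed = 4)
  spec <- build_stacked_autoencoder(c(32L, 32L, 1L), feature_dim = 64L)
  cfg <- train_config(optimizer = "adam", max_epochs = 4L,
                      minibatch = 16L, learning_rate = 0.002)
  model <- train_network(spec, ds, cfg, seed = 6)
  .fixtures$sae <- list(data = ds, model = model)
  .fixtures$sae
}

# The standard synthetic selection matrix: 300 samples, 4 classes,
# 5 informative + 5 redundant + 40 noise columns, separation 3.
std_selection_data <- function(seed) {
  make_feature_dataset(300, 4, 5, 5, 40, 3, seed = seed)
}

reduced_selection_config <- function() {
  selection_config(population = 15L, gwo_iterations = 30L,
                   jaya_iterations = 20L)
}
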