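# Shared fixtures. Corpora and fitted models are expensive, so they are
# built lazily once per test run and cached; every consumer sees the same
# seeded objects. Sizes follow the package's desk-scale experiment
# profile: 300-patch corpora of 128 px patches and a depth-4 / 8-filter
# U-Net trained for 10 epochs.

.fixtures <- new.env()

desk_unet_config <- function() {
  unet_config(depth = 4, base_filters = 8, max_filters = 64,
              input_size = c(128L, 128L))
}

desk_train_config <- function(partition = "100:0") {
  train_config(epochs = 10L, batch_size = 2L, learning_rate = 0.002,
               seed = 31L, partition = partition)
}

# 300 ideal patches, used for the parameter-recovery experiment.
fixture_corpus_ideal <- function() {
  if (is.null(.fixtures$corpus_ideal)) {
    dir <- file.path(tempdir(), "ki67pi-fixture-corpus-ideal")
    if (!file.exists(file.path(dir, "index.csv"))) {
      render_corpus(dir, 300, ideal_fraction = 1, width = 128,
                    height = 128, seed = 11)
    }
    .fixtures$corpus_ideal <- read_corpus(dir)
  }
  .fixtures$corpus_ideal
}

# 150 ideal + 150 non-ideal patches, used for the data-partition
# experiment.
fixture_corpus_mixed <- function() {
  if (is.null(.fixtures$corpus_mixed)) {
    dir <- file.path(tempdir(), "ki67pi-fixture-corpus-mixed")
    if (!file.exists(file.path(dir, "index.csv"))) {
      render_corpus(dir, 300, ideal_fraction = 0.5, width = 128,
                    height = 128, seed = 12)
    }
    .fixtures$corpus_mixed <- read_corpus(dir)
  }
  .fixtures$corpus_mixed
}

# Small corpus for fast training-contract tests.
fixture_corpus_small <- function() {
  if (is.null(.fixtures$corpus_small)) {
    dir <- file.path(tempdir(), "ki67pi-fixture-corpus-small")
    if (!file.exists(file.path(dir, "index.csv"))) {
      render_corpus(dir, 12, ideal_fraction = 1, width = 64, height = 64,
                    n_nuclei_ideal = c(10L, 20L), seed = 13)
    }
    .fixtures$corpus_small <- read_corpus(dir)
  }
  .fixtures$corpus_small
}

# Main desk-scale fit: RMSE loss on the ideal corpus.
fixture_fit_main <- function() {
  if (is.null(.fixtures$fit_main)) {
    .fixtures$fit_main <- train_unet(
      build_unet(desk_unet_config(), seed = 21),
      fixture_corpus_ideal(),
      loss = loss_config("rmse"),
      control = desk_train_config("100:0"))
  }
  .fixtures$fit_main
}

# Pair of fits for the weak-supervision comparison: identical seeds and
# epochs, differing only in the ideal:non-ideal partition.
fixture_fits_partition <- function() {
  if (is.null(.fixtures$fits_partition)) {
    .fixtures$fits_partition <- lapply(
      setNames(c("100:0", "50:50"), c("100:0", "50:50")),
      function(part) {
        train_unet(build_unet(desk_unet_config(), seed = 21),
                   fixture_corpus_mixed(),
                   loss = loss_config("rmse"),
                   control = desk_train_config(part))
      })
  }
  .fixtures$fits_partition
}

# Synthetic pyramid slide with one off-centre tissue disc.
fixture_slide <- function() {
  if (is.null(.fixtures$slide)) {
    dir <- file.path(tempdir(), "ki67pi-fixture-slide")
    spec <- synthetic_slide_spec(
      2048, 2048, pyramid_factor = 4, n_levels = 3,
      tissue_regions = list(list(center = c(1000, 1100), radius = 700)),
      target_pi = 30, seed = 5)
    if (!file.exists(file.path(dir, "manifest.json"))) {
      build_synthetic_slide(spec, dir)
    }
    .fixtures$slide <- list(manifest = file.path(dir, "manifest.json"),
                            spec = spec, dir = dir)
  }
  .fixtures$slide
}

# Held-out evaluation of a fit on its own test subset: per-class mean F1
# and the manual/automatic PI vectors.
evaluate_fit_on_test <- function(fit, corpus) {
  rows <- match(fit$splits$path[fit$splits$subset == "test"], corpus$path)
  f1 <- matrix(NA_real_, length(rows), 2,
               dimnames = list(NULL, c("pos", "neg")))
  gt_pi <- numeric(length(rows)); auto_pi <- numeric(length(rows))
  for (j in seq_along(rows)) {
    p <- read_patch(corpus, rows[j])
    sc <- score_patch(fit, p$image)
    ev <- evaluate_detections(p$annotations, sc$detections)
    f1[j, ] <- ev$f1
    gt <- table(factor(p$annotations$class, c("pos", "neg")))
    gt_pi[j] <- 100 * gt[["pos"]] / sum(gt)
    auto_pi[j] <- sc$pi$pi
  }
  list(f1_pos = mean(f1[, "pos"]), f1_neg = mean(f1[, "neg"]),
       gt_pi = gt_pi, auto_pi = auto_pi)
}
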