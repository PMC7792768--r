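test_that("patch specs validate their invariants", {
  expect_error(patch_spec(ideal = TRUE, artifacts = "fold"),
               class = "ki67pi_contract_error")
  expect_error(patch_spec(artifacts = "glitter", ideal = FALSE),
               class = "ki67pi_contract_error")
  expect_equal(patch_spec(n_positive = 10, n_negative = 30)$target_pi, 25)
  expect_true(is.na(patch_spec()$target_pi))
})

test_that("rendering is deterministic and annotations match the spec", {
  spec <- patch_spec(96, 96, n_positive = 5, n_negative = 15, seed = 42)
  a <- render_patch(spec)
  b <- render_patch(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  expect_equal(nrow(a$annotations), 20)
  expect_equal(sum(a$annotations$class == "pos"), 5)
  # annotation PI equals the count ratio
  expect_equal(compute_pi(5, 15)$pi, 25)

  # empty case
  e <- render_patch(patch_spec(64, 64, seed = 1))
  expect_equal(nrow(e$annotations), 0)
  expect_equal(dim(e$image), c(64, 64, 3))
})

test_that("annotated centres sit on nucleus-coloured pixels", {
  base <- list(pos = c(120, 70, 20), neg = c(60, 60, 140))
  for (seed in 1:5) {
    p <- render_patch(patch_spec(128, 128, n_positive = 8,
                                 n_negative = 24, seed = seed))
    ann <- p$annotations
    for (i in seq_len(nrow(ann))) {
      px <- p$image[ann$y[i] + 1, ann$x[i] + 1, ]
      d <- sqrt(sum((px - base[[ann$class[i]]])^2))
      expect_lt(d, 60)
    }
    # centres respect the margin and minimum separation
    expect_true(all(ann$x >= 4 & ann$x <= 123 & ann$y >= 4 & ann$y <= 123))
    dmat <- as.matrix(dist(ann[, c("x", "y")]))
    diag(dmat) <- Inf
    expect_gte(min(dmat), 6)
  }
})

test_that("a crowded spec fails with a placement error", {
  expect_error(render_patch(patch_spec(48, 48, n_positive = 200,
                                       n_negative = 200, seed = 1)),
               class = "ki67pi_placement_error")
})

test_that("fold artifact draws a dark streak and carries no annotations", {
  spec <- patch_spec(128, 128, ideal = FALSE, artifacts = "fold", seed = 9)
  p <- render_patch(spec)
  expect_equal(nrow(p$annotations), 0)
  lum <- apply(p$image, c(1, 2), mean)
  bg <- mean(c(235, 220, 225))
  # a substantial set of pixels is much darker than the background
  expect_gt(sum(lum < bg - 60), 200)
})

test_that("corpus honours ideal fraction, strata and determinism", {
  dir1 <- withr::local_tempdir()
  idx <- render_corpus(dir1, 6, ideal_fraction = 0.5, width = 64,
                       height = 64, n_nuclei_ideal = c(10, 20), seed = 3)
  expect_equal(sum(idx$ideal), 3)
  expect_equal(sum(!idx$ideal), 3)
  expect_true(all(file.exists(file.path(dir1, idx$path))))

  dir2 <- withr::local_tempdir()
  idx2 <- render_corpus(dir2, 30, ideal_fraction = 0.5, width = 64,
                        height = 64, n_nuclei_ideal = c(10, 20), seed = 4)
  expect_equal(as.integer(table(idx2$stratum)[c("Low", "Medium", "High")]),
               c(10L, 10L, 10L))
  # stratum labels are consistent with the recorded ground-truth PI
  expect_equal(classify_pi_range(idx2$gt_pi), idx2$stratum)

  dir3 <- withr::local_tempdir()
  render_corpus(dir3, 6, ideal_fraction = 0.5, width = 64, height = 64,
                n_nuclei_ideal = c(10, 20), seed = 3)
  expect_identical(readBin(file.path(dir1, "index.csv"), "raw", 1e5),
                   readBin(file.path(dir3, "index.csv"), "raw", 1e5))
  f <- idx$path[1]
  expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                   readBin(file.path(dir3, f), "raw", 1e6))
})

test_that("patch PNG/CSV round-trips reproduce the rendered objects", {
  dir <- withr::local_tempdir()
  idx <- render_corpus(dir, 2, ideal_fraction = 1, width = 64, height = 64,
                       n_nuclei_ideal = c(8, 12), seed = 6)
  idx <- read_corpus(dir)
  p <- read_patch(idx, 1)
  expect_equal(dim(p$image), c(64, 64, 3))
  expect_true(all(p$image >= 0 & p$image <= 255))
  expect_true(all(p$annotations$class %in% c("pos", "neg")))
})

test_that("slide specs validate and pyramids have floor-divided dims", {
  spec <- synthetic_slide_spec(4096, 4096, pyramid_factor = 4, n_levels = 3)
  expect_equal(vapply(spec$level_dims, `[[`, numeric(1), "w"),
               c(4096, 1024, 256))
  expect_error(synthetic_slide_spec(256, 256, pyramid_factor = 4,
                                    n_levels = 4),
               class = "ki67pi_contract_error")
  expect_error(
    synthetic_slide_spec(1024, 1024, tissue_regions = list(
      list(center = c(1000, 512), radius = 100))),
    class = "ki67pi_contract_error")
})

test_that("slide rendering matches its tissue geometry and ground truth", {
  dir <- withr::local_tempdir()
  # disc covering ~10% of the slide area; the lowest level is 16x
  # downsampled, coarse enough that individual nuclei wash out of the
  # low-resolution histogram (as in real pyramids)
  r <- round(sqrt(0.1 * 2048^2 / pi))
  spec <- synthetic_slide_spec(2048, 2048, pyramid_factor = 4,
    n_levels = 3,
    tissue_regions = list(list(center = c(1024, 1024), radius = r)),
    target_pi = 25, seed = 8)
  mp <- build_synthetic_slide(spec, dir)
  man <- read_slide_manifest(mp)
  expect_equal(man$levels$downsample, c(1, 4, 16))
  lr <- extract_lowres(man)
  tm <- tissue_mask(lr$image)
  frac <- mean(tm$mask)
  expect_lt(abs(frac - 0.1), 0.02)

  ann <- read_annotations(file.path(dir, "annotations.csv"))
  expect_gt(nrow(ann), 0)
  cls <- table(factor(ann$class, c("pos", "neg")))
  expect_lt(abs(100 * cls[["pos"]] / sum(cls) - 25), 2)

  # no tissue regions -> all-white slide, empty annotations
  dir2 <- withr::local_tempdir()
  mp2 <- build_synthetic_slide(
    synthetic_slide_spec(256, 256, pyramid_factor = 2, n_levels = 2,
                         seed = 9), dir2)
  ann2 <- read_annotations(file.path(dir2, "annotations.csv"))
  expect_equal(nrow(ann2), 0)
  lvl0 <- png::readPNG(file.path(dir2, "level_0.png")) * 255
  expect_gt(min(lvl0), 230)
})
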