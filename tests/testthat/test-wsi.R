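local_small_slide <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  spec <- synthetic_slide_spec(
    1024, 1024, pyramid_factor = 4, n_levels = 3,
    tissue_regions = list(list(center = c(500, 540), radius = 350)),
    target_pi = 20, seed = 17)
  list(manifest = build_synthetic_slide(spec, dir), spec = spec,
       dir = dir)
}

test_that("manifests resolve levels and report missing fields", {
  s <- local_small_slide()
  man <- read_slide_manifest(s$manifest)
  expect_equal(man$levels$downsample, c(1, 4, 16))
  lr <- extract_lowres(man)
  expect_equal(lr$level, 2L)
  expect_equal(lr$downsample, 16)
  expect_equal(dim(lr$image)[1:2], c(64, 64))

  # single-level "pyramid"
  dir <- withr::local_tempdir()
  png::writePNG(array(1, c(16, 16, 3)), file.path(dir, "only.png"))
  jsonlite::write_json(list(levels = list(list(
    path = "only.png", width = 16, height = 16, downsample = 1))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  man1 <- read_slide_manifest(file.path(dir, "manifest.json"))
  expect_equal(extract_lowres(man1)$downsample, 1)

  # corrupt manifest names the missing field
  jsonlite::write_json(list(levels = list(list(path = "only.png",
                                               width = 16))),
                       file.path(dir, "bad.json"), auto_unbox = TRUE)
  expect_error(read_slide_manifest(file.path(dir, "bad.json")),
               "height|downsample", class = "ki67pi_io_error")
})

test_that("the tissue mask recovers the analytic disc", {
  s <- local_small_slide()
  man <- read_slide_manifest(s$manifest)
  lr <- extract_lowres(man)
  tm <- tissue_mask(lr$image)
  f <- lr$downsample
  n <- dim(tm$mask)[1]
  ctr <- (seq_len(n) - 1) * f + (f - 1) / 2
  disc <- outer((ctr - 540)^2, (ctr - 500)^2, "+") <= 350^2
  iou <- sum(tm$mask & disc) / sum(tm$mask | disc)
  expect_gte(iou, 0.95)
  expect_lte(sum(tm$mask), length(tm$mask))

  # all-white slide: empty mask with a warning
  white <- array(255, c(32, 32, 3))
  expect_warning(tmw <- tissue_mask(white), "constant")
  expect_false(any(tmw$mask))
})

test_that("tiling covers the mask, round-trips crops and pads borders", {
  s <- local_small_slide()
  man <- read_slide_manifest(s$manifest)
  tm <- tissue_mask(extract_lowres(man)$image)
  tg <- tile_slide(tm, man)
  expect_true(any(tg$grid$tissue))

  img0 <- png::readPNG(file.path(s$dir, "level_0.png")) * 255
  for (nm in names(tg$tiles)) {
    xy <- as.integer(strsplit(sub("tile_", "", nm), "_")[[1]])
    crop <- img0[(xy[2] + 1):min(xy[2] + 256, 1024),
                 (xy[1] + 1):min(xy[1] + 256, 1024), , drop = FALSE]
    expect_identical(tg$tiles[[nm]][seq_len(dim(crop)[1]),
                                    seq_len(dim(crop)[2]), ],
                     crop)
    # padded remainder (if any) is white
    if (dim(crop)[1] < 256) {
      expect_true(all(tg$tiles[[nm]][(dim(crop)[1] + 1):256, , ] == 255))
    }
  }

  # coverage completeness is exact when any overlap flags a tile, and the
  # default 10% rule may only drop boundary slivers
  f <- tg$downsample
  fg <- which(tm$mask, arr.ind = TRUE)
  key <- paste(floor((fg[, 2] - 1) * f / 256) * 256,
               floor((fg[, 1] - 1) * f / 256) * 256)
  tg_any <- tile_slide(tm, man, min_tissue = 1e-9, extract = FALSE)
  flagged_any <- paste(tg_any$grid$x[tg_any$grid$tissue],
                       tg_any$grid$y[tg_any$grid$tissue])
  expect_true(all(key %in% flagged_any))
  flagged <- paste(tg$grid$x[tg$grid$tissue], tg$grid$y[tg$grid$tissue])
  expect_gte(mean(key %in% flagged), 0.98)

  # empty mask -> zero tiles
  tm0 <- list(mask = matrix(FALSE, 64, 64), threshold = NA)
  expect_equal(sum(tile_slide(tm0, man, extract = FALSE)$grid$tissue), 0)
})

test_that("flagged tiles track the analytic disc area", {
  s <- fixture_slide()
  man <- read_slide_manifest(s$manifest)
  tm <- tissue_mask(extract_lowres(man)$image)
  disc_area <- pi * s$spec$tissue_regions[[1]]$radius^2
  # the tissue footprint inside flagged tiles matches the disc area
  tg <- tile_slide(tm, man, extract = FALSE)
  f <- tg$downsample
  fg <- which(tm$mask, arr.ind = TRUE)
  tile_key <- paste(floor((fg[, 2] - 1) * f / 256) * 256,
                    floor((fg[, 1] - 1) * f / 256) * 256)
  flagged <- paste(tg$grid$x[tg$grid$tissue], tg$grid$y[tg$grid$tissue])
  covered <- sum(tile_key %in% flagged) * f^2
  expect_lt(abs(covered - disc_area) / disc_area, 0.15)
  # at a balanced tissue threshold the flagged-tile count itself matches
  # the disc area in tile units (the permissive 10% default deliberately
  # over-flags boundary tiles so edge tissue is analysed)
  tg50 <- tile_slide(tm, man, min_tissue = 0.5, extract = FALSE)
  expect_lt(abs(sum(tg50$grid$tissue) - disc_area / 256^2) /
            (disc_area / 256^2), 0.15)
})

test_that("per-tile counts aggregate annotations for the hotspot rule", {
  s <- local_small_slide()
  man <- read_slide_manifest(s$manifest)
  tm <- tissue_mask(extract_lowres(man)$image)
  tg <- tile_slide(tm, man, extract = FALSE)
  ann <- read_annotations(file.path(s$dir, "annotations.csv"))
  pc <- tile_counts_from_annotations(tg, ann)
  # near-complete coverage: the 10% rule may drop a boundary sliver tile
  # holding at most a handful of edge nuclei
  expect_gte((sum(pc$pos) + sum(pc$neg)) / nrow(ann), 0.995)
  hs <- wsi_hotspot_pi(pc[, c("id", "pos", "neg")])
  gt <- table(factor(ann$class, c("pos", "neg")))
  expect_lt(abs(hs$pi$pi - 100 * gt[["pos"]] / sum(gt)), 2)
})
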