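# Whole-slide preprocessing: read the pyramid manifest, mask tissue at the
# lowest resolution and tile candidate regions at level 0.

#' Read and validate a pyramid slide manifest
#'
#' @param path Path to a `manifest.json` written by
#'   [build_synthetic_slide()] (or any manifest listing
#'   `levels[{path,width,height,downsample}]`).
#' @return A list with `levels` (data frame) and `dir`.
#' @export
read_slide_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_ki67("manifest '%s' not found", path, class = "ki67pi_io_error")
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- m$levels
  if (is.null(lv)) {
    stop_ki67("manifest '%s' is missing the 'levels' field", path,
              class = "ki67pi_io_error")
  }
  lv <- as.data.frame(lv)
  for (field in c("path", "width", "height", "downsample")) {
    if (is.null(lv[[field]])) {
      stop_ki67("manifest '%s' levels are missing the '%s' field", path,
                field, class = "ki67pi_io_error")
    }
  }
  list(levels = lv[order(lv$downsample), , drop = FALSE],
       dir = dirname(path))
}

read_level <- function(manifest, i) {
  p <- file.path(manifest$dir, manifest$levels$path[i])
  if (!file.exists(p)) {
    stop_ki67("pyramid level image '%s' not found", p,
              class = "ki67pi_io_error")
  }
  png::readPNG(p) * 255
}

#' Extract the lowest-resolution pyramid level
#'
#' @param manifest A manifest from [read_slide_manifest()].
#' @return A list with `image` (0-255 RGB array), `level` (0-based level
#'   index) and `downsample` (factor to level 0).
#' @export
extract_lowres <- function(manifest) {
  i <- which.max(manifest$levels$downsample)
  list(image = read_level(manifest, i), level = i - 1L,
       downsample = manifest$levels$downsample[i])
}

#' Tissue mask by Otsu thresholding of the red channel
#'
#' On bright-field slides tissue absorbs light, so at low resolution the
#' tissue is the dark class of the red channel: the mask keeps pixels
#' whose red value is below the Otsu threshold. Objects smaller than
#' `min_object_frac` of the level area (default 0.01%) are removed as
#' debris.
#'
#' @param lowres A 0-255 RGB array (typically from [extract_lowres()]).
#' @param min_object_frac Minimum object area as a fraction of the level
#'   area.
#' @return A list with `mask` (logical matrix), `threshold`, and the
#'   original `dim`. A constant red channel yields an empty mask with a
#'   warning.
#' @export
tissue_mask <- function(lowres, min_object_frac = 1e-4) {
  assert_rgb_image(lowres, "low-resolution slide image")
  red <- lowres[, , 1]
  thr <- tryCatch(otsu_threshold(red), ki67pi_degenerate_error = function(e) {
    warning("constant red channel: empty tissue mask")
    NA_real_
  })
  if (is.na(thr)) {
    return(list(mask = matrix(FALSE, nrow(red), ncol(red)), threshold = NA))
  }
  mask <- red < thr
  min_px <- ceiling(min_object_frac * length(red))
  if (any(mask) && min_px > 1) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_px)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  list(mask = mask, threshold = thr)
}

#' Tile a slide's tissue regions at level 0
#'
#' Lays a regular non-overlapping grid of `tile`-pixel tiles over level 0,
#' flags a tile as tissue when at least `min_tissue` of its footprint maps
#' to mask foreground at the low-resolution level, and extracts the
#' flagged tiles. Border tiles are padded to full size with white; reads
#' beyond the level-0 bounds are clipped and padded, never an error.
#'
#' @param mask A tissue mask from [tissue_mask()].
#' @param manifest A manifest from [read_slide_manifest()].
#' @param tile Tile side in pixels (level 0).
#' @param min_tissue Minimum tissue fraction of a tile's footprint.
#' @param downsample The mask's downsample factor to level 0 (defaults to
#'   the manifest's lowest-resolution level).
#' @param extract If `FALSE`, only the grid is computed.
#' @return A list with `grid` (data frame `x`, `y`, `tissue`; level-0 tile
#'   origins) and `tiles` (named list `tile_<x>_<y>` of 0-255 RGB arrays
#'   for tissue tiles; `NULL` unless `extract`).
#' @export
tile_slide <- function(mask, manifest, tile = 256L, min_tissue = 0.1,
                       downsample = NULL, extract = TRUE) {
  if (is.null(downsample)) {
    downsample <- max(manifest$levels$downsample)
  }
  m <- mask$mask
  lvl0 <- manifest$levels[manifest$levels$downsample == 1, ]
  w0 <- lvl0$width[1]; h0 <- lvl0$height[1]
  ox <- seq(0L, max(0L, w0 - 1L), by = tile)
  oy <- seq(0L, max(0L, h0 - 1L), by = tile)
  grid <- expand.grid(x = ox, y = oy)
  # fraction of each tile footprint covered by mask foreground
  frac <- vapply(seq_len(nrow(grid)), function(i) {
    x0 <- grid$x[i]; y0 <- grid$y[i]
    cs <- floor(x0 / downsample):floor((min(x0 + tile, w0) - 1) / downsample)
    rs <- floor(y0 / downsample):floor((min(y0 + tile, h0) - 1) / downsample)
    cs <- cs[cs >= 0 & cs < ncol(m)] + 1L
    rs <- rs[rs >= 0 & rs < nrow(m)] + 1L
    if (!length(cs) || !length(rs)) return(0)
    mean(m[rs, cs, drop = FALSE])
  }, numeric(1))
  grid$tissue <- frac >= min_tissue
  tiles <- NULL
  if (extract && any(grid$tissue)) {
    img0 <- read_level(manifest, which(manifest$levels$downsample == 1))
    tiles <- lapply(which(grid$tissue), function(i) {
      extract_tile(img0, grid$x[i], grid$y[i], tile)
    })
    names(tiles) <- sprintf("tile_%d_%d", grid$x[grid$tissue],
                            grid$y[grid$tissue])
  }
  list(grid = grid, tiles = tiles, tile = tile, downsample = downsample)
}

# Crop a tile at level-0 origin (x0, y0), padding with white to full size.
extract_tile <- function(img0, x0, y0, tile) {
  h <- dim(img0)[1]; w <- dim(img0)[2]
  out <- array(255, c(tile, tile, 3))
  rs <- (y0 + 1):min(y0 + tile, h)
  cs <- (x0 + 1):min(x0 + tile, w)
  if (length(rs) > 0 && length(cs) > 0 && y0 < h && x0 < w) {
    out[seq_along(rs), seq_along(cs), ] <- img0[rs, cs, , drop = FALSE]
  }
  out
}

#' Per-tile nucleus counts from level-0 annotations
#'
#' Assigns each annotated nucleus to the tile containing its centre and
#' returns the per-tile class counts for the tissue-flagged tiles — the
#' `patch_counts` input of [wsi_hotspot_pi()].
#'
#' @param grid A tile grid from [tile_slide()].
#' @param annotations Level-0 annotation data frame.
#' @param tile Tile side in pixels.
#' @return A data frame `id`, `x`, `y`, `pos`, `neg` (tissue tiles only).
#' @export
tile_counts_from_annotations <- function(grid, annotations, tile = 256L) {
  g <- grid$grid
  if (is.null(g)) g <- grid
  tx <- floor(annotations$x / tile) * tile
  ty <- floor(annotations$y / tile) * tile
  key <- paste(tx, ty)
  gkey <- paste(g$x, g$y)
  out <- g[g$tissue, c("x", "y"), drop = FALSE]
  okey <- paste(out$x, out$y)
  out$pos <- vapply(okey, function(k) {
    sum(key == k & annotations$class == "pos")
  }, numeric(1))
  out$neg <- vapply(okey, function(k) {
    sum(key == k & annotations$class == "neg")
  }, numeric(1))
  data.frame(id = sprintf("tile_%d_%d", out$x, out$y), out,
             row.names = NULL, stringsAsFactors = FALSE)
}
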