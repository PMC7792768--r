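# Synthetic whole-slide pyramids: per-level PNG images plus a JSON
# manifest, emulating the multi-resolution layout of scanner formats with
# bit-exact, dependency-free files.

#' Specification of a synthetic pyramid slide
#'
#' @param level0_width,level0_height Level-0 (full resolution) size in
#'   pixels.
#' @param pyramid_factor Integer downsample factor between levels (>= 2).
#' @param n_levels Number of pyramid levels (>= 2); level `L` has
#'   dimensions `floor(level0 / pyramid_factor^L)`, and every level must
#'   remain at least 16 px on each side.
#' @param tissue_regions List of tissue discs, each
#'   `list(center = c(x, y), radius = r)` in level-0 pixel coordinates
#'   and lying inside the level-0 bounds. An empty list gives an all-white
#'   slide.
#' @param target_pi Ki67+ percentage of the nuclei rendered in every
#'   tissue region.
#' @param nucleus_spacing Centre grid spacing (pixels) of the jittered
#'   nucleus layout inside tissue regions.
#' @param nucleus_radius_range Min/max nucleus semi-axis in pixels.
#' @param seed Integer seed.
#' @return An object of class `slide_spec`.
#' @export
synthetic_slide_spec <- function(level0_width, level0_height,
                                 pyramid_factor = 4L, n_levels = 3L,
                                 tissue_regions = list(),
                                 target_pi = 20,
                                 nucleus_spacing = 12,
                                 nucleus_radius_range = c(4, 6),
                                 seed = 1L) {
  stopifnot(pyramid_factor >= 2, n_levels >= 2,
            target_pi >= 0, target_pi <= 100)
  dims <- lapply(0:(n_levels - 1), function(L) {
    c(w = floor(level0_width / pyramid_factor^L),
      h = floor(level0_height / pyramid_factor^L))
  })
  if (any(vapply(dims, min, numeric(1)) < 16)) {
    stop_ki67("pyramid level smaller than 16 px: reduce n_levels or factor",
              class = "ki67pi_contract_error")
  }
  for (reg in tissue_regions) {
    stopifnot(length(reg$center) == 2, reg$radius > 0)
    if (reg$center[1] - reg$radius < 0 ||
        reg$center[1] + reg$radius > level0_width - 1 ||
        reg$center[2] - reg$radius < 0 ||
        reg$center[2] + reg$radius > level0_height - 1) {
      stop_ki67("tissue region at (%g, %g) exceeds level-0 bounds",
                reg$center[1], reg$center[2],
                class = "ki67pi_contract_error")
    }
  }
  structure(list(level0_width = as.integer(level0_width),
                 level0_height = as.integer(level0_height),
                 pyramid_factor = as.integer(pyramid_factor),
                 n_levels = as.integer(n_levels),
                 tissue_regions = tissue_regions,
                 target_pi = target_pi,
                 nucleus_spacing = nucleus_spacing,
                 nucleus_radius_range = as.numeric(nucleus_radius_range),
                 seed = as.integer(seed), level_dims = dims),
            class = "slide_spec")
}

# Mean over f x f blocks of a matrix, cropping to a whole number of blocks.
block_mean <- function(m, f, out_h, out_w) {
  m <- m[seq_len(out_h * f), seq_len(out_w * f), drop = FALSE]
  m <- rowsum(m, rep(seq_len(out_h), each = f)) / f
  t(rowsum(t(m), rep(seq_len(out_w), each = f)) / f)
}

#' Build a synthetic pyramid slide on disk
#'
#' Renders the level-0 image (near-white glass background, pale pink
#' tissue discs filled with brown/blue nuclei at the requested PI), then
#' derives each coarser level by block averaging. Writes one PNG per level,
#' a JSON manifest (`manifest.json` listing
#' `levels[{path,width,height,downsample}]`) and the ground-truth
#' annotation CSV `annotations.csv` in level-0 coordinates. Nuclei centres
#' are laid out on a jittered grid inside each tissue disc, preserving the
#' minimum separation the patch generator guarantees.
#'
#' @param spec A [synthetic_slide_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
build_synthetic_slide <- function(spec, out_dir) {
  stopifnot(inherits(spec, "slide_spec"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop_ki67("cannot create output directory '%s'", out_dir,
              class = "ki67pi_io_error")
  }
  w <- spec$level0_width; h <- spec$level0_height
  with_seed(spec$seed, {
    glass <- 250
    img <- array(glass, c(h, w, 3))
    img <- img + array(rnorm(h * w * 3, 0, 1.5), c(h, w, 3))
    anns <- list()

    tissue_col <- c(228, 205, 215)
    for (reg in spec$tissue_regions) {
      cx <- reg$center[1]; cy <- reg$center[2]; r <- reg$radius
      rows <- max(1, floor(cy + 1 - r)):min(h, ceiling(cy + 1 + r))
      cols <- max(1, floor(cx + 1 - r)):min(w, ceiling(cx + 1 + r))
      d2 <- outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, "+")
      inside <- which(d2 <= r^2, arr.ind = TRUE)
      px <- cbind(row = rows[inside[, 1]], col = cols[inside[, 2]])
      img <- blend_pixels(img, px, tissue_col)

      # jittered-grid nucleus layout inside the disc
      s <- spec$nucleus_spacing
      margin <- spec$nucleus_radius_range[2] + 1
      gx <- seq(cx - r + margin, cx + r - margin, by = s)
      gy <- seq(cy - r + margin, cy + r - margin, by = s)
      cand <- expand.grid(x = gx, y = gy)
      cand <- cand[(cand$x - cx)^2 + (cand$y - cy)^2 <= (r - margin)^2, ]
      if (nrow(cand) == 0) next
      jit <- s / 2 - spec$nucleus_radius_range[2] / 2
      jit <- max(min(jit, 1.5), 0)
      cand$x <- round(cand$x + runif(nrow(cand), -jit, jit))
      cand$y <- round(cand$y + runif(nrow(cand), -jit, jit))
      n <- nrow(cand)
      n_pos <- round(spec$target_pi / 100 * n)
      classes <- sample(rep(c("pos", "neg"), c(n_pos, n - n_pos)))
      rr <- spec$nucleus_radius_range
      # batch all nucleus pixels into one assignment per channel: painting
      # thousands of ellipses one by one would copy the level-0 array each
      # time
      idx_all <- vector("list", n)
      col_all <- vector("list", n)
      for (i in seq_len(n)) {
        r1 <- runif(1, rr[1], rr[2]); r2 <- runif(1, rr[1], rr[2])
        col <- KI67_COLORS[[classes[i]]] + runif(3, -20, 20)
        epx <- ellipse_pixels(h, w, cand$x[i], cand$y[i],
                              max(r1, r2), min(r1, r2), runif(1, 0, pi))
        idx_all[[i]] <- epx[, 1] + (epx[, 2] - 1) * h
        col_all[[i]] <- matrix(col, nrow(epx), 3, byrow = TRUE)
      }
      li <- unlist(idx_all)
      cols <- do.call(rbind, col_all)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[li] <- cols[, ch]        # later nuclei overwrite earlier
        img[, , ch] <- plane
      }
      anns[[length(anns) + 1]] <- annotation_df(cand$x, cand$y, classes)
    }
    img <- pmin(pmax(img, 0), 255)

    levels <- list()
    for (L in 0:(spec$n_levels - 1)) {
      d <- spec$level_dims[[L + 1]]
      lev <- if (L == 0) img else {
        f <- spec$pyramid_factor^L
        out <- array(0, c(d[["h"]], d[["w"]], 3))
        for (ch in 1:3) {
          out[, , ch] <- block_mean(img[, , ch], f, d[["h"]], d[["w"]])
        }
        out
      }
      path <- sprintf("level_%d.png", L)
      png::writePNG(lev / 255, file.path(out_dir, path))
      levels[[L + 1]] <- list(path = path,
                              width = unname(d[["w"]]),
                              height = unname(d[["h"]]),
                              downsample = spec$pyramid_factor^L)
    }

    ann <- if (length(anns)) do.call(rbind, anns) else annotation_df()
    write_annotations(ann, file.path(out_dir, "annotations.csv"))
    manifest <- list(levels = levels,
                     channels = list(pos = 1, neg = 2),
                     annotations = "annotations.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(file.path(out_dir, "manifest.json"))
  })
}
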