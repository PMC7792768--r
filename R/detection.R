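#' Otsu threshold of a real-valued map
#'
#' Histogram-based threshold maximising between-class variance, computed
#' over a 256-bin histogram spanning the map's value range. Used both to
#' binarise prediction channels and (on the red channel) to mask tissue at
#' low resolution.
#'
#' @param values Numeric vector, matrix or array with at least two
#'   distinct values.
#' @param levels Number of histogram bins.
#' @return The threshold scalar, strictly inside the value range.
#' @examples
#' x <- c(rep(0.1, 50), rep(0.9, 50))
#' th <- otsu_threshold(x)
#' th > 0.1 && th < 0.9  # TRUE
#' @export
otsu_threshold <- function(values, levels = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    stop_ki67("Otsu threshold undefined: map is constant",
              class = "ki67pi_degenerate_error")
  }
  EBImage::otsu(matrix(v, ncol = 1), range = rng, levels = levels)
}

#' Separate and locate objects in a binary mask
#'
#' Connected components that contain several distance-transform maxima
#' (touching nuclei) are split by watershed on the Euclidean distance
#' transform; each resulting region contributes one centroid. Markers are
#' distance-transform maxima with a minimum separation of `min_sep` pixels
#' (default the kernel sigma — the nucleus-core scale; larger separations
#' merge legitimate neighbours at the closest annotated spacing), which
#' makes the split deterministic.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param min_sep Minimum separation of watershed markers in pixels.
#' @param tolerance Minimum depth (in distance-transform units) between a
#'   marker and its saddle for a split to happen.
#' @param values Optional numeric matrix of the underlying response map;
#'   when supplied, each centroid row also carries the region's maximum
#'   response in a `peak` column.
#' @return A data frame of centroids `x`, `y` (0-based, x = column),
#'   ordered by `y` then `x` (plus `peak` when `values` is given).
#' @examples
#' m <- matrix(FALSE, 30, 30); m[5:9, 5:9] <- TRUE; m[20:24, 18:22] <- TRUE
#' separate_and_count(m)  # two centroids
#' @export
separate_and_count <- function(mask, min_sep = 3, tolerance = 0.5,
                               values = NULL) {
  mask <- mask > 0
  if (!any(mask)) {
    out <- data.frame(x = numeric(), y = numeric())
    if (!is.null(values)) out$peak <- numeric()
    return(out)
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = min_sep)
  lab <- EBImage::imageData(ws)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  cx <- tapply(idx[, 2] - 1, labs, mean)  # column -> x
  cy <- tapply(idx[, 1] - 1, labs, mean)  # row -> y
  out <- data.frame(x = as.numeric(cx), y = as.numeric(cy))
  if (!is.null(values)) {
    out$peak <- as.numeric(tapply(values[lab > 0], labs, max))
  }
  out[order(out$y, out$x), , drop = FALSE]
}

#' Decode nuclei centres from a multi-channel proximity-map prediction
#'
#' For each class channel (1 = Ki67+, 2 = Ki67-): a channel whose maximum
#' is below `floor` times the nominal kernel peak is declared empty —
#' running Otsu on a near-empty map would manufacture a noise threshold.
#' Otherwise the channel is Otsu-binarised, merged detections are split by
#' watershed and one centroid per region is emitted. Regions whose peak
#' response is below `min_peak` times the kernel peak are discarded: a
#' regression decoder trained to unit-peak targets answers true nuclei
#' with near-unit bumps, while cross-channel leakage (for example a faint
#' Ki67+ response over blue nuclei) stays far below the trained amplitude,
#' and Otsu — being scale-free — would otherwise happily binarise it.
#'
#' @param pred Numeric `H x W x 3` array, non-negative.
#' @param floor Channel-level detection floor as a fraction of the kernel
#'   peak.
#' @param min_peak Per-region prominence floor as a fraction of the kernel
#'   peak.
#' @param config The [proximity_config()] the model was trained against
#'   (supplies the kernel peak and sigma).
#' @param tolerance Watershed split tolerance, see [separate_and_count()].
#' @return An annotation-dialect data frame (`x`, `y`, `class`) with
#'   attribute `floor`.
#' @export
detect_nuclei <- function(pred, floor = 0.05, min_peak = 0.25,
                          config = proximity_config(), tolerance = 0.5) {
  assert_rgb_image(pred, "prediction map")
  peak <- kernel_peak(config)
  res <- lapply(c("pos", "neg"), function(cl) {
    ch <- pred[, , config$channels[[cl]]]
    if (max(ch) < floor * peak) {
      return(annotation_df())
    }
    thr <- tryCatch(otsu_threshold(ch),
                    ki67pi_degenerate_error = function(e) NA_real_)
    if (is.na(thr)) {
      return(annotation_df())
    }
    cent <- separate_and_count(ch > thr, min_sep = config$sigma,
                               tolerance = tolerance, values = ch)
    cent <- cent[cent$peak >= min_peak * peak, , drop = FALSE]
    annotation_df(cent$x, cent$y, rep(cl, nrow(cent)))
  })
  out <- rbind(res[[1]], res[[2]])
  attr(out, "floor") <- floor
  out
}
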