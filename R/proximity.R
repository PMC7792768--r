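#' Gaussian proximity-map configuration
#'
#' Point annotations carry too little information to train a dense
#' detector, so each annotated nucleus centre is replaced by a small 2-D
#' Gaussian bump: the regression target becomes a per-class "proximity map"
#' whose value encodes closeness to a nucleus centre. The kernel is
#' \deqn{g(x_1, x_2) = \frac{1}{2\pi\sigma^2}
#'       e^{-\frac{x_1^2 + x_2^2}{2\sigma^2}}}
#' with `sigma = 3` pixels by default so the bump stays inside a typical
#' tumour-nucleus footprint at x20 magnification.
#'
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param truncation Kernel support radius in multiples of `sigma`.
#' @param amplitude `"unit_peak"` rescales the kernel so its centre equals
#'   1 (targets live in \[0, 1\], which conditions the regression losses
#'   well); `"density"` keeps the literal bivariate-normal amplitude
#'   `1 / (2 pi sigma^2)` at the centre. Detection decoding is invariant to
#'   this global scale.
#' @return An object of class `proximity_config`.
#' @examples
#' cfg <- proximity_config()
#' k <- gaussian_kernel(cfg)
#' dim(k)        # 19 x 19 for sigma = 3, truncation = 3
#' max(k)        # 1 in unit_peak mode
#' @export
proximity_config <- function(sigma = 3, truncation = 3,
                             amplitude = c("unit_peak", "density")) {
  amplitude <- match.arg(amplitude)
  if (!is.numeric(sigma) || sigma <= 0) {
    stop_ki67("sigma must be > 0", class = "ki67pi_contract_error")
  }
  if (!is.numeric(truncation) || truncation < 1) {
    stop_ki67("truncation must be >= 1", class = "ki67pi_contract_error")
  }
  structure(list(sigma = sigma, truncation = truncation, amplitude = amplitude,
                 channels = c(pos = 1L, neg = 2L)),
            class = "proximity_config")
}

#' Peak (centre) value of the proximity kernel
#' @param config A [proximity_config()].
#' @return The kernel's maximum value: 1 for `unit_peak`,
#'   `1/(2 pi sigma^2)` for `density`.
#' @export
kernel_peak <- function(config = proximity_config()) {
  if (config$amplitude == "unit_peak") 1 else 1 / (2 * pi * config$sigma^2)
}

#' @rdname proximity_config
#' @param config A [proximity_config()].
#' @return `gaussian_kernel()` returns a square matrix of side
#'   `2 * truncation * sigma + 1`, centred, radially symmetric and maximal
#'   at its centre.
#' @export
gaussian_kernel <- function(config = proximity_config()) {
  r <- ceiling(config$truncation * config$sigma)
  d <- seq(-r, r)
  g <- exp(-outer(d^2, d^2, "+") / (2 * config$sigma^2))
  if (config$amplitude == "density") {
    g <- g / (2 * pi * config$sigma^2)
  }
  g
}

#' Build a multi-channel Gaussian proximity map from point annotations
#'
#' Stamps the Gaussian kernel at every annotated nucleus centre, one
#' channel per class (channel 1 = Ki67+, channel 2 = Ki67-, channel 3 is
#' the background complement and stays all-zero in targets). Overlapping
#' kernels combine by per-pixel maximum, which keeps values bounded by the
#' single-kernel peak and leaves a local maximum at every annotated centre.
#' Kernels are clipped at the image border.
#'
#' @param annotations Annotation data frame (see [annotation_df()]).
#' @param shape Integer vector `c(height, width)` of the target map.
#' @param config A [proximity_config()].
#' @return A numeric array `H x W x 3`.
#' @examples
#' ann <- annotation_df(50, 50, "pos")
#' m <- build_proximity_map(ann, c(100, 100))
#' m[51, 51, 1]  # 1: unit peak at the annotated centre
#' @export
build_proximity_map <- function(annotations, shape,
                                config = proximity_config()) {
  stopifnot(length(shape) == 2)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  bad <- annotations$x < 0 | annotations$x > w - 1 |
         annotations$y < 0 | annotations$y > h - 1
  if (any(bad)) {
    i <- which(bad)[1]
    stop_ki67("annotation (%g, %g) lies outside a %d x %d map",
              annotations$x[i], annotations$y[i], h, w,
              class = "ki67pi_coordinate_error")
  }
  g <- gaussian_kernel(config)
  r <- (nrow(g) - 1L) %/% 2L
  out <- array(0, dim = c(h, w, 3L))
  for (cls in names(config$channels)) {
    ch <- config$channels[[cls]]
    sel <- annotations$class == cls
    if (!any(sel)) next
    plane <- matrix(0, h, w)
    cx <- round(annotations$x[sel]); cy <- round(annotations$y[sel])
    for (i in seq_along(cx)) {
      r0 <- cy[i] + 1L; c0 <- cx[i] + 1L
      rows <- max(1L, r0 - r):min(h, r0 + r)
      cols <- max(1L, c0 - r):min(w, c0 + r)
      krows <- rows - r0 + r + 1L
      kcols <- cols - c0 + r + 1L
      plane[rows, cols] <- pmax(plane[rows, cols], g[krows, kcols])
    }
    out[, , ch] <- plane
  }
  out
}

#' Read/write proximity maps as 32-bit float TIFF
#'
#' Targets and predictions are stored as 3-channel 32-bit floating point
#' TIFF files next to their patches (`<patch>_target.tiff`).
#'
#' @param map A numeric `H x W x 3` array.
#' @param path Destination/source path.
#' @export
write_proximity_map <- function(map, path) {
  stopifnot(is.array(map), length(dim(map)) == 3L)
  tiff::writeTIFF(map, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_proximity_map
#' @export
read_proximity_map <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) != 3L) {
    stop_ki67("'%s' is not a multi-channel proximity map", path,
              class = "ki67pi_io_error")
  }
  m
}
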