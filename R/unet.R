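#' U-Net model configuration
#'
#' The detector is a U-Net encoder-decoder regressing the 3-channel
#' proximity map from a 3-channel RGB patch. Each encoder level applies
#' two 3x3 same-padded convolutions with ReLU and halves the resolution by
#' 2x2 max-pooling while doubling the filter count; the decoder mirrors
#' the encoder with 2x2 stride-2 transposed convolutions and skip
#' connections; a final 1x1 convolution with ReLU yields three
#' non-negative output channels. The full-scale configuration is six
#' levels deep starting at 32 filters (so the bottleneck reaches 1024);
#' the desk-scale profile used by the package's own experiments is
#' `depth = 4, base_filters = 8` on 128 px patches — the same code path at
#' reduced size.
#'
#' @param depth Number of resolution levels (>= 2); level `depth` is the
#'   bottleneck.
#' @param base_filters Filters at the first level; doubled per level.
#' @param max_filters Cap on the per-level filter count.
#' @param input_size `c(height, width)`; both must be divisible by
#'   `2^(depth - 1)`.
#' @param in_channels,out_channels Input (RGB) and output (proximity map)
#'   channel counts.
#' @return An object of class `unet_config`.
#' @examples
#' unet_filters(unet_config())  # 32 64 128 256 512 1024
#' @export
unet_config <- function(depth = 6L, base_filters = 32L, max_filters = 1024L,
                        input_size = c(256L, 256L),
                        in_channels = 3L, out_channels = 3L) {
  stopifnot(depth >= 2, base_filters >= 1, max_filters >= base_filters)
  div <- 2^(depth - 1)
  if (any(input_size %% div != 0)) {
    stop_ki67("input size %d x %d is not divisible by 2^(depth-1) = %d",
              input_size[1], input_size[2], div,
              class = "ki67pi_config_error")
  }
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 max_filters = as.integer(max_filters),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "unet_config")
}

#' @rdname unet_config
#' @param config A `unet_config`.
#' @return `unet_filters()` returns the per-level filter counts.
#' @export
unet_filters <- function(config) {
  pmin(config$base_filters * 2^(seq_len(config$depth) - 1),
       config$max_filters)
}

init_conv <- function(k, cin, cout) {
  # He-normal initialisation for ReLU layers
  sd <- sqrt(2 / (k * k * cin))
  list(W = array(rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)),
       b = numeric(cout))
}

#' Build an (untrained) U-Net
#'
#' Initialises all weights (He-normal, seeded) and returns the model
#' handle. Use [train_unet()] to fit it or [predict.ki67_unet()] to run
#' the forward pass.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `ki67_unet` with elements `config` and
#'   `weights`.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  f <- unet_filters(config)
  with_seed(seed, {
    w <- list()
    cin <- config$in_channels
    for (l in seq_len(config$depth)) {
      w[[sprintf("enc_%d_conv1", l)]] <- init_conv(3L, cin, f[l])
      w[[sprintf("enc_%d_conv2", l)]] <- init_conv(3L, f[l], f[l])
      cin <- f[l]
    }
    for (l in (config$depth - 1):1) {
      w[[sprintf("up_%d", l)]] <- init_conv(2L, cin, f[l])
      w[[sprintf("dec_%d_conv1", l)]] <- init_conv(3L, 2L * f[l], f[l])
      w[[sprintf("dec_%d_conv2", l)]] <- init_conv(3L, f[l], f[l])
      cin <- f[l]
    }
    w[["final"]] <- init_conv(1L, f[1], config$out_channels)
    structure(list(config = config, weights = w), class = "ki67_unet")
  })
}

#' @export
print.ki67_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("U-Net proximity-map regressor (untrained)\n"))
  cat(sprintf("  depth %d, filters %s\n", cfg$depth,
              paste(unet_filters(cfg), collapse = "-")))
  cat(sprintf("  input %d x %d x %d -> output x %d (ReLU, >= 0)\n",
              cfg$input_size[1], cfg$input_size[2], cfg$in_channels,
              cfg$out_channels))
  cat(sprintf("  parameters: %s\n",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$weights,
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Forward pass of a (trained or untrained) U-Net
#'
#' @param object A `ki67_unet` or `ki67_unet_fit`.
#' @param image A numeric `H x W x 3` RGB array on the 0-255 scale, with
#'   `H` and `W` divisible by `2^(depth - 1)`. Intensities are normalised
#'   to \[0, 1\] internally.
#' @param ... Unused.
#' @return The predicted proximity map, a non-negative `H x W x 3` array.
#' @export
predict.ki67_unet <- function(object, image, ...) {
  assert_rgb_image(image, "input patch")
  div <- 2^(object$config$depth - 1)
  d <- dim(image)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop_ki67("input %d x %d is not divisible by 2^(depth-1) = %d",
              d[1], d[2], div, class = "ki67pi_contract_error")
  }
  cpp_unet_forward(object$weights, image / 255, object$config$depth)
}
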