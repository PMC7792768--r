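# Synthetic Ki67-like patch rendering.
#
# The generator emulates DAB-stained breast-tissue patches: brown (Ki67+)
# and blue (Ki67-) elliptical nuclei on a pale pink background, with
# optional "non-ideal" content (tissue folds, overstained smears, stromal
# texture, non-tumour cells) that carries no annotations. Everything is
# drawn from a seeded RNG, so a spec plus seed reproduces an image
# bit-exactly.

# Base colours (RGB, 0-255). Classes are separable but share a stained-
# tissue palette; per-nucleus jitter keeps the task non-trivial.
KI67_COLORS <- list(
  pos = c(120, 70, 20),      # DAB brown
  neg = c(60, 60, 140),      # hematoxylin blue
  background = c(235, 220, 225),
  fold = c(70, 50, 70),
  overstain = c(140, 90, 40),
  speckle = c(155, 105, 55),
  stroma = c(215, 180, 195),
  nontumor = c(170, 175, 205)
)

ARTIFACT_KINDS <- c("fold", "overstain", "stroma", "nontumor_cells")

#' Specification of one synthetic Ki67 patch
#'
#' @param width,height Patch size in pixels.
#' @param n_positive,n_negative Number of Ki67+ (brown) and Ki67- (blue)
#'   nuclei to render and annotate.
#' @param nucleus_radius_range Min/max nucleus semi-axis in pixels at the
#'   x20-equivalent scale.
#' @param ideal If `TRUE` the patch is "pristine": tumour nuclei only, no
#'   artifacts. Non-ideal patches add the requested `artifacts`.
#' @param artifacts Character subset of
#'   `c("fold", "overstain", "stroma", "nontumor_cells")`. Must be empty
#'   for ideal patches.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   rendering.
#' @return An object of class `patch_spec`.
#' @examples
#' spec <- patch_spec(128, 128, n_positive = 10, n_negative = 30, seed = 7)
#' spec$target_pi  # 25
#' @export
patch_spec <- function(width = 256L, height = 256L,
                       n_positive = 0L, n_negative = 0L,
                       nucleus_radius_range = c(4, 8),
                       ideal = TRUE, artifacts = character(), seed = 1L) {
  stopifnot(width >= 32, height >= 32, n_positive >= 0, n_negative >= 0,
            length(nucleus_radius_range) == 2,
            nucleus_radius_range[1] > 0,
            nucleus_radius_range[1] <= nucleus_radius_range[2])
  artifacts <- unique(as.character(artifacts))
  if (!all(artifacts %in% ARTIFACT_KINDS)) {
    stop_ki67("unknown artifact kind(s): %s",
              paste(setdiff(artifacts, ARTIFACT_KINDS), collapse = ", "),
              class = "ki67pi_contract_error")
  }
  if (ideal && length(artifacts)) {
    stop_ki67("ideal patches cannot carry artifacts",
              class = "ki67pi_contract_error")
  }
  n_tot <- n_positive + n_negative
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
    target_pi = if (n_tot > 0) 100 * n_positive / n_tot else NA_real_,
    nucleus_radius_range = as.numeric(nucleus_radius_range),
    ideal = isTRUE(ideal), artifacts = artifacts, seed = as.integer(seed)
  ), class = "patch_spec")
}

# Pixel (row, col) index pairs inside an ellipse centred at 0-based
# (cx, cy) with semi-axes a >= b and orientation theta.
ellipse_pixels <- function(h, w, cx, cy, a, b, theta) {
  r <- ceiling(max(a, b))
  rows <- max(1L, floor(cy + 1 - r)):min(h, ceiling(cy + 1 + r))
  cols <- max(1L, floor(cx + 1 - r)):min(w, ceiling(cx + 1 + r))
  dy <- rows - 1 - cy
  dx <- cols - 1 - cx
  ct <- cos(theta); st <- sin(theta)
  # outer(dy, dx): rows index y, cols index x
  u <- outer(dy, dx, function(yy, xx) (xx * ct + yy * st) / a)
  v <- outer(dy, dx, function(yy, xx) (-xx * st + yy * ct) / b)
  inside <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  cbind(row = rows[inside[, 1]], col = cols[inside[, 2]])
}

# Paint `color` (length 3) over pixel index pairs with opacity alpha.
blend_pixels <- function(img, px, color, alpha = 1) {
  if (nrow(px) == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  li <- px[, 1] + (px[, 2] - 1) * h
  for (ch in 1:3) {
    off <- (ch - 1) * h * w
    img[li + off] <- (1 - alpha) * img[li + off] + alpha * color[ch]
  }
  img
}

# Bilinear upsample of a coarse matrix to h x w (used for stromal texture).
bilinear_upsample <- function(g, h, w) {
  gh <- nrow(g); gw <- ncol(g)
  ry <- seq(1, gh, length.out = h)
  rx <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ry), gh - 1); fy <- ry - y0
  x0 <- pmin(floor(rx), gw - 1); fx <- rx - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fyv <- rep(fy, w); fxv <- rep(fx, each = h)
  m <- a * (1 - fyv) * (1 - fxv) + b * fyv * (1 - fxv) +
       cc * (1 - fyv) * fxv + d * fyv * fxv
  matrix(m, h, w)
}

draw_fold <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  # quadratic Bezier from one border to another through a random interior
  # control point, darkened along a band
  edge_point <- function() {
    side <- sample(4, 1)
    switch(side,
      c(runif(1, 0, w - 1), 0), c(runif(1, 0, w - 1), h - 1),
      c(0, runif(1, 0, h - 1)), c(w - 1, runif(1, 0, h - 1)))
  }
  p0 <- edge_point(); p2 <- edge_point()
  p1 <- c(runif(1, 0.2 * w, 0.8 * w), runif(1, 0.2 * h, 0.8 * h))
  t <- seq(0, 1, length.out = 2L * max(h, w))
  bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  half <- runif(1, 2, 4)
  off <- expand.grid(dr = -ceiling(half):ceiling(half),
                     dc = -ceiling(half):ceiling(half))
  off <- off[off$dr^2 + off$dc^2 <= half^2, ]
  rows <- outer(round(by) + 1, off$dr, "+")
  cols <- outer(round(bx) + 1, off$dc, "+")
  keep <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  px <- unique(cbind(row = rows[keep], col = cols[keep]))
  blend_pixels(img, px, KI67_COLORS$fold, alpha = 0.85)
}

draw_overstain <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  cx <- runif(1, 0.25 * w, 0.75 * w); cy <- runif(1, 0.25 * h, 0.75 * h)
  a <- runif(1, 0.22, 0.38) * min(h, w); b <- runif(1, 0.6, 1) * a
  px <- ellipse_pixels(h, w, cx, cy, a, b, runif(1, 0, pi))
  img <- blend_pixels(img, px, KI67_COLORS$overstain, alpha = 0.35)
  # diffuse brown speckles inside the smear: nucleus-sized but paler and
  # translucent, never annotated
  for (i in seq_len(sample(8:14, 1))) {
    scx <- cx + runif(1, -0.8, 0.8) * a; scy <- cy + runif(1, -0.8, 0.8) * b
    sa <- runif(1, 2.5, 5)
    spx <- ellipse_pixels(h, w, scx, scy, sa, runif(1, 0.7, 1) * sa,
                          runif(1, 0, pi))
    img <- blend_pixels(img, spx, KI67_COLORS$speckle + runif(3, -15, 15),
                        alpha = 0.55)
  }
  img
}

draw_stroma <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  g <- matrix(rnorm(81), 9, 9)
  m <- bilinear_upsample(g, h, w)
  alpha <- pmax(m, 0) / max(abs(m)) * 0.45
  col <- KI67_COLORS$stroma
  for (ch in 1:3) {
    img[, , ch] <- (1 - alpha) * img[, , ch] + alpha * col[ch]
  }
  img
}

draw_nontumor <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  for (i in seq_len(sample(6:14, 1))) {
    a <- runif(1, 2, 4.5)
    px <- ellipse_pixels(h, w, runif(1, 5, w - 6), runif(1, 5, h - 6),
                         a, runif(1, 0.6, 1) * a, runif(1, 0, pi))
    img <- blend_pixels(img, px, KI67_COLORS$nontumor + runif(3, -10, 10),
                        alpha = 0.9)
  }
  img
}

# Rejection-sample integer nucleus centres with a minimum mutual distance
# and a border margin. Errors out when the patch is too crowded.
place_centers <- function(n, w, h, margin, min_sep = 6,
                          max_attempts = 200L * max(n, 1L)) {
  if (n == 0) return(cbind(x = numeric(), y = numeric()))
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L; attempts <- 0L
  lo_x <- ceiling(margin); hi_x <- w - 1 - ceiling(margin)
  lo_y <- ceiling(margin); hi_y <- h - 1 - ceiling(margin)
  if (hi_x < lo_x || hi_y < lo_y) {
    stop_ki67("patch too small for nucleus margin %g", margin,
              class = "ki67pi_placement_error")
  }
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop_ki67(paste0("could not place %d nuclei in a %d x %d patch ",
                       "(min separation %g) within %d attempts"),
                n, w, h, min_sep, max_attempts,
                class = "ki67pi_placement_error")
    }
    cx <- sample(lo_x:hi_x, 1); cy <- sample(lo_y:hi_y, 1)
    if (placed > 0 &&
        min((xs[1:placed] - cx)^2 + (ys[1:placed] - cy)^2) < min_sep^2) {
      next
    }
    placed <- placed + 1L
    xs[placed] <- cx; ys[placed] <- cy
  }
  cbind(x = xs, y = ys)
}

#' Render a synthetic Ki67 patch with exact ground truth
#'
#' Draws the requested numbers of brown (Ki67+) and blue (Ki67-)
#' elliptical nuclei on a pale pink background, preceded by any requested
#' artifact overlays (which carry no annotations). Nuclei are painted
#' last, so every annotated centre lies on a pixel of its class colour.
#' Centres are at least 6 px apart (mild overlap of ellipses is allowed,
#' exercising watershed separation) and at least one nucleus radius inside
#' the border.
#'
#' @param spec A [patch_spec()].
#' @return A list with `image` (numeric `H x W x 3` array, 0-255) and
#'   `annotations` (data frame `x`, `y`, `class`, one row per nucleus).
#' @examples
#' p <- render_patch(patch_spec(96, 96, n_positive = 3, n_negative = 9,
#'                              seed = 42))
#' nrow(p$annotations)  # 12
#' @export
render_patch <- function(spec) {
  stopifnot(inherits(spec, "patch_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    img <- array(rep(KI67_COLORS$background, each = h * w), c(h, w, 3))
    img <- img + array(rnorm(h * w * 3, 0, 2), c(h, w, 3))

    if (!spec$ideal) {
      if ("stroma" %in% spec$artifacts) img <- draw_stroma(img)
      if ("overstain" %in% spec$artifacts) img <- draw_overstain(img)
      if ("fold" %in% spec$artifacts) img <- draw_fold(img)
      if ("nontumor_cells" %in% spec$artifacts) img <- draw_nontumor(img)
    }

    rr <- spec$nucleus_radius_range
    n <- spec$n_positive + spec$n_negative
    centers <- place_centers(n, w, h, margin = rr[2])
    classes <- rep(c("pos", "neg"), c(spec$n_positive, spec$n_negative))
    if (n > 1) classes <- sample(classes)

    for (i in seq_len(n)) {
      r1 <- runif(1, rr[1], rr[2]); r2 <- runif(1, rr[1], rr[2])
      a <- max(r1, r2); b <- min(r1, r2)
      if (n > 1) {
        dmin <- sqrt(min((centers[-i, 1] - centers[i, 1])^2 +
                         (centers[-i, 2] - centers[i, 2])^2))
        if (a > dmin - 2) {            # never cover a neighbour's centre
          sc <- (dmin - 2) / a
          a <- a * sc; b <- b * sc
        }
      }
      col <- KI67_COLORS[[classes[i]]] + runif(3, -20, 20)
      px <- ellipse_pixels(h, w, centers[i, 1], centers[i, 2], a, b,
                           runif(1, 0, pi))
      img <- blend_pixels(img, px, col)
    }

    img <- pmin(pmax(img, 0), 255)
    list(image = img,
         annotations = annotation_df(centers[, 1], centers[, 2], classes))
  })
}
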