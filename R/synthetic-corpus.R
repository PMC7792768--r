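# Seeded corpus generation: a directory of synthetic patches with exact
# annotations and an index carrying the ideal/non-ideal label, the ground
# truth PI and its Low/Medium/High stratum.

# Distribute `counts[j]` items of each subset j across strata of the given
# sizes, proportionally with largest-remainder rounding. Column sums equal
# `counts`; row sums never exceed `sizes`. Deterministic.
allocate_across_strata <- function(sizes, counts) {
  stopifnot(sum(counts) <= sum(sizes))
  S <- length(sizes); J <- length(counts)
  out <- matrix(0L, S, J)
  remaining <- as.integer(sizes)
  for (j in seq_len(J)) {
    if (counts[j] == 0 || sum(remaining) == 0) next
    a <- largest_remainder(counts[j], remaining / sum(remaining))
    a <- pmin(a, remaining)
    deficit <- counts[j] - sum(a)
    while (deficit > 0) {
      i <- which.max(remaining - a)
      a[i] <- a[i] + 1L
      deficit <- deficit - 1L
    }
    out[, j] <- a
    remaining <- remaining - a
  }
  out
}

# Sample an integer Ki67+ count for `n` nuclei whose realised PI falls in
# the requested stratum (scheme A: Low < 10, Medium 10-30, High > 30).
sample_pos_count <- function(n, stratum) {
  valid <- switch(stratum,
    Low = 0:max(0, ceiling(n / 10) - 1),
    Medium = ceiling(n / 10):floor(3 * n / 10),
    High = (floor(3 * n / 10) + 1):n)
  valid <- valid[valid >= 0 & valid <= n &
                 classify_pi_range(100 * valid / n) == stratum]
  if (!length(valid)) {
    stop_ki67("no %s-stratum Ki67+ count exists for %d nuclei", stratum, n,
              class = "ki67pi_contract_error")
  }
  if (length(valid) == 1) valid else sample(valid, 1)
}

#' Generate a synthetic patch corpus on disk
#'
#' Writes `n_patches` seeded synthetic patches as PNG with per-patch
#' annotation CSVs and an index file `index.csv` with columns
#' `path,ideal,gt_pi,stratum`. Ideal/non-ideal counts follow
#' `ideal_fraction` exactly (largest-remainder rounding), and the
#' Low/Medium/High PI strata follow `pi_mixture` exactly, balanced across
#' the ideal and non-ideal pools. Non-ideal patches carry 1-3 random
#' artifact kinds and fewer tumour nuclei. The same seed reproduces every
#' file byte-identically.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_patches Number of patches (>= 1).
#' @param pi_mixture Named proportions for strata `Low`, `Medium`, `High`.
#' @param ideal_fraction Fraction of ideal patches in \[0, 1\].
#' @param width,height Patch size in pixels.
#' @param n_nuclei_ideal,n_nuclei_nonideal Integer ranges (min, max) for
#'   the per-patch total nucleus count.
#' @param seed Corpus seed.
#' @return The index data frame, invisibly, with attribute `dir`.
#' @export
render_corpus <- function(out_dir, n_patches,
                          pi_mixture = c(Low = 1, Medium = 1, High = 1) / 3,
                          ideal_fraction = 0.5,
                          width = 128L, height = 128L,
                          n_nuclei_ideal = c(25L, 60L),
                          n_nuclei_nonideal = c(5L, 20L),
                          seed = 1L) {
  stopifnot(n_patches >= 1, ideal_fraction >= 0, ideal_fraction <= 1,
            length(pi_mixture) == 3)
  pi_mixture <- pi_mixture / sum(pi_mixture)
  strata <- c("Low", "Medium", "High")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop_ki67("cannot create output directory '%s'", out_dir,
              class = "ki67pi_io_error")
  }

  stratum_counts <- largest_remainder(n_patches, pi_mixture)
  n_ideal <- largest_remainder(n_patches, c(ideal_fraction,
                                            1 - ideal_fraction))[1]
  # per-stratum ideal counts, proportional with exact totals
  ideal_by_stratum <- allocate_across_strata(stratum_counts,
                                             c(n_ideal, n_patches - n_ideal))

  with_seed(seed, {
    rows <- list()
    k <- 0L
    patch_seeds <- sample.int(.Machine$integer.max - 1L, n_patches)
    for (s in seq_along(strata)) {
      flags <- rep(c(TRUE, FALSE), ideal_by_stratum[s, ])
      for (ideal in flags) {
        k <- k + 1L
        nr <- if (ideal) n_nuclei_ideal else n_nuclei_nonideal
        n_tot <- sample(nr[1]:nr[2], 1)
        n_pos <- sample_pos_count(n_tot, strata[s])
        artifacts <- if (ideal) character() else {
          sample(ARTIFACT_KINDS, sample(1:3, 1))
        }
        spec <- patch_spec(width, height, n_pos, n_tot - n_pos,
                           ideal = ideal, artifacts = artifacts,
                           seed = patch_seeds[k])
        patch <- render_patch(spec)
        name <- sprintf("patch_%04d", k)
        png::writePNG(patch$image / 255,
                      file.path(out_dir, paste0(name, ".png")))
        write_annotations(patch$annotations,
                          file.path(out_dir, paste0(name, ".csv")))
        rows[[k]] <- data.frame(
          path = paste0(name, ".png"), ideal = ideal,
          gt_pi = 100 * n_pos / n_tot, stratum = strata[s],
          stringsAsFactors = FALSE)
      }
    }
    index <- do.call(rbind, rows)
    write.csv(index, file.path(out_dir, "index.csv"),
              row.names = FALSE, quote = FALSE)
    attr(index, "dir") <- out_dir
    invisible(index)
  })
}

#' Read a corpus index written by [render_corpus()]
#' @param dir Corpus directory containing `index.csv`.
#' @return The index data frame with attribute `dir`.
#' @export
read_corpus <- function(dir) {
  path <- file.path(dir, "index.csv")
  if (!file.exists(path)) {
    stop_ki67("no index.csv under '%s'", dir, class = "ki67pi_io_error")
  }
  index <- read.csv(path, stringsAsFactors = FALSE)
  attr(index, "dir") <- dir
  index
}

#' Read a corpus patch and its annotations
#' @param index A corpus index (from [render_corpus()] or [read_corpus()]).
#' @param i Row number.
#' @return A list with `image` (0-255 array) and `annotations`.
#' @export
read_patch <- function(index, i) {
  dir <- attr(index, "dir")
  img <- png::readPNG(file.path(dir, index$path[i])) * 255
  ann <- read_annotations(file.path(
    dir, sub("\\.png$", ".csv", index$path[i])))
  list(image = img, annotations = ann)
}
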