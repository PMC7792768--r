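#' Proliferation index from nuclei counts
#'
#' The proliferation index is the percentage of tumour nuclei that are
#' Ki67-positive: `PI = 100 * pos / (pos + neg)`. When no nuclei were
#' counted the PI is undefined and flagged rather than raised as an error,
#' so blank tiles can be carried through aggregation and excluded there.
#'
#' @param pos,neg Non-negative nucleus counts.
#' @return An object of class `pi_result` with fields `pi` (percent, `NA`
#'   when undefined), `pos_total`, `neg_total`, `defined`.
#' @examples
#' compute_pi(10, 30)$pi   # 25
#' compute_pi(0, 0)$defined  # FALSE
#' @export
compute_pi <- function(pos, neg) {
  stopifnot(length(pos) == 1, length(neg) == 1, pos >= 0, neg >= 0)
  total <- pos + neg
  structure(list(
    pi = if (total > 0) 100 * pos / total else NA_real_,
    pos_total = as.numeric(pos),
    neg_total = as.numeric(neg),
    defined = total > 0
  ), class = "pi_result")
}

#' @export
print.pi_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("PI = %.2f%% (Ki67+ %d / total %d)\n",
                x$pi, as.integer(x$pos_total),
                as.integer(x$pos_total + x$neg_total)))
  } else {
    cat("PI undefined (no nuclei counted)\n")
  }
  invisible(x)
}

#' Classify a PI value into Low/Medium/High ranges
#'
#' Two published cut-point schemes are supported: scheme `"A"` uses
#' Low < 10, Medium 10-30 (closed), High > 30 — the common clinical
#' convention; scheme `"B"` uses Low < 25, Medium 25-75 (closed),
#' High > 75, the convention of Protein-Atlas-style range labels. Boundary
#' values belong to Medium in both schemes.
#'
#' @param pi Numeric vector of defined PI values in \[0, 100\].
#' @param scheme `"A"` (10/30 cut-points) or `"B"` (25/75).
#' @return A character vector of labels `"Low"`, `"Medium"`, `"High"`.
#' @examples
#' classify_pi_range(c(5, 10, 15, 30, 31))        # Low Med Med Med High
#' classify_pi_range(80, scheme = "B")            # High
#' @export
classify_pi_range <- function(pi, scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  if (any(is.na(pi))) {
    stop_ki67("classify_pi_range requires defined PI values",
              class = "ki67pi_contract_error")
  }
  cuts <- if (scheme == "A") c(10, 30) else c(25, 75)
  ifelse(pi < cuts[1], "Low", ifelse(pi <= cuts[2], "Medium", "High"))
}

# Count pos/neg rows of a detection/annotation data frame.
count_classes <- function(det) {
  c(pos = sum(det$class == "pos"), neg = sum(det$class == "neg"))
}

#' PI of a tissue microarray from per-tile detections
#'
#' A TMA core is mostly tumour, so the whole recomposed image is scored:
#' positive and negative counts are pooled over all tiles (no hotspot
#' filtering) and the PI computed from the totals.
#'
#' @param tile_detections A list of detection data frames (see
#'   [annotation_df()] for the dialect).
#' @return A `pi_result`.
#' @examples
#' t1 <- annotation_df(c(1, 2), c(1, 2), c("pos", "neg"))
#' tma_pi(list(t1, t1))$pi   # 50
#' @export
tma_pi <- function(tile_detections) {
  stopifnot(is.list(tile_detections), length(tile_detections) >= 1)
  counts <- rowSums(vapply(tile_detections, count_classes, numeric(2)))
  compute_pi(counts[["pos"]], counts[["neg"]])
}

#' Whole-slide PI via the hotspot rule
#'
#' Pathologists score WSIs on hotspots rather than the whole section. The
#' automated analogue: let `N(i)` be the total tumour-nucleus count
#' (both classes) of analysed patch `i` and `Navg` their mean over all `k`
#' analysed patches. Only patches with `N(i) >= Navg` contribute; their
#' positive and negative counts are accumulated separately and the PI is
#' computed from the accumulated totals. The comparison is inclusive, so
#' the selection is never empty while any patch contains nuclei.
#'
#' @param patch_counts A data frame with columns `id`, `pos`, `neg`, one
#'   row per analysed (tissue) patch.
#' @return A list with elements `pi` (a `pi_result`) and `hotspot` (fields
#'   `navg`, `included` ids, `k`).
#' @examples
#' pc <- data.frame(id = c("A", "B", "C"),
#'                  pos = c(5, 1, 2), neg = c(5, 1, 6))
#' res <- wsi_hotspot_pi(pc)
#' res$pi$pi             # 38.89: patches A and C pass N >= Navg
#' res$hotspot$included  # "A" "C"
#' @export
wsi_hotspot_pi <- function(patch_counts) {
  stopifnot(is.data.frame(patch_counts), nrow(patch_counts) >= 1,
            all(c("pos", "neg") %in% names(patch_counts)))
  if (is.null(patch_counts$id)) {
    patch_counts$id <- seq_len(nrow(patch_counts))
  }
  n_i <- patch_counts$pos + patch_counts$neg
  navg <- mean(n_i)
  inc <- n_i >= navg
  res <- compute_pi(sum(patch_counts$pos[inc]), sum(patch_counts$neg[inc]))
  list(pi = res,
       hotspot = list(navg = navg,
                      included = patch_counts$id[inc],
                      k = nrow(patch_counts)))
}
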