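#' Match predicted nuclei centres to ground-truth annotations
#'
#' Detections are points, so performance is measured by one-to-one
#' matching: all ground-truth/prediction pairs are sorted by Euclidean
#' distance and accepted greedily while the distance is at most `radius`
#' and both endpoints are unused. A matched pair is a true positive; an
#' unmatched prediction a false positive; an unmatched ground-truth point
#' a false negative. The default radius of 6 px equals twice the proximity
#' kernel sigma, i.e. the stamped kernel support at x20 scale.
#'
#' @param gt,pred Data frames (or 2-column matrices) of points with
#'   columns `x`, `y`.
#' @param radius Maximum centre-to-centre distance (pixels) for a match.
#' @return An object of class `match_result`: fields `tp`, `fp`, `fn` and
#'   `pairs` (data frame `gt`, `pred`, `distance`, 1-based row indices).
#' @examples
#' m <- match_detections(data.frame(x = 10, y = 10),
#'                       data.frame(x = 12, y = 11))
#' c(m$tp, m$fp, m$fn)  # 1 0 0
#' @export
match_detections <- function(gt, pred, radius = 6) {
  stopifnot(radius > 0)
  gt <- as.data.frame(gt); pred <- as.data.frame(pred)
  ng <- nrow(gt); np <- nrow(pred)
  pairs <- data.frame(gt = integer(), pred = integer(), distance = numeric())
  if (ng > 0 && np > 0) {
    d <- sqrt(outer(gt$x, pred$x, "-")^2 + outer(gt$y, pred$y, "-")^2)
    cand <- which(d <= radius, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      dist <- d[cand]
      # sort by distance; ties broken by gt then pred index for determinism
      o <- order(dist, cand[, 1], cand[, 2])
      used_g <- logical(ng); used_p <- logical(np)
      keep <- integer(0)
      for (i in o) {
        g <- cand[i, 1]; p <- cand[i, 2]
        if (!used_g[g] && !used_p[p]) {
          used_g[g] <- TRUE; used_p[p] <- TRUE
          keep <- c(keep, i)
        }
      }
      pairs <- data.frame(gt = cand[keep, 1], pred = cand[keep, 2],
                          distance = dist[keep])
    }
  }
  structure(list(tp = nrow(pairs), fp = np - nrow(pairs),
                 fn = ng - nrow(pairs), pairs = pairs, radius = radius),
            class = "match_result")
}

#' F1 score of a detection match
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`. When ground truth and prediction are
#' both empty no error was committed and the score is 1; when the
#' denominator is zero otherwise the score is 0.
#'
#' @param m A `match_result` from [match_detections()], or a list with
#'   fields `tp`, `fp`, `fn`.
#' @return A scalar in \[0, 1\].
#' @examples
#' f1_score(list(tp = 8, fp = 2, fn = 2))  # 0.8
#' @export
f1_score <- function(m) {
  denom <- 2 * m$tp + m$fp + m$fn
  if (denom == 0) return(1)
  2 * m$tp / denom
}

#' Per-class detection evaluation of one image
#'
#' Splits ground truth and predictions by class, matches each class
#' separately and reports counts and F1 per class.
#'
#' @param gt_ann,pred_ann Annotation data frames (`x`, `y`, `class`).
#' @inheritParams match_detections
#' @return A data frame with one row per class (`pos`, `neg`) and columns
#'   `tp`, `fp`, `fn`, `f1`.
#' @export
evaluate_detections <- function(gt_ann, pred_ann, radius = 6) {
  do.call(rbind, lapply(c("pos", "neg"), function(cl) {
    m <- match_detections(gt_ann[gt_ann$class == cl, , drop = FALSE],
                          pred_ann[pred_ann$class == cl, , drop = FALSE],
                          radius = radius)
    data.frame(class = cl, tp = m$tp, fp = m$fp, fn = m$fn,
               f1 = f1_score(m), stringsAsFactors = FALSE)
  }))
}

#' PI difference between manual and automated scoring
#'
#' Per image the signed difference `PI_manual - PI_auto` is retained;
#' cohort summaries report the mean of absolute differences. Pairs where
#' either PI is undefined (`NA`) are excluded and counted.
#'
#' @param manual,auto Numeric vectors of PI percentages.
#' @return A list with `signed` (vector), `mean_abs`, `n_excluded`.
#' @examples
#' pi_difference(30, 25)$signed  # 5
#' @export
pi_difference <- function(manual, auto) {
  stopifnot(length(manual) == length(auto))
  ok <- !(is.na(manual) | is.na(auto))
  signed <- manual[ok] - auto[ok]
  list(signed = signed,
       mean_abs = if (any(ok)) mean(abs(signed)) else NA_real_,
       n_excluded = sum(!ok))
}

#' Pearson correlation between manual and automated PI
#'
#' Standard product-moment correlation with a two-sided t-test p-value,
#' measuring how consistently the automated PI tracks the manual PI across
#' a cohort.
#'
#' @param manual,auto Numeric vectors (length >= 3, non-degenerate).
#' @return A list with `r` and `p_value`.
#' @export
pearson_r <- function(manual, auto) {
  stopifnot(length(manual) == length(auto))
  ok <- !(is.na(manual) | is.na(auto))
  manual <- manual[ok]; auto <- auto[ok]
  if (length(manual) < 3) {
    stop_ki67("pearson_r needs at least 3 defined pairs",
              class = "ki67pi_contract_error")
  }
  if (stats::sd(manual) == 0 || stats::sd(auto) == 0) {
    stop_ki67("pearson_r undefined: zero variance in input",
              class = "ki67pi_degenerate_error")
  }
  ct <- stats::cor.test(manual, auto, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' PI-range classification accuracy
#'
#' Fraction of images whose automated PI falls in the same Low/Medium/High
#' range as the manual PI under the chosen cut-point scheme (see
#' [classify_pi_range()]). Pairs with undefined PI are excluded pairwise.
#'
#' @param manual,auto Numeric vectors of PI percentages.
#' @param scheme Range scheme, `"A"` or `"B"`.
#' @return A list with `accuracy`, `n`, `n_excluded`.
#' @examples
#' range_accuracy(c(5, 15, 80), c(20, 30, 90), scheme = "B")$accuracy # 2/3
#' @export
range_accuracy <- function(manual, auto, scheme = c("A", "B")) {
  scheme <- match.arg(scheme)
  stopifnot(length(manual) == length(auto))
  ok <- !(is.na(manual) | is.na(auto))
  if (!any(ok)) {
    stop_ki67("range_accuracy undefined: no defined PI pairs",
              class = "ki67pi_degenerate_error")
  }
  acc <- mean(classify_pi_range(manual[ok], scheme) ==
              classify_pi_range(auto[ok], scheme))
  list(accuracy = acc, n = sum(ok), n_excluded = sum(!ok))
}
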