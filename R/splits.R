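# Train/validation/test partitioning with the ideal/non-ideal
# weak-supervision protocol.
#
# The published protocol nominally describes a 70:10:20 split, but its
# actual partition counts (330 ideal patches -> 240/30/60; 142 non-ideal
# -> 103/13/26) correspond to fractions 8/11, 1/11, 2/11 with
# largest-remainder rounding, which is what `split_fractions` defaults to.
# The ideal pool is always split this way; for mixed partitions the
# non-ideal pool is split with the same fractions and appended subset-wise.

#' Build seeded, stratified train/val/test splits
#'
#' @param index A corpus index data frame with columns `path`, `ideal`,
#'   `gt_pi` (and optionally `stratum`; recomputed from `gt_pi` under
#'   scheme A when absent).
#' @param partition Ideal:non-ideal mix: `"100:0"` trains on ideal patches
#'   only; `"70:30"` adds non-ideal patches at 30% of the total (drawn as
#'   a seeded stratified sample of the non-ideal pool); `"50:50"` adds as
#'   many non-ideal patches as there are ideal ones.
#' @param seed Integer seed for shuffling and non-ideal sampling.
#' @param split_fractions Train/val/test fractions (summing to 1) applied
#'   to each pool with largest-remainder rounding.
#' @return A data frame `path`, `ideal`, `stratum`, `subset`
#'   (`train`/`val`/`test`), one row per patch used by the partition.
#'   Stratification on the Low/Medium/High PI ranges is preserved within
#'   each pool, and no patch appears in two subsets.
#' @examples
#' idx <- data.frame(path = sprintf("p%03d.png", 1:33),
#'                   ideal = TRUE,
#'                   gt_pi = rep(c(5, 20, 50), each = 11))
#' table(make_splits(idx, "100:0", seed = 1)$subset)  # 24/3/6
#' @export
make_splits <- function(index, partition = c("100:0", "70:30", "50:50"),
                        seed = 1L,
                        split_fractions = c(8, 1, 2) / 11) {
  partition <- match.arg(partition)
  stopifnot(is.data.frame(index),
            all(c("path", "ideal", "gt_pi") %in% names(index)),
            abs(sum(split_fractions) - 1) < 1e-8,
            length(split_fractions) == 3)
  if (is.null(index$stratum)) {
    index$stratum <- classify_pi_range(index$gt_pi, scheme = "A")
  }
  ideal_pool <- index[index$ideal, , drop = FALSE]
  nonideal_pool <- index[!index$ideal, , drop = FALSE]
  n_i <- nrow(ideal_pool)
  if (n_i == 0) {
    stop_ki67("no ideal patches in the corpus index",
              class = "ki67pi_sampling_error")
  }
  n_n <- switch(partition,
    "100:0" = 0L,
    # non-ideal patches make up 30% of the total: ceiling(3/7 of the ideal
    # pool) in exact integer arithmetic (330 ideal -> 142 non-ideal)
    "70:30" = as.integer((n_i * 3L + 6L) %/% 7L),
    "50:50" = n_i)

  with_seed(seed, {
    out <- assign_subsets(ideal_pool, split_fractions)
    if (n_n > 0) {
      if (nrow(nonideal_pool) < n_n) {
        stop_ki67("partition %s needs %d non-ideal patches, corpus has %d",
                  partition, n_n, nrow(nonideal_pool),
                  class = "ki67pi_sampling_error")
      }
      take <- sample_stratified(nonideal_pool, n_n)
      out <- rbind(out, assign_subsets(take, split_fractions))
    }
    rownames(out) <- NULL
    out
  })
}

# Seeded stratified subsample of n rows, proportional across strata.
sample_stratified <- function(pool, n) {
  strata <- c("Low", "Medium", "High")
  sizes <- vapply(strata, function(s) sum(pool$stratum == s), integer(1))
  per <- drop(allocate_across_strata(sizes, n))
  short <- which(sizes < per)
  if (length(short)) {
    stop_ki67("stratum %s has too few patches for the requested sample",
              strata[short[1]], class = "ki67pi_sampling_error")
  }
  rows <- unlist(lapply(seq_along(strata), function(s) {
    cand <- which(pool$stratum == strata[s])
    if (per[s] == 0) integer() else cand[sample.int(length(cand), per[s])]
  }))
  pool[rows, , drop = FALSE]
}

# Split one pool into train/val/test: global counts by largest remainder,
# distributed across PI strata proportionally, shuffled within stratum.
assign_subsets <- function(pool, fracs) {
  subsets <- c("train", "val", "test")
  counts <- largest_remainder(nrow(pool), fracs)
  strata <- c("Low", "Medium", "High")
  sizes <- vapply(strata, function(s) sum(pool$stratum == s), integer(1))
  if (any(sizes == 0) && nrow(pool) >= 3) {
    stop_ki67("stratum %s is empty: cannot stratify the split",
              strata[which(sizes == 0)[1]], class = "ki67pi_sampling_error")
  }
  alloc <- allocate_across_strata(sizes, counts)
  pool$subset <- NA_character_
  for (s in seq_along(strata)) {
    rows <- which(pool$stratum == strata[s])
    rows <- rows[sample.int(length(rows))]
    lab <- rep(subsets, alloc[s, ])
    pool$subset[rows[seq_along(lab)]] <- lab
  }
  pool[!is.na(pool$subset),
       c("path", "ideal", "stratum", "subset"), drop = FALSE]
}

#' Summarise a split as the published bookkeeping table row
#'
#' @param splits A data frame from [make_splits()].
#' @return A data frame with one row per subset and columns `ideal`,
#'   `nonideal`, `total`.
#' @export
split_counts <- function(splits) {
  subsets <- c("train", "val", "test")
  do.call(rbind, lapply(subsets, function(ss) {
    sel <- splits$subset == ss
    data.frame(subset = ss, ideal = sum(sel & splits$ideal),
               nonideal = sum(sel & !splits$ideal), total = sum(sel),
               stringsAsFactors = FALSE)
  }))
}
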