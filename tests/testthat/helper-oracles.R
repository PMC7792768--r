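# Independent oracles used to cross-check the package implementations.
# These are deliberately written as direct transcriptions of the formulas
# (or brute-force algorithms), not as calls into the code paths they test.

# Direct evaluation of the isotropic Gaussian density kernel at offset
# (dx, dy).
oracle_gauss <- function(dx, dy, sigma) {
  exp(-(dx^2 + dy^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
}

# Direct transcription of the four regression-loss formulas with mean
# reduction.
oracle_loss <- function(kind, r, delta = 0.1) {
  switch(kind,
    mse = sum(r^2) / length(r),
    rmse = sqrt(sum(r^2) / length(r)),
    huber = {
      v <- numeric(length(r))
      for (i in seq_along(r)) {
        v[i] <- if (abs(r[i]) <= delta) r[i]^2 / 2 else {
          delta * abs(r[i]) - delta^2 / 2
        }
      }
      sum(v) / length(r)
    },
    logcosh = sum(log(cosh(r))) / length(r)
  )
}

# Brute-force hotspot PI: average nucleus count, inclusive threshold,
# accumulate both classes over qualifying patches.
oracle_hotspot <- function(pos, neg) {
  n <- pos + neg
  navg <- sum(n) / length(n)
  p_tot <- 0; n_tot <- 0
  for (i in seq_along(n)) {
    if (n[i] >= navg) {
      p_tot <- p_tot + pos[i]
      n_tot <- n_tot + neg[i]
    }
  }
  if (p_tot + n_tot == 0) NA_real_ else 100 * p_tot / (p_tot + n_tot)
}

# Maximum bipartite matching size (Kuhn's augmenting-path algorithm)
# between ground-truth and predicted points under a distance cap: the
# optimal-assignment TP count.
oracle_max_matching <- function(gt, pred, radius) {
  ng <- nrow(gt); np <- nrow(pred)
  if (ng == 0 || np == 0) return(0L)
  adj <- (outer(gt$x, pred$x, "-")^2 +
          outer(gt$y, pred$y, "-")^2) <= radius^2
  e <- new.env()
  e$match_p <- rep(0L, np)
  aug <- function(g) {
    for (p in which(adj[g, ])) {
      if (!e$seen[p]) {
        e$seen[p] <- TRUE
        if (e$match_p[p] == 0L || aug(e$match_p[p])) {
          e$match_p[p] <- g
          return(TRUE)
        }
      }
    }
    FALSE
  }
  tp <- 0L
  for (g in seq_len(ng)) {
    e$seen <- rep(FALSE, np)
    if (aug(g)) tp <- tp + 1L
  }
  tp
}

# Random annotation set with a guaranteed minimum pairwise distance,
# sampled by rejection.
random_annotations <- function(n, size, min_dist, margin = 10) {
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n) {
    cand <- c(sample(margin:(size - 1 - margin), 1),
              sample(margin:(size - 1 - margin), 1))
    if (nrow(pts) == 0 ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >
          min_dist^2) {
      pts <- rbind(pts, cand)
    }
  }
  annotation_df(pts[, 1], pts[, 2],
                sample(c("pos", "neg"), n, replace = TRUE))
}
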