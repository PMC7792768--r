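# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps every generator seeded and
# side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Largest-remainder apportionment of n items into length(fracs) buckets.
# Ties go to the earlier bucket, so allocation is deterministic.
largest_remainder <- function(n, fracs) {
  stopifnot(n >= 0, all(fracs >= 0), abs(sum(fracs) - 1) < 1e-8)
  q <- n * fracs
  f <- floor(q)
  k <- n - sum(f)
  if (k > 0) {
    r <- q - f
    idx <- order(-r, seq_along(r))[seq_len(k)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

stop_ki67 <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ki67pi_error")))
}

is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L && is.numeric(img)
}

assert_rgb_image <- function(img, what = "image") {
  if (!is_rgb_image(img)) {
    stop_ki67("%s must be a numeric H x W x 3 array", what, class = "ki67pi_contract_error")
  }
  invisible(img)
}
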