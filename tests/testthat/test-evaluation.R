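test_that("matching follows greedy-by-distance with one-to-one pairing", {
  m <- match_detections(data.frame(x = 10, y = 10),
                        data.frame(x = 12, y = 11), radius = 6)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  expect_equal(m$pairs$distance, sqrt(5))

  # empty predictions: everything is a miss
  m2 <- match_detections(data.frame(x = c(1, 2), y = c(1, 2)),
                         data.frame(x = numeric(), y = numeric()))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 0, 2))

  # the nearer of two candidate predictions is matched
  m3 <- match_detections(data.frame(x = 10, y = 10),
                         data.frame(x = c(11, 13), y = c(10, 10)))
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1, 1, 0))
  expect_equal(m3$pairs$pred, 1)

  # beyond the radius nothing matches
  m4 <- match_detections(data.frame(x = 0, y = 0),
                         data.frame(x = 10, y = 10), radius = 6)
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0, 1, 1))
})

test_that("F1 handles the boundary conventions", {
  expect_equal(f1_score(list(tp = 8, fp = 2, fn = 2)), 0.8)
  expect_equal(f1_score(list(tp = 0, fp = 3, fn = 1)), 0)
  expect_equal(f1_score(list(tp = 5, fp = 0, fn = 0)), 1)
  # both empty: no error committed
  expect_equal(f1_score(match_detections(data.frame(x = numeric(),
                                                    y = numeric()),
                                         data.frame(x = numeric(),
                                                    y = numeric()))), 1)
})

test_that("swapping ground truth and prediction swaps fp and fn only", {
  set.seed(41)
  for (rep in 1:10) {
    gt <- data.frame(x = runif(15, 0, 100), y = runif(15, 0, 100))
    pr <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100))
    a <- match_detections(gt, pr)
    b <- match_detections(pr, gt)
    expect_equal(a$tp, b$tp)
    expect_equal(a$fp, b$fn)
    expect_equal(a$fn, b$fp)
    expect_equal(f1_score(a), f1_score(b))
  }
})

test_that("greedy matching equals optimal assignment on small point sets", {
  set.seed(42)
  agree <- 0; diff_sizes <- c()
  # point sets at detection density: up to 30 nuclei in a 128 px patch
  for (rep in 1:300) {
    ng <- sample(0:30, 1); np <- sample(0:30, 1)
    gt <- data.frame(x = runif(ng, 0, 128), y = runif(ng, 0, 128))
    pr <- data.frame(x = runif(np, 0, 128), y = runif(np, 0, 128))
    tp_greedy <- match_detections(gt, pr, radius = 6)$tp
    tp_opt <- oracle_max_matching(gt, pr, radius = 6)
    if (tp_greedy == tp_opt) agree <- agree + 1 else {
      diff_sizes <- c(diff_sizes, tp_opt - tp_greedy)
    }
  }
  expect_gte(agree / 300, 0.99)
  if (length(diff_sizes)) expect_lte(max(diff_sizes), 1)
})

test_that("PI difference keeps the sign per image, absolute in summary", {
  d <- pi_difference(c(30, 25, 40), c(25, 30, 40))
  expect_equal(d$signed, c(5, -5, 0))
  expect_equal(d$mean_abs, 10 / 3)
  expect_equal(pi_difference(c(30, NA), c(25, 10))$n_excluded, 1)
})

test_that("Pearson correlation matches its defining cases", {
  x <- c(5, 20, 35, 50, 80)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, 100 - x)$r, -1)
  set.seed(43)
  a <- runif(1000); b <- runif(1000)
  expect_lt(abs(pearson_r(a, b)$r), 0.1)
  expect_error(pearson_r(c(1, 2), c(1, 2)),
               class = "ki67pi_contract_error")
  expect_error(pearson_r(rep(5, 10), runif(10)),
               class = "ki67pi_degenerate_error")
})

test_that("range accuracy counts label agreement under a scheme", {
  expect_equal(range_accuracy(c(5, 15, 80), c(5, 12, 85))$accuracy, 1)
  expect_equal(range_accuracy(c(5, 15, 80), c(20, 30, 90),
                              scheme = "B")$accuracy, 2 / 3)
  r <- range_accuracy(c(5, NA, 80), c(6, 10, 80))
  expect_equal(r$n, 2)
  expect_equal(r$n_excluded, 1)
  expect_error(range_accuracy(c(NA_real_), c(NA_real_)),
               class = "ki67pi_degenerate_error")
})

test_that("per-image detection evaluation splits classes", {
  gt <- annotation_df(c(10, 20, 30), c(10, 20, 30),
                      c("pos", "pos", "neg"))
  pred <- annotation_df(c(11, 50, 31), c(10, 50, 30),
                        c("pos", "neg", "neg"))
  ev <- evaluate_detections(gt, pred)
  expect_equal(ev$tp, c(1, 1))
  expect_equal(ev$fp, c(0, 1))
  expect_equal(ev$fn, c(1, 0))
})
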