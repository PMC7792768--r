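test_that("the default architecture doubles filters from 32 to 1024", {
  cfg <- unet_config()
  expect_equal(unet_filters(cfg), c(32, 64, 128, 256, 512, 1024))
  expect_equal(cfg$base_filters * 2^(cfg$depth - 1), cfg$max_filters)
})

test_that("indivisible input dimensions are rejected", {
  expect_error(unet_config(depth = 6, input_size = c(100, 100)),
               class = "ki67pi_config_error")
  net <- build_unet(unet_config(depth = 3, base_filters = 4,
                                max_filters = 16, input_size = c(32, 32)))
  expect_error(predict(net, array(0, c(30, 30, 3))),
               class = "ki67pi_contract_error")
})

test_that("forward pass preserves spatial size and is non-negative", {
  cfg <- unet_config(depth = 3, base_filters = 4, max_filters = 16,
                     input_size = c(32, 32))
  net <- build_unet(cfg, seed = 2)
  x <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  y <- predict(net, x)
  expect_equal(dim(y), c(32, 32, 3))
  expect_gte(min(y), 0)

  # a 256 x 256 x 3 input maps to a 256 x 256 x 3 output on a six-level
  # model (reduced filter widths keep this cheap; depth drives geometry)
  cfg6 <- unet_config(depth = 6, base_filters = 2, max_filters = 64,
                      input_size = c(256, 256))
  net6 <- build_unet(cfg6, seed = 3)
  y6 <- predict(net6, array(runif(256 * 256 * 3, 0, 255), c(256, 256, 3)))
  expect_equal(dim(y6), c(256, 256, 3))
  expect_gte(min(y6), 0)
})

test_that("batch loss equals the R loss on the network's own output", {
  cfg <- unet_config(depth = 2, base_filters = 3, max_filters = 6,
                     input_size = c(16, 16))
  net <- build_unet(cfg, seed = 4)
  set.seed(5)
  xs <- lapply(1:3, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  ts <- lapply(1:3, function(i) array(runif(16 * 16 * 3, 0, 0.3),
                                      c(16, 16, 3)))
  preds <- lapply(xs, function(x) {
    cpp_unet_forward(net$weights, x, cfg$depth)
  })
  for (kind in c("mse", "rmse", "huber", "logcosh")) {
    got <- cpp_unet_batch(net$weights, xs, ts, cfg$depth, kind, 0.1,
                          FALSE)$loss
    want <- unet_loss(simplify2array(preds), simplify2array(ts),
                      loss_config(kind))
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("analytic gradients match finite differences where smooth", {
  cfg <- unet_config(depth = 2, base_filters = 3, max_filters = 6,
                     input_size = c(8, 8))
  net <- build_unet(cfg, seed = 3)
  # lift all biases so every ReLU stays active: the loss is then locally
  # smooth and central differences are trustworthy
  for (nm in names(net$weights)) {
    net$weights[[nm]]$b <- net$weights[[nm]]$b + 1
  }
  set.seed(6)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- array(runif(8 * 8 * 3, 0, 0.3), c(8, 8, 3))
  r <- cpp_unet_batch(net$weights, list(x), list(y), cfg$depth, "mse",
                      0.1, TRUE)
  h <- 3e-4
  set.seed(7)
  dirs <- rapply(net$weights, function(w) {
    array(rnorm(length(w)), dim = if (is.null(dim(w))) length(w) else
          dim(w))
  }, how = "replace")
  wp <- net$weights; wm <- net$weights; dot <- 0
  for (nm in names(net$weights)) {
    for (part in c("W", "b")) {
      wp[[nm]][[part]] <- wp[[nm]][[part]] + h * dirs[[nm]][[part]]
      wm[[nm]][[part]] <- wm[[nm]][[part]] - h * dirs[[nm]][[part]]
      dot <- dot + sum(r$grads[[nm]][[part]] * dirs[[nm]][[part]])
    }
  }
  lp <- cpp_unet_batch(wp, list(x), list(y), cfg$depth, "mse", 0.1,
                       FALSE)$loss
  lm <- cpp_unet_batch(wm, list(x), list(y), cfg$depth, "mse", 0.1,
                       FALSE)$loss
  expect_equal((lp - lm) / (2 * h), dot, tolerance = 1e-3)
})

test_that("training runs, records history and is seed-reproducible", {
  corpus <- fixture_corpus_small()
  cfg <- unet_config(depth = 2, base_filters = 4, max_filters = 8,
                     input_size = c(64, 64))
  ctl <- train_config(epochs = 1, batch_size = 4, seed = 5,
                      partition = "100:0")
  fit <- train_unet(build_unet(cfg, seed = 9), corpus, control = ctl)
  expect_s3_class(fit, "ki67_unet_fit")
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$train_loss))

  fit2 <- train_unet(build_unet(cfg, seed = 9), corpus, control = ctl)
  expect_identical(fit$history$train_loss, fit2$history$train_loss)

  # empty training set is a config error
  sp <- fit$splits
  sp$subset[sp$subset == "train"] <- "test"
  expect_error(train_unet(build_unet(cfg, seed = 9), corpus, splits = sp,
                          control = ctl),
               class = "ki67pi_config_error")
})

test_that("desk-scale training reduces the loss over ten epochs", {
  fit <- fixture_fit_main()
  h <- fit$history
  expect_equal(nrow(h), 10)
  expect_lt(h$train_loss[10], h$train_loss[1])
  expect_lt(h$val_loss[10], h$val_loss[1])
})

test_that("a trained model is quiet on a blank white patch", {
  fit <- fixture_fit_main()
  white <- array(255, c(128, 128, 3))
  pred <- predict(fit, white)
  # class channels stay near zero relative to the unit training peak, and
  # nothing survives the decode
  expect_lt(max(pred[, , 1:2]), 0.1)
  expect_equal(nrow(detect_nuclei(pred, config = fit$prox)), 0)
})
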