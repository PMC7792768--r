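#' Training protocol configuration
#'
#' Defaults follow the full-scale training protocol (100 epochs, batch
#' size 16, learning rate 0.001, Adam); the desk-scale profile used in
#' the package's own experiments shrinks this to <= 10 epochs and batch
#' size 8 together with the reduced [unet_config()] profile.
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Seed for shuffling (and the default split).
#' @param partition Ideal:non-ideal data partition, see [make_splits()].
#' @param augment If `TRUE`, random horizontal/vertical flips are applied
#'   per epoch (image and target together). Off by default.
#' @param checkpoint `"best_val"` keeps the weights of the epoch with the
#'   lowest validation loss; `"last"` keeps the final epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L,
                         learning_rate = 0.001, seed = 1L,
                         partition = c("100:0", "70:30", "50:50"),
                         augment = FALSE,
                         checkpoint = c("best_val", "last")) {
  partition <- match.arg(partition)
  checkpoint <- match.arg(checkpoint)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 partition = partition, augment = isTRUE(augment),
                 checkpoint = checkpoint),
            class = "train_config")
}

# Load one corpus sample as normalised input + proximity-map target.
load_sample <- function(index, i, prox) {
  p <- read_patch(index, i)
  list(x = p$image / 255,
       y = build_proximity_map(p$annotations, dim(p$image)[1:2], prox),
       annotations = p$annotations)
}

adam_init <- function(weights) {
  rapply(weights, function(w) array(0, dim = dim(w) %||% length(w)),
         how = "replace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(weights, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (nm in names(weights)) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[part]]
      state$m[[nm]][[part]] <- b1 * state$m[[nm]][[part]] + (1 - b1) * g
      state$v[[nm]][[part]] <- b2 * state$v[[nm]][[part]] + (1 - b2) * g^2
      weights[[nm]][[part]] <- weights[[nm]][[part]] -
        lr * (state$m[[nm]][[part]] / c1) /
        (sqrt(state$v[[nm]][[part]] / c2) + eps)
    }
  }
  list(weights = weights, state = state)
}

flip_sample <- function(s, flip_h, flip_v) {
  f <- function(a) {
    if (flip_h) a <- a[, dim(a)[2]:1, , drop = FALSE]
    if (flip_v) a <- a[dim(a)[1]:1, , , drop = FALSE]
    a
  }
  s$x <- f(s$x); s$y <- f(s$y)
  s
}

#' Train the U-Net detector on a synthetic (or compatible) corpus
#'
#' Builds proximity-map targets from the per-patch annotations, splits the
#' corpus according to the requested ideal/non-ideal partition (stratified
#' on the Low/Medium/High PI ranges), and optimises the chosen regression
#' loss with Adam. Per-epoch training and validation losses are recorded;
#' the returned fit carries the checkpointed weights (best validation loss
#' by default). With a fixed seed the run is reproducible on one device.
#'
#' @param model A `ki67_unet` from [build_unet()].
#' @param corpus A corpus index (from [render_corpus()] / [read_corpus()]).
#' @param splits Optional split assignment from [make_splits()]; computed
#'   from `control$partition` and `control$seed` when `NULL`.
#' @param loss A [loss_config()].
#' @param control A [train_config()].
#' @param prox The [proximity_config()] defining the regression targets.
#' @param verbose Print per-epoch losses.
#' @return An object of class `ki67_unet_fit`.
#' @export
train_unet <- function(model, corpus, splits = NULL,
                       loss = loss_config("rmse"),
                       control = train_config(),
                       prox = proximity_config(), verbose = FALSE) {
  stopifnot(inherits(model, "ki67_unet"), inherits(loss, "loss_config"),
            inherits(control, "train_config"))
  if (is.null(splits)) {
    splits <- make_splits(corpus, control$partition, seed = control$seed)
  }
  row_of <- match(splits$path, corpus$path)
  train_rows <- row_of[splits$subset == "train"]
  val_rows <- row_of[splits$subset == "val"]
  if (length(train_rows) == 0) {
    stop_ki67("training subset is empty", class = "ki67pi_config_error")
  }

  train_data <- lapply(train_rows, function(i) load_sample(corpus, i, prox))
  val_data <- lapply(val_rows, function(i) load_sample(corpus, i, prox))

  depth <- model$config$depth
  weights <- model$weights
  state <- list(m = adam_init(weights), v = adam_init(weights))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  t_step <- 0L

  eval_loss <- function(w, data, chunk = 8L) {
    if (length(data) == 0) return(NA_real_)
    tot <- 0
    for (i0 in seq(1, length(data), by = chunk)) {
      idx <- i0:min(i0 + chunk - 1, length(data))
      r <- cpp_unet_batch(w, lapply(data[idx], `[[`, "x"),
                          lapply(data[idx], `[[`, "y"),
                          depth, loss$kind, loss$delta, FALSE)
      tot <- tot + r$loss * length(idx)
    }
    tot / length(data)
  }

  with_seed(control$seed, {
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(length(train_data))
      ep_loss <- 0
      for (i0 in seq(1, length(ord), by = control$batch_size)) {
        idx <- ord[i0:min(i0 + control$batch_size - 1, length(ord))]
        batch <- train_data[idx]
        if (control$augment) {
          batch <- lapply(batch, function(s) {
            flip_sample(s, runif(1) < 0.5, runif(1) < 0.5)
          })
        }
        r <- cpp_unet_batch(weights, lapply(batch, `[[`, "x"),
                            lapply(batch, `[[`, "y"),
                            depth, loss$kind, loss$delta, TRUE)
        t_step <- t_step + 1L
        upd <- adam_step(weights, r$grads, state, control$learning_rate,
                         t_step)
        weights <- upd$weights; state <- upd$state
        ep_loss <- ep_loss + r$loss * length(idx)
      }
      ep_loss <- ep_loss / length(train_data)
      vl <- eval_loss(weights, val_data)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss,
                                           val_loss = vl))
      crit <- if (is.na(vl)) ep_loss else vl
      if (crit < best$loss) {
        best <- list(loss = crit, weights = weights, epoch = epoch)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f",
                        epoch, ep_loss, vl))
      }
    }
  })

  final_weights <- if (control$checkpoint == "best_val") {
    best$weights
  } else {
    weights
  }
  structure(list(config = model$config, weights = final_weights,
                 history = history, best_epoch = best$epoch,
                 loss = loss, control = control, prox = prox,
                 splits = splits),
            class = c("ki67_unet_fit", "ki67_unet"))
}

#' @export
print.ki67_unet_fit <- function(x, ...) {
  cat("Fitted U-Net proximity-map regressor\n")
  cat(sprintf("  depth %d, filters %s, loss %s, partition %s\n",
              x$config$depth, paste(unet_filters(x$config), collapse = "-"),
              x$loss$kind, x$control$partition))
  n <- nrow(x$history)
  cat(sprintf("  %d epochs; final train loss %.5f, val loss %.5f\n",
              n, x$history$train_loss[n], x$history$val_loss[n]))
  cat(sprintf("  checkpoint: epoch %d (%s)\n", x$best_epoch,
              x$control$checkpoint))
  invisible(x)
}

#' @export
summary.ki67_unet_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  sc <- split_counts(object$splits)
  cat("\nSplit bookkeeping (ideal:nonideal per subset):\n")
  print(sc, row.names = FALSE)
  invisible(object)
}

#' @export
plot.ki67_unet_fit <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = sprintf("%s loss", x$loss$kind), ylim = ylim, ...)
  if (!all(is.na(h$val_loss))) {
    lines(h$epoch, h$val_loss, lty = 2)
    legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Detect nuclei and score the PI of one patch with a fitted model
#'
#' Convenience wrapper: forward pass, detection decoding and PI in one
#' step.
#'
#' @param fit A `ki67_unet_fit`.
#' @param image RGB array, 0-255 scale.
#' @param floor Detection floor, see [detect_nuclei()].
#' @return A list with `detections` (annotation dialect) and `pi`
#'   (a `pi_result`).
#' @export
score_patch <- function(fit, image, floor = 0.05) {
  det <- detect_nuclei(predict(fit, image), floor = floor,
                       config = fit$prox)
  cls <- count_classes(det)
  list(detections = det, pi = compute_pi(cls[["pos"]], cls[["neg"]]))
}
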