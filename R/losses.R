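#' Regression loss configuration
#'
#' Proximity-map regression is trained with one of four per-pixel
#' regression losses, each reduced by the mean over all pixels, channels
#' and batch items (`n` below is that total element count, residual
#' `r = y - yhat`):
#' \itemize{
#'   \item `huber`: `mean( 0.5 r^2 )` where `|r| <= delta`, else
#'     `mean( delta |r| - delta^2 / 2 )` — quadratic near zero, linear in
#'     the tails, so stray bright pixels are not over-penalised.
#'   \item `logcosh`: `mean( log cosh r )` — smooth Huber-like behaviour
#'     without a tuning constant.
#'   \item `mse`: `mean( r^2 )`.
#'   \item `rmse`: `sqrt(mean( r^2 ))`, the square root taken over the
#'     whole batch.
#' }
#'
#' @param kind One of `"rmse"`, `"huber"`, `"logcosh"`, `"mse"`. RMSE is
#'   the default: it gave the best PI-range accuracy and correlation in
#'   development and is the loss the shipped defaults assume.
#' @param delta Huber transition point (> 0, default 0.1 — about a tenth
#'   of the unit kernel peak).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(kind = c("rmse", "huber", "logcosh", "mse"),
                        delta = 0.1) {
  kind <- match.arg(kind)
  if (!is.numeric(delta) || delta <= 0) {
    stop_ki67("huber delta must be > 0", class = "ki67pi_contract_error")
  }
  structure(list(kind = kind, delta = delta), class = "loss_config")
}

#' Evaluate a regression loss between prediction and target maps
#'
#' @param y_pred,y_true Numeric arrays of identical shape (a single map or
#'   a batch).
#' @param config A [loss_config()].
#' @return A non-negative scalar; zero iff `y_pred == y_true`.
#' @examples
#' unet_loss(array(0, c(2, 2)), array(0, c(2, 2)))          # 0
#' unet_loss(c(1, 0, 0), c(0, 0, 0), loss_config("mse"))    # 1/3
#' @export
unet_loss <- function(y_pred, y_true, config = loss_config()) {
  if (!identical(dim(y_pred), dim(y_true)) ||
      length(y_pred) != length(y_true)) {
    stop_ki67("y_pred and y_true must have identical shape",
              class = "ki67pi_contract_error")
  }
  r <- as.numeric(y_pred) - as.numeric(y_true)
  switch(config$kind,
    mse = mean(r^2),
    rmse = sqrt(mean(r^2)),
    huber = {
      a <- abs(r)
      d <- config$delta
      mean(ifelse(a <= d, 0.5 * r^2, d * a - d^2 / 2))
    },
    logcosh = {
      # log(cosh(r)) computed overflow-safely as |r| + log1p(exp(-2|r|)) - log 2
      a <- abs(r)
      mean(a + log1p(exp(-2 * a)) - log(2))
    }
  )
}

#' Gradient of [unet_loss()] with respect to `y_pred`
#'
#' Used for optimiser checks; training itself computes the same gradient
#' in compiled code.
#' @inheritParams unet_loss
#' @return Numeric array shaped like `y_pred`.
#' @export
unet_loss_grad <- function(y_pred, y_true, config = loss_config()) {
  if (!identical(dim(y_pred), dim(y_true))) {
    stop_ki67("y_pred and y_true must have identical shape",
              class = "ki67pi_contract_error")
  }
  r <- y_pred - y_true
  n <- length(r)
  g <- switch(config$kind,
    mse = 2 * r / n,
    rmse = {
      l <- sqrt(mean(r^2))
      if (l == 0) r * 0 else r / (n * l)
    },
    huber = pmin(pmax(r, -config$delta), config$delta) / n,
    logcosh = tanh(r) / n
  )
  if (!is.null(dim(y_pred))) dim(g) <- dim(y_pred)
  g
}
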