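#' Fit the label-distribution hemoglobin regressor
#'
#' Trains the compact SE-headed convolutional network on eye images (usually
#' masked to the conjunctiva with [apply_mask()]) against scalar hemoglobin
#' labels. Each label is encoded as a Gaussian distribution over the support
#' grid ([encode_label()]); the network's softmax output is fit by minimizing
#' the composite KL + lambda * L1 loss ([combined_loss()]) with minibatch
#' stochastic gradient descent (momentum 0.9, weight decay 5e-4, batch size
#' 64, learning rate 0.01 by default). Training stops early when validation
#' MAE has not improved for `patience` epochs, and the parameters from the
#' best validation epoch are restored. Everything is reproducible under
#' `seed`.
#'
#' @param x `n x H x W x 3` image array, values in `[0, 255]`. Images whose
#'   side differs from `net$input_size` are bilinearly resized.
#' @param y Numeric hemoglobin labels in the grid range.
#' @param x_val,y_val Optional validation set used for early stopping; when
#'   omitted, training loss is monitored instead.
#' @param net A [net_config()] (default: desk-scale 64x64, depth 4).
#' @param grid A [support_grid()]; `grid$n_bins` must equal `net$n_output`.
#' @param sigma Label-encoding sd (default 1).
#' @param lambda Weight of the L1 loss term (default 1).
#' @param epochs Maximum training epochs (default 80; 0 returns the
#'   initialized, untrained model with empty history).
#' @param batch_size Minibatch size (default 64).
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @param patience Early-stopping patience in epochs (default 15; must be
#'   less than `epochs` when `epochs > 0`).
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param verbose Print one line per epoch.
#' @return An object of class `"hb_ldl"` with components `net` (trained
#'   `"hb_net"`), `grid`, `sigma`, `lambda`, `history` (data.frame
#'   `epoch, train_loss, val_mae`), `best_epoch`, `fitted.values`, `y`,
#'   `call`. Methods: [predict.hb_ldl()], `print`, `summary`, `coef`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(40, simulator_config(seed = 1))
#' imgs <- as_image_array(ds)
#' fit <- hb_ldl(imgs, ds$hb, epochs = 2, patience = 1, seed = 1)
#' predict(fit, imgs[1:2, , , , drop = FALSE])
#' }
#' @export
hb_ldl <- function(x, y, x_val = NULL, y_val = NULL,
                   net = net_config(), grid = support_grid(),
                   sigma = 1, lambda = 1,
                   epochs = 80L, batch_size = 64L,
                   lr = 0.01, momentum = 0.9, weight_decay = 5e-4,
                   patience = 15L, seed = 1L, verbose = FALSE) {
  cl <- match.call()
  check_grid(grid)
  if (grid$n_bins != net$n_output)
    stop("`grid$n_bins` must equal `net$n_output`")
  x <- coerce_images(x, net$input_size)
  n <- dim(x)[1]
  if (n == 0L || length(y) != n) stop("`x` and `y` sizes must match (non-empty)")
  if (any(y < grid$k_min | y > grid$k_max))
    stop("labels outside the support grid range")
  if (epochs > 0L && patience >= epochs + 1L)
    patience <- epochs # cap: patience cannot exceed the epoch budget
  has_val <- !is.null(x_val)
  if (has_val) {
    x_val <- coerce_images(x_val, net$input_size)
    if (length(y_val) != dim(x_val)[1]) stop("validation sizes must match")
  }

  model <- cnn_init(net, seed = seed)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_mae = numeric(0))
  best <- list(params = model$params, metric = Inf, epoch = 0L)
  velocity <- NULL
  wait <- 0L
  if (epochs > 0L) {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        out <- cnn_loss_and_grad(model, x[idx, , , , drop = FALSE], y[idx],
                                 sigma = sigma, lambda = lambda, grid = grid)
        if (!is.finite(out$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        st <- sgd_step(model$params, out$grads, velocity,
                       lr, momentum, weight_decay)
        model$params <- st$params; velocity <- st$velocity
        ep_loss <- ep_loss + out$loss * length(idx); nb <- nb + length(idx)
      }
      ep_loss <- ep_loss / nb
      monitor <- if (has_val) {
        mean(abs(cnn_predict(model, x_val, grid) - y_val))
      } else ep_loss
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = ep_loss,
                                  val_mae = if (has_val) monitor else NA_real_))
      if (verbose)
        message(sprintf("epoch %3d  train loss %.4f  %s %.4f", ep, ep_loss,
                        if (has_val) "val MAE" else "monitor", monitor))
      if (monitor < best$metric - 1e-8) {
        best <- list(params = model$params, metric = monitor, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    model$params <- best$params
  }
  fitted <- cnn_predict(model, x, grid)
  structure(list(net = model, grid = grid, sigma = sigma, lambda = lambda,
                 history = history, best_epoch = best$epoch,
                 fitted.values = fitted, y = y, call = cl),
            class = "hb_ldl")
}

coerce_images <- function(x, input_size) {
  if (inherits(x, "hb_sim_dataset")) x <- as_image_array(x)
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(1L, d); d <- dim(x) }
  if (length(d) != 4L || d[4] != 3L)
    stop("images must be an n x H x W x 3 array")
  if (d[2] != input_size || d[3] != input_size)
    x <- resize_images(x, input_size)
  x
}

#' Resize a batch of images
#'
#' Bilinear resizing (via EBImage) of an `n x H x W x 3` array to square
#' side `size`; used to bring bounding-box crops to the network's input size.
#'
#' @param images `n x H x W x 3` array in `[0, 255]`.
#' @param size Target side length.
#' @return `n x size x size x 3` array.
#' @export
resize_images <- function(images, size) {
  d <- dim(images)
  out <- array(0, c(d[1], size, size, 3L))
  for (i in seq_len(d[1])) {
    im <- EBImage::resize(EBImage::Image(images[i, , , ] / 255,
                                         colormode = "Color"),
                          w = size, h = size)
    out[i, , , ] <- EBImage::imageData(im) * 255
  }
  out
}

#' Predict hemoglobin from a fitted model
#'
#' @param object An `"hb_ldl"` fit.
#' @param newdata `n x H x W x 3` image array (resized if needed); omitted
#'   returns fitted values.
#' @param type `"response"` (decoded Hb values, always inside the support
#'   interval) or `"distribution"` (matrix of label-distribution
#'   probabilities).
#' @param ... Unused.
#' @export
predict.hb_ldl <- function(object, newdata = NULL,
                           type = c("response", "distribution"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted.values)
    newdata <- NULL
    stop("`type = \"distribution\"` requires `newdata`")
  }
  newdata <- coerce_images(newdata, object$net$config$input_size)
  cnn_predict(object$net, newdata, object$grid, type = type)
}

#' @export
print.hb_ldl <- function(x, ...) {
  cfg <- x$net$config
  cat("Label-distribution hemoglobin regressor (hb_ldl)\n")
  cat(sprintf("  network: %d conv blocks, channels %s, SE reduction %d, %d-way head\n",
              cfg$depth, paste(cfg$channels, collapse = "/"),
              cfg$se_reduction, cfg$n_output))
  cat(sprintf("  support: [%g, %g] in %d bins; sigma = %g, lambda = %g\n",
              x$grid$k_min, x$grid$k_max, x$grid$n_bins, x$sigma, x$lambda))
  if (nrow(x$history) > 0L)
    cat(sprintf("  trained %d epochs (best at %d), final train loss %.4f\n",
                nrow(x$history), x$best_epoch,
                x$history$train_loss[nrow(x$history)]))
  else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' @export
summary.hb_ldl <- function(object, ...) {
  res <- object$y - object$fitted.values
  m <- regression_metrics(object$y, object$fitted.values)
  out <- list(fit = object, metrics = m, residual_summary = summary(res))
  class(out) <- "summary.hb_ldl"
  out
}

#' @export
print.summary.hb_ldl <- function(x, ...) {
  print(x$fit)
  cat("\nTraining-set metrics:\n")
  print(x$metrics)
  cat("\nResiduals:\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
coef.hb_ldl <- function(object, ...) object$net$params

#' @export
residuals.hb_ldl <- function(object, ...) object$y - object$fitted.values

#' @export
fitted.hb_ldl <- function(object, ...) object$fitted.values

#' Plot training history of a fitted hemoglobin regressor
#'
#' @param x An `"hb_ldl"` fit with a non-empty history.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hb_ldl <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) stop("no training history to plot")
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "train loss", ...)
  if (any(is.finite(h$val_mae))) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(h$epoch, h$val_mae, type = "l", lty = 2, col = 2,
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4)
    graphics::mtext("validation MAE", side = 4, line = 2)
  }
  invisible(x)
}

#' Simulate hemoglobin draws from the predicted label distributions
#'
#' For each image, draws `nsim` support-grid values according to the model's
#' predicted probability distribution — a posterior-style sample expressing
#' the network's label uncertainty.
#'
#' @param object An `"hb_ldl"` fit.
#' @param nsim Number of draws per image.
#' @param seed Optional seed.
#' @param newdata Image array; required.
#' @param ... Unused.
#' @return `n x nsim` matrix of sampled Hb support values.
#' @export
simulate.hb_ldl <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  probs <- predict(object, newdata, type = "distribution")
  k <- object$grid$values
  t(apply(probs, 1L, function(p) sample(k, nsim, replace = TRUE, prob = p)))
}
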