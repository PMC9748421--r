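#' Support grid of candidate hemoglobin values
#'
#' Builds the ordered, uniformly spaced set of discrete hemoglobin values over
#' which label distributions and the network's softmax head are defined. The
#' grid is realized as the centers of `n_bins` equal-width bins spanning
#' `[k_min, k_max]`, so the default `support_grid()` gives 15 values
#' 5.5, 6.5, ..., 19.5 g/dL — a 15-way output head covering the candidate
#' range \eqn{[5, 20]} while labels themselves live in \eqn{[6, 18]}.
#'
#' @param k_min,k_max Lower and upper bound of the candidate Hb range (g/dL).
#' @param n_bins Number of support points (and width of the network's output
#'   layer). Must be at least 2.
#' @return An object of class `"hb_grid"`: a list with `values` (the support
#'   points), `k_min`, `k_max`, `n_bins` and `spacing`.
#' @examples
#' g <- support_grid()
#' g$values # 5.5 6.5 ... 19.5
#' @export
support_grid <- function(k_min = 5, k_max = 20, n_bins = 15L) {
  if (!is.numeric(k_min) || !is.numeric(k_max) || k_min >= k_max)
    stop("`k_min` must be strictly less than `k_max`")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    stop("`n_bins` must be an integer >= 2")
  spacing <- (k_max - k_min) / n_bins
  values <- k_min + spacing * (seq_len(n_bins) - 0.5)
  structure(
    list(values = values, k_min = k_min, k_max = k_max,
         n_bins = n_bins, spacing = spacing),
    class = "hb_grid"
  )
}

is_hb_grid <- function(x) inherits(x, "hb_grid")

check_grid <- function(grid) {
  if (!is_hb_grid(grid)) stop("`grid` must be a support_grid() object")
  grid
}

#' Encode a scalar hemoglobin label as a distribution over the support grid
#'
#' Replaces the scalar truth value `y` by a discrete Gaussian label
#' distribution centered at `y`: each support point k receives probability
#' proportional to \eqn{\exp(-(k - y)^2 / (2\sigma^2))}, renormalized to sum
#' to one over the grid. Neighboring Hb values thereby share training signal
#' (label distribution learning). The Gaussian density on a discrete support
#' is unnormalized, and the KL loss requires a probability vector, hence the
#' renormalization.
#'
#' @param y Scalar hemoglobin label, in `[6, 18]`.
#' @param sigma Standard deviation of the label kernel, in label units.
#'   Default 1 (one grid spacing on the default grid).
#' @param grid A [support_grid()] object.
#' @return Numeric probability vector of length `grid$n_bins` summing to 1.
#' @examples
#' p <- encode_label(12.5, sigma = 1)
#' sum(p) # 1
#' @export
encode_label <- function(y, sigma = 1, grid = support_grid()) {
  check_grid(grid)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a positive finite scalar")
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y))
    stop("`y` must be a finite scalar")
  # log-space for numerical safety at small sigma
  lp <- -(grid$values - y)^2 / (2 * sigma^2)
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Softmax over network logits
#'
#' Maps a vector of unnormalized scores to a probability distribution over the
#' support grid, \eqn{p_k = \exp(z_k) / \sum_n \exp(z_n)}, computed with
#' max-subtraction for numerical stability.
#'
#' @param logits Finite numeric vector (or matrix with one row per sample).
#' @return Probability vector (or row-stochastic matrix) of the same shape.
#' @examples
#' softmax_probs(c(1, 0)) # ~ c(0.731, 0.269)
#' @export
softmax_probs <- function(logits) {
  if (!is.numeric(logits) || any(!is.finite(logits)))
    stop("`logits` must be finite numeric")
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- logits - max(logits)
    e <- exp(z)
    e / sum(e)
  }
}

#' Kullback-Leibler divergence between two label distributions
#'
#' \eqn{KL(p \| q) = \sum_k p_k \ln(p_k / q_k)}, the (asymmetric) discrepancy
#' used as training loss between the encoded true distribution and the
#' network's softmax output. Terms with \eqn{p_k = 0} contribute 0; predicted
#' probabilities are floored at `1e-12` inside the logarithm so pathological
#' inputs do not produce `-Inf`.
#'
#' @param p_true,p_pred Probability vectors of equal length on the same grid.
#' @return Non-negative scalar; 0 iff the distributions are equal.
#' @examples
#' kl_divergence(c(.5, .5), c(.25, .75)) # 0.5*log(2) + 0.5*log(2/3)
#' @export
kl_divergence <- function(p_true, p_pred) {
  if (length(p_true) != length(p_pred))
    stop("distributions must have the same length (same support grid)")
  check_distribution(p_true, "p_true")
  check_distribution(p_pred, "p_pred")
  if (any(p_pred == 0 & p_true > 0))
    stop("`p_pred` has zero mass where `p_true` is positive; KL is infinite")
  pos <- p_true > 0
  sum(p_true[pos] * (log(p_true[pos]) - log(pmax(p_pred[pos], 1e-12))))
}

check_distribution <- function(p, name) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop("`", name, "` must be a non-negative finite numeric vector")
  if (abs(sum(p) - 1) > 1e-6)
    stop("`", name, "` must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

#' Decode a continuous prediction from a label distribution
#'
#' Reads a scalar hemoglobin estimate off a probability distribution as the
#' expectation over the support grid, \eqn{\hat y = \sum_k k \, p_k}.
#' Expectation decoding (rather than argmax) yields a continuous value and is
#' what the L1 component of the training loss compares against the truth;
#' decoded values are guaranteed to lie inside `[min(grid), max(grid)]`.
#'
#' @param probs Probability vector (or row-stochastic matrix, one sample per
#'   row) over `grid`.
#' @param grid A [support_grid()] object.
#' @return Scalar (or vector) expected hemoglobin value.
#' @export
decode_prediction <- function(probs, grid = support_grid()) {
  check_grid(grid)
  if (is.matrix(probs)) {
    stopifnot(ncol(probs) == grid$n_bins)
    drop(probs %*% grid$values)
  } else {
    stopifnot(length(probs) == grid$n_bins)
    sum(probs * grid$values)
  }
}

#' Composite label-distribution training loss
#'
#' The training objective of the hemoglobin regressor: the KL divergence
#' between the Gaussian-encoded truth and the softmax of the logits, plus
#' `lambda` times the L1 error between the expectation-decoded prediction and
#' the scalar truth,
#' \deqn{\ell(z) = KL(p(y,\sigma) \| \mathrm{softmax}(z)) +
#'   \lambda \, | \hat y(z) - y |.}
#'
#' @param logits Numeric vector of length `grid$n_bins`.
#' @param y Scalar truth label.
#' @param sigma Label-encoding standard deviation (see [encode_label()]).
#' @param grid A [support_grid()] object.
#' @param lambda Non-negative weight of the L1 term (default 1).
#' @return A list of class `"hb_loss"` with components `kl`, `l1`, and
#'   `total = kl + lambda * l1`.
#' @seealso [combined_loss_grad()] for the analytic gradient.
#' @export
combined_loss <- function(logits, y, sigma = 1, grid = support_grid(),
                          lambda = 1) {
  check_grid(grid)
  if (!is.numeric(lambda) || lambda < 0) stop("`lambda` must be >= 0")
  p_true <- encode_label(y, sigma, grid)
  p_pred <- softmax_probs(logits)
  kl <- kl_divergence(p_true, p_pred)
  l1 <- abs(decode_prediction(p_pred, grid) - y)
  structure(list(kl = kl, l1 = l1, total = kl + lambda * l1),
            class = "hb_loss")
}

#' Analytic gradient of the composite loss with respect to the logits
#'
#' With \eqn{p = \mathrm{softmax}(z)}, target \eqn{t} and decoded value
#' \eqn{\hat y = \sum_k k p_k}, the gradient is
#' \eqn{(p - t) + \lambda\,\mathrm{sign}(\hat y - y)\, p \odot (k - \hat y)}.
#' Used by the network's backward pass; its agreement with finite differences
#' is asserted in the test suite.
#'
#' @inheritParams combined_loss
#' @return Numeric vector, same length as `logits`.
#' @export
combined_loss_grad <- function(logits, y, sigma = 1, grid = support_grid(),
                               lambda = 1) {
  check_grid(grid)
  p <- softmax_probs(logits)
  t <- encode_label(y, sigma, grid)
  yhat <- sum(p * grid$values)
  (p - t) + lambda * sign(yhat - y) * p * (grid$values - yhat)
}

#' @export
print.hb_grid <- function(x, ...) {
  cat("Hemoglobin support grid: ", x$n_bins, " points on [",
      x$k_min, ", ", x$k_max, "], spacing ", format(x$spacing), "\n", sep = "")
  invisible(x)
}

#' @export
print.hb_loss <- function(x, ...) {
  cat(sprintf("composite loss: total = %.6g (KL %.6g, L1 %.6g)\n",
              x$total, x$kl, x$l1))
  invisible(x)
}
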