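#' Regression metrics for hemoglobin predictions
#'
#' Computes the three headline regression indices: the coefficient of
#' determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, the explained variance
#' score \eqn{EVS = 1 - Var(y - \hat y)/Var(y)} (equal to \eqn{R^2} when the
#' residuals have zero mean), and the mean absolute error. Variances use the
#' population (1/n) convention so EVS and R-squared agree exactly on
#' mean-zero residuals.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return A list of class `"hb_reg_metrics"` with `r2`, `evs`, `mae`, `n`.
#'   If `y_true` is constant, `r2` and `evs` are `NA` (with a warning);
#'   `mae` is always returned.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4)) # r2 = 0.5, mae = 1/3
#' @export
regression_metrics <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n == 0L || length(y_pred) != n)
    stop("`y_true` and `y_pred` must be equal-length, non-empty")
  mae <- mean(abs(y_true - y_pred))
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    warning("constant `y_true`: r2 and evs undefined")
    r2 <- NA_real_; evs <- NA_real_
  } else {
    r2 <- 1 - sum((y_true - y_pred)^2) / ss_tot
    res <- y_true - y_pred
    evs <- 1 - mean((res - mean(res))^2) / (ss_tot / n)
  }
  structure(list(r2 = r2, evs = evs, mae = mae, n = n),
            class = "hb_reg_metrics")
}

#' @export
print.hb_reg_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.3f   EVS = %.3f   MAE = %.3f   (n = %d)\n",
              x$r2, x$evs, x$mae, x$n))
  invisible(x)
}

#' Percentile-bootstrap confidence intervals for regression metrics
#'
#' Resamples (truth, prediction) pairs with replacement `n_boot` times and
#' reports percentile intervals for R-squared, EVS and MAE at level
#' `1 - alpha`.
#'
#' @param y_true,y_pred Paired vectors.
#' @param n_boot Number of bootstrap resamples (>= 100; default 2000).
#' @param alpha Two-sided miss probability (default 0.05 for 95% intervals).
#' @param seed Optional seed for reproducibility.
#' @return A list of class `"hb_reg_ci"`: for each metric, `point`, `lo`,
#'   `hi`.
#' @export
bootstrap_ci <- function(y_true, y_pred, n_boot = 2000L, alpha = 0.05,
                         seed = NULL) {
  if (n_boot < 100L) stop("`n_boot` must be >= 100")
  n <- length(y_true)
  if (n < 3L) stop("too few pairs to resample")
  if (!is.null(seed)) set.seed(seed)
  pt <- regression_metrics(y_true, y_pred)
  draws <- matrix(NA_real_, n_boot, 3L,
                  dimnames = list(NULL, c("r2", "evs", "mae")))
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    m <- suppressWarnings(regression_metrics(y_true[i], y_pred[i]))
    draws[b, ] <- c(m$r2, m$evs, m$mae)
  }
  q <- function(col) stats::quantile(draws[, col], c(alpha / 2, 1 - alpha / 2),
                                     na.rm = TRUE, names = FALSE)
  out <- list(
    r2 = list(point = pt$r2, lo = q("r2")[1], hi = q("r2")[2]),
    evs = list(point = pt$evs, lo = q("evs")[1], hi = q("evs")[2]),
    mae = list(point = pt$mae, lo = q("mae")[1], hi = q("mae")[2])
  )
  class(out) <- "hb_reg_ci"
  out
}

#' @export
print.hb_reg_ci <- function(x, ...) {
  for (nm in c("r2", "evs", "mae"))
    cat(sprintf("%-4s %.3f (%.3f, %.3f)\n", toupper(nm),
                x[[nm]]$point, x[[nm]]$lo, x[[nm]]$hi))
  invisible(x)
}

#' Serialize metric point estimates and intervals to JSON
#'
#' @param ci An `"hb_reg_ci"` object.
#' @param path Optional output path; otherwise the JSON string is returned.
#' @export
metrics_json <- function(ci, path = NULL) {
  obj <- lapply(unclass(ci), function(m) m)
  if (is.null(path)) jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Stratified k-fold cross-validated evaluation
#'
#' Splits a dataset into `k` folds stratified by hemoglobin bin (skewed
#' labels make unstratified folds unstable at small n), calls a
#' user-supplied training function on each training partition, predicts the
#' held-out fold, and reports per-fold metrics plus pooled metrics computed
#' on the concatenated out-of-fold predictions.
#'
#' @param x Sample container indexable by `subset_fn` (default treats `x`
#'   as an `n x ...` array and subsets its first margin).
#' @param y Numeric label vector.
#' @param k Number of folds (default 10; `k <= length(y)`).
#' @param train_fn `function(x_train, y_train)` returning any object `pred_fn`
#'   can use.
#' @param pred_fn `function(fit, x_test)` returning numeric predictions.
#' @param bin_width Stratification bin width (default 1).
#' @param seed Seed for the fold assignment.
#' @param subset_fn Optional `function(x, idx)`; defaults to first-margin
#'   array subsetting.
#' @return A list of class `"hb_cv"`: `folds` (per-fold index vectors),
#'   `per_fold` (list of `"hb_reg_metrics"`), `pooled` metrics, `oof`
#'   (data.frame of out-of-fold truth/prediction).
#' @export
kfold_evaluate <- function(x, y, k = 10L, train_fn, pred_fn,
                           bin_width = 1, seed = 1L, subset_fn = NULL) {
  n <- length(y)
  if (k < 2L) stop("`k` must be >= 2")
  if (k > n) stop("`k` must not exceed the number of samples")
  if (is.null(subset_fn)) {
    subset_fn <- function(x, idx) {
      d <- length(dim(x))
      if (d == 4L) x[idx, , , , drop = FALSE]
      else if (d == 3L) x[idx, , , drop = FALSE]
      else if (d == 2L) x[idx, , drop = FALSE]
      else x[idx]
    }
  }
  set.seed(seed)
  bins <- bin_labels(y, bin_width)$assignment
  # deal folds cyclically through the bin-sorted (randomly tie-broken)
  # sample order: stratified within bins, fold sizes balanced to within 1
  ord <- order(bins, stats::runif(n))
  fold <- integer(n)
  fold[ord] <- rep_len(sample.int(k), n)
  per_fold <- vector("list", k)
  oof <- data.frame(idx = integer(0), y = numeric(0), pred = numeric(0))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    if (length(test_idx) == 0L) next
    train_idx <- which(fold != f)
    fit <- train_fn(subset_fn(x, train_idx), y[train_idx])
    pred <- pred_fn(fit, subset_fn(x, test_idx))
    per_fold[[f]] <- suppressWarnings(regression_metrics(y[test_idx], pred))
    oof <- rbind(oof, data.frame(idx = test_idx, y = y[test_idx],
                                 pred = pred))
  }
  structure(list(folds = split(seq_len(n), fold), per_fold = per_fold,
                 pooled = regression_metrics(oof$y, oof$pred), oof = oof),
            class = "hb_cv")
}

#' @export
print.hb_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, pooled out-of-fold metrics:\n",
              length(x$folds)))
  print(x$pooled)
  invisible(x)
}
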