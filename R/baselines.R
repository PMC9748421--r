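#' Extract color features from an eye image
#'
#' The feature-engineering arm: per-region means and standard deviations of
#' the R, G, B channels, the ratios R/G and R/B of the channel means, and
#' the erythema index \eqn{EI = \log_{10}(\bar R / \bar G)} — the classical
#' redness summary used for conjunctival pallor. When a mask is supplied the
#' statistics are computed over mask pixels only (the conjunctiva); otherwise
#' over the whole image. Ratio denominators are floored at 1e-6.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param mask Optional binary mask; must be non-empty if given.
#' @return Named numeric vector with elements `mean_r`, `mean_g`, `mean_b`,
#'   `sd_r`, `sd_g`, `sd_b`, `ratio_rg`, `ratio_rb`, `ei`.
#' @export
extract_color_features <- function(image, mask = NULL) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("`image` must be H x W x 3")
  if (!is.null(mask)) {
    mask <- normalize_mask(mask)
    if (sum(mask) == 0L) stop("empty mask: no pixels to summarize")
    sel <- mask == 1L
  } else {
    sel <- matrix(TRUE, d[1], d[2])
  }
  ch <- lapply(1:3, function(k) image[, , k][sel])
  mu <- vapply(ch, mean, numeric(1))
  sdv <- vapply(ch, stats::sd, numeric(1))
  sdv[is.na(sdv)] <- 0 # single-pixel region
  eps <- 1e-6
  c(mean_r = mu[1], mean_g = mu[2], mean_b = mu[3],
    sd_r = sdv[1], sd_g = sdv[2], sd_b = sdv[3],
    ratio_rg = mu[1] / max(mu[2], eps),
    ratio_rb = mu[1] / max(mu[3], eps),
    ei = log10(max(mu[1], eps) / max(mu[2], eps)))
}

#' Color-feature matrix for a dataset
#'
#' @param dataset An `"hb_sim_dataset"` (or list of samples).
#' @param use_mask Compute features over the ground-truth mask (`TRUE`) or
#'   the whole image (`FALSE`).
#' @return Numeric matrix, one named-column row per image.
#' @export
dataset_features <- function(dataset, use_mask = TRUE) {
  samples <- if (inherits(dataset, "hb_sim_dataset")) dataset$samples else dataset
  t(vapply(samples, function(s)
    extract_color_features(s$image, if (use_mask) s$mask else NULL),
    numeric(9L)))
}

#' Fit a feature-engineering baseline regressor
#'
#' Off-the-shelf regressors on extracted color features, mirroring the
#' classical comparison arm: decision tree (rpart), linear model (lm),
#' support-vector regression (e1071), k-nearest-neighbor regression (caret),
#' random forest (randomForest), and gradient-boosted trees (xgboost). Only
#' feature extraction is bespoke in this package; the regressors are called
#' through their standard interfaces.
#'
#' @param features Numeric matrix with named columns (>= 10 rows).
#' @param hb Numeric label vector.
#' @param kind One of `"decision-tree"`, `"linear"`, `"svm"`, `"knn"`,
#'   `"random-forest"`, `"boosting"`.
#' @param seed Seed fixed before fitting (some learners are stochastic).
#' @return An object of class `"hb_baseline"` with a `predict` method taking
#'   a feature matrix.
#' @export
fit_baseline <- function(features, hb,
                         kind = c("decision-tree", "linear", "svm", "knn",
                                  "random-forest", "boosting"),
                         seed = 1L) {
  kind <- match.arg(kind)
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 10L) stop("need at least 10 rows to fit a baseline")
  if (nrow(features) != length(hb)) stop("feature rows and labels must match")
  set.seed(seed)
  df <- as.data.frame(features)
  df$.hb <- hb
  fit <- switch(
    kind,
    "decision-tree" = rpart::rpart(.hb ~ ., data = df),
    "linear" = stats::lm(.hb ~ ., data = df),
    "svm" = e1071::svm(.hb ~ ., data = df),
    "knn" = caret::knnreg(features, hb),
    "random-forest" = randomForest::randomForest(features, hb),
    "boosting" = xgboost::xgboost(features, hb, nrounds = 100L,
                                  max_depth = 3, learning_rate = 0.1,
                                  verbosity = 0)
  )
  structure(list(kind = kind, fit = fit,
                 feature_names = colnames(features)),
            class = "hb_baseline")
}

#' @export
predict.hb_baseline <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  colnames(newdata) <- object$feature_names
  switch(
    object$kind,
    "decision-tree" = ,
    "linear" = ,
    "svm" = unname(stats::predict(object$fit,
                                  newdata = as.data.frame(newdata))),
    "knn" = ,
    "random-forest" = unname(stats::predict(object$fit, newdata)),
    "boosting" = unname(stats::predict(object$fit, newdata))
  )
}

#' @export
print.hb_baseline <- function(x, ...) {
  cat("Baseline hemoglobin regressor:", x$kind, "on",
      length(x$feature_names), "color features\n")
  invisible(x)
}
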