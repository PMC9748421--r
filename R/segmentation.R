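#' Restrict an eye image to its (causal) eyelid region
#'
#' Applies a binary eyelid mask to an image, implementing the causal-region
#' extraction step: only conjunctival pixels carry a causal relation to
#' hemoglobin, so the regressor is fed the masked region. Masks may come from
#' the simulator's oracle, from PNG files, or from any external segmenter —
#' the package deliberately consumes masks rather than re-implementing an
#' instance-segmentation network.
#'
#' @param image `H x W x 3` numeric array.
#' @param mask `H x W` 0/1 matrix (or 0/255 as read from PNG).
#' @param mode One of `"zero-background"` (keep size, zero non-mask pixels),
#'   `"bbox-crop"` (tight bounding box of the mask, optionally padded), or
#'   `"masked-crop"` (bounding-box crop of the zero-background image).
#' @param pad Padding in pixels around the bounding box for crop modes.
#' @return The masked / cropped image array.
#' @export
apply_mask <- function(image, mask,
                       mode = c("zero-background", "bbox-crop", "masked-crop"),
                       pad = 0L) {
  mode <- match.arg(mode)
  mask <- normalize_mask(mask)
  d <- dim(image)
  if (length(d) != 3L || any(d[1:2] != dim(mask)))
    stop("`image` must be H x W x 3 with the same H, W as `mask`")
  if (mode == "zero-background") {
    out <- image * array(rep(mask, 3L), dim = d)
    return(out)
  }
  if (sum(mask) == 0L)
    stop("empty mask: bounding-box crop is undefined")
  idx <- which(mask == 1L, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(d[1], max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(d[2], max(idx[, 2]) + pad)
  src <- if (mode == "masked-crop")
    image * array(rep(mask, 3L), dim = d) else image
  src[r0:r1, c0:c1, , drop = FALSE]
}

normalize_mask <- function(mask) {
  if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  matrix(as.integer(mask > 0.5 * max(1, max(mask))), nrow(mask), ncol(mask))
}

#' Intersection over union of two binary masks
#'
#' \eqn{|a \cap b| / |a \cup b|}. By convention two empty masks have IoU 1
#' (a warning is emitted); exactly one empty mask gives 0.
#'
#' @param a,b Binary masks of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  a <- normalize_mask(a); b <- normalize_mask(b)
  if (!all(dim(a) == dim(b))) stop("masks must have identical shapes")
  inter <- sum(a & b); uni <- sum(a | b)
  if (uni == 0L) {
    warning("both masks empty; IoU defined as 1 by convention")
    return(1)
  }
  inter / uni
}

#' Evaluate predicted eyelid masks against ground truth
#'
#' Single-class, one-instance-per-image matching: a predicted mask is a true
#' positive at IoU threshold t iff its IoU with the truth is at least t; an
#' image with a non-empty prediction that misses is a false positive, a
#' non-empty truth without a matching prediction a false negative. At each
#' threshold `AP = TP / (TP + FP)` and `AR = TP / (TP + FN)` (0 when the
#' denominator is 0); `ap_50_95` / `ar_50_95` average the ten standard
#' thresholds 0.50, 0.55, ..., 0.95, and `miou` is the mean per-image IoU.
#' There is no confidence-ranked precision-recall integral because the task
#' has one unscored instance per image.
#'
#' @param predicted,truth Lists of binary masks (or `n x H x W` arrays),
#'   aligned by index.
#' @param thresholds IoU thresholds in (0, 1); default `seq(0.5, 0.95, 0.05)`.
#' @return A list of class `"hb_seg_metrics"`: `ap`, `ar` (named by
#'   threshold), `ap_50_95`, `ar_50_95`, `miou`, `iou` (per image).
#' @export
evaluate_segmentation <- function(predicted, truth,
                                  thresholds = seq(0.5, 0.95, by = 0.05)) {
  predicted <- mask_list(predicted); truth <- mask_list(truth)
  if (length(predicted) == 0L) stop("empty mask list")
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have the same length")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("`thresholds` must lie in (0, 1)")
  ious <- mapply(function(p, t) {
    if (sum(p) == 0L && sum(t) == 0L) 1 else suppressWarnings(mask_iou(p, t))
  }, predicted, truth)
  has_pred <- vapply(predicted, function(m) sum(m) > 0L, logical(1))
  has_truth <- vapply(truth, function(m) sum(m) > 0L, logical(1))
  ap <- ar <- stats::setNames(numeric(length(thresholds)),
                              format(thresholds, nsmall = 2))
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    tp <- sum(has_pred & has_truth & ious >= t)
    fp <- sum(has_pred & !(has_truth & ious >= t))
    fn <- sum(has_truth & !(has_pred & ious >= t))
    ap[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    ar[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  std <- seq(0.5, 0.95, by = 0.05)
  std_ap <- vapply(std, function(t) {
    tp <- sum(has_pred & has_truth & ious >= t)
    fp <- sum(has_pred & !(has_truth & ious >= t))
    if (tp + fp > 0) tp / (tp + fp) else 0
  }, numeric(1))
  std_ar <- vapply(std, function(t) {
    tp <- sum(has_pred & has_truth & ious >= t)
    fn <- sum(has_truth & !(has_pred & ious >= t))
    if (tp + fn > 0) tp / (tp + fn) else 0
  }, numeric(1))
  structure(list(ap = ap, ar = ar,
                 ap_50_95 = mean(std_ap), ar_50_95 = mean(std_ar),
                 miou = mean(ious), iou = ious),
            class = "hb_seg_metrics")
}

mask_list <- function(x) {
  if (is.list(x)) return(lapply(x, normalize_mask))
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[1]), function(i) normalize_mask(x[i, , ])))
  stop("masks must be a list of matrices or an n x H x W array")
}

#' @export
print.hb_seg_metrics <- function(x, ...) {
  cat(sprintf("Segmentation metrics over %d images\n", length(x$iou)))
  cat(sprintf("  mIoU       %.3f\n", x$miou))
  cat(sprintf("  AP@0.50    %.3f   AR@0.50    %.3f\n",
              x$ap[["0.50"]], x$ar[["0.50"]]))
  cat(sprintf("  AP@.5:.95  %.3f   AR@.5:.95  %.3f\n",
              x$ap_50_95, x$ar_50_95))
  invisible(x)
}

#' Serialize segmentation metrics to JSON
#'
#' @param x An `"hb_seg_metrics"` object.
#' @param path Optional file path; if omitted the JSON string is returned.
#' @export
seg_metrics_json <- function(x, path = NULL) {
  obj <- list(ap = as.list(x$ap), ar = as.list(x$ar),
              ap_50_95 = x$ap_50_95, miou = x$miou)
  if (is.null(path)) jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}
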