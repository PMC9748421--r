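#' Bin continuous hemoglobin labels into equal-width classes
#'
#' SMOTE is defined for classes, so the continuous label is discretized into
#' uniform bins covering the label range (default `[6, 18]`). Values equal to
#' the upper range limit fall in the last bin.
#'
#' @param hb Numeric vector of labels.
#' @param bin_width Positive bin width in label units (default 1 g/dL).
#' @param range Label range covered by the bins.
#' @return A list of class `"hb_bins"`: `edges`, `assignment` (1-based bin
#'   index per label), `counts` (named per-bin counts, non-empty bins only).
#' @export
bin_labels <- function(hb, bin_width = 1, range = c(6, 18)) {
  if (length(hb) == 0L) stop("`hb` must be non-empty")
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  assignment <- findInterval(hb, edges, rightmost.closed = TRUE,
                             all.inside = TRUE)
  counts <- table(factor(assignment, levels = seq_len(length(edges) - 1L)))
  structure(list(edges = edges, assignment = assignment,
                 counts = counts[counts > 0]),
            class = "hb_bins")
}

#' Balance a skewed continuous-label dataset by per-bin SMOTE up-sampling
#'
#' Brings every non-empty label bin up to the size of the largest bin by
#' synthetic-minority oversampling: a synthetic sample is
#' \eqn{x_i + u (x_j - x_i)} with \eqn{u \sim U(0,1)} and \eqn{x_j} one of the
#' `k_neighbors` nearest same-bin neighbors of a randomly chosen seed
#' \eqn{x_i}; its label is interpolated with the same `u`. Bins with a single
#' member fall back to duplication with small Gaussian jitter (sd = 1% of the
#' feature dynamic range), since nearest-neighbor interpolation is undefined
#' there. Already-balanced data are returned unchanged.
#'
#' For images, interpolate in flattened low-resolution pixel space (see
#' [flatten_images()]); clinically one would balance the training partition
#' only — up-sampling the test partition as well is supported by simply
#' calling this on both partitions, mirroring protocols that balance each
#' split separately.
#'
#' @param x Numeric matrix, one row per sample (features or flattened
#'   pixels).
#' @param hb Numeric label vector, `length(hb) == nrow(x)`.
#' @param bin_width Bin width passed to [bin_labels()].
#' @param k_neighbors Number of nearest same-bin neighbors considered
#'   (>= 1); capped at bin size - 1.
#' @return A list of class `"hb_balanced"`: `x` (original rows first, then
#'   synthetic), `hb`, `synthetic` (logical), `bins` (post-balance
#'   [bin_labels()] of the returned labels).
#' @export
smote_balance <- function(x, hb, bin_width = 1, k_neighbors = 5L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(hb)) stop("`x` rows and `hb` length must match")
  if (k_neighbors < 1L) stop("`k_neighbors` must be >= 1")
  bins <- bin_labels(hb, bin_width)
  counts <- table(bins$assignment)
  target <- max(counts)
  new_x <- list(); new_hb <- numeric(0)
  rng_range <- diff(range(x))
  for (b in as.integer(names(counts))) {
    need <- target - counts[[as.character(b)]]
    if (need == 0L) next
    members <- which(bins$assignment == b)
    xb <- x[members, , drop = FALSE]
    if (length(members) == 1L) {
      jit_sd <- 0.01 * max(rng_range, .Machine$double.eps)
      syn <- matrix(rep(xb[1, ], need), nrow = need, byrow = TRUE) +
        matrix(stats::rnorm(need * ncol(x), 0, jit_sd), nrow = need)
      new_x[[length(new_x) + 1L]] <- syn
      new_hb <- c(new_hb, rep(hb[members], need))
      next
    }
    d <- as.matrix(stats::dist(xb))
    diag(d) <- Inf
    k_eff <- min(k_neighbors, length(members) - 1L)
    nn <- apply(d, 1L, function(row) order(row)[seq_len(k_eff)],
                simplify = FALSE)
    if (is.matrix(nn)) nn <- asplit(nn, 2L) # k_eff == 1 edge shape
    i_seed <- sample(length(members), need, replace = TRUE)
    j_pick <- vapply(i_seed, function(i) nn[[i]][sample.int(k_eff, 1L)],
                     numeric(1))
    u <- stats::runif(need)
    syn <- xb[i_seed, , drop = FALSE] +
      u * (xb[j_pick, , drop = FALSE] - xb[i_seed, , drop = FALSE])
    new_x[[length(new_x) + 1L]] <- syn
    new_hb <- c(new_hb,
                hb[members][i_seed] + u * (hb[members][j_pick] -
                                             hb[members][i_seed]))
  }
  if (length(new_x) > 0L) {
    x_out <- rbind(x, do.call(rbind, new_x))
    hb_out <- c(hb, new_hb)
  } else {
    x_out <- x; hb_out <- hb
  }
  structure(list(x = x_out, hb = hb_out,
                 synthetic = c(rep(FALSE, length(hb)),
                               rep(TRUE, length(hb_out) - length(hb))),
                 bins = bin_labels(hb_out, bin_width)),
            class = "hb_balanced")
}

#' Flatten images to low-resolution pixel vectors
#'
#' Down-scales each image to `size x size` (bilinear, via EBImage) and
#' flattens it to one row, the feature space in which [smote_balance()]
#' interpolates images.
#'
#' @param images `n x H x W x 3` array or an `"hb_sim_dataset"`.
#' @param size Target side length (default 32).
#' @return Numeric matrix `n x (size*size*3)`.
#' @export
flatten_images <- function(images, size = 32L) {
  if (inherits(images, "hb_sim_dataset")) images <- as_image_array(images)
  n <- dim(images)[1]
  out <- matrix(0, n, size * size * 3L)
  for (i in seq_len(n)) {
    im <- EBImage::resize(EBImage::Image(images[i, , , ] / 255,
                                         colormode = "Color"),
                          w = size, h = size)
    out[i, ] <- as.numeric(EBImage::imageData(im)) * 255
  }
  out
}
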