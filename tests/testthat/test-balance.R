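test_that("label binning covers the range and counts correctly", {
  b <- bin_labels(c(6.1, 6.4, 17.9), bin_width = 1)
  expect_equal(unname(b$counts[["1"]]), 2)   # bin [6,7)
  expect_equal(unname(b$counts[["12"]]), 1)  # bin [17,18]
  expect_equal(length(b$counts), 2)

  b2 <- bin_labels(rep(9.5, 5), bin_width = 1)
  expect_equal(length(b2$counts), 1)

  set.seed(1)
  hb <- sample_hb(1000, simulator_config())
  b3 <- bin_labels(hb, bin_width = 1)
  expect_equal(sum(b3$counts), 1000)
  expect_equal(length(b3$assignment), 1000)

  # the upper boundary falls into the last bin, not past it
  b4 <- bin_labels(c(6, 18), bin_width = 1)
  expect_equal(sort(as.integer(names(b4$counts))), c(1L, 12L))

  expect_error(bin_labels(numeric(0)), "non-empty")
  expect_error(bin_labels(c(7, 8), bin_width = 0), "bin_width")
})

test_that("balanced data pass through SMOTE unchanged", {
  set.seed(2)
  x <- matrix(rnorm(40), 20, 2)
  hb <- rep(c(7.5, 10.5), each = 10) # two bins, both size 10
  out <- smote_balance(x, hb)
  expect_identical(out$x, x)
  expect_identical(out$hb, hb)
  expect_false(any(out$synthetic))
})

test_that("synthetic samples are convex combinations of same-bin parents", {
  set.seed(3)
  # one bin with 2 members, one with 4: the small bin needs 2 synthetics
  x <- rbind(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE),
             matrix(rnorm(8, 10), 4, 2))
  hb <- c(7.2, 7.8, 10.1, 10.4, 10.6, 10.9)
  out <- smote_balance(x, hb, k_neighbors = 5)
  counts <- table(bin_labels(out$hb)$assignment)
  expect_true(all(counts == max(counts)))
  syn <- out$x[out$synthetic & out$hb < 9, , drop = FALSE]
  expect_equal(nrow(syn), 2)
  # componentwise inside the hull of the two low-bin parents
  expect_true(all(syn[, 1] >= 0 & syn[, 1] <= 1))
  expect_true(all(syn[, 2] >= 0 & syn[, 2] <= 1))
  # interpolated labels stay inside the parents' label interval
  expect_true(all(out$hb[out$synthetic & out$hb < 9] >= 7.2 &
                    out$hb[out$synthetic & out$hb < 9] <= 7.8))
})

test_that("post-balance counts all equal the pre-balance maximum", {
  set.seed(4)
  cfg <- simulator_config()
  hb <- sample_hb(300, cfg)
  x <- matrix(rnorm(300 * 6), 300, 6)
  pre <- table(bin_labels(hb)$assignment)
  out <- smote_balance(x, hb)
  post <- table(bin_labels(out$hb)$assignment)
  expect_true(all(post == max(pre)))
  expect_equal(nrow(out$x), length(pre) * max(pre))
  expect_equal(nrow(out$x), length(out$hb))
  # original samples are preserved verbatim at the head
  expect_identical(out$x[1:300, ], x)
})

test_that("convexity and label consistency hold across random datasets", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60
    hb <- sample_hb(n, simulator_config())
    x <- matrix(runif(n * 3), n, 3)
    out <- smote_balance(x, hb, k_neighbors = 3)
    bins <- bin_labels(out$hb)
    pre_bins <- bin_labels(hb)
    for (i in which(out$synthetic)) {
      b <- bins$assignment[i]
      parents <- which(pre_bins$assignment == b)
      if (length(parents) < 2) next # jitter fallback, tested separately
      lo <- apply(x[parents, , drop = FALSE], 2, min)
      hi <- apply(x[parents, , drop = FALSE], 2, max)
      expect_true(all(out$x[i, ] >= lo - 1e-12 & out$x[i, ] <= hi + 1e-12))
      expect_true(out$hb[i] >= min(hb[parents]) - 1e-12 &&
                    out$hb[i] <= max(hb[parents]) + 1e-12)
    }
  }
})

test_that("singleton bins fall back to jittered duplication", {
  set.seed(6)
  x <- rbind(c(5, 5), matrix(rnorm(6, 0), 3, 2))
  hb <- c(17.5, 8.1, 8.5, 8.9)
  out <- smote_balance(x, hb)
  syn <- out$x[out$synthetic & out$hb > 16, , drop = FALSE]
  expect_equal(nrow(syn), 2)
  # near-copies of the lone parent (1% of dynamic range jitter)
  expect_true(all(abs(syn - rep(c(5, 5), each = 2)) < 1))
  expect_true(all(out$hb[out$synthetic & out$hb > 16] == 17.5))
})

test_that("smote rejects invalid neighborhood sizes and mismatched input", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(smote_balance(x, rnorm(10, 10), k_neighbors = 0), "k_neighbors")
  expect_error(smote_balance(x, rnorm(5, 10)), "match")
})

test_that("image flattening produces one low-resolution row per image", {
  ds <- cached_dataset("tiny", 4, simulator_config(seed = 31))
  flat <- flatten_images(as_image_array(ds), size = 16)
  expect_equal(dim(flat), c(4, 16 * 16 * 3))
  expect_true(all(is.finite(flat)))
  expect_true(all(flat >= 0 & flat <= 255))
})
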