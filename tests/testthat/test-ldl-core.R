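test_that("support grid gives uniform bin centers and rejects degenerate input", {
  g <- support_grid(5, 20, 15)
  expect_equal(g$spacing, 1)
  expect_equal(g$values[1], 5.5)
  expect_equal(g$values[15], 19.5)
  expect_equal(diff(g$values), rep(1, 14))

  g2 <- support_grid(0, 1, 2)
  expect_equal(g2$values, c(0.25, 0.75))

  expect_error(support_grid(5, 20, 1), "n_bins")
  expect_error(support_grid(20, 5, 15), "k_min")
})

test_that("Gaussian label encoding is a normalized, symmetric distribution", {
  g <- support_grid()
  p <- encode_label(12.5, 1, g)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(which.max(p), which(g$values == 12.5))
  # symmetric about 12.5: bins at equal distance carry equal mass
  expect_equal(p[7], p[9], tolerance = 1e-12)
  expect_equal(p[5], p[11], tolerance = 1e-12)

  # vanishing-sigma limit approaches one-hot
  p0 <- encode_label(12.5, 0.01, g)
  expect_gt(max(p0), 0.999)
  expect_equal(which.max(p0), 8L)

  # direct independent evaluation at sigma = 2
  expected <- exp(-(g$values - 12.5)^2 / 8)
  expected <- expected / sum(expected)
  expect_equal(encode_label(12.5, 2, g), expected, tolerance = 1e-12)

  expect_error(encode_label(12.5, 0, g), "sigma")
  expect_error(encode_label(12.5, -1, g), "sigma")
})

test_that("encoding normalizes for random labels and widths", {
  set.seed(42)
  g <- support_grid()
  for (i in 1:200) {
    p <- encode_label(runif(1, 6, 18), runif(1, 0.05, 4), g)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-9)
  }
})

test_that("softmax is normalized, shift-invariant, and rejects non-finite input", {
  expect_equal(softmax_probs(rep(0, 15)), rep(1 / 15, 15))
  expect_equal(softmax_probs(c(1, 0)),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  set.seed(1)
  z <- rnorm(15)
  expect_equal(softmax_probs(z), softmax_probs(z + 17.3), tolerance = 1e-12)
  expect_equal(sum(softmax_probs(z * 50)), 1, tolerance = 1e-9)
  expect_error(softmax_probs(c(1, NaN)), "finite")
  expect_error(softmax_probs(c(1, Inf)), "finite")
})

test_that("KL divergence matches hand computation and is asymmetric", {
  expect_equal(kl_divergence(c(.5, .5), c(.25, .75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(kl_divergence(c(.25, .75), c(.5, .5)),
               0.25 * log(.5) + 0.75 * log(1.5), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(kl_divergence(c(.5, .5), c(.25, .75)),
                                kl_divergence(c(.25, .75), c(.5, .5)))))
  expect_error(kl_divergence(c(.5, .5), c(.2, .3, .5)), "length")
  expect_error(kl_divergence(c(1, 0), c(0, 1)), "zero mass")
})

test_that("KL is nonnegative and zero iff the distributions agree", {
  set.seed(7)
  for (i in 1:1000) {
    k <- sample(2:15, 1)
    p <- softmax_probs(rnorm(k))
    q <- softmax_probs(rnorm(k))
    kl <- kl_divergence(p, q)
    expect_gte(kl, 0)
    expect_equal(kl_divergence(p, p), 0, tolerance = 1e-12)
    if (max(abs(p - q)) > 1e-4) expect_gt(kl, 0)
  }
})

test_that("expectation decoding handles degenerate and composite cases", {
  g <- support_grid()
  onehot <- rep(0, 15); onehot[which(g$values == 9.5)] <- 1
  expect_equal(decode_prediction(onehot, g), 9.5)
  expect_equal(decode_prediction(rep(1 / 15, 15), g), 12.5)
  two <- rep(0, 15)
  two[which(g$values == 8.5)] <- 0.5
  two[which(g$values == 10.5)] <- 0.5
  expect_equal(decode_prediction(two, g), 9.5)
})

test_that("encode/decode round trip stays within half a grid spacing", {
  g <- support_grid()
  for (y in seq(8, 17, by = 0.1))
    expect_lte(abs(decode_prediction(encode_label(y, 1, g), g) - y), 0.5)
})

test_that("composite loss composes KL and L1 terms", {
  g <- support_grid()
  y <- 12.5
  target <- encode_label(y, 1, g)
  # logits realizing the target exactly: kl vanishes, l1 is only truncation
  l <- combined_loss(log(target), y, sigma = 1, grid = g)
  expect_lt(l$kl, 1e-12)
  expect_lt(l$l1, 1e-6)

  set.seed(3)
  for (i in 1:20) {
    z <- rnorm(15)
    yy <- runif(1, 6, 18)
    lam <- runif(1, 0, 2)
    l <- combined_loss(z, yy, sigma = 1, grid = g, lambda = lam)
    expect_gte(l$total, l$kl)
    expect_gte(l$total, lam * l$l1)
    expect_equal(l$total, l$kl + lam * l$l1, tolerance = 1e-12)
  }

  # two-point grid: total equals hand-assembled components
  g2 <- support_grid(7.5, 11.5, 2) # support values 8.5, 10.5
  expect_equal(g2$values, c(8.5, 10.5))
  z <- c(1, 0)
  y2 <- 8.5
  p <- c(exp(1), 1) / (exp(1) + 1)
  t2 <- encode_label(y2, 1, g2)
  kl_hand <- sum(t2 * log(t2 / p))
  l1_hand <- abs(sum(p * g2$values) - y2)
  l2 <- combined_loss(z, y2, sigma = 1, grid = g2, lambda = 1)
  expect_equal(l2$total, kl_hand + l1_hand, tolerance = 1e-12)
})

test_that("analytic loss gradient matches finite differences", {
  g <- support_grid()
  set.seed(11)
  for (i in 1:20) {
    z <- rnorm(15)
    y <- runif(1, 6.5, 17.5)
    lam <- sample(c(0, 0.5, 1, 2), 1)
    gr <- combined_loss_grad(z, y, sigma = 1, grid = g, lambda = lam)
    fd <- vapply(seq_along(z), function(j) {
      e <- 1e-6
      zp <- z; zp[j] <- zp[j] + e
      zm <- z; zm[j] <- zm[j] - e
      (combined_loss(zp, y, 1, g, lam)$total -
         combined_loss(zm, y, 1, g, lam)$total) / (2 * e)
    }, numeric(1))
    rel <- max(abs(gr - fd)) / max(max(abs(fd)), 1e-8)
    expect_lt(rel, 1e-4)
  }
})

test_that("KL to the target decreases along the line toward the target logits", {
  g <- support_grid()
  set.seed(5)
  y <- 11.2
  target <- encode_label(y, 1, g)
  z0 <- rnorm(15)
  zt <- log(target)
  kls <- vapply(seq(0, 1, by = 0.25), function(a) {
    kl_divergence(target, softmax_probs((1 - a) * z0 + a * zt))
  }, numeric(1))
  expect_true(all(diff(kls) <= 1e-12))
})
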