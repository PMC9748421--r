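test_that("forward pass honors the shape contract and is finite", {
  net <- cnn_init(net_config(input_size = 64, depth = 4), seed = 1)
  set.seed(1)
  imgs <- array(runif(4 * 64 * 64 * 3, 0, 255), c(4, 64, 64, 3))
  logits <- cnn_forward(net, imgs)$logits
  expect_equal(dim(logits), c(4L, 15L))
  expect_true(all(is.finite(logits)))
})

test_that("initialization and forward are deterministic under a seed", {
  set.seed(42)
  imgs <- array(runif(2 * 64 * 64 * 3, 0, 255), c(2, 64, 64, 3))
  n1 <- cnn_init(net_config(), seed = 7)
  n2 <- cnn_init(net_config(), seed = 7)
  expect_identical(cnn_forward(n1, imgs)$logits, cnn_forward(n2, imgs)$logits)
  n3 <- cnn_init(net_config(), seed = 8)
  expect_false(identical(cnn_forward(n1, imgs)$logits,
                         cnn_forward(n3, imgs)$logits))
})

test_that("network config validates its invariants", {
  expect_error(net_config(input_size = 63), "divisible")
  expect_error(net_config(n_output = 1), "n_output")
  expect_error(net_config(depth = 0), "depth")
  cfg <- net_config(width_multiplier = 0.75)
  expect_equal(cfg$channels, c(6L, 12L, 24L, 48L))
})

test_that("backpropagated gradients match finite differences", {
  # small net keeps the finite-difference sweep cheap
  pk <- asNamespace("palpebral")
  cfg <- net_config(input_size = 16, depth = 2, width_multiplier = 0.5,
                    n_output = 15)
  for (trial in 1:3) {
    net <- cnn_init(cfg, seed = trial)
    set.seed(trial)
    imgs <- array(runif(2 * 16 * 16 * 3, 0, 255), c(2, 16, 16, 3))
    y <- runif(2, 7, 17)
    out <- pk$cnn_loss_and_grad(net, imgs, y)
    expect_true(all(is.finite(unlist(out$grads))))
    pv <- pk$flatten_params(net$params)
    gv <- pk$flatten_params(out$grads)
    idx <- sample(length(pv), 30)
    fd <- vapply(idx, function(i) {
      e <- 1e-5
      up <- pv; up[i] <- up[i] + e
      dn <- pv; dn[i] <- dn[i] - e
      nu <- net; nu$params <- pk$relist_params(up, net$params)
      nd <- net; nd$params <- pk$relist_params(dn, net$params)
      (pk$cnn_loss_and_grad(nu, imgs, y, with_grads = FALSE)$loss -
         pk$cnn_loss_and_grad(nd, imgs, y, with_grads = FALSE)$loss) / (2 * e)
    }, numeric(1))
    rel <- abs(fd - gv[idx]) / pmax(abs(fd), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("predictions are bounded by the support interval", {
  net <- cnn_init(net_config(), seed = 3)
  set.seed(3)
  imgs <- array(runif(6 * 64 * 64 * 3, 0, 255), c(6, 64, 64, 3))
  pred <- cnn_predict(net, imgs)
  expect_true(all(pred >= 5.5 & pred <= 19.5))

  # batching invariance: per-image calls equal the batch call
  singles <- vapply(1:6, function(i) cnn_predict(net, imgs[i, , , ]),
                    numeric(1))
  expect_equal(pred, singles, tolerance = 1e-12)
})

test_that("a flat-output head decodes to the support midpoint", {
  net <- cnn_init(net_config(), seed = 4)
  net$params$out$W[] <- 0
  net$params$out$b[] <- 0
  set.seed(4)
  imgs <- array(runif(3 * 64 * 64 * 3, 0, 255), c(3, 64, 64, 3))
  expect_equal(cnn_predict(net, imgs), rep(12.5, 3), tolerance = 1e-12)
})

test_that("zero-epoch fits return untrained parameters and empty history", {
  ds <- cached_dataset("net20", 20, simulator_config(seed = 41))
  x <- as_image_array(ds)
  fit <- hb_ldl(x, ds$hb, epochs = 0, seed = 5)
  ref <- cnn_init(net_config(), seed = 5)
  expect_identical(fit$net$params, ref$params)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training is bitwise reproducible under a fixed seed", {
  ds <- cached_dataset("net20", 20, simulator_config(seed = 41))
  x <- as_image_array(ds)
  f1 <- hb_ldl(x, ds$hb, epochs = 3, batch_size = 8, patience = 3, seed = 9)
  f2 <- hb_ldl(x, ds$hb, epochs = 3, batch_size = 8, patience = 3, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)
})

test_that("training loss decreases over the first epochs on clean data", {
  cfg <- simulator_config(noise_sd = 0, lighting_jitter_sd = 0, seed = 43)
  ds <- generate_dataset(48, cfg)
  x <- masked_array(ds)
  drops <- vapply(1:3, function(s) {
    fit <- hb_ldl(x, ds$hb, epochs = 5, batch_size = 16, patience = 5,
                  seed = s)
    fit$history$train_loss[5] < fit$history$train_loss[1]
  }, logical(1))
  expect_gte(sum(drops), 2) # median over 3 seeds
})

test_that("degenerate training inputs are rejected", {
  ds <- cached_dataset("net20", 20, simulator_config(seed = 41))
  x <- as_image_array(ds)
  expect_error(hb_ldl(x, ds$hb[1:5]), "match")
  expect_error(hb_ldl(x, rep(25, 20)), "support grid")
  expect_error(hb_ldl(x, ds$hb, net = net_config(n_output = 10)), "n_bins")
})

test_that("model methods expose fit, residuals, uncertainty, and history", {
  ds <- cached_dataset("net20", 20, simulator_config(seed = 41))
  x <- as_image_array(ds)
  fit <- hb_ldl(x, ds$hb, epochs = 2, batch_size = 8, patience = 2, seed = 2)
  expect_s3_class(fit, "hb_ldl")
  expect_equal(residuals(fit), ds$hb - fitted(fit))
  expect_length(predict(fit, x[1:3, , , , drop = FALSE]), 3)
  probs <- predict(fit, x[1:3, , , , drop = FALSE], type = "distribution")
  expect_equal(dim(probs), c(3L, 15L))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 50, seed = 1, newdata = x[1:2, , , , drop = FALSE])
  expect_equal(dim(sims), c(2L, 50L))
  expect_true(all(sims %in% fit$grid$values))
  expect_output(print(fit), "Label-distribution")
  expect_output(print(summary(fit)), "MAE")
  expect_type(coef(fit), "list")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
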