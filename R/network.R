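# Compact convolutional network with a squeeze-and-excitation head,
# implemented directly in vectorized base R. Convolutions are evaluated as
# im2col gathers (one index gather per kernel offset) followed by a single
# BLAS matrix multiply; the backward pass mirrors each step analytically.
# Feature maps live as (N * positions) x channels matrices, positions in
# column-major image order, which keeps every op a matrix op.

#' Configuration of the hemoglobin regression network
#'
#' A small stack of stride-2 3x3 convolution + ReLU blocks, followed by a
#' squeeze-and-excitation (SE) channel-attention head — global average
#' pooling, a bottleneck transform with reduction `se_reduction`, sigmoid
#' gating of the channels — then global pooling and a linear projection to
#' `n_output` logits over the hemoglobin support grid. The default is the
#' desk-scale configuration (64x64 inputs, 4 blocks); `input_size = 224`
#' with a deeper stack reproduces the full-scale input geometry.
#'
#' @param input_size Side length of the (square) input; must be divisible by
#'   `2^depth`.
#' @param depth Number of stride-2 conv blocks (default 4).
#' @param width_multiplier Scales the channel widths `8, 16, 32, ...`
#'   (default 1; 0.75 mirrors a small-model setting).
#' @param se_reduction Bottleneck reduction ratio of the SE head (default 4).
#' @param n_output Number of logits = support-grid bins (default 15).
#' @return A list of class `"hb_net_config"`.
#' @export
net_config <- function(input_size = 64L, depth = 4L, width_multiplier = 1,
                       se_reduction = 4L, n_output = 15L) {
  input_size <- as.integer(input_size); depth <- as.integer(depth)
  if (n_output < 2L) stop("`n_output` must be >= 2")
  if (depth < 1L) stop("`depth` must be >= 1")
  if (input_size %% (2L^depth) != 0L)
    stop("`input_size` must be divisible by 2^depth")
  channels <- pmax(4L, as.integer(round(width_multiplier * 8L * 2L^(seq_len(depth) - 1L))))
  structure(list(input_size = input_size, depth = depth,
                 width_multiplier = width_multiplier,
                 channels = channels, se_reduction = as.integer(se_reduction),
                 n_output = as.integer(n_output)),
            class = "hb_net_config")
}

# per-layer geometry: output size and, for each 3x3 offset, the map from
# output position to input position (NA = padding)
conv_geom <- function(H, W, stride = 2L, pad = 1L) {
  H_out <- (H + 2L * pad - 3L) %/% stride + 1L
  W_out <- (W + 2L * pad - 3L) %/% stride + 1L
  ro <- rep(seq_len(H_out), times = W_out)
  co <- rep(seq_len(W_out), each = H_out)
  base <- vector("list", 9L)
  o <- 1L
  for (b in 0:2) for (a in 0:2) {       # column-major offset order (a = dy)
    r_in <- (ro - 1L) * stride + a - pad + 1L
    c_in <- (co - 1L) * stride + b - pad + 1L
    idx <- (c_in - 1L) * H + r_in
    idx[r_in < 1L | r_in > H | c_in < 1L | c_in > W] <- NA_integer_
    base[[o]] <- idx
    o <- o + 1L
  }
  list(H_in = H, W_in = W, P_in = H * W, H_out = H_out, W_out = W_out,
       P_out = H_out * W_out, base = base)
}

batch_gather_idx <- function(geom, o, N) {
  idx <- rep(geom$base[[o]], times = N) +
    rep((seq_len(N) - 1L) * geom$P_in, each = geom$P_out)
  idx[is.na(idx)] <- N * geom$P_in + 1L
  idx
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

#' Initialize the hemoglobin regression network
#'
#' Builds layer geometries and He-initialized parameters; fully reproducible
#' under `seed`.
#'
#' @param config A [net_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A list of class `"hb_net"` with `config`, `geoms`, `params`.
#' @export
cnn_init <- function(config = net_config(), seed = 1L) {
  set.seed(seed)
  geoms <- vector("list", config$depth)
  H <- config$input_size
  c_in <- 3L
  params <- list(conv = vector("list", config$depth))
  for (l in seq_len(config$depth)) {
    geoms[[l]] <- conv_geom(H, H)
    c_out <- config$channels[l]
    params$conv[[l]] <- list(W = he_init(9L * c_in, c_out, 9L * c_in),
                             b = numeric(c_out))
    H <- geoms[[l]]$H_out
    c_in <- c_out
  }
  C <- c_in
  h <- max(2L, C %/% config$se_reduction)
  params$se <- list(W1 = he_init(C, h, C), b1 = numeric(h),
                    W2 = he_init(h, C, h), b2 = numeric(C))
  params$out <- list(W = he_init(C, config$n_output, C),
                     b = numeric(config$n_output))
  structure(list(config = config, geoms = geoms, params = params),
            class = "hb_net")
}

# images: n x H x W x 3 array in [0,255] -> (n*P) x 3 matrix in [0,1]
stack_images <- function(images) {
  if (length(dim(images)) == 3L) dim(images) <- c(1L, dim(images))
  n <- dim(images)[1]; P <- dim(images)[2] * dim(images)[3]
  X <- matrix(0, n * P, 3L)
  for (i in seq_len(n)) {
    im <- images[i, , , ]
    X[((i - 1L) * P + 1L):(i * P), ] <- matrix(as.vector(im), P, 3L)
  }
  X / 255
}

#' Forward pass of the network
#'
#' @param net An [cnn_init()] object.
#' @param images `n x H x W x 3` array in `[0, 255]` (a single `H x W x 3`
#'   image is promoted to a batch of one).
#' @param keep_cache Keep intermediate activations for the backward pass.
#' @return A list with `logits` (`n x n_output`) and, if requested, `cache`.
#' @export
cnn_forward <- function(net, images, keep_cache = FALSE) {
  X <- stack_images(images)
  N <- nrow(X) / net$geoms[[1]]$P_in
  cache <- list(N = N, layers = vector("list", net$config$depth))
  A <- X
  for (l in seq_len(net$config$depth)) {
    g <- net$geoms[[l]]
    Cin <- ncol(A)
    Aa <- rbind(A, 0)
    Xcol <- matrix(0, N * g$P_out, 9L * Cin)
    for (o in 1:9) {
      idx <- batch_gather_idx(g, o, N)
      Xcol[, ((o - 1L) * Cin + 1L):(o * Cin)] <- Aa[idx, , drop = FALSE]
    }
    p <- net$params$conv[[l]]
    Z <- Xcol %*% p$W
    Z <- Z + rep(p$b, each = nrow(Z))
    A <- Z * (Z > 0)
    if (keep_cache)
      cache$layers[[l]] <- list(Xcol = Xcol, relu_mask = (Z > 0))
  }
  # SE head on the final feature map F = A, P positions per image
  P <- net$geoms[[net$config$depth]]$P_out
  C <- ncol(A)
  grp <- rep(seq_len(N), each = P)
  s <- rowsum(A, grp) / P                       # squeeze: N x C
  se <- net$params$se
  U <- s %*% se$W1 + rep(se$b1, each = N)
  Hh <- U * (U > 0)
  V <- Hh %*% se$W2 + rep(se$b2, each = N)
  E <- 1 / (1 + exp(-V))                        # excitation gates: N x C
  G <- A * E[grp, , drop = FALSE]               # channel gating
  gvec <- rowsum(G, grp) / P                    # pooled gated features
  logits <- gvec %*% net$params$out$W + rep(net$params$out$b, each = N)
  dimnames(logits) <- NULL
  if (keep_cache) {
    cache$F <- A; cache$grp <- grp; cache$P <- P
    cache$s <- s; cache$U <- U; cache$Hh <- Hh; cache$E <- E
    cache$gvec <- gvec
  }
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

# backward pass from dlogits (N x K) to parameter gradients; the returned
# list mirrors the params structure (and field order) exactly so that
# flatten_params() aligns the two
cnn_backward <- function(net, cache, dlogits) {
  N <- cache$N; P <- cache$P; grp <- cache$grp
  grads <- list(conv = vector("list", net$config$depth),
                se = NULL, out = NULL)
  grads$out <- list(W = crossprod(cache$gvec, dlogits),
                    b = colSums(dlogits))
  dg <- dlogits %*% t(net$params$out$W)          # N x C
  dG <- dg[grp, , drop = FALSE] / P              # (N*P) x C
  dF_gate <- dG * cache$E[grp, , drop = FALSE]
  dE <- rowsum(dG * cache$F, grp)                # N x C
  dV <- dE * cache$E * (1 - cache$E)
  dH <- dV %*% t(net$params$se$W2)
  dU <- dH * (cache$U > 0)
  grads$se <- list(W1 = crossprod(cache$s, dU), b1 = colSums(dU),
                   W2 = crossprod(cache$Hh, dV), b2 = colSums(dV))
  ds <- dU %*% t(net$params$se$W1)
  dA <- dF_gate + ds[grp, , drop = FALSE] / P
  for (l in rev(seq_len(net$config$depth))) {
    g <- net$geoms[[l]]
    lc <- cache$layers[[l]]
    dZ <- dA * lc$relu_mask
    grads$conv[[l]] <- list(W = crossprod(lc$Xcol, dZ), b = colSums(dZ))
    if (l > 1L) {
      Cin <- nrow(net$params$conv[[l]]$W) / 9L
      dXcol <- dZ %*% t(net$params$conv[[l]]$W)
      dAa <- matrix(0, N * g$P_in + 1L, Cin)
      for (o in 1:9) {
        idx <- batch_gather_idx(g, o, N)
        dAa[idx, ] <- dAa[idx, ] +
          dXcol[, ((o - 1L) * Cin + 1L):(o * Cin), drop = FALSE]
      }
      dA <- dAa[seq_len(N * g$P_in), , drop = FALSE]
    }
  }
  grads
}

# mean composite loss over a batch and its parameter gradients
cnn_loss_and_grad <- function(net, images, y, sigma = 1, lambda = 1,
                              grid = support_grid(), with_grads = TRUE) {
  fw <- cnn_forward(net, images, keep_cache = with_grads)
  N <- nrow(fw$logits)
  kvals <- grid$values
  Pm <- softmax_probs(fw$logits)
  yhat <- drop(Pm %*% kvals)
  Tm <- t(vapply(y, encode_label, numeric(grid$n_bins),
                 sigma = sigma, grid = grid))
  pos <- Tm > 0
  kl <- rowSums(Tm * (log(pmax(Tm, 1e-300)) - log(pmax(Pm, 1e-12))) * pos)
  l1 <- abs(yhat - y)
  loss <- mean(kl + lambda * l1)
  if (!with_grads)
    return(list(loss = loss, kl = mean(kl), l1 = mean(l1), yhat = yhat))
  sgn <- sign(yhat - y)
  dlogits <- (Pm - Tm) +
    lambda * sgn * Pm * (matrix(kvals, N, grid$n_bins, byrow = TRUE) - yhat)
  dlogits <- dlogits / N
  grads <- cnn_backward(net, fw$cache, dlogits)
  list(loss = loss, kl = mean(kl), l1 = mean(l1), yhat = yhat, grads = grads)
}

# flatten/unflatten parameters (used by SGD and by gradient checking)
flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

relist_params <- function(vec, skeleton) {
  utils::relist(vec, skeleton)
}

# one SGD-with-momentum step; returns updated params and velocity
sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  pv <- flatten_params(params)
  gv <- flatten_params(grads) + weight_decay * pv
  if (is.null(velocity)) velocity <- numeric(length(pv))
  velocity <- momentum * velocity - lr * gv
  list(params = relist_params(pv + velocity, params), velocity = velocity)
}

#' Predict hemoglobin values with a network
#'
#' Runs the forward pass and expectation-decodes each softmax distribution;
#' predictions therefore always lie inside the support interval.
#'
#' @param net An `"hb_net"` object.
#' @param images `n x H x W x 3` array (or one `H x W x 3` image).
#' @param grid Support grid matching `net$config$n_output`.
#' @param type `"response"` for decoded values, `"distribution"` for the
#'   `n x n_bins` probability matrix.
#' @return Numeric vector of Hb estimates, or a probability matrix.
#' @export
cnn_predict <- function(net, images, grid = support_grid(),
                        type = c("response", "distribution")) {
  type <- match.arg(type)
  logits <- cnn_forward(net, images)$logits
  probs <- softmax_probs(logits)
  if (type == "distribution") return(probs)
  decode_prediction(probs, grid)
}
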