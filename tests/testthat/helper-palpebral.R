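# shared fixtures, built in code at test time

# small masked-input dataset cache so several tests can reuse one simulation
local_sim_cache <- new.env(parent = emptyenv())

cached_dataset <- function(key, n, config) {
  if (is.null(local_sim_cache[[key]]))
    local_sim_cache[[key]] <- generate_dataset(n, config)
  local_sim_cache[[key]]
}

masked_array <- function(dataset, mode = "zero-background") {
  n <- length(dataset$samples)
  d <- dim(dataset$samples[[1]]$image)
  out <- array(0, c(n, d[1], d[2], 3L))
  for (i in seq_len(n)) {
    s <- dataset$samples[[i]]
    img <- if (mode == "none") s$image else apply_mask(s$image, s$mask, mode)
    if (!all(dim(img)[1:2] == d[1:2])) {
      dim(img) <- c(1L, dim(img))
      img <- resize_images(img, d[1])[1, , , ]
    }
    out[i, , , ] <- img
  }
  out
}

# independent brute-force regression metrics (loop arithmetic, no reuse of
# package internals)
brute_metrics <- function(y, p) {
  n <- length(y)
  mae <- 0
  for (i in seq_len(n)) mae <- mae + abs(y[i] - p[i]) / n
  my <- sum(y) / n
  sst <- 0; ssr <- 0
  for (i in seq_len(n)) {
    sst <- sst + (y[i] - my)^2
    ssr <- ssr + (y[i] - p[i])^2
  }
  res <- y - p
  mres <- sum(res) / n
  vres <- sum((res - mres)^2) / n
  list(r2 = 1 - ssr / sst, evs = 1 - vres / (sst / n), mae = mae)
}

# independent brute-force single-threshold mask metrics
brute_seg <- function(pred, truth, t) {
  n <- length(pred)
  tp <- fp <- fn <- 0
  ious <- numeric(n)
  for (i in seq_len(n)) {
    a <- pred[[i]]; b <- truth[[i]]
    inter <- sum(a == 1 & b == 1); uni <- sum(a == 1 | b == 1)
    iou <- if (uni == 0) 1 else inter / uni
    ious[i] <- iou
    hp <- sum(a) > 0; ht <- sum(b) > 0
    if (hp && ht && iou >= t) tp <- tp + 1
    if (hp && !(ht && iou >= t)) fp <- fp + 1
    if (ht && !(hp && iou >= t)) fn <- fn + 1
  }
  list(ap = if (tp + fp > 0) tp / (tp + fp) else 0,
       ar = if (tp + fn > 0) tp / (tp + fn) else 0,
       miou = mean(ious))
}

rand_rect_mask <- function(H, W) {
  m <- matrix(0L, H, W)
  r <- sort(sample.int(H, 2)); c <- sort(sample.int(W, 2))
  m[r[1]:r[2], c[1]:c[2]] <- 1L
  m
}
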