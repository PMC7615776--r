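# shared fixtures and independent oracle routines used across test files

# reference row layer-norm (eps matches the production default)
ref_ln <- function(v, eps = 1e-5) {
  (v - mean(v)) / sqrt(mean((v - mean(v))^2) + eps)
}

# random feature map C x H x W
rand_map <- function(C, H, W) array(rnorm(C * H * W), c(C, H, W))

# a small random blob mask: a disc of radius r at (cx, cy) labelled cls
blob_mask <- function(size, cx, cy, r, cls = 1L) {
  m <- matrix(0L, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    if ((i - cx)^2 + (j - cy)^2 <= r^2) m[i, j] <- cls
  }
  m
}

# explicit-loop directed Hausdorff oracle on boundary point sets:
# all-pairs distances, max (or per-percentile) of the directed minima
oracle_hausdorff <- function(pred, gt, cls, percentile = 100) {
  bnd <- function(mask) {
    d <- dim(mask)
    pts <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (mask[i, j]) {
        edge <- i == 1 || j == 1 || i == d[1] || j == d[2] ||
          !mask[i - 1, j] || !mask[i + 1, j] ||
          !mask[i, j - 1] || !mask[i, j + 1]
        if (edge) pts <- rbind(pts, c(i, j))
      }
    }
    pts
  }
  A <- bnd(pred == cls); B <- bnd(gt == cls)
  if (is.null(A) || is.null(B)) return(NA_real_)
  dmin <- function(P, Q) {
    out <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        dd <- sqrt(sum((P[i, ] - Q[j, ])^2))
        if (dd < best) best <- dd
      }
      out[i] <- best
    }
    out
  }
  dab <- dmin(A, B); dba <- dmin(B, A)
  if (percentile == 100) max(max(dab), max(dba))
  else max(quantile(dab, 0.95, names = FALSE),
           quantile(dba, 0.95, names = FALSE))
}

# explicit-loop cross-window attention oracle (gates off): window tokens are
# layer-normed, GELU'd, projected; each output window is the attention-
# weighted sum of the input windows
oracle_pwga <- function(win, wt, Wq, Wk) {
  nw <- dim(win$tokens)[1]
  dimc <- dim(win$tokens)[3]
  tmat <- t(apply(wt, 1, ref_ln))
  tmat <- tmat * pnorm(tmat)
  q <- tmat %*% Wq; k <- tmat %*% Wk
  ref <- win
  ref$tokens[] <- 0
  for (o in seq_len(nw)) {
    lg <- sapply(seq_len(nw), function(p) sum(q[o, ] * k[p, ])) / sqrt(dimc)
    a <- exp(lg - max(lg)); a <- a / sum(a)
    for (p in seq_len(nw)) {
      ref$tokens[o, , ] <- ref$tokens[o, , ] + a[p] * win$tokens[p, , ]
    }
  }
  merge_windows(ref)
}

# tiny training setup shared by train/acceptance tests
tiny_train_cfg <- function(size = 32L, ...) {
  args <- list(
    net = desk_config(input_size = size, num_classes = 5L,
                      dims = c(16L, 32L, 64L, 128L), heads = c(1L, 2L, 4L, 8L),
                      window = 2L, patch_size = 2L,
                      decoder_dims = c(64L, 32L, 16L, 16L)),
    batch_size = 4L, epochs = 1L, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}
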