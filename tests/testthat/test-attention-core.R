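# window partitioning, gated window attention against the loop oracle, and
# the DSG-ViT block contracts

test_that("window partition counts tokens and round-trips exactly", {
  set.seed(21)
  w <- partition_windows(rand_map(1, 4, 4), 2)
  expect_equal(dim(w$tokens), c(4, 4, 1))

  w1 <- partition_windows(rand_map(1, 2, 2), 2)
  expect_equal(dim(w1$tokens), c(1, 4, 1))
  # row-major single window: tokens follow reading order of the map
  x <- array(0, c(1, 2, 2)); x[1, , ] <- matrix(1:4, 2, 2, byrow = TRUE)
  expect_equal(as.vector(partition_windows(x, 2)$tokens[1, , 1]), 1:4)

  x <- rand_map(3, 8, 8)
  expect_identical(merge_windows(partition_windows(x, 4)), x)

  expect_error(partition_windows(rand_map(1, 6, 8), 4), "height")
  expect_error(partition_windows(rand_map(1, 8, 6), 4), "width")
})

test_that("brute-force attention oracle has its closed-form properties", {
  set.seed(22)
  v <- matrix(rnorm(3), 1, 3)
  expect_equal(brute_force_attention(matrix(1, 1, 2), matrix(1, 1, 2), v), v)
  # two identical keys: output is the mean of the values
  q <- matrix(rnorm(4), 2, 2)
  k <- matrix(rep(c(0.3, -0.7), each = 2), 2, 2)
  vv <- matrix(rnorm(6), 2, 3)
  out <- brute_force_attention(q, k, vv)
  expect_equal(out[1, ], colMeans(vv), tolerance = 1e-12)
  expect_error(brute_force_attention(q, k[1, , drop = FALSE], vv), "token")
})

test_that("gates-off DWGA equals loop-oracle attention; softmax rows sum to 1", {
  set.seed(23)
  for (m in c(2, 4)) {
    for (heads in c(1, 2)) {
      dimc <- 8
      hd <- dimc / heads
      x <- rand_map(dimc, 2 * m, 2 * m)
      win <- partition_windows(x, m)
      w <- projection_weights(dimc, heads)
      rp <- rel_pos_tables(m, hd, heads)
      g <- gate_set(heads)
      g$g_q[] <- 0; g$g_k[] <- 0; g$g_v2[] <- 0; g$g_v1[] <- 1
      out <- dwga(win, w, rp, g)
      for (wi in seq_len(dim(win$tokens)[1])) {
        tk <- win$tokens[wi, , ]
        ref <- matrix(0, m * m, dimc)
        for (h in seq_len(heads)) {
          cols <- (h - 1) * hd + seq_len(hd)
          ref[, cols] <- brute_force_attention(
            tk %*% w$Wq[, cols], tk %*% w$Wk[, cols], tk %*% w$Wv[, cols])
        }
        expect_lt(max(abs(out$tokens[wi, , ] - ref)), 1e-5)
      }
      for (a in attr(out, "attention")) {
        expect_lt(max(abs(rowSums(a) - 1)), 1e-6)
      }
    }
  }
})

test_that("zero position tables with arbitrary gates reduce to plain attention", {
  set.seed(24)
  m <- 2; dimc <- 6
  x <- rand_map(dimc, 4, 4)
  win <- partition_windows(x, m)
  w <- projection_weights(dimc, 1)
  rp <- rel_pos_tables(m, dimc, 1)
  rp$rq[] <- 0; rp$rk[] <- 0; rp$rv[] <- 0
  g <- gate_set(1, init = 2.7); g$g_v1[] <- 1; g$g_v2[] <- 0.4
  out <- dwga(win, w, rp, g)
  g0 <- gate_set(1); g0$g_q[] <- 0; g0$g_k[] <- 0; g0$g_v1[] <- 1; g0$g_v2[] <- 0
  ref <- dwga(win, w, rp, g0)
  expect_equal(out$tokens, ref$tokens, tolerance = 1e-12)
})

test_that("window tokens support zero and mean initialization", {
  set.seed(25)
  win <- partition_windows(rand_map(3, 4, 4), 2)
  z <- make_window_tokens(win, "zeros")
  expect_true(all(z == 0) && all(dim(z) == c(4, 3)))
  cw <- win; cw$tokens[1, , ] <- 5
  expect_equal(make_window_tokens(cw, "mean")[1, ], rep(5, 3))
  w1 <- partition_windows(array(c(1, 3, 1, 3), c(1, 2, 2)), 2)
  expect_equal(as.numeric(make_window_tokens(w1, "mean")), 2)
})

test_that("PWGA: single window is the identity on values; gates-off matches a loop oracle", {
  set.seed(26)
  dimc <- 8; m <- 4
  x <- rand_map(dimc, m, m)
  win <- partition_windows(x, m)
  w <- projection_weights(dimc, 1)
  w$ln_gamma <- rep(1, dimc); w$ln_beta <- numeric(dimc)
  rp <- rel_pos_tables(1, dimc, 1, n_offsets = 1)
  out <- pwga(win, make_window_tokens(win), w, rp, gate_set(1))
  expect_equal(out, merge_windows(win), tolerance = 1e-12,
               ignore_attr = TRUE)

  # 4 windows, gates off, against explicit cross-window attention
  m <- 2; dimc <- 6
  x <- rand_map(dimc, 4, 4)
  win <- partition_windows(x, m)
  wt <- make_window_tokens(win)
  w <- projection_weights(dimc, 1)
  w$ln_gamma <- rep(1, dimc); w$ln_beta <- numeric(dimc)
  rp <- rel_pos_tables(1, dimc, 1,
                       n_offsets = (2 * win$grid[1] - 1) * (2 * win$grid[2] - 1))
  g <- gate_set(1); g$g_q[] <- 0; g$g_k[] <- 0
  out <- pwga(win, wt, w, rp, g)
  tmat <- t(apply(wt, 1, ref_ln))
  tmat <- tmat * pnorm(tmat)
  q <- tmat %*% w$Wq; k <- tmat %*% w$Wk
  ref <- win
  ref$tokens[] <- 0
  for (o in 1:4) {
    lg <- sapply(1:4, function(p) sum(q[o, ] * k[p, ])) / sqrt(dimc)
    a <- exp(lg - max(lg)); a <- a / sum(a)
    for (p in 1:4) ref$tokens[o, , ] <- ref$tokens[o, , ] + a[p] * win$tokens[p, , ]
  }
  expect_lt(max(abs(out - merge_windows(ref))), 1e-5)
  for (a in attr(out, "attention")) expect_lt(max(abs(rowSums(a) - 1)), 1e-6)

  expect_error(pwga(win, wt[1:2, ], w, rp, g), "window count mismatch")
})

test_that("DWGA output is covariant under whole-window translation", {
  set.seed(27)
  m <- 2; dimc <- 4
  x <- rand_map(dimc, 4, 4)
  # translate by m pixels with wrap-around: window contents are preserved,
  # only the window order changes (here: swap of grid columns)
  x2 <- x[, , c(3, 4, 1, 2)]
  w <- projection_weights(dimc, 1)
  rp <- rel_pos_tables(m, dimc, 1)
  g <- gate_set(1, init = 0.8)
  o1 <- dwga(partition_windows(x, m), w, rp, g)
  o2 <- dwga(partition_windows(x2, m), w, rp, g)
  perm <- c(2, 1, 4, 3)  # window reordering induced by the column swap
  expect_equal(o2$tokens, o1$tokens[perm, , ], tolerance = 1e-12)
})

test_that("the DSG-ViT block keeps shape, reduces to identity, and trains its gates", {
  set.seed(28)
  cfg <- block_config(dim = 8, heads = 2, window_size = 2, input_hw = c(4, 4))
  blk <- dsg_vit_block(cfg)
  x <- rand_map(8, 4, 4)
  y <- dsg_block_forward(blk, x)
  expect_equal(dim(y), dim(x))

  blk0 <- dsg_vit_block(cfg)
  blk0$proj$W$value[] <- 0; blk0$proj$b$value[] <- 0
  blk0$mlp2$W$value[] <- 0; blk0$mlp2$b$value[] <- 0
  expect_identical(dsg_block_forward(blk0, x), x)

  xb <- ag(array(aperm(x, c(2, 3, 1)), c(4, 4, 8, 1)))
  loss <- function() {
    o <- dsg_block_forward(blk, xb)
    ag_mean(ag_mul(o, o))
  }
  ps <- collect_params(blk)
  ag_zero_grad(ps)
  ag_backward(loss())
  for (nm in names(ps)) {
    expect_false(is.null(ps[[nm]]$grad), info = nm)
    expect_gt(max(abs(ps[[nm]]$grad)), 0)
  }
  # finite-difference check on the query gate specifically
  expect_lt(ag_grad_check(loss, blk$g_q), 1e-4)
})
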