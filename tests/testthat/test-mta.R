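# mixed three-branch attention: ranges, closed-form degeneracies, branch
# recomputation, fusion oracle

test_that("channel attention is bounded, shares its conv, and degrades to 0.5", {
  set.seed(31)
  x <- rand_map(8, 6, 6)
  l <- layer_channel_attn(8)
  cm <- channel_attention(x, l)
  expect_equal(dim(cm), c(8, 1, 1))
  expect_true(all(cm > 0 & cm < 1))

  # constant per channel: max-pool branch equals avg-pool branch pre-sigmoid,
  # so the output equals sigmoid(2 * LeakyReLU(W %*% mu + b))
  xc <- array(rep(1:8, times = 36), c(8, 6, 6))
  v <- as.vector(channel_attention(xc, l))
  lr <- function(z) ifelse(z > 0, z, 0.01 * z)
  pre <- lr(as.vector(t(1:8) %*% ag_value(l$lin$W)) + ag_value(l$lin$b))
  expect_equal(v, 1 / (1 + exp(-2 * pre)), tolerance = 1e-10)

  l0 <- layer_channel_attn(8)
  l0$lin$W$value[] <- 0; l0$lin$b$value[] <- 0
  expect_true(all(channel_attention(x, l0) == 0.5))
})

test_that("the spatial pyramid sums its three branches and stays in (0,1)", {
  set.seed(32)
  x <- rand_map(8, 10, 10)
  l <- layer_spatial_pyramid(8)
  s <- spatial_pyramid_attention(x, l, details = TRUE)
  expect_equal(dim(s), c(1, 10, 10))
  expect_true(all(s > 0 & s < 1))
  br <- attr(s, "branches")
  expect_length(br, 3)
  # independently recomputed branch sum reproduces the module value
  total <- br[[1]] + br[[2]] + br[[3]]
  expect_lt(max(abs(1 / (1 + exp(-total)) - s)), 1e-6)
  # each branch preserves the spatial size
  for (b in br) expect_equal(dim(b), c(1, 10, 10))
})

test_that("the global branch round-trips patches and normalizes attention", {
  set.seed(33)
  x <- rand_map(8, 8, 8)
  g <- global_vit_attention(x, 2, details = TRUE)
  expect_equal(dim(g), dim(x))
  for (a in attr(g, "attention")) expect_lt(max(abs(rowSums(a) - 1)), 1e-6)
  expect_error(global_vit_attention(x, 3), "divisible")

  # zeroed attention/MLP projections and position code: residual-only path,
  # G = per-patch layer-norm of the flattened input, reshaped back
  l0 <- layer_global_vit(8, 8, 8, 2)
  l0$Wo$W$value[] <- 0; l0$Wo$b$value[] <- 0
  l0$mlp2$W$value[] <- 0; l0$mlp2$b$value[] <- 0
  l0$c_loc$value[] <- 0
  g0 <- global_vit_attention(x, 2, l0)
  ref <- array(0, dim(x))
  for (pr in 1:4) for (pc in 1:4) {
    tok <- numeric(8 * 4)
    for (cc in 1:8) for (tr in 1:2) for (tc in 1:2) {
      tok[(tr - 1) * 2 + tc + 4 * (cc - 1)] <-
        x[cc, (pr - 1) * 2 + tr, (pc - 1) * 2 + tc]
    }
    tok <- ref_ln(tok)
    for (cc in 1:8) for (tr in 1:2) for (tc in 1:2) {
      ref[cc, (pr - 1) * 2 + tr, (pc - 1) * 2 + tc] <-
        tok[(tr - 1) * 2 + tc + 4 * (cc - 1)]
    }
  }
  expect_lt(max(abs(g0 - ref)), 1e-10)
})

test_that("fusion follows (C x S) + G with broadcasting, against a loop oracle", {
  set.seed(34)
  cm <- array(runif(3), c(3, 1, 1))
  sm <- array(runif(16), c(1, 4, 4))
  gm <- array(rnorm(48), c(3, 4, 4))
  f <- mta_fuse(cm, sm, gm)
  ref <- array(0, c(3, 4, 4))
  for (cc in 1:3) for (h in 1:4) for (w in 1:4) {
    ref[cc, h, w] <- cm[cc, 1, 1] * sm[1, h, w] + gm[cc, h, w]
  }
  expect_equal(f, ref, tolerance = 1e-12)

  expect_equal(mta_fuse(array(1, c(3, 1, 1)), sm, array(0, c(3, 4, 4)))[2, , ],
               sm[1, , ])
  expect_equal(mta_fuse(cm, array(0, c(1, 4, 4)), gm), gm)
  expect_error(mta_fuse(cm, sm, array(0, c(2, 4, 4))), "incompatible")
})

test_that("the full module keeps shape and zero weights give the 0.25 field", {
  set.seed(35)
  for (hw in list(c(8, 8), c(4, 4))) {
    x <- rand_map(8, hw[1], hw[2])
    l <- mta_layer(8, hw)
    out <- mta_forward(l, x)
    expect_equal(dim(out), dim(x))
    expect_true(all(is.finite(out)))
  }
  l0 <- mta_layer(8, c(8, 8))
  for (p in collect_params(l0)) p$value[] <- 0
  out0 <- mta_forward(l0, rand_map(8, 8, 8))
  # sigmoid(0)^2 = 0.25 per position; the global path is exactly zero
  expect_equal(max(abs(out0 - 0.25)), 0)
})

test_that("branch maps recomputed with the module weights match its internals", {
  set.seed(36)
  x <- rand_map(8, 8, 8)
  l <- mta_layer(8, c(8, 8))
  out <- mta_forward(l, x, details = TRUE)
  cm <- channel_attention(x, l$ca)
  sm <- spatial_pyramid_attention(x, l$sp)
  gm <- global_vit_attention(x, l$patch_size, l$gv)
  expect_lt(max(abs(attr(out, "channel_map") - cm)), 1e-6)
  expect_lt(max(abs(attr(out, "spatial_map") - sm)), 1e-6)
  expect_lt(max(abs(out - mta_fuse(cm, sm, gm))), 1e-6)
})
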