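# structural contracts of the assembled network

test_that("patch merging halves space, doubles channels, halves elements", {
  set.seed(41)
  x <- rand_map(4, 6, 6)
  y <- patch_merge(x)
  expect_equal(dim(y), c(8, 3, 3))
  expect_equal(length(y), length(x) / 2)
  expect_error(patch_merge(rand_map(4, 5, 6)), "even")

  # 2x2 constant map: the single output position is the linear map of the
  # 4 concatenated (equal) pixel vectors
  l <- layer_patch_merge(3)
  xc <- array(0, c(3, 2, 2))
  for (cc in 1:3) xc[cc, , ] <- cc
  y1 <- patch_merge(xc, l)
  tok <- rep(1:3, each = 4)  # neighbourhood-position-major token layout
  expect_equal(as.vector(y1),
               as.vector(tok %*% ag_value(l$lin$W)) + ag_value(l$lin$b),
               tolerance = 1e-10)
})

test_that("encoder stage resolutions and block counts follow the presets", {
  set.seed(42)
  img <- array(runif(64 * 64), c(1, 64, 64))
  cfg <- desk_config(depths = "Middle-1")
  expect_equal(cfg$depths, c(2L, 2L, 6L, 2L))
  cfgb <- desk_config(depths = "Base")
  expect_equal(cfgb$depths, c(1L, 1L, 3L, 1L))
  expect_error(network_config(depths = "Huge"), "preset")

  model <- dsga_net(cfgb)
  expect_equal(sum(vapply(model$stages, function(s) length(s$blocks),
                          numeric(1))), 6)
  feats <- encoder_forward(img, model)
  expect_equal(lapply(feats, dim),
               list(c(16L, 32L, 32L), c(32L, 16L, 16L),
                    c(64L, 8L, 8L), c(128L, 4L, 4L)))
})

test_that("bottleneck and decoder steps keep the resolution bookkeeping", {
  set.seed(43)
  x <- rand_map(16, 7, 7)
  y <- bottleneck(x, out_channels = 24)
  expect_equal(dim(y), c(24, 7, 7))
  l0 <- layer_conv2d(16, 24, 3, pad = 1)
  l0$W$value[] <- 0; l0$b$value[] <- 0
  expect_true(all(bottleneck(x, l0) == 0))
  # identity-initialized kernel preserves the input (pre-ReLU ok for |x| -> relu(x)=x if x>0)
  li <- layer_conv2d(16, 16, 3, pad = 1, init = "identity")
  xp <- abs(x)
  expect_equal(bottleneck(xp, li), xp, tolerance = 1e-12)

  d <- rand_map(32, 7, 7)
  skip <- rand_map(24, 14, 14)
  out <- decoder_step(d, skip, out_channels = 16)
  expect_equal(dim(out), c(16, 14, 14))
  out2 <- decoder_step(d, out_channels = 16)
  expect_equal(dim(out2), c(16, 14, 14))
  expect_error(decoder_step(d, rand_map(24, 10, 10)), "mismatch")

  # three steps from 4x4 with skips at 8, 16, 32 land at 32 before the head
  z <- rand_map(32, 4, 4)
  for (r in c(8, 16, 32)) z <- decoder_step(z, rand_map(8, r, r))
  expect_equal(dim(z)[2:3], c(32, 32))
})

test_that("full forward yields class logits at input resolution, deterministically", {
  set.seed(44)
  cfg <- desk_config(input_size = 32, num_classes = 5,
                     dims = c(16, 32, 64, 128), window = 2,
                     decoder_dims = c(64, 32, 16, 16))
  model <- dsga_net(cfg)
  img <- array(runif(32 * 32), c(1, 32, 32))
  lg <- net_forward(model, img)
  expect_equal(dim(lg), c(5, 32, 32))
  expect_identical(net_forward(model, img), lg)
  mask <- predict(model, img)
  expect_true(all(mask %in% 0:4))
  pr <- predict(model, img, type = "prob")
  expect_lt(max(abs(apply(pr, c(2, 3), sum) - 1)), 1e-8)
})

test_that("every MTA ablation variant is constructible and runs", {
  set.seed(45)
  img <- array(runif(32 * 32), c(1, 32, 32))
  for (stages in list(integer(0), 1L, 1:2, 1:3)) {
    cfg <- desk_config(input_size = 32, num_classes = 3,
                       dims = c(16, 32, 64, 128), window = 2,
                       decoder_dims = c(64, 32, 16, 16),
                       mta_stages = stages)
    model <- dsga_net(cfg)
    expect_equal(dim(net_forward(model, img)), c(3, 32, 32))
    expect_equal(sum(!vapply(model$mta, is.null, logical(1))),
                 length(stages))
  }
})

test_that("all parameters receive gradients after one optimization step", {
  set.seed(46)
  # patch size 2 keeps every stage at >= 2x2 resolution so no attention
  # degenerates to a single token (which would starve the logit gates)
  cfg <- desk_config(input_size = 32, num_classes = 3,
                     dims = c(16, 32, 64, 128), window = 2, patch_size = 2,
                     decoder_dims = c(64, 32, 16, 16))
  model <- dsga_net(cfg)
  xb <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  tgt <- sample(3, 32 * 32 * 2, replace = TRUE)
  out <- .net_forward(model, ag(xb), training = TRUE)
  d <- dim(ag_value(out))
  lmat <- ag_reshape(ag_aperm(out, c(1, 2, 4, 3)),
                     c(d[1] * d[2] * d[4], d[3]))
  loss <- .seg_loss(lmat, tgt, 3)
  params <- collect_params(model)
  ag_zero_grad(params)
  ag_backward(loss)
  gate_names <- grep("g_[qkv]", names(params), value = TRUE)
  expect_gt(length(gate_names), 0)
  for (nm in names(params)) {
    expect_false(is.null(params[[nm]]$grad), info = nm)
    expect_gt(max(abs(params[[nm]]$grad)), 0)
  }
  before <- lapply(params, ag_value)
  .sgd_update(params, new.env(), 0.01, 0.9, 4e-4)
  moved <- vapply(names(params), function(nm)
    max(abs(before[[nm]] - params[[nm]]$value)) > 0, logical(1))
  expect_true(all(moved))
})

test_that("parameter counts are a pure function of the configuration", {
  cfg <- desk_config(input_size = 32, num_classes = 3,
                     dims = c(16, 32, 64, 128), window = 2,
                     decoder_dims = c(64, 32, 16, 16))
  set.seed(1); s1 <- model_summary(dsga_net(cfg))
  set.seed(999); s2 <- model_summary(dsga_net(cfg))
  expect_identical(s1$name, s2$name)
  expect_identical(s1$count, s2$count)
  expect_identical(attr(s1, "total"), attr(s2, "total"))
})

test_that("checkpoints round-trip to identical predictions", {
  set.seed(47)
  cfg <- desk_config(input_size = 32, num_classes = 3,
                     dims = c(16, 32, 64, 128), window = 2,
                     decoder_dims = c(64, 32, 16, 16))
  model <- dsga_net(cfg)
  img <- array(runif(32 * 32), c(1, 32, 32))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  m2 <- load_checkpoint(f)
  expect_identical(net_forward(m2, img), net_forward(model, img))
})

test_that("transposed-convolution upsampling is selectable", {
  set.seed(48)
  cfg <- desk_config(input_size = 32, num_classes = 3,
                     dims = c(16, 32, 64, 128), window = 2,
                     decoder_dims = c(64, 32, 16, 16), upsample = "deconv")
  model <- dsga_net(cfg)
  img <- array(runif(32 * 32), c(1, 32, 32))
  expect_equal(dim(net_forward(model, img)), c(3, 32, 32))
})
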