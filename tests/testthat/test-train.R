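# training loop, evaluation drivers, ablation harness, CLI plumbing

test_that("a tiny run completes, logs, checkpoints, and is seed-deterministic", {
  sp <- phantom_spec(size = 32, seed = 1)
  data <- list(train = phantom_batch(sp, 1:8), val = phantom_batch(sp, 9:10))
  out <- tempfile("run")
  cfg <- tiny_train_cfg(epochs = 2L)
  fit <- dsga_train(cfg, data, out_dir = out)
  expect_length(fit$record$epoch_loss, 2)
  expect_true(all(is.finite(fit$record$epoch_loss)))
  expect_true(file.exists(fit$checkpoint))
  expect_true(file.exists(file.path(out, "run.jsonl")))
  log1 <- jsonlite::stream_in(file(file.path(out, "run.jsonl")),
                              verbose = FALSE)
  expect_equal(log1$lr[1], 0.01)
  expect_equal(log1$momentum[1], 0.9)
  expect_equal(log1$weight_decay[1], 4e-4)

  # same seed, fresh run: identical first-epoch loss
  fit2 <- dsga_train(cfg, data)
  expect_identical(fit$record$epoch_loss[1], fit2$record$epoch_loss[1])
  # different seed: different loss
  fit3 <- dsga_train(tiny_train_cfg(epochs = 1L, seed = 2L), data)
  expect_false(identical(fit$record$epoch_loss[1],
                         fit3$record$epoch_loss[1]))
  unlink(out, recursive = TRUE)
})

test_that("loss decreases over the first optimization steps on a fixed batch", {
  sp <- phantom_spec(size = 32, seed = 4)
  data <- list(train = phantom_batch(sp, 1:4), val = NULL)
  cfg <- tiny_train_cfg(epochs = 6L, augment = FALSE)
  fit <- dsga_train(cfg, data)
  sl <- fit$record$step_loss
  expect_gt(length(sl), 4)
  expect_lt(mean(tail(sl, 3)), mean(head(sl, 3)))
})

test_that("checkpoints round-trip through evaluation with identical metrics", {
  sp <- phantom_spec(size = 32, seed = 5)
  data <- list(train = phantom_batch(sp, 1:4), val = phantom_batch(sp, 5:6))
  fit <- dsga_train(tiny_train_cfg(), data)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, f)
  r1 <- dsga_evaluate(fit$model, data$val)
  r2 <- dsga_evaluate(f, data$val)
  expect_identical(r1, r2)
})

test_that("evaluation debug modes pin the metric plumbing", {
  sp <- phantom_spec(size = 32, seed = 6)
  data <- list(train = phantom_batch(sp, 1:4), val = phantom_batch(sp, 5:6))
  fit <- dsga_train(tiny_train_cfg(), data)
  rg <- dsga_evaluate(fit$model, data$val, debug_pred = "gt")
  expect_true(all(rg$mean_dsc == 1))
  expect_true(all(rg$mean_hd == 0))
  re <- suppressMessages(dsga_evaluate(fit$model, data$val,
                                       debug_pred = "empty"))
  dsc_cols <- grep("^dsc_", names(re))
  expect_true(all(re[, dsc_cols] == 0))
  # report files
  pre <- tempfile()
  dsga_evaluate(fit$model, data$val, out_prefix = pre)
  expect_true(file.exists(paste0(pre, ".csv")))
  js <- jsonlite::read_json(paste0(pre, ".json"))
  expect_true(is.numeric(js$mean_dsc))
})

test_that("config hashes are stable under field reordering", {
  cfg <- tiny_train_cfg()
  h1 <- config_hash(cfg)
  shuffled <- cfg
  shuffled[] <- cfg[rev(seq_along(cfg))]
  names(shuffled) <- rev(names(cfg))
  h2 <- config_hash(shuffled)
  expect_identical(h1, h2)
  other <- tiny_train_cfg(seed = 99L)
  expect_false(identical(h1, config_hash(other)))
})

test_that("the ablation harness runs every variant of each axis", {
  sp <- phantom_spec(size = 32, seed = 2)
  base <- tiny_train_cfg(max_steps = 1L)
  tb <- dsga_ablate(base, sp, n_train = 4, n_val = 2, axis = "mta_stages")
  expect_identical(tb$variant, c("0-MTA", "1-MTA", "2-MTA", "3-MTA"))
  expect_true(all(is.finite(tb$val_dsc)))
  # more skip connections add parameters
  expect_true(all(diff(tb$n_params) > 0))
  td <- dsga_ablate(base, sp, n_train = 4, n_val = 2, axis = "depths")
  expect_identical(td$variant, c("Base", "Middle-1", "Middle-2"))
  expect_true(all(diff(td$n_params) > 0))
  tr <- dsga_ablate(base, sp, n_train = 2, n_val = 1, axis = "resolution",
                    resolutions = c(32L, 64L))
  expect_identical(tr$variant, c("32x32", "64x64"))
})

test_that("the CLI dispatches generate-data and summary", {
  d <- tempfile("clids")
  dsga_cli(c("generate-data", "--out", d, "--size", "16", "--classes", "3",
             "--n-train", "2", "--n-val", "1", "--n-test", "1"))
  expect_true(file.exists(file.path(d, "manifest.json")))
  ds <- load_phantom_dataset(d)
  expect_length(ds$train, 2)
  sp <- phantom_spec(size = 32, seed = 3)
  data <- list(train = phantom_batch(sp, 1:2), val = NULL)
  fit <- dsga_train(tiny_train_cfg(max_steps = 1L), data)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, f)
  out <- capture.output(dsga_cli(c("summary", "--checkpoint", f)))
  expect_true(any(grepl("parameters:", out)))
  unlink(d, recursive = TRUE)
})
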