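# Training loop (SGD with the reference optimizer settings), evaluation and
# ablation drivers.
#
# One master seed fans out into independent streams for data order, weight
# initialization and augmentation, so ablation variants trained from the
# same seed see the same sample order.

#' Training configuration
#'
#' Optimizer defaults follow the reference protocol: SGD, learning rate
#' 0.01, momentum 0.9, weight decay 0.0004, batch size 24 (override
#' downwards for desk-scale runs). The defaults are echoed into every run
#' record.
#'
#' @param net a [network_config()] (default [desk_config()]).
#' @param lr learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size samples per optimization step.
#' @param epochs passes over the training set.
#' @param max_steps optional hard cap on optimization steps (overrides
#'   `epochs` when reached first).
#' @param seed master seed (fans out to data / init / augmentation streams).
#' @param augment apply random flips / right-angle rotations to training
#'   batches.
#' @param augment_prob probability that a training sample is augmented at
#'   all (default 0.5, the usual convention in this model family: half the
#'   samples pass through unchanged, which keeps short runs converging).
#' @param w_ce,w_dice loss weights.
#' @param lr_poly_power if non-`NULL`, polynomial learning-rate decay
#'   `lr * (1 - step/total)^power`; constant learning rate otherwise.
#' @return a `train_config` object.
#' @export
train_config <- function(net = desk_config(), lr = 0.01, momentum = 0.9,
                         weight_decay = 0.0004, batch_size = 24L,
                         epochs = 2L, max_steps = NULL, seed = 1L,
                         augment = TRUE, augment_prob = 0.5,
                         w_ce = 0.5, w_dice = 0.5,
                         lr_poly_power = NULL) {
  structure(list(net = net, lr = lr, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), max_steps = max_steps,
                 seed = as.integer(seed), augment = augment,
                 augment_prob = augment_prob,
                 w_ce = w_ce, w_dice = w_dice,
                 lr_poly_power = lr_poly_power),
            class = "train_config")
}

#' Order-independent configuration hash
#'
#' Fields are sorted by name recursively before hashing, so two configs
#' with the same values but different field order hash identically.
#'
#' @param cfg any list-like configuration.
#' @return character md5 digest.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x))) x <- x[order(names(x))]
    }
    x
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(canon(unclass(cfg)), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

# stack a list of phantom samples into an (H, W, C, B) node + target vector
.make_batch <- function(samples) {
  d <- dim(samples[[1]]$image)           # C x H x W
  B <- length(samples)
  xb <- array(0, c(d[2], d[3], d[1], B))
  tg <- integer(d[2] * d[3] * B)
  for (i in seq_len(B)) {
    xb[, , , i] <- aperm(samples[[i]]$image, c(2, 3, 1))
    tg[(i - 1L) * d[2] * d[3] + seq_len(d[2] * d[3])] <-
      as.vector(samples[[i]]$mask) + 1L
  }
  list(x = xb, target = tg, H = d[2], W = d[3], B = B)
}

# batched loss node from a model and a prepared batch
.batch_loss <- function(model, batch, cfg) {
  out <- .net_forward(model, ag(batch$x), training = TRUE)
  d <- dim(ag_value(out))
  lmat <- ag_reshape(ag_aperm(out, c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], d[3]))
  .seg_loss(lmat, batch$target, model$cfg$num_classes, cfg$w_ce, cfg$w_dice)
}

#' Train a DSGA-Net on phantom samples
#'
#' Runs seeded SGD, evaluates the validation mean foreground Dice after
#' every epoch (and at the final step), and returns the best-validation
#' model together with a run record.
#'
#' @param cfg a [train_config()].
#' @param data list with `train` and `val` lists of `phantom_sample` (e.g.
#'   from [load_phantom_dataset()] or [phantom_batch()]).
#' @param out_dir optional directory for the checkpoint and a JSONL run log.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best validation weights), `record` (losses,
#'   validation Dice, config hash, wall time) and `checkpoint` (path or
#'   `NULL`).
#' @export
dsga_train <- function(cfg, data, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.null(data$train) || length(data$train) == 0) {
    stop("no training data supplied")
  }
  t_start <- Sys.time()
  .with_seed(derive_seed(cfg$seed, "init"), model <- dsga_net(cfg$net))
  params <- collect_params(model)
  opt_env <- new.env(parent = emptyenv())
  n <- length(data$train)
  spe <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$epochs * spe
  if (!is.null(cfg$max_steps)) total_steps <- min(total_steps, cfg$max_steps)
  n_epochs <- ceiling(total_steps / spe)
  step_loss <- numeric(0)
  epoch_loss <- numeric(0)
  val_dsc <- numeric(0)
  best <- list(dsc = -Inf, params = NULL, states = NULL)
  hash <- config_hash(cfg)
  log_line <- function(rec) {
    if (!is.null(out_dir)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = file.path(out_dir, "run.jsonl"), append = TRUE)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_line(list(event = "config", hash = hash,
                  r_version = as.character(getRversion()),
                  lr = cfg$lr, momentum = cfg$momentum,
                  weight_decay = cfg$weight_decay,
                  batch_size = cfg$batch_size, seed = cfg$seed))
  }
  step <- 0L
  for (ep in seq_len(n_epochs)) {
    ord <- .with_seed(derive_seed(cfg$seed, paste0("order", ep)),
                      sample.int(n))
    losses <- numeric(0)
    for (b in seq_len(spe)) {
      if (step >= total_steps) break
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      samples <- data$train[idx]
      if (cfg$augment) {
        samples <- lapply(seq_along(samples), function(i) {
          sd_i <- derive_seed(cfg$seed, paste0("aug", step, "_", i))
          take <- .with_seed(sd_i, stats::runif(1)) <
            (cfg$augment_prob %||% 1)
          if (take) augment(samples[[i]], sd_i + 1L) else samples[[i]]
        })
      }
      batch <- .make_batch(samples)
      loss <- .batch_loss(model, batch, cfg)
      ag_zero_grad(params)
      ag_backward(loss)
      lr <- cfg$lr
      if (!is.null(cfg$lr_poly_power)) {
        lr <- cfg$lr * (1 - step / total_steps)^cfg$lr_poly_power
      }
      .sgd_update(params, opt_env, lr, cfg$momentum, cfg$weight_decay)
      step <- step + 1L
      losses <- c(losses, as.numeric(ag_value(loss)))
    }
    step_loss <- c(step_loss, losses)
    epoch_loss <- c(epoch_loss, mean(losses))
    vd <- NA_real_
    if (!is.null(data$val) && length(data$val)) {
      vd <- .validation_dsc(model, data$val)
      if (!is.na(vd) && vd > best$dsc) {
        best$dsc <- vd
        best$params <- lapply(params, ag_value)
        best$states <- .collect_states(model)
      }
    }
    val_dsc <- c(val_dsc, vd)
    if (verbose) {
      cat(sprintf("epoch %d/%d  loss %.4f  val DSC %.4f\n",
                  ep, n_epochs, mean(losses), vd))
    }
    log_line(list(event = "epoch", epoch = ep, loss = mean(losses),
                  val_dsc = vd))
    if (step >= total_steps) break
  }
  if (!is.null(best$params)) {
    for (nm in names(params)) params[[nm]]$value <- best$params[[nm]]
    .assign_states(model, best$states)
  }
  ckpt <- NULL
  if (!is.null(out_dir)) {
    ckpt <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(model, ckpt)
  }
  record <- list(step_loss = step_loss, epoch_loss = epoch_loss,
                 val_dsc = val_dsc, best_val_dsc = best$dsc,
                 steps = step, config_hash = hash, seed = cfg$seed,
                 wall_time = as.numeric(Sys.time() - t_start, units = "secs"))
  list(model = model, record = record, checkpoint = ckpt)
}

# momentum SGD update over named parameter nodes; buffers live in env
.sgd_update <- function(params, env, lr, momentum, weight_decay) {
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    g <- g + weight_decay * p$value
    buf <- env[[nm]]
    buf <- if (is.null(buf)) g else momentum * buf + g
    env[[nm]] <- buf
    p$value <- p$value - lr * buf
  }
  invisible(NULL)
}

# mean foreground DSC over a sample list (batched forward, eval mode)
.validation_dsc <- function(model, samples, batch_size = 8L) {
  scores <- numeric(0)
  K <- model$cfg$num_classes
  i <- 1L
  while (i <= length(samples)) {
    chunk <- samples[i:min(i + batch_size - 1L, length(samples))]
    batch <- .make_batch(chunk)
    out <- ag_value(ag_no_grad(.net_forward(model, ag(batch$x),
                                            training = FALSE)))
    for (j in seq_along(chunk)) {
      lg <- out[, , , j]
      pred <- apply(lg, c(1, 2), which.max) - 1L
      ev <- evaluate_masks(pred, chunk[[j]]$mask, K)
      scores <- c(scores, ev$mean_dsc)
    }
    i <- i + batch_size
  }
  mean(scores)
}

#' Evaluate a model or checkpoint on a sample list
#'
#' Computes per-class and mean Dice and Hausdorff (HD95 by default) for
#' every case; deterministic. Debug modes replace the prediction with the
#' ground truth (`"gt"`: all Dice 1, HD 0) or with all-background
#' (`"empty"`: foreground Dice 0) to validate the metric plumbing.
#'
#' @param model a `dsga_net` model or a checkpoint path.
#' @param samples list of `phantom_sample`.
#' @param percentile Hausdorff percentile (95 or 100).
#' @param debug_pred `"model"`, `"gt"` or `"empty"`.
#' @param out_prefix optional path prefix: writes `<prefix>.csv` (one row
#'   per case) and `<prefix>.json` (summary).
#' @return data.frame with one row per case: per-class `dsc_k` / `hd_k`
#'   columns plus `mean_dsc`, `mean_hd`.
#' @export
dsga_evaluate <- function(model, samples, percentile = 95,
                          debug_pred = c("model", "gt", "empty"),
                          out_prefix = NULL) {
  debug_pred <- match.arg(debug_pred)
  if (is.character(model)) model <- load_checkpoint(model)
  K <- model$cfg$num_classes
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    pred <- switch(debug_pred,
      model = predict(model, s$image, type = "mask"),
      gt = s$mask,
      empty = matrix(0L, nrow(s$mask), ncol(s$mask)))
    ev <- evaluate_masks(pred, s$mask, K, percentile)
    row <- c(list(case = i), as.list(stats::setNames(ev$dsc,
               paste0("dsc_", seq_len(K - 1L)))),
             as.list(stats::setNames(ev$hd, paste0("hd_", seq_len(K - 1L)))),
             list(mean_dsc = ev$mean_dsc, mean_hd = ev$mean_hd))
    as.data.frame(row)
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_prefix)) write_metrics(report, out_prefix)
  report
}

#' Run an ablation axis
#'
#' Trains one variant per grid point of the requested axis - number of MTA
#' skip connections (0..3), encoder depth preset (Base / Middle-1 /
#' Middle-2), or input resolution - with shared seed and data stream, and
#' tabulates the final validation Dice.
#'
#' @param base_cfg a [train_config()] used as template.
#' @param spec a [phantom_spec()]; data are generated per variant (re-sized
#'   for the resolution axis).
#' @param n_train,n_val split sizes.
#' @param axis `"mta_stages"`, `"depths"` or `"resolution"`.
#' @param resolutions the two input sizes for the resolution axis (default:
#'   the base size and its double).
#' @param verbose print progress.
#' @return data.frame: variant label, final validation mean DSC, steps,
#'   parameter count, wall time.
#' @export
dsga_ablate <- function(base_cfg, spec, n_train = 8L, n_val = 4L,
                        axis = c("mta_stages", "depths", "resolution"),
                        resolutions = NULL, verbose = FALSE) {
  axis <- match.arg(axis)
  variants <- switch(axis,
    mta_stages = list("0-MTA" = integer(0), "1-MTA" = 1L, "2-MTA" = 1:2,
                      "3-MTA" = 1:3),
    depths = list("Base" = "Base", "Middle-1" = "Middle-1",
                  "Middle-2" = "Middle-2"),
    resolution = {
      rs <- resolutions %||% c(base_cfg$net$input_size,
                               2L * base_cfg$net$input_size)
      stats::setNames(as.list(rs), paste0(rs, "x", rs))
    })
  rows <- lapply(names(variants), function(vn) {
    cfg <- base_cfg
    sp <- spec
    if (axis == "mta_stages") {
      cfg$net <- do.call(network_config, utils::modifyList(
        .cfg_args(cfg$net), list(mta_stages = variants[[vn]])))
    } else if (axis == "depths") {
      cfg$net <- do.call(network_config, utils::modifyList(
        .cfg_args(cfg$net), list(depths = variants[[vn]])))
    } else {
      sp$size <- as.integer(variants[[vn]])
      cfg$net <- do.call(network_config, utils::modifyList(
        .cfg_args(cfg$net), list(input_size = as.integer(variants[[vn]]))))
    }
    data <- list(train = phantom_batch(sp, seq_len(n_train)),
                 val = phantom_batch(sp, n_train + seq_len(n_val)))
    if (verbose) cat("ablation variant", vn, "\n")
    fit <- dsga_train(cfg, data)
    data.frame(variant = vn, val_dsc = fit$record$best_val_dsc,
               steps = fit$record$steps,
               n_params = attr(model_summary(fit$model), "total"),
               wall_time = fit$record$wall_time)
  })
  do.call(rbind, rows)
}

# reconstruct the argument list of a network_config (for modifyList-style
# variant construction)
.cfg_args <- function(net) {
  list(input_size = net$input_size, in_channels = net$in_channels,
       num_classes = net$num_classes,
       depths = net$depth_name %||% net$depths,
       dims = net$dims, heads = net$heads, window = net$window,
       patch_size = net$patch_size, mta_stages = net$mta_stages,
       mta_patch = net$mta_patch, decoder_dims = net$decoder_dims,
       mlp_ratio = net$mlp_ratio, upsample = net$upsample)
}
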