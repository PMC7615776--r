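# DSGA-Net assembly: 4-stage gated-attention encoder with patch merging,
# 3x3-conv bottleneck, MTA skip connections on encoder stages 1-3, and a
# cascaded upsampling decoder ending in a 1x1 segmentation head.
#
# Stage s operates at resolution input/(patch_size * 2^(s-1)) with an
# effective window size min(window, resolution); the deepest (stage-4)
# feature bypasses the MTA and enters the decoder through the bottleneck.

#' Network configuration
#'
#' @param input_size input image edge length (square input, default 224).
#' @param in_channels image channels (1 grayscale, 3 RGB).
#' @param num_classes segmentation classes including background.
#' @param depths number of DSG-ViT blocks per stage, or a preset name:
#'   `"Base"` = (1,1,3,1), `"Middle-1"` = (2,2,6,2), `"Middle-2"` = (3,3,9,3).
#' @param dims embedding width per stage.
#' @param heads attention heads per stage (`dims` divisible by `heads`).
#' @param window window size `m`; per stage the effective window is
#'   `min(window, resolution)` and must divide the stage resolution.
#' @param patch_size patch-embedding factor (stage-1 resolution =
#'   `input_size / patch_size`).
#' @param mta_stages integer subset of `1:3`: encoder stages whose features
#'   reach the decoder through an MTA skip (empty = skip-free U-shape).
#' @param mta_patch patch size of the MTA global branch.
#' @param decoder_dims decoder widths: bottleneck output, then the three
#'   decoder steps / restoration stage.
#' @param mlp_ratio feed-forward expansion in the DSG-ViT blocks.
#' @param upsample `"bilinear"` (default) or `"deconv"` (transposed
#'   convolution) for the decoder upsampling operator.
#' @return a `network_config` list.
#' @export
network_config <- function(input_size = 224L, in_channels = 1L,
                           num_classes = 9L, depths = "Middle-1",
                           dims = c(96L, 192L, 384L, 768L),
                           heads = c(3L, 6L, 12L, 24L),
                           window = 7L, patch_size = 4L,
                           mta_stages = 1:3, mta_patch = 2L,
                           decoder_dims = c(512L, 256L, 128L, 64L),
                           mlp_ratio = 4, upsample = c("bilinear", "deconv")) {
  presets <- list("Base" = c(1L, 1L, 3L, 1L),
                  "Middle-1" = c(2L, 2L, 6L, 2L),
                  "Middle-2" = c(3L, 3L, 9L, 3L))
  if (is.character(depths)) {
    if (!depths %in% names(presets)) {
      stop("unknown depth preset '", depths, "'; use one of ",
           paste(names(presets), collapse = ", "))
    }
    depth_name <- depths
    depths <- presets[[depths]]
  } else depth_name <- NULL
  upsample <- match.arg(upsample)
  stopifnot(length(depths) == 4, length(dims) == 4, length(heads) == 4,
            all(dims %% heads == 0))
  if (input_size %% (patch_size * 8L) != 0) {
    stop("input_size ", input_size, " must be divisible by patch_size * 8 = ",
         patch_size * 8L)
  }
  if (bitwAnd(patch_size, patch_size - 1L) != 0L) {
    stop("patch_size must be a power of 2, got ", patch_size)
  }
  res <- input_size %/% (patch_size * 2L^(0:3))
  eff_win <- pmin(window, res)
  for (s in 1:4) {
    if (res[s] %% eff_win[s] != 0) {
      stop("stage ", s, " resolution ", res[s],
           " is not divisible by window size ", eff_win[s])
    }
  }
  mta_stages <- sort(unique(as.integer(mta_stages)))
  stopifnot(all(mta_stages %in% 1:3))
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 depths = as.integer(depths), depth_name = depth_name,
                 dims = as.integer(dims), heads = as.integer(heads),
                 window = as.integer(window),
                 patch_size = as.integer(patch_size),
                 mta_stages = mta_stages, mta_patch = as.integer(mta_patch),
                 decoder_dims = as.integer(decoder_dims),
                 mlp_ratio = mlp_ratio, upsample = upsample,
                 stage_res = as.integer(res),
                 stage_window = as.integer(eff_win)),
            class = "network_config")
}

#' Desk-scale configuration preset
#'
#' A small network for CPU-scale experiments on 64x64 phantoms: "Base"
#' depths (1,1,3,1), stage widths (16, 32, 64, 128), heads (1, 2, 4, 8),
#' window 4, patch factor 2 and slim decoder widths. The fine patch factor
#' keeps stage 1 at half the image resolution, which small-structure
#' boundary accuracy depends on.
#'
#' @param input_size input edge length, default 64.
#' @param num_classes segmentation classes including background.
#' @param ... overrides passed on to [network_config()].
#' @export
desk_config <- function(input_size = 64L, num_classes = 5L, ...) {
  args <- list(input_size = input_size, in_channels = 1L,
               num_classes = num_classes, depths = "Base",
               dims = c(16L, 32L, 64L, 128L), heads = c(1L, 2L, 4L, 8L),
               window = 4L, patch_size = 2L,
               decoder_dims = c(64L, 32L, 32L, 32L))
  over <- list(...)
  args[names(over)] <- over
  do.call(network_config, args)
}

## ---- patch merging --------------------------------------------------------

layer_patch_merge <- function(C) {
  list(lin = layer_linear(4L * C, 2L * C), C = C)
}

.merge_out_idx <- function(H2, W2, C2, B) {
  # token rows (w, b) -> image (H2, W2, C2, B); windows row-major
  ho <- rep(seq_len(H2), times = W2 * B * C2)
  wo <- rep(rep(seq_len(W2), each = H2), times = B * C2)
  dims_after <- H2 * W2
  cc <- rep(rep(seq_len(C2), each = dims_after), times = B)
  bb <- rep(seq_len(B), each = dims_after * C2)
  w <- (ho - 1L) * W2 + wo
  nwB <- H2 * W2 * B
  (w + H2 * W2 * (bb - 1L)) + nwB * (cc - 1L)
}

# x: node H x W x C x B -> node H/2 x W/2 x 2C x B
.patch_merge_fwd <- function(l, x) {
  d <- dim(ag_value(x))
  if (d[1] %% 2L != 0 || d[2] %% 2L != 0) {
    stop("patch merge requires even spatial dimensions, got ",
         d[1], "x", d[2])
  }
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L; C <- d[3]; B <- d[4]
  wi <- .win_idx(d[1], d[2], C, B, 2L)
  tok <- ag_gather(x, wi$idx, c(4L * wi$nw * B, C), unique_idx = TRUE)
  tok <- ag_reshape(tok, c(4L, wi$nw, B, C))
  tok <- ag_reshape(ag_aperm(tok, c(2, 3, 1, 4)), c(wi$nw * B, 4L * C))
  y <- linear_fwd(l$lin, tok)                       # (nw*B) x 2C
  idx <- .merge_out_idx(H2, W2, 2L * C, B)
  ag_gather(y, idx, c(H2, W2, 2L * C, B), unique_idx = TRUE)
}

#' Patch merging downsampling
#'
#' Concatenates each 2x2 spatial neighborhood across channels (4C features)
#' and applies a learnable linear map to 2C, halving the resolution and
#' doubling the channel width.
#'
#' @param x numeric array `C x H x W` with even `H`, `W`.
#' @param weights optional `layer_patch_merge` layer to reuse.
#' @return numeric array `2C x H/2 x W/2`.
#' @export
patch_merge <- function(x, weights = NULL) {
  d <- dim(x)
  l <- weights %||% layer_patch_merge(d[1])
  xb <- ag(array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1)))
  v <- ag_value(ag_no_grad(.patch_merge_fwd(l, xb)))
  aperm(array(v[, , , 1], c(d[2] %/% 2L, d[3] %/% 2L, 2L * d[1])), c(3, 1, 2))
}

## ---- model construction ---------------------------------------------------

#' Construct a DSGA-Net model
#'
#' Builds the full encoder / MTA / decoder network with randomly initialized
#' weights according to `cfg`. Seed the R RNG beforehand for reproducible
#' initialization.
#'
#' @param cfg a [network_config()].
#' @return a `dsga_net` model object.
#' @export
dsga_net <- function(cfg) {
  dims <- cfg$dims; res <- cfg$stage_res; win <- cfg$stage_window
  stages <- vector("list", 4L)
  for (s in 1:4) {
    blocks <- lapply(seq_len(cfg$depths[s]), function(i)
      dsg_vit_block(block_config(dims[s], cfg$heads[s], win[s],
                                 input_hw = c(res[s], res[s]),
                                 mlp_ratio = cfg$mlp_ratio)))
    merge <- if (s > 1) layer_patch_merge(dims[s - 1L]) else NULL
    stages[[s]] <- list(merge = merge, blocks = blocks)
  }
  mta <- vector("list", 3L)
  for (s in cfg$mta_stages) {
    P <- min(cfg$mta_patch, res[s])
    mta[[s]] <- mta_layer(dims[s], c(res[s], res[s]), patch_size = P)
  }
  dd <- cfg$decoder_dims
  dec <- vector("list", 3L)
  for (i in 1:3) {
    skip_stage <- 4L - i
    c_skip <- if (skip_stage %in% cfg$mta_stages) dims[skip_stage] else 0L
    c_in <- dd[i] + c_skip
    dec[[i]] <- list(
      conv = layer_conv2d(c_in, dd[i + 1L], 3L, pad = 1L),
      deconv = if (cfg$upsample == "deconv") layer_deconv2d(dd[i], dd[i], 2L)
               else NULL)
  }
  model <- list(
    cfg = cfg,
    embed = layer_conv2d(cfg$in_channels, dims[1], cfg$patch_size,
                         stride = cfg$patch_size),
    stages = stages,
    mta = mta,
    bottleneck_conv = layer_conv2d(dims[4], dd[1], 3L, pad = 1L),
    dec = dec,
    # restoration H/patch -> H as a cascade of x2 upsample+conv stages, so
    # boundaries are refined at every intermediate scale
    restore = lapply(seq_len(as.integer(log2(cfg$patch_size))), function(i)
      list(conv = layer_conv2d(dd[4], dd[4], 3L, pad = 1L),
           deconv = if (cfg$upsample == "deconv")
             layer_deconv2d(dd[4], dd[4], 2L) else NULL)),
    head = layer_conv2d(dd[4], cfg$num_classes, 1L)
  )
  class(model) <- "dsga_net"
  model
}

# one encoder stage on a feature node
.stage_fwd <- function(model, s, x, aux = NULL) {
  st <- model$stages[[s]]
  if (!is.null(st$merge)) x <- .patch_merge_fwd(st$merge, x)
  d <- dim(ag_value(x))
  m <- model$cfg$stage_window[s]
  wi <- .win_idx(d[1], d[2], d[3], d[4], m)
  tok <- ag_gather(x, wi$idx, c(wi$m2 * wi$nw * d[4], d[3]), unique_idx = TRUE)
  for (blk in st$blocks) {
    tok <- .block_fwd_tokens(blk, tok, wi$nw, d[4], wi$gr, wi$gc, aux = aux)
  }
  ag_gather(tok, wi$inv, d, unique_idx = TRUE)
}

# full forward on a batched node (H, W, C, B); returns list of nodes
.net_forward <- function(model, xb, training = FALSE, aux = NULL,
                         keep_stages = FALSE) {
  cfg <- model$cfg
  x <- conv2d_fwd(model$embed, xb)
  feats <- vector("list", 4L)
  for (s in 1:4) {
    x <- .stage_fwd(model, s, x, aux = aux)
    feats[[s]] <- x
  }
  d <- .bottleneck_fwd(model, feats[[4]])
  for (i in 1:3) {
    skip_stage <- 4L - i
    skip <- NULL
    if (skip_stage %in% cfg$mta_stages) {
      skip <- .mta_fwd(model$mta[[skip_stage]], feats[[skip_stage]],
                       training = training, aux = aux)
    }
    d <- .decoder_step_fwd(model$dec[[i]], d, skip)
  }
  for (st in model$restore) {
    d <- if (!is.null(st$deconv)) deconv2d_fwd(st$deconv, d)
         else upsample_bilinear(d, 2L)
    d <- ag_relu(conv2d_fwd(st$conv, d))
  }
  logits <- conv2d_fwd(model$head, d)
  if (keep_stages) list(logits = logits, stages = feats) else logits
}

.bottleneck_fwd <- function(model, x) {
  ag_relu(conv2d_fwd(model$bottleneck_conv, x))
}

.decoder_step_fwd <- function(step, x, skip = NULL) {
  up <- if (!is.null(step$deconv)) deconv2d_fwd(step$deconv, x)
        else upsample_bilinear(x, 2L)
  if (!is.null(skip)) {
    du <- dim(ag_value(up)); ds <- dim(ag_value(skip))
    if (du[1] != ds[1] || du[2] != ds[2]) {
      stop("decoder skip mismatch: upsampled feature is ", du[1], "x", du[2],
           " but skip is ", ds[1], "x", ds[2])
    }
    up <- ag_concat(list(up, skip), axis = 3)
  }
  ag_relu(conv2d_fwd(step$conv, up))
}

## ---- user-facing operations -----------------------------------------------

.img_to_node <- function(img, in_channels) {
  d <- dim(img)
  if (length(d) == 2L) { img <- array(img, c(1, d)); d <- dim(img) }
  stopifnot(length(d) == 3L, d[1] == in_channels)
  ag(array(aperm(img, c(2, 3, 1)), c(d[2], d[3], d[1], 1)))
}

.node_to_map <- function(node) {
  v <- ag_value(node)
  d <- dim(v)
  aperm(array(v[, , , 1], d[1:3]), c(3, 1, 2))
}

#' Run the encoder and return all four stage features
#'
#' @param img numeric array `C x H x W` (or `H x W` for single-channel).
#' @param cfg a [network_config()], or an existing `dsga_net` model whose
#'   weights should be used.
#' @return list of four `C_s x H_s x W_s` arrays at resolutions `H/4` to
#'   `H/32`.
#' @export
encoder_forward <- function(img, cfg) {
  model <- if (inherits(cfg, "dsga_net")) cfg else dsga_net(cfg)
  xb <- .img_to_node(img, model$cfg$in_channels)
  feats <- ag_no_grad({
    x <- conv2d_fwd(model$embed, xb)
    out <- vector("list", 4L)
    for (s in 1:4) { x <- .stage_fwd(model, s, x); out[[s]] <- x }
    out
  })
  lapply(feats, .node_to_map)
}

#' Bottleneck transform of the deepest encoder feature
#'
#' A 3x3 convolution (padding 1, spatial size preserved) followed by ReLU,
#' mapping the stage-4 width onto the decoder's deepest width.
#'
#' @param x numeric array `C x H x W`.
#' @param weights optional conv layer to reuse (e.g. `model$bottleneck_conv`).
#' @param out_channels decoder width when constructing fresh weights.
#' @return numeric array `out_channels x H x W`.
#' @export
bottleneck <- function(x, weights = NULL, out_channels = 512L) {
  d <- dim(x)
  l <- weights %||% layer_conv2d(d[1], out_channels, 3L, pad = 1L)
  xb <- ag(array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1)))
  .node_to_map(ag_no_grad(ag_relu(conv2d_fwd(l, xb))))
}

#' One decoder step: upsample, fuse skip, convolve
#'
#' Doubles the spatial size (bilinear by default), concatenates the skip
#' feature (when provided) along channels, then applies a 3x3 convolution
#' and ReLU.
#'
#' @param x numeric array `C x H x W`.
#' @param skip optional skip feature `C_s x 2H x 2W` (e.g. an MTA output).
#' @param weights optional decoder step layer to reuse.
#' @param out_channels output width when constructing fresh weights.
#' @return numeric array `out_channels x 2H x 2W`.
#' @export
decoder_step <- function(x, skip = NULL, weights = NULL, out_channels = NULL) {
  d <- dim(x)
  c_skip <- if (is.null(skip)) 0L else dim(skip)[1]
  out_channels <- out_channels %||% max(d[1] %/% 2L, 1L)
  l <- weights %||% list(conv = layer_conv2d(d[1] + c_skip, out_channels, 3L,
                                             pad = 1L), deconv = NULL)
  xb <- ag(array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1)))
  sb <- if (!is.null(skip)) {
    ds <- dim(skip)
    ag(array(aperm(skip, c(2, 3, 1)), c(ds[2], ds[3], ds[1], 1)))
  } else NULL
  .node_to_map(ag_no_grad(.decoder_step_fwd(l, xb, sb)))
}

#' Full forward pass to segmentation logits
#'
#' Deterministic in evaluation mode: the same weights and input always give
#' bit-identical logits.
#'
#' @param model a `dsga_net` model.
#' @param img numeric array `C x H x W` matching the model's configuration.
#' @return numeric array `num_classes x H x W` of unnormalized class scores.
#' @export
net_forward <- function(model, img) {
  xb <- .img_to_node(img, model$cfg$in_channels)
  .node_to_map(ag_no_grad(.net_forward(model, xb, training = FALSE)))
}

#' Predict a label mask
#'
#' @param object a `dsga_net` model.
#' @param img numeric array `C x H x W`.
#' @param type `"mask"` (integer classes 0-based), `"logits"`, or `"prob"`.
#' @param ... unused.
#' @return `H x W` integer mask, or a `num_classes x H x W` array.
#' @export
predict.dsga_net <- function(object, img, type = c("mask", "logits", "prob"),
                             ...) {
  type <- match.arg(type)
  lg <- net_forward(object, img)
  if (type == "logits") return(lg)
  if (type == "prob") {
    e <- exp(sweep(lg, c(2, 3), apply(lg, c(2, 3), max)))
    return(sweep(e, c(2, 3), apply(e, c(2, 3), sum), `/`))
  }
  apply(lg, c(2, 3), which.max) - 1L
}

## ---- summary & checkpoints ------------------------------------------------

#' Count and list the learnable parameters of a model
#'
#' @param model any layer structure (typically a `dsga_net`).
#' @return a data.frame (name, shape, count) with attribute `total`; printed
#'   as a compact table.
#' @export
model_summary <- function(model) {
  ps <- collect_params(model)
  df <- data.frame(
    name = names(ps),
    shape = vapply(ps, function(p)
      paste(dim(p$value) %||% length(p$value), collapse = "x"), character(1)),
    count = vapply(ps, function(p) length(p$value), numeric(1)),
    row.names = NULL
  )
  attr(df, "total") <- sum(df$count)
  class(df) <- c("dsga_summary", "data.frame")
  df
}

#' @export
print.dsga_summary <- function(x, ...) {
  cat("parameters:", nrow(x), "tensors,", format(attr(x, "total"),
      big.mark = ","), "values\n")
  groups <- sub("\\..*$", "", x$name)
  agg <- tapply(x$count, groups, sum)
  for (g in names(agg)) cat(sprintf("  %-16s %12s\n", g,
                                    format(agg[[g]], big.mark = ",")))
  invisible(x)
}

# walk a model for batchnorm state environments
.collect_states <- function(x, prefix = "") {
  out <- list()
  if (is.environment(x) && !inherits(x, "ag_node") &&
      !is.null(x$running_mean)) {
    out[[prefix]] <- list(running_mean = x$running_mean,
                          running_var = x$running_var)
    return(out)
  }
  if (is.list(x) && !inherits(x, "ag_node")) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      child <- paste0(prefix, if (nzchar(prefix)) "." else "", nm)
      out <- c(out, .collect_states(x[[i]], child))
    }
  }
  out
}

.assign_states <- function(x, states, prefix = "") {
  if (is.environment(x) && !inherits(x, "ag_node") &&
      !is.null(x$running_mean)) {
    st <- states[[prefix]]
    if (!is.null(st)) {
      x$running_mean <- st$running_mean
      x$running_var <- st$running_var
    }
    return(invisible(NULL))
  }
  if (is.list(x) && !inherits(x, "ag_node")) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      child <- paste0(prefix, if (nzchar(prefix)) "." else "", nm)
      .assign_states(x[[i]], states, child)
    }
  }
  invisible(NULL)
}

#' Save / load model checkpoints
#'
#' A checkpoint bundles the configuration, all parameter values and the
#' batch-norm running statistics; loading reconstructs the model and
#' restores them, so `load_checkpoint(save_checkpoint(m, f))` evaluates
#' identically to `m`.
#'
#' @param model a `dsga_net` model.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @name checkpoints
NULL

#' @rdname checkpoints
#' @export
save_checkpoint <- function(model, path) {
  ps <- collect_params(model)
  saveRDS(list(cfg = model$cfg,
               params = lapply(ps, ag_value),
               states = .collect_states(model)), path)
  invisible(path)
}

#' @rdname checkpoints
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- dsga_net(ck$cfg)
  ps <- collect_params(model)
  if (!setequal(names(ps), names(ck$params))) {
    stop("checkpoint/config mismatch: parameter names differ")
  }
  for (nm in names(ps)) {
    tgt <- ps[[nm]]
    val <- ck$params[[nm]]
    if (length(tgt$value) != length(val)) {
      stop("checkpoint/config mismatch for parameter ", nm)
    }
    dim(val) <- dim(tgt$value) %||% NULL
    tgt$value <- val
  }
  .assign_states(model, ck$states)
  model
}
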