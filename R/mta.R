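# Mixed three-branch attention (MTA) skip module.
#
# Three parallel views of an encoder feature map X (C x H x W):
#   channel:  C(X) = sigmoid( LReLU(conv1x1(maxpool(X))) + LReLU(conv1x1(avgpool(X))) )
#   spatial:  S    = sigmoid( S_3 + S_5 + S_7 ), each branch conv(k)-BN-ReLU
#             twice (k in {3,5,7}, padding {1,2,3}, stride 1), channels C -> C/4 -> 1
#   global:   G    = one ViT block over P x P patches (MHSA + MLP, residuals)
# fused as MTA = (C (x) S) (+) G, broadcast multiply then elementwise add.
# The 1x1 channel conv is shared between the two pooling branches, so a
# per-channel-constant input yields identical branch outputs pre-sigmoid.

## ---- channel attention ----------------------------------------------------

layer_channel_attn <- function(C) {
  list(lin = layer_linear(C, C, sd = 0.02), C = C)
}

# x: node H x W x C x B -> node B x C in (0,1)
.channel_attn_fwd <- function(l, x) {
  mx <- linear_fwd(l$lin, global_max_pool(x))
  av <- linear_fwd(l$lin, global_avg_pool(x))
  ag_sigmoid(ag_add(ag_leaky_relu(mx), ag_leaky_relu(av)))
}

#' Channel attention map
#'
#' Global max- and average-pooling over the spatial axes, a shared 1x1
#' convolution (a linear map over channels), LeakyReLU on each branch,
#' elementwise sum, sigmoid.
#'
#' @param x numeric array `C x H x W`.
#' @param weights optional layer (list with `lin`) to reuse; a fresh
#'   randomly initialized layer is created otherwise.
#' @return numeric array `C x 1 x 1` with entries in (0, 1).
#' @export
channel_attention <- function(x, weights = NULL) {
  d <- dim(x)
  l <- weights %||% layer_channel_attn(d[1])
  xb <- ag(array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1)))
  v <- ag_value(ag_no_grad(.channel_attn_fwd(l, xb)))
  array(as.vector(v), c(d[1], 1, 1))
}

## ---- multi-scale spatial pyramid ------------------------------------------

layer_spatial_pyramid <- function(C) {
  mid <- max(1L, C %/% 4L)
  branch <- function(k, p) {
    list(conv_in = layer_conv2d(C, mid, k, pad = p),
         bn_in = layer_batchnorm(mid),
         conv_out = layer_conv2d(mid, 1L, k, pad = p),
         bn_out = layer_batchnorm(1L),
         k = k, p = p)
  }
  list(b3 = branch(3L, 1L), b5 = branch(5L, 2L), b7 = branch(7L, 3L), C = C)
}

.pyramid_branch_fwd <- function(br, x, training) {
  h <- ag_relu(bn_fwd(br$bn_in, conv2d_fwd(br$conv_in, x), training))
  ag_relu(bn_fwd(br$bn_out, conv2d_fwd(br$conv_out, h), training))
}

# x: node H x W x C x B -> node H x W x 1 x B in (0,1); optionally records the
# pre-sigmoid branch maps in aux
.spatial_pyramid_fwd <- function(l, x, training, aux = NULL) {
  s3 <- .pyramid_branch_fwd(l$b3, x, training)
  s5 <- .pyramid_branch_fwd(l$b5, x, training)
  s7 <- .pyramid_branch_fwd(l$b7, x, training)
  if (!is.null(aux)) {
    aux$pyramid_branches <- lapply(list(s3, s5, s7), ag_value)
  }
  ag_sigmoid(ag_add(ag_add(s3, s5), s7))
}

#' Multi-scale spatial pyramid attention map
#'
#' Three parallel two-stage convolution branches with kernel sizes 3, 5, 7
#' (paddings 1, 2, 3, stride 1, BatchNorm + ReLU after each convolution,
#' channels `C -> C/4 -> 1`), summed and squashed by a sigmoid.
#'
#' @param x numeric array `C x H x W`.
#' @param weights optional layer from an existing module; fresh random
#'   weights otherwise.
#' @param details if `TRUE`, attach the three pre-sigmoid branch maps as
#'   `attr(, "branches")`.
#' @return numeric array `1 x H x W` with entries in (0, 1).
#' @export
spatial_pyramid_attention <- function(x, weights = NULL, details = FALSE) {
  d <- dim(x)
  l <- weights %||% layer_spatial_pyramid(d[1])
  xb <- ag(array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1)))
  aux <- if (details) new.env(parent = emptyenv()) else NULL
  v <- ag_value(ag_no_grad(.spatial_pyramid_fwd(l, xb, training = FALSE,
                                                aux = aux)))
  out <- array(aperm(v[, , , 1, drop = FALSE], c(3, 1, 2, 4)), c(1, d[2], d[3]))
  if (details) {
    attr(out, "branches") <- lapply(aux$pyramid_branches, function(b)
      array(aperm(b[, , , 1, drop = FALSE], c(3, 1, 2, 4)), c(1, d[2], d[3])))
  }
  out
}

## ---- global ViT branch ----------------------------------------------------

.pick_heads <- function(dim) {
  for (h in c(4L, 2L)) if (dim %% h == 0 && dim >= 2 * h) return(h)
  1L
}

layer_global_vit <- function(C, H, W, P, heads = NULL) {
  if (H %% P != 0) stop("height ", H, " is not divisible by patch size ", P)
  if (W %% P != 0) stop("width ", W, " is not divisible by patch size ", P)
  dim <- P * P * C
  heads <- heads %||% .pick_heads(dim)
  np <- (H %/% P) * (W %/% P)
  list(
    c_loc = ag_param(matrix(init_trunc_normal(np * dim), np, dim)),
    ln_in = layer_layernorm(dim),
    Wq = ag_param(matrix(init_trunc_normal(dim * dim), dim, dim)),
    Wk = ag_param(matrix(init_trunc_normal(dim * dim), dim, dim)),
    Wv = ag_param(matrix(init_trunc_normal(dim * dim), dim, dim)),
    Wo = layer_linear(dim, dim),
    ln_mlp = layer_layernorm(dim),
    mlp1 = layer_linear(dim, dim * 2L),
    mlp2 = layer_linear(dim * 2L, dim),
    C = C, H = H, W = W, P = P, heads = heads, np = np, dim = dim
  )
}

# standard multi-head self-attention over (np, b) token rows
.mhsa <- function(l, tok, np, B, aux = NULL) {
  dim <- l$dim; heads <- l$heads; hd <- dim %/% heads
  Q <- ag_matmul(tok, l$Wq); K <- ag_matmul(tok, l$Wk); V <- ag_matmul(tok, l$Wv)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols_h <- (h - 1L) * hd + seq_len(hd)
    q3 <- ag_aperm(ag_reshape(ag_cols(Q, cols_h), c(np, B, hd)), c(1, 3, 2))
    k3 <- ag_aperm(ag_reshape(ag_cols(K, cols_h), c(np, B, hd)), c(1, 3, 2))
    v3 <- ag_aperm(ag_reshape(ag_cols(V, cols_h), c(np, B, hd)), c(1, 3, 2))
    lg <- ag_scale(ag_bmm(q3, k3, tb = TRUE), 1 / sqrt(hd))
    lm <- ag_reshape(ag_aperm(lg, c(1, 3, 2)), c(np * B, np))
    attn <- ag_softmax_rows(lm)
    if (!is.null(aux)) aux$mhsa_attn[[length(aux$mhsa_attn) + 1L]] <- ag_value(attn)
    a3 <- ag_aperm(ag_reshape(attn, c(np, B, np)), c(1, 3, 2))
    oh <- ag_bmm(a3, v3)
    outs[[h]] <- ag_reshape(ag_aperm(oh, c(1, 3, 2)), c(np * B, hd))
  }
  o <- if (heads == 1) outs[[1]] else ag_concat(outs, axis = 2)
  linear_fwd(l$Wo, o)
}

# x: node H x W x C x B -> node H x W x C x B
.global_vit_fwd <- function(l, x, aux = NULL) {
  d <- dim(ag_value(x))
  P <- l$P; np <- l$np; B <- d[4]; dimt <- l$dim
  wi <- .win_idx(d[1], d[2], d[3], B, P)
  # (P^2 * np * B x C) rows (t, patch, b)  ->  (np*B x P^2*C) rows (patch, b)
  tok <- ag_gather(x, wi$idx, c(P * P * np * B, d[3]), unique_idx = TRUE)
  tok <- ag_reshape(tok, c(P * P, np, B, d[3]))
  f <- ag_reshape(ag_aperm(tok, c(2, 3, 1, 4)), c(np * B, dimt))
  cexp <- ag_gather(l$c_loc,
                    as.vector(outer(rep(seq_len(np), times = B),
                                    (seq_len(dimt) - 1L) * np, `+`)),
                    c(np * B, dimt))
  fn <- ln_fwd(l$ln_in, ag_add(f, cexp))
  g <- ag_add(.mhsa(l, fn, np, B, aux = aux), ln_fwd(l$ln_in, f))
  g2 <- ag_add(linear_fwd(l$mlp2, ag_gelu(linear_fwd(l$mlp1,
                                                     ln_fwd(l$ln_mlp, g)))), g)
  # sequence -> image (exact inverse of the flatten above)
  back <- ag_reshape(g2, c(np, B, P * P, d[3]))
  back <- ag_reshape(ag_aperm(back, c(3, 1, 2, 4)), c(P * P * np * B, d[3]))
  ag_gather(back, wi$inv, d, unique_idx = TRUE)
}

#' Global patch self-attention map
#'
#' Splits the feature map into `P x P` patches, adds a learnable position
#' code, and applies one standard transformer block (multi-head
#' self-attention + MLP with layer norms and residuals); the token sequence
#' is then reshaped back to `C x H x W`.
#'
#' @param x numeric array `C x H x W`.
#' @param P patch size (must divide `H` and `W`).
#' @param weights optional layer to reuse.
#' @param details if `TRUE`, attach per-head attention matrices as
#'   `attr(, "attention")`.
#' @return numeric array `C x H x W`.
#' @export
global_vit_attention <- function(x, P = 2L, weights = NULL, details = FALSE) {
  d <- dim(x)
  l <- weights %||% layer_global_vit(d[1], d[2], d[3], P)
  xb <- ag(array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1)))
  aux <- if (details) { e <- new.env(parent = emptyenv()); e$mhsa_attn <- list(); e } else NULL
  v <- ag_value(ag_no_grad(.global_vit_fwd(l, xb, aux = aux)))
  out <- aperm(array(v[, , , 1], d[c(2, 3, 1)]), c(3, 1, 2))
  if (details) attr(out, "attention") <- aux$mhsa_attn
  out
}

## ---- fusion ---------------------------------------------------------------

#' Fuse the three attention branches
#'
#' `MTA = (C (x) S) (+) G`: the channel map broadcast-multiplies the spatial
#' map to a `C x H x W` field, to which the global map is added elementwise.
#'
#' @param c_map numeric array `C x 1 x 1`.
#' @param s_map numeric array `1 x H x W`.
#' @param g_map numeric array `C x H x W`.
#' @return numeric array `C x H x W`.
#' @export
mta_fuse <- function(c_map, s_map, g_map) {
  dc <- dim(c_map); ds <- dim(s_map); dg <- dim(g_map)
  if (dc[2] != 1 || dc[3] != 1 || ds[1] != 1 ||
      dg[1] != dc[1] || dg[2] != ds[2] || dg[3] != ds[3]) {
    stop("incompatible branch shapes: channel ", paste(dc, collapse = "x"),
         ", spatial ", paste(ds, collapse = "x"),
         ", global ", paste(dg, collapse = "x"))
  }
  C <- dc[1]; H <- ds[2]; W <- ds[3]
  cs <- array(as.vector(c_map), c(C, H, W)) *
    aperm(array(s_map[1, , ], c(H, W, C)), c(3, 1, 2))
  cs + g_map
}

## ---- full module ----------------------------------------------------------

#' Construct a mixed three-branch attention module
#'
#' @param channels feature channels `C`.
#' @param input_hw spatial size `c(H, W)` of the stage feature map.
#' @param patch_size patch size of the global branch (must divide `H`, `W`).
#' @param heads heads of the global branch (default: largest of 4, 2, 1 that
#'   divides the patch-token width).
#' @return an `mta_layer` object.
#' @export
mta_layer <- function(channels, input_hw, patch_size = 2L, heads = NULL) {
  l <- list(
    ca = layer_channel_attn(channels),
    sp = layer_spatial_pyramid(channels),
    gv = layer_global_vit(channels, input_hw[1], input_hw[2], patch_size,
                          heads = heads),
    channels = channels, input_hw = input_hw, patch_size = patch_size
  )
  class(l) <- "mta_layer"
  l
}

# node path used by the network: x node (H,W,C,B) -> node (H,W,C,B)
.mta_fwd <- function(l, x, training, aux = NULL) {
  d <- dim(ag_value(x))
  cm <- .channel_attn_fwd(l$ca, x)                       # B x C
  sm <- .spatial_pyramid_fwd(l$sp, x, training, aux)     # H x W x 1 x B
  gm <- .global_vit_fwd(l$gv, x, aux)                    # H x W x C x B
  if (!is.null(aux)) {
    aux$channel_map <- ag_value(cm)
    aux$spatial_map <- ag_value(sm)
  }
  cs <- ag_mul(expand_channel_map(cm, d[1], d[2]), expand_spatial_map(sm, d[3]))
  ag_add(cs, gm)
}

#' Apply a mixed three-branch attention module
#'
#' @param l an [mta_layer()].
#' @param x numeric array `C x H x W`.
#' @param details if `TRUE`, attach the channel/spatial maps and the global
#'   branch attention matrices as attributes.
#' @return numeric array `C x H x W` (same shape as the input).
#' @export
mta_forward <- function(l, x, details = FALSE) {
  d <- dim(x)
  stopifnot(d[1] == l$channels)
  xb <- ag(array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1)))
  aux <- if (details) {
    e <- new.env(parent = emptyenv()); e$mhsa_attn <- list(); e
  } else NULL
  v <- ag_value(ag_no_grad(.mta_fwd(l, xb, training = FALSE, aux = aux)))
  out <- aperm(array(v[, , , 1], d[c(2, 3, 1)]), c(3, 1, 2))
  if (details) {
    attr(out, "channel_map") <- array(as.vector(aux$channel_map), c(d[1], 1, 1))
    attr(out, "spatial_map") <- array(aperm(aux$spatial_map[, , , 1, drop = FALSE],
                                            c(3, 1, 2, 4)), c(1, d[2], d[3]))
    attr(out, "branches") <- aux$pyramid_branches
    attr(out, "attention") <- aux$mhsa_attn
  }
  out
}
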