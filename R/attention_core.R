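# Depth-separable gated window attention.
#
# DWGA computes self-attention inside each non-overlapping m x m window with
# learnable relative-position terms on query, key and value, each weighted by
# a learnable scalar gate per head:
#
#   D_o = sum_p softmax_p[ (q_o.k_p + G_Q q_o.r^q_{p-o} + G_K k_p.r^k_{p-o})
#                           / sqrt(d_h) ] * (G_V1 v_p + G_V2 r^v_{p-o})
#
# PWGA then attends ACROSS windows: queries/keys come from GELU(LN(window
# tokens)) with their own gated grid-offset position terms, while the values
# are the (untransformed) per-window feature maps, so cross-window mixing is
# a convex recombination of whole windows. Setting G_Q = G_K = G_V2 = 0 and
# G_V1 = 1 recovers plain windowed attention - the testable degenerate limit.

## ---- index helpers --------------------------------------------------------

# relative-position index I[o, p] in 1..(2m-1)^2 for row-major window positions
.relpos_index <- function(m) {
  o <- seq_len(m * m)
  or <- (o - 1L) %/% m + 1L; oc <- (o - 1L) %% m + 1L
  dr <- outer(or, or, function(a, b) b - a)  # pr - or, rows o cols p
  dc <- outer(oc, oc, function(a, b) b - a)
  (dr + m - 1L) * (2L * m - 1L) + (dc + m - 1L) + 1L
}

# same over a gr x gc window grid, index range (2gr-1)*(2gc-1)
.relpos_index_grid <- function(gr, gc) {
  w <- seq_len(gr * gc)
  wr <- (w - 1L) %/% gc + 1L; wc <- (w - 1L) %% gc + 1L
  dr <- outer(wr, wr, function(a, b) b - a)
  dc <- outer(wc, wc, function(a, b) b - a)
  (dr + gr - 1L) * (2L * gc - 1L) + (dc + gc - 1L) + 1L
}

.win_cache <- new.env(parent = emptyenv())

# gather index mapping image (H,W,C,B) -> token matrix (m^2*nw*B x C) with
# rows ordered (token-in-window row-major, window row-major, batch), plus the
# inverse permutation for merging back
.win_idx <- function(H, W, C, B, m) {
  key <- paste(H, W, C, B, m, sep = "_")
  cached <- .win_cache[[key]]
  if (!is.null(cached)) return(cached)
  m2 <- m * m; gr <- H %/% m; gc <- W %/% m; nw <- gr * gc
  tv <- rep(seq_len(m2), times = nw * B)
  wv <- rep(rep(seq_len(nw), each = m2), times = B)
  bv <- rep(seq_len(B), each = m2 * nw)
  tr <- (tv - 1L) %/% m + 1L; tc <- (tv - 1L) %% m + 1L
  wr <- (wv - 1L) %/% gc + 1L; wc <- (wv - 1L) %% gc + 1L
  r_img <- (wr - 1L) * m + tr
  c_img <- (wc - 1L) * m + tc
  base <- r_img + H * (c_img - 1L) + H * W * C * (bv - 1L)
  idx <- as.vector(outer(base, (seq_len(C) - 1L) * H * W, `+`))
  inv <- integer(length(idx))
  inv[idx] <- seq_along(idx)
  res <- list(idx = idx, inv = inv, nw = nw, m2 = m2, gr = gr, gc = gc)
  if (length(idx) <= 2^24) .win_cache[[key]] <- res
  res
}

.check_divisible <- function(H, W, m) {
  if (H %% m != 0) {
    stop("height ", H, " is not divisible by window size ", m)
  }
  if (W %% m != 0) {
    stop("width ", W, " is not divisible by window size ", m)
  }
}

## ---- user-facing window partition -----------------------------------------

#' Partition a feature map into non-overlapping windows
#'
#' Splits a `C x H x W` feature map into `m x m` windows. Token order is
#' row-major within each window, and windows are enumerated row-major across
#' the window grid, so [merge_windows()] is the exact inverse.
#'
#' @param x numeric array `C x H x W`.
#' @param m window size in pixels; must divide both `H` and `W`.
#' @return an object of class `windowed_features`: list with `tokens`
#'   (`num_windows x m^2 x C`), `window_size`, `grid` (rows, cols of the
#'   window grid), `channels`, `height`, `width`, and `origins` (the top-left
#'   pixel of each window).
#' @export
partition_windows <- function(x, m) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  C <- d[1]; H <- d[2]; W <- d[3]
  .check_divisible(H, W, m)
  gr <- H %/% m; gc <- W %/% m; nw <- gr * gc; m2 <- m * m
  tokens <- array(0, c(nw, m2, C))
  for (w in seq_len(nw)) {
    wr <- (w - 1L) %/% gc + 1L; wc <- (w - 1L) %% gc + 1L
    for (t in seq_len(m2)) {
      tr <- (t - 1L) %/% m + 1L; tc <- (t - 1L) %% m + 1L
      tokens[w, t, ] <- x[, (wr - 1L) * m + tr, (wc - 1L) * m + tc]
    }
  }
  origins <- cbind(row = ((seq_len(nw) - 1L) %/% gc) * m + 1L,
                   col = ((seq_len(nw) - 1L) %% gc) * m + 1L)
  structure(list(tokens = tokens, window_size = m, grid = c(gr, gc),
                 channels = C, height = H, width = W, origins = origins),
            class = "windowed_features")
}

#' Reassemble windows into the parent feature map
#'
#' Exact inverse of [partition_windows()] (bit-exact round trip).
#'
#' @param win a `windowed_features` object.
#' @return numeric array `C x H x W`.
#' @export
merge_windows <- function(win) {
  m <- win$window_size; gc <- win$grid[2]
  x <- array(0, c(win$channels, win$height, win$width))
  nw <- dim(win$tokens)[1]; m2 <- m * m
  for (w in seq_len(nw)) {
    wr <- (w - 1L) %/% gc + 1L; wc <- (w - 1L) %% gc + 1L
    for (t in seq_len(m2)) {
      tr <- (t - 1L) %/% m + 1L; tc <- (t - 1L) %% m + 1L
      x[, (wr - 1L) * m + tr, (wc - 1L) * m + tc] <- win$tokens[w, t, ]
    }
  }
  x
}

#' Reference attention computed by explicit loops
#'
#' Standard scaled dot-product attention `out_o = sum_p softmax_p(q_o.k_p /
#' sqrt(d)) v_p`, computed token by token with no vectorized shortcuts.
#' Serves as the independent oracle for the production attention paths in the
#' test suite.
#'
#' @param q,k,v numeric matrices `n_tokens x head_dim` (`v` may have a
#'   different number of columns).
#' @return matrix with the shape of `v`.
#' @export
brute_force_attention <- function(q, k, v) {
  if (!all(dim(q) == dim(k)) || nrow(k) != nrow(v)) {
    stop("q, k, v must share the token count and q/k the head_dim")
  }
  n <- nrow(q); d <- ncol(q)
  out <- matrix(0, n, ncol(v))
  for (o in seq_len(n)) {
    logits <- numeric(n)
    for (p in seq_len(n)) {
      s <- 0
      for (j in seq_len(d)) s <- s + q[o, j] * k[p, j]
      logits[p] <- s / sqrt(d)
    }
    mx <- max(logits)
    w <- exp(logits - mx)
    w <- w / sum(w)
    for (p in seq_len(n)) {
      out[o, ] <- out[o, ] + w[p] * v[p, ]
    }
  }
  out
}

#' Summarize each window into a single token
#'
#' @param win a `windowed_features` object.
#' @param mode `"mean"` (default; per-window token average) or `"zeros"`.
#' @return matrix `num_windows x C`.
#' @export
make_window_tokens <- function(win, mode = c("mean", "zeros")) {
  mode <- match.arg(mode)
  d <- dim(win$tokens)
  if (mode == "zeros") return(matrix(0, d[1], d[3]))
  t(apply(win$tokens, 1, colMeans))
}

## ---- weight containers ----------------------------------------------------

#' Weight containers for the gated attention operators
#'
#' `projection_weights()` draws the query/key/value maps, `rel_pos_tables()`
#' the learnable relative-position embeddings (one `(2m-1)^2 x head_dim`
#' table per head for r^q, r^k, r^v), and `gate_set()` the four per-head
#' scalar gates (initialized to 1 so position terms start active).
#'
#' @param dim embedding width.
#' @param heads number of attention heads (`dim` must be divisible).
#' @param m window size (or, for the cross-window grid tables, pass
#'   `n_offsets` directly).
#' @param head_dim per-head width.
#' @param n_offsets number of distinct relative offsets; defaults to
#'   `(2m-1)^2`.
#' @param init gate initialization value.
#' @name attention-weights
NULL

#' @rdname attention-weights
#' @export
projection_weights <- function(dim, heads = 1) {
  stopifnot(dim %% heads == 0)
  list(Wq = matrix(init_trunc_normal(dim * dim), dim, dim),
       Wk = matrix(init_trunc_normal(dim * dim), dim, dim),
       Wv = matrix(init_trunc_normal(dim * dim), dim, dim))
}

#' @rdname attention-weights
#' @export
rel_pos_tables <- function(m, head_dim, heads = 1, n_offsets = NULL) {
  R <- if (is.null(n_offsets)) (2 * m - 1)^2 else n_offsets
  tab <- function() array(init_trunc_normal(R * head_dim * heads),
                          c(R, head_dim, heads))
  list(rq = tab(), rk = tab(), rv = tab())
}

#' @rdname attention-weights
#' @export
gate_set <- function(heads = 1, init = 1) {
  list(g_q = rep(init, heads), g_k = rep(init, heads),
       g_v1 = rep(init, heads), g_v2 = rep(init, heads))
}

## ---- DWGA core ------------------------------------------------------------

# slice head h from a (R, hd, heads) parameter as a (R x hd) node
.head_slice <- function(tab, h, R, hd) {
  off <- (h - 1L) * R * hd
  ag_gather(tab, off + seq_len(R * hd), c(R, hd), unique_idx = TRUE)
}

.gate_at <- function(g, h) ag_gather(g, h, 1L, unique_idx = TRUE)

# tok: node (T x dim), rows ordered (t, w, b). All weight args are nodes.
# all gather/scatter index vectors here are duplicate-free: distinct (query,
# window) rows always pair with distinct relative offsets across keys
.attn_idx_cache <- new.env(parent = emptyenv())

.dwga_idx <- function(m, nw, B) {
  key <- paste("d", m, nw, B, sep = "_")
  cached <- .attn_idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  m2 <- m * m; WB <- nw * B; T_ <- m2 * WB
  Imat <- .relpos_index(m)
  oo <- rep(seq_len(m2), times = m2 * WB)
  pp <- rep(rep(seq_len(m2), each = m2), times = WB)
  wb <- rep(seq_len(WB), each = m2 * m2)
  Iv <- Imat[cbind(oo, pp)]
  idx_q <- (oo + m2 * (wb - 1L)) + (Iv - 1L) * T_
  idx_k <- (pp + m2 * (wb - 1L)) + (Iv - 1L) * T_
  oo2 <- rep(seq_len(m2), times = WB * m2)
  wb2 <- rep(rep(seq_len(WB), each = m2), times = m2)
  pp2 <- rep(seq_len(m2), each = m2 * WB)
  idx_sc <- (oo2 + m2 * (wb2 - 1L)) + (Imat[cbind(oo2, pp2)] - 1L) * T_
  res <- list(idx_q = idx_q, idx_k = idx_k, idx_sc = idx_sc)
  if (length(idx_q) <= 2^24) .attn_idx_cache[[key]] <- res
  res
}

.pwga_idx <- function(nw, B, gr, gc) {
  key <- paste("p", nw, B, gr, gc, sep = "_")
  cached <- .attn_idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  nwB <- nw * B
  Ig <- .relpos_index_grid(gr, gc)
  oo <- rep(seq_len(nw), times = nw * B)
  pp <- rep(rep(seq_len(nw), each = nw), times = B)
  bb <- rep(seq_len(B), each = nw * nw)
  Iv <- Ig[cbind(oo, pp)]
  res <- list(idx_q = (oo + nw * (bb - 1L)) + (Iv - 1L) * nwB,
              idx_k = (pp + nw * (bb - 1L)) + (Iv - 1L) * nwB)
  if (length(res$idx_q) <= 2^24) .attn_idx_cache[[key]] <- res
  res
}

.dwga_core <- function(tok, m, nw, B, Wq, Wk, Wv, rq, rk, rv,
                       gq, gk, gv1, gv2, heads, aux = NULL) {
  dimn <- ncol(ag_value(tok))
  hd <- dimn %/% heads
  m2 <- m * m; WB <- nw * B; T_ <- m2 * WB; R <- (2L * m - 1L)^2
  ix <- .dwga_idx(m, nw, B)
  idx_q <- ix$idx_q; idx_k <- ix$idx_k; idx_sc <- ix$idx_sc
  Q <- ag_matmul(tok, Wq); K <- ag_matmul(tok, Wk); V <- ag_matmul(tok, Wv)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols_h <- (h - 1L) * hd + seq_len(hd)
    q <- ag_cols(Q, cols_h); k <- ag_cols(K, cols_h); v <- ag_cols(V, cols_h)
    q3 <- ag_aperm(ag_reshape(q, c(m2, WB, hd)), c(1, 3, 2))
    k3 <- ag_aperm(ag_reshape(k, c(m2, WB, hd)), c(1, 3, 2))
    v3 <- ag_aperm(ag_reshape(v, c(m2, WB, hd)), c(1, 3, 2))
    qk <- ag_bmm(q3, k3, tb = TRUE)                    # (o, p, wb)
    rq_h <- .head_slice(rq, h, R, hd)
    rk_h <- .head_slice(rk, h, R, hd)
    rv_h <- .head_slice(rv, h, R, hd)
    Aq <- ag_matmul(q, ag_aperm(rq_h, c(2, 1)))        # T x R
    Ak <- ag_matmul(k, ag_aperm(rk_h, c(2, 1)))
    term_q <- ag_gather(Aq, idx_q, c(m2, m2, WB), unique_idx = TRUE)
    term_k <- ag_gather(Ak, idx_k, c(m2, m2, WB), unique_idx = TRUE)
    logits <- ag_add(qk, ag_add(ag_mul_scalar(term_q, .gate_at(gq, h)),
                                ag_mul_scalar(term_k, .gate_at(gk, h))))
    logits <- ag_scale(logits, 1 / sqrt(hd))
    lm <- ag_reshape(ag_aperm(logits, c(1, 3, 2)), c(T_, m2))
    attn <- ag_softmax_rows(lm)                        # rows (o, wb), cols p
    if (!is.null(aux)) aux$dwga_attn[[length(aux$dwga_attn) + 1L]] <- ag_value(attn)
    attn3 <- ag_aperm(ag_reshape(attn, c(m2, WB, m2)), c(1, 3, 2))
    out1 <- ag_bmm(attn3, v3)                          # (o, hd, wb)
    out1 <- ag_reshape(ag_aperm(out1, c(1, 3, 2)), c(T_, hd))
    Msc <- ag_scatter(attn, idx_sc, T_ * R, dims = c(T_, R),
                      unique_idx = TRUE)
    out2 <- ag_matmul(Msc, rv_h)
    outs[[h]] <- ag_add(ag_mul_scalar(out1, .gate_at(gv1, h)),
                        ag_mul_scalar(out2, .gate_at(gv2, h)))
  }
  if (heads == 1) outs[[1]] else ag_concat(outs, axis = 2)
}

## ---- PWGA core ------------------------------------------------------------

# mean window tokens from a (T x dim) token node; rows of result are (w, b)
.window_token_means <- function(tok, m2, nw, B) {
  dimn <- ncol(ag_value(tok))
  m <- ag_reshape(tok, c(m2, nw * B * dimn))
  ag_reshape(ag_colmeans(m), c(nw * B, dimn))
}

# tok: node (T x dim) = DWGA output; wt: node (nw*B x dim) window tokens.
.pwga_core <- function(tok, wt, m, nw, B, gr, gc, ln, Wq, Wk,
                       rqg, rkg, gq, gk, heads, aux = NULL) {
  dimn <- ncol(ag_value(tok))
  hd <- dimn %/% heads
  m2 <- m * m; nwB <- nw * B
  Rg <- (2L * gr - 1L) * (2L * gc - 1L)
  ix <- .pwga_idx(nw, B, gr, gc)
  idx_q <- ix$idx_q; idx_k <- ix$idx_k
  tq <- ag_gelu(ag_layernorm(wt, ln$gamma, ln$beta))
  Q <- ag_matmul(tq, Wq); K <- ag_matmul(tq, Wk)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols_h <- (h - 1L) * hd + seq_len(hd)
    q <- ag_cols(Q, cols_h); k <- ag_cols(K, cols_h)
    q3 <- ag_aperm(ag_reshape(q, c(nw, B, hd)), c(1, 3, 2))
    k3 <- ag_aperm(ag_reshape(k, c(nw, B, hd)), c(1, 3, 2))
    qk <- ag_bmm(q3, k3, tb = TRUE)                    # (w_o, w_p, b)
    rq_h <- .head_slice(rqg, h, Rg, hd)
    rk_h <- .head_slice(rkg, h, Rg, hd)
    term_q <- ag_gather(ag_matmul(q, ag_aperm(rq_h, c(2, 1))), idx_q,
                        c(nw, nw, B), unique_idx = TRUE)
    term_k <- ag_gather(ag_matmul(k, ag_aperm(rk_h, c(2, 1))), idx_k,
                        c(nw, nw, B), unique_idx = TRUE)
    logits <- ag_add(qk, ag_add(ag_mul_scalar(term_q, .gate_at(gq, h)),
                                ag_mul_scalar(term_k, .gate_at(gk, h))))
    logits <- ag_scale(logits, 1 / sqrt(hd))
    lm <- ag_reshape(ag_aperm(logits, c(1, 3, 2)), c(nwB, nw))
    attn <- ag_softmax_rows(lm)                        # rows (w_o, b)
    if (!is.null(aux)) aux$pwga_attn[[length(aux$pwga_attn) + 1L]] <- ag_value(attn)
    attn3 <- ag_aperm(ag_reshape(attn, c(nw, B, nw)), c(1, 3, 2))
    # values: untransformed window feature maps (head slice of the tokens)
    vtok <- ag_cols(tok, cols_h)
    vz <- ag_reshape(vtok, c(m2, nw, B, hd))
    vz <- ag_reshape(ag_aperm(vz, c(2, 1, 4, 3)), c(nw, m2 * hd, B))
    ob <- ag_bmm(attn3, vz)                            # (w_o, m2*hd, b)
    ob <- ag_reshape(ob, c(nw, m2, hd, B))
    ob <- ag_reshape(ag_aperm(ob, c(2, 1, 4, 3)), c(m2 * nw * B, hd))
    outs[[h]] <- ob
  }
  if (heads == 1) outs[[1]] else ag_concat(outs, axis = 2)
}

## ---- user-facing operator wrappers ----------------------------------------

# convert windowed_features tokens (nw, m2, C) -> internal (T x C) matrix
.win_to_mat <- function(win) {
  d <- dim(win$tokens)
  matrix(aperm(win$tokens, c(2, 1, 3)), d[1] * d[2], d[3])
}

.mat_to_win <- function(mat, win) {
  d <- dim(win$tokens)
  win$tokens <- aperm(array(mat, c(d[2], d[1], d[3])), c(2, 1, 3))
  win
}

#' Depthwise gated window self-attention (single map, explicit weights)
#'
#' Applies DWGA to a partitioned feature map with explicitly supplied
#' weights, independently inside every window. Multi-head when the
#' relative-position tables carry a third dimension > 1.
#'
#' @param win a `windowed_features` object from [partition_windows()].
#' @param w list with `Wq`, `Wk`, `Wv` (`dim x dim` matrices), e.g. from
#'   [projection_weights()].
#' @param rp list with `rq`, `rk`, `rv` relative-position tables
#'   (`(2m-1)^2 x head_dim x heads`), e.g. from [rel_pos_tables()].
#' @param g list with gate vectors `g_q`, `g_k`, `g_v1`, `g_v2` (length
#'   `heads`), e.g. from [gate_set()].
#' @return a `windowed_features` object of the same shape, with the per-head
#'   attention matrices (rows: query position within window stacked over
#'   windows; columns: key position) in `attr(, "attention")`.
#' @export
dwga <- function(win, w, rp, g) {
  heads <- dim(rp$rq)[3]
  aux <- new.env(parent = emptyenv()); aux$dwga_attn <- list()
  out <- ag_no_grad(
    .dwga_core(ag(.win_to_mat(win)), win$window_size, dim(win$tokens)[1], 1L,
               ag(w$Wq), ag(w$Wk), ag(w$Wv),
               ag(rp$rq), ag(rp$rk), ag(rp$rv),
               ag(g$g_q), ag(g$g_k), ag(g$g_v1), ag(g$g_v2),
               heads, aux = aux))
  res <- .mat_to_win(ag_value(out), win)
  attr(res, "attention") <- aux$dwga_attn
  res
}

#' Pointwise gated cross-window attention (single map, explicit weights)
#'
#' Window tokens are layer-normalized, passed through GELU, and projected to
#' queries and keys with gated grid-offset position terms; the values are the
#' untransformed per-window feature maps, and attention mixes whole windows.
#'
#' @param z a `windowed_features` object (normally the DWGA output).
#' @param wt window tokens, matrix `num_windows x dim` (see
#'   [make_window_tokens()]).
#' @param w list with `Wq`, `Wk` (`dim x dim`) and `ln_gamma`, `ln_beta`
#'   (length `dim`) for the token normalization.
#' @param rp list with `rq`, `rk` grid-offset tables
#'   (`(2gr-1)(2gc-1) x head_dim x heads`).
#' @param g list with gate vectors `g_q`, `g_k`.
#' @return the reassembled feature map, numeric array `C x H x W`, with
#'   per-head cross-window attention matrices in `attr(, "attention")`.
#' @export
pwga <- function(z, wt, w, rp, g) {
  nw <- dim(z$tokens)[1]
  if (nrow(wt) != nw) {
    stop("window count mismatch: features have ", nw, " windows but ",
         nrow(wt), " window tokens were supplied")
  }
  heads <- dim(rp$rq)[3]
  ln <- list(gamma = ag(w$ln_gamma %||% rep(1, ncol(wt))),
             beta = ag(w$ln_beta %||% numeric(ncol(wt))))
  aux <- new.env(parent = emptyenv()); aux$pwga_attn <- list()
  out <- ag_no_grad(
    .pwga_core(ag(.win_to_mat(z)), ag(wt), z$window_size, nw, 1L,
               z$grid[1], z$grid[2], ln, ag(w$Wq), ag(w$Wk),
               ag(rp$rq), ag(rp$rk), ag(g$g_q), ag(g$g_k),
               heads, aux = aux))
  res <- merge_windows(.mat_to_win(ag_value(out), z))
  attr(res, "attention") <- aux$pwga_attn
  res
}

## ---- DSG-ViT block --------------------------------------------------------

#' Configuration of one DSG-ViT block
#'
#' @param dim embedding width (divisible by `heads`).
#' @param heads attention heads.
#' @param window_size window edge length `m`.
#' @param input_hw spatial size `c(H, W)` the block will operate on (fixes
#'   the cross-window grid for the PWGA position tables).
#' @param mlp_ratio expansion factor of the feed-forward layer.
#' @param drop dropout rate (0 disables; kept for configurability).
#' @export
block_config <- function(dim, heads, window_size, input_hw,
                         mlp_ratio = 4, drop = 0) {
  stopifnot(dim %% heads == 0, window_size >= 1)
  list(dim = dim, heads = heads, window_size = window_size,
       input_hw = input_hw, mlp_ratio = mlp_ratio, drop = drop)
}

#' Construct a DSG-ViT block
#'
#' One transformer block: `y = x + W_o . DSG_Attn(LN(x))`;
#' `out = y + MLP(LN(y))`, where DSG_Attn is DWGA followed by PWGA over mean
#' window tokens. With the output projection and the MLP output weights
#' zeroed, the block is the identity map.
#'
#' @param cfg a [block_config()].
#' @return a block object (list of layers / parameter nodes).
#' @export
dsg_vit_block <- function(cfg) {
  dim <- cfg$dim; heads <- cfg$heads; m <- cfg$window_size
  hd <- dim %/% heads
  H <- cfg$input_hw[1]; W <- cfg$input_hw[2]
  .check_divisible(H, W, m)
  gr <- H %/% m; gc <- W %/% m
  R <- (2L * m - 1L)^2
  Rg <- (2L * gr - 1L) * (2L * gc - 1L)
  tab <- function(R) ag_param(array(init_trunc_normal(R * hd * heads),
                                    c(R, hd, heads)))
  blk <- list(
    cfg = cfg,
    ln1 = layer_layernorm(dim),
    Wq = ag_param(matrix(init_trunc_normal(dim * dim), dim, dim)),
    Wk = ag_param(matrix(init_trunc_normal(dim * dim), dim, dim)),
    Wv = ag_param(matrix(init_trunc_normal(dim * dim), dim, dim)),
    rq = tab(R), rk = tab(R), rv = tab(R),
    g_q = ag_param(rep(1, heads)), g_k = ag_param(rep(1, heads)),
    g_v1 = ag_param(rep(1, heads)), g_v2 = ag_param(rep(1, heads))
  )
  # with a single window, cross-window attention is the identity (one
  # softmax weight of 1), so PWGA and its parameters are elided
  if (gr * gc > 1L) {
    blk <- c(blk, list(
      ln_wt = layer_layernorm(dim),
      pWq = ag_param(matrix(init_trunc_normal(dim * dim), dim, dim)),
      pWk = ag_param(matrix(init_trunc_normal(dim * dim), dim, dim)),
      prq = tab(Rg), prk = tab(Rg),
      pg_q = ag_param(rep(1, heads)), pg_k = ag_param(rep(1, heads))
    ))
  }
  blk <- c(blk, list(
    proj = layer_linear(dim, dim),
    ln2 = layer_layernorm(dim),
    mlp1 = layer_linear(dim, dim * cfg$mlp_ratio),
    mlp2 = layer_linear(dim * cfg$mlp_ratio, dim)
  ))
  class(blk) <- "dsg_vit_block"
  blk
}

# token-space forward: tok node (T x dim), rows (t, w, b)
.block_fwd_tokens <- function(blk, tok, nw, B, gr, gc, aux = NULL) {
  m <- blk$cfg$window_size
  m2 <- m * m
  z <- ln_fwd(blk$ln1, tok)
  a <- .dwga_core(z, m, nw, B, blk$Wq, blk$Wk, blk$Wv,
                  blk$rq, blk$rk, blk$rv,
                  blk$g_q, blk$g_k, blk$g_v1, blk$g_v2,
                  blk$cfg$heads, aux = aux)
  if (!is.null(blk$pWq)) {
    wt <- .window_token_means(a, m2, nw, B)
    a <- .pwga_core(a, wt, m, nw, B, gr, gc, blk$ln_wt, blk$pWq, blk$pWk,
                    blk$prq, blk$prk, blk$pg_q, blk$pg_k,
                    blk$cfg$heads, aux = aux)
  }
  y <- ag_add(tok, linear_fwd(blk$proj, a))
  ag_add(y, linear_fwd(blk$mlp2, ag_gelu(linear_fwd(blk$mlp1,
                                                    ln_fwd(blk$ln2, y)))))
}

#' Apply a DSG-ViT block to a feature map
#'
#' @param blk a block from [dsg_vit_block()].
#' @param x numeric array `C x H x W` (or an `ag_node` holding `H x W x C x B`
#'   for internal batched use).
#' @param aux optional environment collecting attention matrices.
#' @return array (or node) with the same shape as the input.
#' @export
dsg_block_forward <- function(blk, x, aux = NULL) {
  m <- blk$cfg$window_size
  plain <- !inherits(x, "ag_node")
  if (plain) {
    d <- dim(x)  # C x H x W
    xb <- ag(array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1)))
  } else xb <- x
  db <- dim(ag_value(xb))
  .check_divisible(db[1], db[2], m)
  wi <- .win_idx(db[1], db[2], db[3], db[4], m)
  run <- function() {
    tok <- ag_gather(xb, wi$idx, c(wi$m2 * wi$nw * db[4], db[3]), unique_idx = TRUE)
    out <- .block_fwd_tokens(blk, tok, wi$nw, db[4], wi$gr, wi$gc, aux = aux)
    ag_gather(out, wi$inv, db, unique_idx = TRUE)
  }
  img <- if (plain) ag_no_grad(run()) else run()
  if (plain) {
    v <- ag_value(img)
    aperm(array(v[, , , 1], db[1:3]), c(3, 1, 2))
  } else img
}
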