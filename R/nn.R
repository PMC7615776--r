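# Layer building blocks on top of the autodiff engine.
#
# Feature maps are arrays `H x W x C x B` internally (column-major friendly);
# token matrices are `N x d`. Layers are plain lists holding parameter nodes
# plus whatever precomputed constants they need; `collect_params()` walks any
# nested structure and returns the flat named parameter list used by the
# optimizer, summaries and checkpoints.

## ---- initializers ---------------------------------------------------------

#' Truncated-normal initializer
#'
#' Samples from N(0, sd^2) truncated to two standard deviations, the usual
#' initialization for transformer projections and relative-position tables.
#'
#' @param n number of draws.
#' @param sd standard deviation before truncation.
#' @export
init_trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(lo + stats::runif(n) * (hi - lo)) * sd
}

init_kaiming <- function(fan_in, n) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

## ---- parameter plumbing ---------------------------------------------------

#' Collect parameter nodes from a nested module structure
#'
#' @param x a layer list (possibly nested); parameter nodes are recognized by
#'   their `is_param` flag.
#' @param prefix name prefix for the returned flat list.
#' @return named list of `ag_node` parameters.
#' @export
collect_params <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "ag_node")) {
    if (isTRUE(x$is_param)) out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      child <- paste0(prefix, if (nzchar(prefix)) "." else "", nm)
      out <- c(out, collect_params(x[[i]], child))
    }
  }
  out
}

#' Stochastic gradient descent with momentum and weight decay
#'
#' Creates an optimizer closure over a parameter list. The update follows the
#' standard convention: `g <- grad + weight_decay * value`,
#' `buf <- momentum * buf + g`, `value <- value - lr * buf`.
#'
#' @param params named list of parameter nodes (from [collect_params()]).
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 coefficient applied to all parameters.
#' @return list with `step()` and `zero_grad()` functions.
#' @export
sgd_optimizer <- function(params, lr = 0.01, momentum = 0.9,
                          weight_decay = 0.0004) {
  buf <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  list(
    step = function() {
      for (i in seq_along(params)) {
        p <- params[[i]]
        g <- p$grad
        if (is.null(g)) next
        g <- g + weight_decay * p$value
        buf[[i]] <<- momentum * buf[[i]] + g
        p$value <- p$value - lr * buf[[i]]
      }
      invisible(NULL)
    },
    zero_grad = function() ag_zero_grad(params)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- dense / norm layers --------------------------------------------------

layer_linear <- function(d_in, d_out, bias = TRUE, sd = 0.02) {
  l <- list(
    W = ag_param(matrix(init_trunc_normal(d_in * d_out, sd), d_in, d_out))
  )
  if (bias) l$b <- ag_param(numeric(d_out))
  l$d_in <- d_in; l$d_out <- d_out
  l
}

linear_fwd <- function(l, x) {
  y <- ag_matmul(x, l$W)
  if (!is.null(l$b)) y <- ag_bias_add(y, l$b)
  y
}

layer_layernorm <- function(d) {
  list(gamma = ag_param(rep(1, d)), beta = ag_param(numeric(d)))
}

ln_fwd <- function(l, x) ag_layernorm(x, l$gamma, l$beta)

layer_batchnorm <- function(C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  list(gamma = ag_param(rep(1, C)), beta = ag_param(numeric(C)), state = st)
}

bn_fwd <- function(l, x, training) {
  ag_batchnorm(x, l$gamma, l$beta, l$state, training = training)
}

## ---- convolution via im2col -----------------------------------------------

# index cache for im2col gathers, keyed by geometry
.conv_cache <- new.env(parent = emptyenv())

.im2col_idx <- function(Hp, Wp, C, B, k, stride) {
  key <- paste(Hp, Wp, C, B, k, stride, sep = "_")
  cached <- .conv_cache[[key]]
  if (!is.null(cached)) return(cached)
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  # top-left flat index (1-based) of each output position, ordered
  # (ho fastest, then wo, then b)
  ho <- rep(seq_len(Ho), times = Wo * B)
  wo <- rep(rep(seq_len(Wo), each = Ho), times = B)
  bb <- rep(seq_len(B), each = Ho * Wo)
  base <- (ho - 1L) * stride + 1L +
    Hp * ((wo - 1L) * stride) +
    Hp * Wp * C * (bb - 1L)
  # kernel/channel offsets, ordered (dh fastest, dw, channel)
  dh <- rep(seq_len(k) - 1L, times = k * C)
  dw <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  ch <- rep(seq_len(C) - 1L, each = k * k)
  koff <- dh + Hp * dw + Hp * Wp * ch
  idx <- outer(base, koff, `+`)
  res <- list(idx = idx, Ho = Ho, Wo = Wo)
  if (length(idx) <= 2^24) .conv_cache[[key]] <- res
  res
}

layer_conv2d <- function(C_in, C_out, k, stride = 1L, pad = 0L,
                         bias = TRUE, init = c("kaiming", "zeros", "identity")) {
  init <- match.arg(init)
  nw <- k * k * C_in * C_out
  w <- switch(init,
    kaiming = init_kaiming(k * k * C_in, nw),
    zeros = numeric(nw),
    identity = {
      stopifnot(C_in == C_out, k %% 2 == 1)
      v <- array(0, c(k, k, C_in, C_out))
      c0 <- (k + 1) / 2
      for (cc in seq_len(C_in)) v[c0, c0, cc, cc] <- 1
      as.vector(v)
    })
  l <- list(W = ag_param(matrix(w, k * k * C_in, C_out)))
  if (bias) l$b <- ag_param(numeric(C_out))
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$C_in <- C_in; l$C_out <- C_out
  l
}

# x: H x W x C x B node -> Ho x Wo x C_out x B node
conv2d_fwd <- function(l, x) {
  d <- dim(ag_value(x))
  stopifnot(d[3] == l$C_in)
  xp <- ag_pad2d(x, l$pad)
  dp <- dim(ag_value(xp))
  ii <- .im2col_idx(dp[1], dp[2], d[3], d[4], l$k, l$stride)
  n_rows <- ii$Ho * ii$Wo * d[4]
  cols <- ag_gather(xp, ii$idx, c(n_rows, l$k * l$k * d[3]),
                    col_unique = TRUE)
  y <- ag_matmul(cols, l$W)
  if (!is.null(l$b)) y <- ag_bias_add(y, l$b)
  # rows are (ho, wo, b); reorder to H x W x C_out x B
  y <- ag_reshape(y, c(ii$Ho, ii$Wo, d[4], l$C_out))
  ag_aperm(y, c(1, 2, 4, 3))
}

## ---- upsampling -----------------------------------------------------------

.upsample_mat <- function(n, f) {
  # bilinear interpolation matrix (n*f x n), half-pixel centers, edge clamped
  nf <- n * f
  U <- matrix(0, nf, n)
  for (i in seq_len(nf)) {
    s <- (i - 0.5) / f + 0.5
    i0 <- floor(s)
    fr <- s - i0
    i0c <- min(max(i0, 1), n)
    i1c <- min(max(i0 + 1, 1), n)
    if (i0 < 1) { i0c <- 1; i1c <- 1; fr <- 0 }
    if (i0 >= n) { i0c <- n; i1c <- n; fr <- 0 }
    U[i, i0c] <- U[i, i0c] + (1 - fr)
    U[i, i1c] <- U[i, i1c] + fr
  }
  U
}

#' Bilinear upsampling of a feature node
#'
#' Separable bilinear interpolation with half-pixel alignment; a linear
#' operator, so gradients flow exactly through its transpose.
#'
#' @param x node, array `H x W x C x B`.
#' @param factor integer scale factor.
#' @return node, array `(H*factor) x (W*factor) x C x B`.
#' @export
upsample_bilinear <- function(x, factor = 2L) {
  d <- dim(ag_value(x))
  Uh <- .upsample_mat(d[1], factor)
  Uw <- .upsample_mat(d[2], factor)
  # rows
  y <- ag_matmul(ag(Uh), ag_reshape(x, c(d[1], d[2] * d[3] * d[4])))
  y <- ag_reshape(y, c(d[1] * factor, d[2], d[3], d[4]))
  # columns
  y <- ag_aperm(y, c(2, 1, 3, 4))
  y <- ag_matmul(ag(Uw), ag_reshape(y, c(d[2], d[1] * factor * d[3] * d[4])))
  y <- ag_reshape(y, c(d[2] * factor, d[1] * factor, d[3], d[4]))
  ag_aperm(y, c(2, 1, 3, 4))
}

layer_deconv2d <- function(C_in, C_out, f) {
  # transposed convolution with kernel f x f, stride f (pixel-shuffle form);
  # Kaiming-scaled init so the upsampled signal keeps its magnitude
  l <- list(lin = layer_linear(C_in, f * f * C_out), f = as.integer(f),
            C_in = C_in, C_out = C_out)
  l$lin$W$value <- matrix(init_kaiming(C_in, C_in * f * f * C_out),
                          C_in, f * f * C_out)
  l
}

deconv2d_fwd <- function(l, x) {
  d <- dim(ag_value(x))
  f <- l$f
  # tokens ordered (h, w, b) x C_in
  tok <- ag_reshape(ag_aperm(x, c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], d[3]))
  y <- linear_fwd(l$lin, tok)            # (h,w,b) x (f*f*C_out), (dh,dw,c) cols
  y <- ag_reshape(y, c(d[1], d[2], d[4], f, f, l$C_out))
  y <- ag_aperm(y, c(4, 1, 5, 2, 6, 3))  # dh, h, dw, w, c, b
  ag_reshape(y, c(d[1] * f, d[2] * f, l$C_out, d[4]))
}

## ---- pooling & broadcasting helpers ---------------------------------------

# global pooling: H x W x C x B -> B x C matrices
global_avg_pool <- function(x) {
  d <- dim(ag_value(x))
  m <- ag_reshape(x, c(d[1] * d[2], d[3] * d[4]))
  v <- ag_colmeans(m)                       # length C*B, c fastest
  ag_aperm(ag_reshape(v, c(d[3], d[4])), c(2, 1))
}

global_max_pool <- function(x) {
  d <- dim(ag_value(x))
  m <- ag_reshape(x, c(d[1] * d[2], d[3] * d[4]))
  v <- ag_colmax(m)
  ag_aperm(ag_reshape(v, c(d[3], d[4])), c(2, 1))
}

# expand a B x C matrix to H x W x C x B
expand_channel_map <- function(x, H, W) ag_expand_channel(x, H, W)

# expand a H x W x 1 x B map across C channels
expand_spatial_map <- function(x, C) ag_expand_spatial(x, C)
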