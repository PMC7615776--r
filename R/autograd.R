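# Reverse-mode automatic differentiation over plain numeric arrays.
#
# A computation is recorded as a DAG of `ag_node` environments created during
# the forward pass; `ag_backward()` walks the nodes in reverse creation order
# and accumulates gradients into every node with `requires = TRUE` (parameters
# and anything downstream of one). Values are ordinary R arrays, so all heavy
# lifting (matmul, batched matmul, softmax) goes through BLAS / vectorized
# base R. There is no in-place mutation of values: every op allocates.

.ag_state <- new.env(parent = emptyenv())
.ag_state$next_id <- 1L
.ag_state$grad_enabled <- TRUE

#' Wrap a numeric array as an autodiff node
#'
#' Constants wrapped with `ag()` take part in the forward computation but
#' never receive gradients. Use [ag_param()] for learnable tensors.
#'
#' @param x numeric vector, matrix or array.
#' @return an `ag_node`.
#' @export
ag <- function(x) {
  if (inherits(x, "ag_node")) return(x)
  .ag_new(x, requires = FALSE)
}

#' Create a learnable parameter node
#'
#' @param x initial numeric value (any shape).
#' @param name optional name used in summaries and checkpoints.
#' @return an `ag_node` with `requires = TRUE` that accumulates `$grad`
#'   during [ag_backward()].
#' @export
ag_param <- function(x, name = NULL) {
  n <- .ag_new(x, requires = TRUE)
  n$is_param <- TRUE
  n$name <- name
  n
}

#' Extract the value of a node (or pass a plain array through)
#' @param x `ag_node` or numeric.
#' @export
ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

.ag_new <- function(value, parents = list(), backward = NULL, requires = NA) {
  if (is.na(requires)) {
    requires <- FALSE
    for (p in parents) if (isTRUE(p$requires)) { requires <- TRUE; break }
  }
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires <- requires
  if (requires) {
    node$parents <- parents
    node$backward <- backward
  } else {
    node$parents <- list()
    node$backward <- NULL
  }
  node$id <- .ag_state$next_id
  .ag_state$next_id <- .ag_state$next_id + 1L
  class(node) <- "ag_node"
  node
}

# Create an op node. When gradients are globally disabled (ag_no_grad) or no
# parent requires them, the node is a leaf: intermediates become collectable.
.ag_op <- function(value, parents, backward) {
  if (!.ag_state$grad_enabled) return(.ag_new(value, requires = FALSE))
  .ag_new(value, parents = parents, backward = backward)
}

#' Evaluate an expression without recording gradients
#'
#' @param expr expression to evaluate (e.g. a forward pass used for metrics).
#' @export
ag_no_grad <- function(expr) {
  old <- .ag_state$grad_enabled
  .ag_state$grad_enabled <- FALSE
  on.exit(.ag_state$grad_enabled <- old)
  force(expr)
}

#' Backpropagate from a scalar node
#'
#' Accumulates `$grad` on every reachable node with `requires = TRUE`.
#' Parameter gradients add onto any existing `$grad` (so batched losses can be
#' backpropagated in pieces); call [ag_zero_grad()] between optimizer steps.
#'
#' @param loss an `ag_node` holding a scalar.
#' @param grad upstream gradient seed, default 1.
#' @export
ag_backward <- function(loss, grad = 1) {
  stopifnot(inherits(loss, "ag_node"))
  if (!isTRUE(loss$requires)) return(invisible(NULL))
  # collect reachable grad-requiring nodes (iterative DFS)
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L); nn <- 0L
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) if (isTRUE(p$requires)) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  loss$grad <- .ag_accum(loss$grad, grad)
  for (nd in nodes[ord]) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (isTRUE(p$requires) && !is.null(gs[[i]])) p$grad <- .ag_accum(p$grad, gs[[i]])
    }
    if (!isTRUE(nd$is_param)) nd$grad <- NULL  # free intermediate grads early
  }
  invisible(NULL)
}

.ag_accum <- function(old, g) if (is.null(old)) g else old + g

#' Clear gradients on a list of parameters
#' @param params list of `ag_node` parameters.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- arithmetic -----------------------------------------------------------

#' Elementwise node arithmetic
#'
#' `ag_add`/`ag_sub`/`ag_mul`/`ag_div` require operands of identical shape;
#' `ag_scale` multiplies by a fixed scalar, `ag_shift` adds one;
#' `ag_mul_scalar` multiplies an array node by a length-1 node (e.g. a
#' learnable gate) and routes gradient to both.
#'
#' @param a,b,x nodes or numeric arrays.
#' @param s fixed numeric scalar (`ag_scale`, `ag_shift`) or length-1 node
#'   (`ag_mul_scalar`).
#' @name ag-arith
NULL

#' @rdname ag-arith
#' @export
ag_add <- function(a, b) {
  a <- ag(a); b <- ag(b)
  .ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

#' @rdname ag-arith
#' @export
ag_sub <- function(a, b) {
  a <- ag(a); b <- ag(b)
  .ag_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

#' @rdname ag-arith
#' @export
ag_mul <- function(a, b) {
  a <- ag(a); b <- ag(b)
  av <- a$value; bv <- b$value
  .ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' @rdname ag-arith
#' @export
ag_div <- function(a, b) {
  a <- ag(a); b <- ag(b)
  av <- a$value; bv <- b$value
  .ag_op(av / bv, list(a, b), function(g) list(g / bv, -g * av / (bv * bv)))
}

#' @rdname ag-arith
#' @export
ag_scale <- function(x, s) {
  x <- ag(x)
  .ag_op(x$value * s, list(x), function(g) list(g * s))
}

#' @rdname ag-arith
#' @export
ag_shift <- function(x, s) {
  x <- ag(x)
  .ag_op(x$value + s, list(x), function(g) list(g))
}

#' @rdname ag-arith
#' @export
ag_mul_scalar <- function(x, s) {
  x <- ag(x); s <- ag(s)
  xv <- x$value; sv <- as.numeric(s$value)[1]
  .ag_op(xv * sv, list(x, s), function(g) list(g * sv, sum(g * xv)))
}

## ---- linear algebra -------------------------------------------------------

#' Matrix product of two 2-D nodes
#' @param a,b nodes holding conforming matrices.
#' @export
ag_matmul <- function(a, b) {
  a <- ag(a); b <- ag(b)
  av <- a$value; bv <- b$value
  .ag_op(av %*% bv, list(a, b),
         function(g) list(g %*% t(bv), crossprod(av, g)))
}

#' Batched matrix product
#'
#' Multiplies `a[, , i] %*% b[, , i]` (or `b` transposed when `tb = TRUE`) for
#' every slice `i` of the last (batch) dimension.
#'
#' @param a node, array `n x k x B`.
#' @param b node, array `k x m x B` (or `m x k x B` when `tb`).
#' @param tb transpose each slice of `b`.
#' @export
ag_bmm <- function(a, b, tb = FALSE) {
  a <- ag(a); b <- ag(b)
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 3L, length(db) == 3L, da[3] == db[3])
  B <- da[3]
  m <- if (tb) db[1] else db[2]
  out <- array(0, c(da[1], m, B))
  for (i in seq_len(B)) {
    ai <- matrix(av[, , i], da[1], da[2])
    bi <- matrix(bv[, , i], db[1], db[2])
    out[, , i] <- if (tb) tcrossprod(ai, bi) else ai %*% bi
  }
  .ag_op(out, list(a, b), function(g) {
    ga <- array(0, da); gb <- array(0, db)
    for (i in seq_len(B)) {
      gi <- matrix(g[, , i], da[1], m)
      ai <- matrix(av[, , i], da[1], da[2])
      bi <- matrix(bv[, , i], db[1], db[2])
      if (tb) {
        ga[, , i] <- gi %*% bi
        gb[, , i] <- crossprod(gi, ai)
      } else {
        ga[, , i] <- tcrossprod(gi, bi)
        gb[, , i] <- crossprod(ai, gi)
      }
    }
    list(ga, gb)
  })
}

## ---- shape ops ------------------------------------------------------------

#' Reshape / permute / gather / scatter primitives
#'
#' `ag_gather` builds an output array whose flat entries are `x[idx]`; its
#' adjoint is a scatter-add, which `ag_scatter` exposes directly (duplicated
#' indices accumulate). These two primitives implement window partitioning,
#' im2col convolution, broadcasting, and relative-position lookups.
#'
#' @param x node.
#' @param dims integer vector of output dimensions.
#' @param perm permutation of the dimensions (as in [aperm()]).
#' @param idx integer vector of 1-based flat indices into `x` (`ag_gather`) or
#'   into the output (`ag_scatter`), one per element of `x`.
#' @param n_out flat length of the scatter output.
#' @name ag-shape
NULL

#' @rdname ag-shape
#' @export
ag_reshape <- function(x, dims) {
  x <- ag(x)
  old <- dim(x$value)
  if (is.null(old)) old <- length(x$value)
  v <- x$value
  dim(v) <- dims
  .ag_op(v, list(x), function(g) { dim(g) <- old; list(g) })
}

#' @rdname ag-shape
#' @export
ag_aperm <- function(x, perm) {
  x <- ag(x)
  .ag_op(aperm(x$value, perm), list(x),
         function(g) list(aperm(g, order(perm))))
}

#' @rdname ag-shape
#' @param unique_idx set `TRUE` when `idx` has no duplicates (a permutation
#'   or sub-selection): the adjoint becomes a direct assignment instead of a
#'   grouped sum.
#' @param col_unique set `TRUE` when `idx` is given as a matrix whose
#'   *columns* are individually duplicate-free (the im2col layout): the
#'   adjoint accumulates column by column.
#' @export
ag_gather <- function(x, idx, dims, unique_idx = FALSE, col_unique = FALSE) {
  x <- ag(x)
  xdim <- dim(x$value)
  if (is.null(xdim)) xdim <- length(x$value)
  n_in <- length(x$value)
  # always index with the flat vector: a matrix index whose column count
  # happens to equal the array's dimensionality would otherwise be taken
  # as coordinate rows
  v <- x$value[as.vector(idx)]
  dim(v) <- dims
  .ag_op(v, list(x), function(g) {
    gv <- if (unique_idx || col_unique) g else as.vector(g)
    gx <- .scatter_add(gv, idx, n_in, unique_idx, col_unique)
    dim(gx) <- xdim
    list(gx)
  })
}

#' @rdname ag-shape
#' @export
ag_scatter <- function(x, idx, n_out, dims = NULL, unique_idx = FALSE,
                       col_unique = FALSE) {
  x <- ag(x)
  xdim <- dim(x$value)
  if (is.null(xdim)) xdim <- length(x$value)
  v <- .scatter_add(as.vector(x$value), idx, n_out, unique_idx, col_unique)
  if (!is.null(dims)) dim(v) <- dims
  .ag_op(v, list(x), function(g) {
    gx <- as.vector(g)[idx]
    dim(gx) <- xdim
    list(gx)
  })
}

# scatter-add of vals into a zero vector of length n: out[i] = sum(vals[idx == i])
.scatter_add <- function(vals, idx, n, unique_idx = FALSE, col_unique = FALSE) {
  out <- numeric(n)
  if (unique_idx) {
    out[idx] <- vals
    return(out)
  }
  if (col_unique && is.matrix(idx)) {
    nr <- nrow(idx)
    for (j in seq_len(ncol(idx))) {
      cj <- idx[, j]
      out[cj] <- out[cj] + vals[((j - 1L) * nr + 1L):(j * nr)]
    }
    return(out)
  }
  acc <- rowsum(vals, group = as.vector(idx), reorder = FALSE)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Broadcast helpers with analytic adjoints
#'
#' `ag_bias_add` adds a length-`d` vector to every row of an `N x d` matrix;
#' `ag_expand_channel` tiles a `B x C` matrix over space to `H x W x C x B`;
#' `ag_expand_spatial` tiles an `H x W x 1 x B` map across `C` channels.
#'
#' @param x node.
#' @param b bias node of length `ncol(x)`.
#' @param H,W,C output spatial size / channel count.
#' @name ag-broadcast
NULL

#' @rdname ag-broadcast
#' @export
ag_bias_add <- function(x, b) {
  x <- ag(x); b <- ag(b)
  v <- x$value
  .ag_op(sweep(v, 2, as.vector(b$value), `+`), list(x, b),
         function(g) list(g, colSums(g)))
}

#' @rdname ag-broadcast
#' @export
ag_expand_channel <- function(x, H, W) {
  x <- ag(x)
  v <- x$value                      # B x C
  B <- nrow(v); C <- ncol(v)
  out <- array(0, c(H, W, C, B))
  for (bb in seq_len(B)) out[, , , bb] <- rep(v[bb, ], each = H * W)
  .ag_op(out, list(x), function(g) {
    gm <- colSums(matrix(g, H * W, C * B))     # (c, b)
    list(t(matrix(gm, C, B)))
  })
}

#' @rdname ag-broadcast
#' @export
ag_expand_spatial <- function(x, C) {
  x <- ag(x)
  v <- x$value                      # H x W x 1 x B
  d <- dim(v)
  H <- d[1]; W <- d[2]; B <- d[4]
  out <- array(0, c(H, W, C, B))
  for (bb in seq_len(B)) out[, , , bb] <- v[, , 1, bb]
  .ag_op(out, list(x), function(g) {
    gs <- rowSums(matrix(aperm(g, c(1, 2, 4, 3)), H * W * B, C))
    list(array(gs, c(H, W, 1, B)))
  })
}

#' Concatenate nodes along an axis
#' @param xs list of nodes with identical shape except along `axis`.
#' @param axis dimension index to bind on.
#' @export
ag_concat <- function(xs, axis) {
  xs <- lapply(xs, ag)
  vals <- lapply(xs, function(x) x$value)
  dims <- lapply(vals, dim)
  nd <- length(dims[[1]])
  sizes <- vapply(dims, function(d) d[axis], numeric(1))
  outdim <- dims[[1]]
  outdim[axis] <- sum(sizes)
  out <- array(0, outdim)
  idx_all <- lapply(outdim, seq_len)
  off <- 0L
  for (i in seq_along(vals)) {
    sl <- idx_all
    sl[[axis]] <- off + seq_len(sizes[i])
    out <- do.call(`[<-`, c(list(out), sl, list(vals[[i]])))
    off <- off + sizes[i]
  }
  .ag_op(out, xs, function(g) {
    gs <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      sl <- idx_all
      sl[[axis]] <- off + seq_len(sizes[i])
      gi <- do.call(`[`, c(list(g), sl, list(drop = FALSE)))
      dim(gi) <- dims[[i]]
      gs[[i]] <- gi
      off <- off + sizes[i]
    }
    gs
  })
}

#' Zero-pad the two leading (spatial) dimensions of a 4-D node
#' @param x node, array `H x W x C x B`.
#' @param pad pixels of zero padding added on each spatial side.
#' @export
ag_pad2d <- function(x, pad) {
  x <- ag(x)
  d <- dim(x$value)
  stopifnot(length(d) == 4L)
  if (pad == 0) return(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x$value
  .ag_op(out, list(x), function(g) {
    list(g[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE])
  })
}

## ---- reductions -----------------------------------------------------------

#' Reductions over nodes
#'
#' `ag_sum`/`ag_mean` reduce to a scalar; `ag_colsums`/`ag_colmeans` reduce a
#' matrix to a row vector; `ag_colmax` takes per-column maxima (gradient flows
#' to the argmax entries only).
#'
#' @param x node (matrix for the column reductions).
#' @name ag-reduce
NULL

#' @rdname ag-reduce
#' @export
ag_sum <- function(x) {
  x <- ag(x)
  d <- dim(x$value); if (is.null(d)) d <- length(x$value)
  .ag_op(sum(x$value), list(x), function(g) list(array(g, d)))
}

#' @rdname ag-reduce
#' @export
ag_mean <- function(x) {
  x <- ag(x)
  n <- length(x$value)
  d <- dim(x$value); if (is.null(d)) d <- n
  .ag_op(sum(x$value) / n, list(x), function(g) list(array(g / n, d)))
}

#' @rdname ag-reduce
#' @export
ag_colsums <- function(x) {
  x <- ag(x)
  v <- x$value
  .ag_op(colSums(v), list(x), function(g) {
    list(matrix(g, nrow(v), ncol(v), byrow = TRUE))
  })
}

#' @rdname ag-reduce
#' @export
ag_colmeans <- function(x) {
  x <- ag(x)
  v <- x$value
  n <- nrow(v)
  .ag_op(colMeans(v), list(x), function(g) {
    list(matrix(g / n, n, ncol(v), byrow = TRUE))
  })
}

#' @rdname ag-reduce
#' @export
ag_colmax <- function(x) {
  x <- ag(x)
  v <- x$value
  am <- max.col(t(v), ties.method = "first")  # argmax per column
  .ag_op(apply(v, 2, max), list(x), function(g) {
    gx <- matrix(0, nrow(v), ncol(v))
    gx[cbind(am, seq_len(ncol(v)))] <- g
    list(gx)
  })
}

## ---- nonlinearities -------------------------------------------------------

#' Activation functions
#'
#' Exact GELU (`x * pnorm(x)`), ReLU, LeakyReLU, sigmoid and tanh as autodiff
#' ops.
#'
#' @param x node.
#' @param slope negative-side slope of LeakyReLU (default 0.01).
#' @name ag-activations
NULL

#' @rdname ag-activations
#' @export
ag_relu <- function(x) {
  x <- ag(x)
  xv <- x$value
  .ag_op(pmax(xv, 0) * 1, list(x), function(g) list(g * (xv > 0)))
}

#' @rdname ag-activations
#' @export
ag_leaky_relu <- function(x, slope = 0.01) {
  x <- ag(x)
  xv <- x$value
  .ag_op(ifelse(xv > 0, xv, slope * xv), list(x),
         function(g) list(g * ifelse(xv > 0, 1, slope)))
}

#' @rdname ag-activations
#' @export
ag_gelu <- function(x) {
  x <- ag(x)
  xv <- x$value
  ph <- stats::pnorm(xv)
  .ag_op(xv * ph, list(x),
         function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

#' @rdname ag-activations
#' @export
ag_sigmoid <- function(x) {
  x <- ag(x)
  v <- 1 / (1 + exp(-x$value))
  .ag_op(v, list(x), function(g) list(g * v * (1 - v)))
}

#' @rdname ag-activations
#' @export
ag_tanh <- function(x) {
  x <- ag(x)
  v <- tanh(x$value)
  .ag_op(v, list(x), function(g) list(g * (1 - v * v)))
}

## ---- normalization & softmax ---------------------------------------------

#' Row-wise softmax with max subtraction
#'
#' Softmax across the columns of each row, stabilized by subtracting the row
#' maximum before exponentiation.
#'
#' @param x node holding a matrix (rows = independent distributions).
#' @export
ag_softmax_rows <- function(x) {
  x <- ag(x)
  v <- x$value
  if (any(!is.finite(v))) {
    stop("non-finite attention logits encountered before softmax ",
         "(numerical overflow)")
  }
  m <- .row_max(v)
  e <- exp(v - m)
  y <- e / rowSums(e)
  .ag_op(y, list(x), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

#' Layer normalization across rows of a token matrix
#'
#' Normalizes each row to zero mean / unit variance over the feature
#' dimension, then applies a learnable per-feature scale and shift.
#'
#' @param x node, matrix `N x d`.
#' @param gamma,beta nodes of length `d`.
#' @param eps variance floor.
#' @export
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- ag(x); gamma <- ag(gamma); beta <- ag(beta)
  v <- x$value
  d <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  y <- sweep(xhat, 2, gv, `*`)
  y <- sweep(y, 2, bv, `+`)
  .ag_op(y, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2, gv, `*`)
    t1 <- rowMeans(dxhat)
    t2 <- rowMeans(dxhat * xhat)
    dx <- inv * (dxhat - t1 - xhat * t2)
    list(dx, dgamma, dbeta)
  })
}

#' Batch normalization over a 4-D feature node
#'
#' Normalizes each channel over the spatial and batch dimensions. In training
#' mode batch statistics are used and exponential running estimates updated in
#' `state`; in evaluation mode the running estimates are used.
#'
#' @param x node, array `H x W x C x B`.
#' @param gamma,beta nodes of length `C`.
#' @param state environment with `running_mean` / `running_var` vectors.
#' @param training logical.
#' @param momentum update rate for the running statistics.
#' @param eps variance floor.
#' @export
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  x <- ag(x); gamma <- ag(gamma); beta <- ag(beta)
  v <- x$value
  d <- dim(v)
  C <- d[3]
  n <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(v, c(1, 2, 4, 3)), nrow = n, ncol = C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    va <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    # unbiased running variance, matching the usual framework convention
    ub <- if (n > 1) va * n / (n - 1) else va
    state$running_var <- (1 - momentum) * state$running_var + momentum * ub
  } else {
    mu <- state$running_mean
    xc <- sweep(xm, 2, mu)
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  ym <- sweep(sweep(xhat, 2, gv, `*`), 2, bv, `+`)
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  .ag_op(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), nrow = n, ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, gv, `*`)
    if (training) {
      t1 <- colMeans(dxhat)
      t2 <- colMeans(dxhat * xhat)
      dxm <- sweep(dxhat, 2, inv, `*`) -
        sweep(matrix(1, n, C), 2, t1 * inv, `*`) -
        sweep(xhat, 2, t2 * inv, `*`)
    } else {
      dxm <- sweep(dxhat, 2, inv, `*`)
    }
    dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    list(dx, dgamma, dbeta)
  })
}

## ---- losses ---------------------------------------------------------------

#' Mean softmax cross-entropy over pixels
#'
#' @param logits node, matrix `N x K` of unnormalized class scores.
#' @param target integer vector of length `N` with class indices in `1..K`.
#' @return scalar node with the mean negative log-likelihood.
#' @export
ag_cross_entropy <- function(logits, target) {
  logits <- ag(logits)
  v <- logits$value
  N <- nrow(v); K <- ncol(v)
  if (any(target < 1L) || any(target > K)) {
    stop("target class id out of range 1..", K)
  }
  m <- .row_max(v)
  e <- exp(v - m)
  p <- e / rowSums(e)
  nll <- -mean(log(pmax(p[cbind(seq_len(N), target)], 1e-300)))
  .ag_op(nll, list(logits), function(g) {
    gx <- p
    gx[cbind(seq_len(N), target)] <- gx[cbind(seq_len(N), target)] - 1
    list(gx * (g / N))
  })
}

## ---- helpers --------------------------------------------------------------

# column-loop row maximum (avoids apply() overhead on wide matrices)
.row_max <- function(v) {
  m <- v[, 1]
  nc <- ncol(v)
  if (nc > 1) for (j in 2:nc) m <- pmax(m, v[, j])
  m
}

# column block extraction as a gather (keeps gradient routing)
ag_cols <- function(x, cols) {
  v <- ag_value(x)
  n <- nrow(v)
  idx <- as.vector(outer(seq_len(n), (cols - 1L) * n, `+`))
  ag_gather(x, idx, c(n, length(cols)), unique_idx = TRUE)
}

#' Numerical gradient check helper
#'
#' Compares the analytic gradient of `fn` (a scalar-valued function of the
#' parameter node `param`) against central finite differences at a few random
#' entries. Intended for tests.
#'
#' @param fn function taking no arguments, returning a scalar `ag_node`; must
#'   reference `param` internally.
#' @param param the parameter node to perturb.
#' @param n_probe number of entries to probe.
#' @param h finite-difference step.
#' @return max absolute relative error over probed entries.
#' @export
ag_grad_check <- function(fn, param, n_probe = 5, h = 1e-5) {
  ag_zero_grad(list(param))
  loss <- fn()
  ag_backward(loss)
  ga <- param$grad
  stopifnot(!is.null(ga))
  idx <- sample(length(param$value), min(n_probe, length(param$value)))
  err <- 0
  for (i in idx) {
    orig <- param$value[i]
    param$value[i] <- orig + h
    up <- as.numeric(ag_value(ag_no_grad(fn())))
    param$value[i] <- orig - h
    dn <- as.numeric(ag_value(ag_no_grad(fn())))
    param$value[i] <- orig
    gn <- (up - dn) / (2 * h)
    scale <- max(abs(gn), abs(ga[i]), 1e-4)
    err <- max(err, abs(gn - ga[i]) / scale)
  }
  err
}
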