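# Tape-based reverse-mode automatic differentiation on dense arrays.
#
# A tensor is an environment holding the value (`v`), the accumulated
# gradient (`g`) and a `requires_grad` flag. Every differentiable operation
# appends one entry to a global tape; `ag_backward()` walks the tape in
# reverse, calling each entry's backward closure and accumulating gradients
# into the input tensors. Feature maps follow the [batch, channels, height,
# width] convention throughout.

the <- new.env(parent = emptyenv())
the$tape <- list()
the$recording <- TRUE
the$training <- FALSE

#' Create an autodiff tensor
#'
#' Wraps a numeric array (or matrix) as a node of the computation graph.
#'
#' @param value Numeric array, matrix or vector.
#' @param requires_grad Should gradients be accumulated into this tensor?
#' @param name Optional label used in diagnostics.
#' @return An object of class `ag_tensor`.
#' @export
ag_tensor <- function(value, requires_grad = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  e$requires_grad <- requires_grad
  e$name <- name
  class(e) <- "ag_tensor"
  e
}

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<ag_tensor", if (!is.null(x$name)) paste0("'", x$name, "'"),
      if (is.null(d)) paste0("len=", length(x$v)) else paste0("[", paste(d, collapse = "x"), "]"),
      if (x$requires_grad) "grad" else "", ">\n")
  invisible(x)
}

#' Trainable parameter tensor
#' @param value Initial numeric value.
#' @param name Parameter label.
#' @return An `ag_tensor` with `requires_grad = TRUE`.
#' @export
ag_param <- function(value, name = NULL) ag_tensor(value, requires_grad = TRUE, name = name)

#' Extract the value of a tensor
#' @param x An `ag_tensor` (plain arrays pass through).
#' @return The underlying numeric array.
#' @export
ag_value <- function(x) if (inherits(x, "ag_tensor")) x$v else x

ag_is_tensor <- function(x) inherits(x, "ag_tensor")

# Record one op on the tape. `bw` maps the output gradient to a list of
# input gradients (NULL entries allowed for inputs that need none).
ag_record <- function(value, inputs, bw) {
  need <- the$recording &&
    any(vapply(inputs, function(i) ag_is_tensor(i) && i$requires_grad, logical(1)))
  out <- ag_tensor(value, requires_grad = need)
  if (need) the$tape[[length(the$tape) + 1L]] <- list(out = out, inputs = inputs, bw = bw)
  out
}

#' Reset the autodiff tape
#' @return Invisibly, NULL.
#' @export
ag_tape_reset <- function() {
  the$tape <- list()
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
ag_no_grad <- function(expr) {
  old <- the$recording
  the$recording <- FALSE
  on.exit(the$recording <- old)
  force(expr)
}

#' Switch batch-norm layers between training and evaluation behaviour
#' @param flag TRUE for training mode (batch statistics), FALSE for
#'   evaluation mode (running statistics).
#' @return The previous mode, invisibly.
#' @export
ag_set_training <- function(flag) {
  old <- the$training
  the$training <- isTRUE(flag)
  invisible(old)
}

#' Reverse-mode gradient accumulation
#'
#' Seeds the gradient of a scalar loss tensor with 1 and walks the tape in
#' reverse, accumulating gradients into every tensor with
#' `requires_grad = TRUE`. The tape is cleared afterwards.
#'
#' @param loss A scalar `ag_tensor`.
#' @return Invisibly, NULL.
#' @export
ag_backward <- function(loss) {
  stopifnot(ag_is_tensor(loss), length(loss$v) == 1L)
  loss$g <- 1
  tape <- the$tape
  for (i in rev(seq_along(tape))) {
    entry <- tape[[i]]
    g <- entry$out$g
    if (is.null(g)) next
    grads <- entry$bw(g)
    for (j in seq_along(entry$inputs)) {
      inp <- entry$inputs[[j]]
      if (!ag_is_tensor(inp) || !inp$requires_grad) next
      gj <- grads[[j]]
      if (is.null(gj)) next
      inp$g <- if (is.null(inp$g)) gj else inp$g + gj
    }
    entry$out$g <- NULL   # free intermediate gradients early
  }
  ag_tape_reset()
  invisible(NULL)
}

#' Zero the gradients of a list of parameters
#' @param params List of `ag_tensor` parameters.
#' @return Invisibly, NULL.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- shape helpers ---------------------------------------------------------

ag_dim <- function(x) dim(ag_value(x))

# channels-first array -> C x (N*H*W) matrix (channel-major view)
to_cmat <- function(a) {
  d <- dim(a)
  m <- aperm(a, c(2L, 1L, 3L, 4L))
  dim(m) <- c(d[2L], d[1L] * d[3L] * d[4L])
  m
}

from_cmat <- function(m, d) {
  dim(m) <- c(d[2L], d[1L], d[3L], d[4L])
  aperm(m, c(2L, 1L, 3L, 4L))
}

# ---- elementwise -----------------------------------------------------------

#' Elementwise sum of two same-shaped tensors
#' @param a,b Tensors of identical shape.
#' @return Tensor `a + b`.
#' @export
ag_add <- function(a, b) {
  ag_record(ag_value(a) + ag_value(b), list(a, b), function(g) list(g, g))
}

#' Elementwise product of two same-shaped tensors
#' @param a,b Tensors of identical shape.
#' @return Tensor `a * b`.
#' @export
ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_record(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' Multiply by a constant (non-learnable) array or scalar
#' @param x Tensor.
#' @param k Constant scalar or array conformable with `x`.
#' @return Tensor `x * k`.
#' @export
ag_mul_const <- function(x, k) {
  ag_record(ag_value(x) * k, list(x), function(g) list(g * k))
}

#' Gate a feature map by a one-channel spatial map
#'
#' Broadcasts `s` of shape [N,1,H,W] across the channel axis of `x`.
#' @param x Feature map [N,C,H,W].
#' @param s Gate [N,1,H,W].
#' @return Tensor of the shape of `x`.
#' @export
ag_mul_spatialgate <- function(x, s) {
  xv <- ag_value(x); sv <- ag_value(s)
  d <- dim(xv)
  se <- sv[, rep(1L, d[2L]), , , drop = FALSE]
  ag_record(xv * se, list(x, s), function(g) {
    gs <- rowSums(aperm(g * xv, c(1L, 3L, 4L, 2L)), dims = 3L)
    dim(gs) <- c(d[1L], 1L, d[3L], d[4L])
    list(g * se, gs)
  })
}

#' Gate a feature map by a per-channel weight
#'
#' Broadcasts `s` of shape [N,C,1,1] across the spatial axes of `x`.
#' @param x Feature map [N,C,H,W].
#' @param s Gate [N,C,1,1].
#' @return Tensor of the shape of `x`.
#' @export
ag_mul_changate <- function(x, s) {
  xv <- ag_value(x); sv <- ag_value(s)
  d <- dim(xv)
  se <- array(sv, dim = c(d[1L] * d[2L], 1L))[, rep(1L, d[3L] * d[4L])]
  dim(se) <- d
  ag_record(xv * se, list(x, s), function(g) {
    gs <- rowSums(g * xv, dims = 2L)
    dim(gs) <- c(d[1L], d[2L], 1L, 1L)
    list(g * se, gs)
  })
}

# ---- activations -----------------------------------------------------------

#' Exact (erf-based) GELU activation
#' @param x Tensor.
#' @return Tensor `x * pnorm(x)`.
#' @export
ag_gelu <- function(x) {
  xv <- ag_value(x)
  ag_record(cpp_gelu_fw(xv), list(x),
            function(g) list(cpp_gelu_bw(xv, g)))
}

#' Rectified linear activation
#' @param x Tensor.
#' @return Tensor `pmax(x, 0)`.
#' @export
ag_relu <- function(x) {
  xv <- ag_value(x)
  mask <- xv > 0
  ag_record(xv * mask, list(x), function(g) list(g * mask))
}

#' Logistic sigmoid activation
#' @param x Tensor.
#' @return Tensor `1 / (1 + exp(-x))`.
#' @export
ag_sigmoid <- function(x) {
  v <- stats::plogis(ag_value(x))
  ag_record(v, list(x), function(g) list(g * v * (1 - v)))
}

# ---- convolution -----------------------------------------------------------

#' 2-D convolution
#'
#' Standard cross-correlation with square kernels, implemented via
#' im2col + GEMM in compiled code. Grouped convolution supports depthwise
#' layers (`groups = channels`).
#'
#' @param x Input tensor [N,C,H,W].
#' @param w Weight tensor [C_out, C_in/groups, k, k].
#' @param b Optional bias tensor of length `C_out` (or NULL).
#' @param stride,pad Integer stride and zero padding.
#' @param groups Number of channel groups.
#' @return Output tensor [N, C_out, H_out, W_out].
#' @export
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  xv <- ag_value(x); wv <- ag_value(w)
  bv <- if (is.null(b)) numeric(0) else as.numeric(ag_value(b))
  v <- cpp_conv2d_fw(xv, wv, bv, as.integer(stride), as.integer(pad), as.integer(groups))
  inputs <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_record(v, inputs, function(g) {
    r <- cpp_conv2d_bw(xv, wv, g, as.integer(stride), as.integer(pad),
                       as.integer(groups), !is.null(b))
    if (is.null(b)) list(r$gx, r$gw) else list(r$gx, r$gw, r$gb)
  })
}

# ---- normalization ---------------------------------------------------------

#' Layer normalization over the channel axis
#'
#' Channels-last semantics on channels-first storage: every spatial position
#' of every sample is normalized across its channel vector, then scaled and
#' shifted per channel. A [N,C] matrix is treated as N positions of C
#' channels.
#'
#' @param x Tensor [N,C,H,W] or matrix [N,C].
#' @param gamma,beta Per-channel scale and shift tensors of length C.
#' @param eps Variance floor.
#' @return Normalized tensor of the shape of `x`.
#' @export
ag_layernorm <- function(x, gamma, beta, eps = 1e-6) {
  xv <- ag_value(x)
  gv <- as.numeric(ag_value(gamma)); bv <- as.numeric(ag_value(beta))
  d <- dim(xv)
  rank4 <- length(d) == 4L
  if (!rank4) dim(xv) <- c(d, 1L, 1L)   # [N,C] as one spatial position
  r <- cpp_ln_fw(xv, gv, bv, eps)
  v <- r$y
  if (!rank4) dim(v) <- d
  ag_record(v, list(x, gamma, beta), function(g) {
    if (!rank4) dim(g) <- c(d, 1L, 1L)
    b <- cpp_ln_bw(r$xhat, r$inv, gv, g)
    gx <- b$gx
    if (!rank4) dim(gx) <- d
    list(gx, b$dgamma, b$dbeta)
  })
}

#' Batch normalization over batch and spatial axes
#'
#' Normalizes each channel over (batch, height, width). In training mode
#' (see [ag_set_training()]) batch statistics are used and running
#' statistics are updated in `state`; in evaluation mode the running
#' statistics are used.
#'
#' @param x Tensor [N,C,H,W].
#' @param gamma,beta Per-channel scale and shift tensors.
#' @param state Environment with numeric fields `running_mean` and
#'   `running_var` (updated by reference in training mode).
#' @param momentum Running-statistics update rate.
#' @param eps Variance floor.
#' @return Normalized tensor of the shape of `x`.
#' @export
ag_batchnorm <- function(x, gamma, beta, state, momentum = 0.1, eps = 1e-5) {
  xv <- ag_value(x)
  gv <- as.numeric(ag_value(gamma)); bv <- as.numeric(ag_value(beta))
  d <- dim(xv)
  m <- to_cmat(xv)                                 # C x P, P = N*H*W
  P <- ncol(m)
  if (the$training) {
    mu <- rowMeans(m)
    xc <- m - mu
    va <- rowMeans(xc * xc)                        # biased, used for normalization
    unb <- if (P > 1L) va * P / (P - 1L) else va
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * unb
    inv <- 1 / sqrt(va + eps)
    xhat <- xc * inv
    v <- from_cmat(xhat * gv + bv, d)
    ag_record(v, list(x, gamma, beta), function(g) {
      gm <- to_cmat(g)
      dgamma <- rowSums(gm * xhat)
      dbeta <- rowSums(gm)
      dxhat <- gm * gv
      t1 <- rowMeans(dxhat)
      t2 <- rowMeans(dxhat * xhat)
      dx <- (dxhat - t1 - xhat * t2) * inv
      list(from_cmat(dx, d), dgamma, dbeta)
    })
  } else {
    inv <- 1 / sqrt(state$running_var + eps)
    xhat <- (m - state$running_mean) * inv
    v <- from_cmat(xhat * gv + bv, d)
    ag_record(v, list(x, gamma, beta), function(g) {
      gm <- to_cmat(g)
      list(from_cmat(gm * gv * inv, d), rowSums(gm * xhat), rowSums(gm))
    })
  }
}

# ---- matrix ops ------------------------------------------------------------

#' Matrix product of two tensors
#' @param a,b Matrix tensors with conformable shapes.
#' @return Tensor `a %*% b`.
#' @export
ag_matmul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_record(av %*% bv, list(a, b),
            function(g) list(g %*% t(bv), t(av) %*% g))
}

#' Affine map of row vectors
#'
#' `x` is [n, d_in], `w` is [d_out, d_in]; returns `x w^T + b` per row.
#' @param x Input matrix tensor.
#' @param w Weight matrix tensor.
#' @param b Bias tensor of length `d_out` (or NULL).
#' @return Matrix tensor [n, d_out].
#' @export
ag_linear <- function(x, w, b = NULL) {
  xv <- ag_value(x); wv <- ag_value(w)
  v <- xv %*% t(wv)
  if (!is.null(b)) v <- sweep(v, 2L, as.numeric(ag_value(b)), "+")
  inputs <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_record(v, inputs, function(g) {
    gx <- g %*% wv
    gw <- t(g) %*% xv
    if (is.null(b)) list(gx, gw) else list(gx, gw, colSums(g))
  })
}

#' Row-wise softmax of a matrix tensor
#' @param x Matrix tensor.
#' @return Matrix tensor with rows summing to 1.
#' @export
ag_softmax_rows <- function(x) {
  xv <- ag_value(x)
  e <- exp(xv - apply(xv, 1L, max))
  v <- e / rowSums(e)
  ag_record(v, list(x), function(g) list(v * (g - rowSums(g * v))))
}

#' Column-wise softmax of a matrix tensor
#' @param x Matrix tensor.
#' @return Matrix tensor with columns summing to 1.
#' @export
ag_softmax_cols <- function(x) {
  xv <- ag_value(x)
  e <- exp(sweep(xv, 2L, apply(xv, 2L, max)))
  v <- sweep(e, 2L, colSums(e), "/")
  ag_record(v, list(x), function(g) {
    list(v * sweep(g, 2L, colSums(g * v)))
  })
}

#' Row-wise L1 normalization of a nonnegative matrix tensor
#' @param x Matrix tensor with nonnegative entries and positive row sums.
#' @return Matrix tensor whose rows sum to 1.
#' @export
ag_l1norm_rows <- function(x) {
  xv <- ag_value(x)
  r <- rowSums(xv)
  v <- xv / r
  ag_record(v, list(x), function(g) list(g / r - rowSums(g * xv) / r^2))
}

# ---- shape ops -------------------------------------------------------------

#' Reshape a tensor (preserving element order)
#' @param x Tensor.
#' @param d New dimension vector.
#' @return Tensor with `dim = d`.
#' @export
ag_reshape <- function(x, d) {
  xv <- ag_value(x)
  old <- dim(xv)
  v <- xv
  dim(v) <- d
  ag_record(v, list(x), function(g) { dim(g) <- old; list(g) })
}

#' Concatenate feature maps along the channel axis
#' @param xs List of tensors [N,Ci,H,W] with equal N, H, W.
#' @return Tensor [N, sum(Ci), H, W].
#' @export
ag_concat_ch <- function(xs) {
  vs <- lapply(xs, ag_value)
  d1 <- dim(vs[[1L]])
  cs <- vapply(vs, function(v) dim(v)[2L], integer(1))
  Ctot <- sum(cs)
  v <- array(0, dim = c(d1[1L], Ctot, d1[3L], d1[4L]))
  off <- 0L
  for (i in seq_along(vs)) {
    v[, off + seq_len(cs[i]), , ] <- vs[[i]]
    off <- off + cs[i]
  }
  ag_record(v, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, off + seq_len(cs[i]), , , drop = FALSE]
      off <- off + cs[i]
    }
    out
  })
}

#' Extract a contiguous range of channels
#' @param x Tensor [N,C,H,W].
#' @param idx Integer vector of channel indices.
#' @return Tensor [N, length(idx), H, W].
#' @export
ag_slice_ch <- function(x, idx) {
  xv <- ag_value(x)
  d <- dim(xv)
  ag_record(xv[, idx, , , drop = FALSE], list(x), function(g) {
    gx <- array(0, dim = d)
    gx[, idx, , ] <- g
    list(gx)
  })
}

# ---- reductions ------------------------------------------------------------

#' Channel-wise mean map
#' @param x Tensor [N,C,H,W].
#' @return Tensor [N,1,H,W].
#' @export
ag_mean_ch <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  v <- rowSums(aperm(xv, c(1L, 3L, 4L, 2L)), dims = 3L) / d[2L]
  dim(v) <- c(d[1L], 1L, d[3L], d[4L])
  ag_record(v, list(x), function(g) {
    list(g[, rep(1L, d[2L]), , , drop = FALSE] / d[2L])
  })
}

#' Channel-wise max map
#' @param x Tensor [N,C,H,W].
#' @return Tensor [N,1,H,W].
#' @export
ag_max_ch <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  m <- to_cmat(xv)                                  # C x P
  P <- ncol(m)
  idx <- max.col(t(m), ties.method = "first")
  v <- m[cbind(idx, seq_len(P))]
  dim(v) <- c(1L, P)
  v <- from_cmat(v, c(d[1L], 1L, d[3L], d[4L]))
  ag_record(v, list(x), function(g) {
    gm <- matrix(0, nrow = d[2L], ncol = P)
    gm[cbind(idx, seq_len(P))] <- to_cmat(g)
    list(from_cmat(gm, d))
  })
}

#' Global average pooling
#' @param x Tensor [N,C,H,W].
#' @return Matrix tensor [N,C].
#' @export
ag_gap <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  hw <- d[3L] * d[4L]
  v <- rowSums(xv, dims = 2L) / hw
  ag_record(v, list(x), function(g) {
    gx <- array(rep(as.numeric(g) / hw, times = hw), dim = d)
    list(gx)
  })
}

#' Global max pooling
#' @param x Tensor [N,C,H,W].
#' @return Matrix tensor [N,C].
#' @export
ag_gmp <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  m <- xv
  dim(m) <- c(d[1L] * d[2L], d[3L] * d[4L])
  idx <- max.col(m, ties.method = "first")
  v <- m[cbind(seq_len(nrow(m)), idx)]
  dim(v) <- c(d[1L], d[2L])
  ag_record(v, list(x), function(g) {
    gm <- matrix(0, nrow = d[1L] * d[2L], ncol = d[3L] * d[4L])
    gm[cbind(seq_len(nrow(gm)), idx)] <- as.numeric(g)
    dim(gm) <- d
    list(gm)
  })
}

#' 2x2 average pooling with stride 2
#' @param x Tensor [N,C,H,W] with even H and W.
#' @return Tensor [N,C,H/2,W/2].
#' @export
ag_avgpool2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  if (d[3L] %% 2L != 0L || d[4L] %% 2L != 0L)
    stop("ag_avgpool2: spatial size must be even")
  ho <- seq(1L, d[3L], by = 2L); he <- ho + 1L
  wo <- seq(1L, d[4L], by = 2L); we <- wo + 1L
  v <- (xv[, , ho, wo, drop = FALSE] + xv[, , he, wo, drop = FALSE] +
        xv[, , ho, we, drop = FALSE] + xv[, , he, we, drop = FALSE]) / 4
  ag_record(v, list(x), function(g) {
    gx <- array(0, dim = d)
    q <- g / 4
    gx[, , ho, wo] <- q; gx[, , he, wo] <- q
    gx[, , ho, we] <- q; gx[, , he, we] <- q
    list(gx)
  })
}

# ---- token layout ----------------------------------------------------------

#' Flatten a feature map into row-major token form
#'
#' Tokens are enumerated row-major over the spatial grid (x inner, y outer),
#' matching the coordinate convention of the spatial decay mask. The result
#' is a [T, C, N] array with T = H*W.
#'
#' @param x Tensor [N,C,H,W].
#' @return Tensor [H*W, C, N].
#' @export
ag_to_tokens <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  v <- aperm(xv, c(4L, 3L, 2L, 1L))
  dim(v) <- c(d[4L] * d[3L], d[2L], d[1L])
  ag_record(v, list(x), function(g) {
    dim(g) <- c(d[4L], d[3L], d[2L], d[1L])
    list(aperm(g, c(4L, 3L, 2L, 1L)))
  })
}

#' Restore a token array to feature-map form
#' @param x Tensor [T, C, N] as produced by [ag_to_tokens()].
#' @param height,width Spatial grid size with `height*width == T`.
#' @return Tensor [N,C,H,W].
#' @export
ag_from_tokens <- function(x, height, width) {
  xv <- ag_value(x)
  d <- dim(xv)
  stopifnot(d[1L] == height * width)
  v <- xv
  dim(v) <- c(width, height, d[2L], d[3L])
  v <- aperm(v, c(4L, 3L, 2L, 1L))
  ag_record(v, list(x), function(g) {
    g <- aperm(g, c(4L, 3L, 2L, 1L))
    dim(g) <- d
    list(g)
  })
}

# ---- losses ----------------------------------------------------------------

#' Categorical cross-entropy from logits
#'
#' Mean negative log softmax probability of the true class, computed with
#' the log-sum-exp stabilization.
#'
#' @param logits Matrix tensor [n, C].
#' @param y Integer vector of 0-based class labels.
#' @return Scalar tensor.
#' @export
ag_cce <- function(logits, y) {
  lv <- ag_value(logits)
  if (any(!is.finite(lv))) stop("ag_cce: non-finite logits")
  n <- nrow(lv)
  stopifnot(length(y) == n, all(y >= 0L), all(y < ncol(lv)))
  mx <- apply(lv, 1L, max)
  lse <- mx + log(rowSums(exp(lv - mx)))
  picked <- lv[cbind(seq_len(n), y + 1L)]
  v <- mean(lse - picked)
  p <- exp(lv - lse)
  ag_record(v, list(logits), function(g) {
    gl <- p
    gl[cbind(seq_len(n), y + 1L)] <- gl[cbind(seq_len(n), y + 1L)] - 1
    list(as.numeric(g) * gl / n)
  })
}
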