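# Enhanced global feature (EGF) branch.
#
# The attention here is Manhattan self-attention (MaSA): standard softmax
# attention whose weight matrix is elementwise multiplied by a spatial decay
# mask gamma^(|x_n - x_m| + |y_n - y_m|) before being applied to the values.
# Tokens are the spatial positions of the feature map, enumerated row-major
# (x inner, y outer, 0-based coordinates). Each head uses its own decay
# value; the per-head schedule gamma_h = 1 - 2^-(5 + h) follows the
# retentive-network convention. Scores are scaled by 1/sqrt(d_head), the
# universal attention normalization.
#
# An EGF block is:
#   t   = PosEmb(x)              (residual depthwise 3x3; first block only)
#   g   = LN(MaSA(t) + t)
#   out = LN(Linear(g) + g)

#' Two-dimensional Manhattan decay mask
#'
#' Entry (n, m) is `gamma^(|x_n - x_m| + |y_n - y_m|)` for tokens enumerated
#' row-major over a height-by-width grid (x inner, 0-based coordinates).
#'
#' @param height,width Grid size (tokens = height * width).
#' @param gamma Decay value in (0, 1].
#' @return A tokens-by-tokens matrix with unit diagonal, symmetric, entries
#'   in (0, 1], with attribute `"gamma"`.
#' @export
manhattan_decay_mask <- function(height, width, gamma) {
  if (height < 1L || width < 1L)
    hemf_stop_validation("grid dimensions must be >= 1")
  if (!is.finite(gamma) || gamma <= 0 || gamma > 1)
    hemf_stop_validation("gamma must lie in (0, 1]")
  t <- seq_len(height * width) - 1L
  xs <- t %% width
  ys <- t %/% width
  d <- abs(outer(xs, xs, "-")) + abs(outer(ys, ys, "-"))
  m <- gamma^d
  attr(m, "gamma") <- gamma
  m
}

#' Default per-head decay schedule
#' @param heads Number of attention heads.
#' @return Numeric vector `1 - 2^-(5 + h)` for h = 0, ..., heads - 1.
#' @export
masa_gamma_schedule <- function(heads) 1 - 2^(-(5 + seq_len(heads) - 1))

# Cache of Manhattan distance matrices keyed by "HxW".
.mask_cache <- new.env(parent = emptyenv())

manhattan_distance_matrix <- function(height, width) {
  key <- paste0(height, "x", width)
  hit <- get0(key, envir = .mask_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  t <- seq_len(height * width) - 1L
  xs <- t %% width
  ys <- t %/% width
  d <- abs(outer(xs, xs, "-")) + abs(outer(ys, ys, "-"))
  .mask_cache[[key]] <- d
  d
}

#' Parameters of a Manhattan self-attention layer
#' @param channels Channel count.
#' @param heads Number of heads (must divide `channels`).
#' @param gammas Per-head decay values; defaults to [masa_gamma_schedule()].
#' @return Named list of projections and decay values.
#' @export
masa_params <- function(channels, heads, gammas = NULL) {
  if (channels %% heads != 0L)
    hemf_stop_config("head count must divide channel count")
  if (is.null(gammas)) gammas <- masa_gamma_schedule(heads)
  if (length(gammas) != heads || any(gammas <= 0) || any(gammas > 1))
    hemf_stop_config("need one decay value in (0,1] per head")
  list(
    channels = channels, heads = heads, gammas = gammas,
    q_proj = nn_conv(channels, channels, 1L),
    k_proj = nn_conv(channels, channels, 1L),
    v_proj = nn_conv(channels, channels, 1L),
    out_proj = nn_conv(channels, channels, 1L)
  )
}

# Composite multi-head decayed-attention op on token arrays [T, C, N].
# masks is a list of T x T constant matrices, one per head. Recorded as a
# single tape entry; the per-sample, per-head softmax matrices are retained
# for the backward pass.
ag_decay_attention <- function(q, k, v, masks, heads, scale) {
  qv <- ag_value(q); kv <- ag_value(k); vv <- ag_value(v)
  d <- dim(qv)
  Tn <- d[1L]; C <- d[2L]; N <- d[3L]
  dh <- C %/% heads
  out <- array(0, dim = d)
  A_store <- vector("list", N * heads)
  for (n in seq_len(N)) {
    for (h in seq_len(heads)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      Q <- qv[, idx, n, drop = FALSE]; dim(Q) <- c(Tn, dh)
      K <- kv[, idx, n, drop = FALSE]; dim(K) <- c(Tn, dh)
      V <- vv[, idx, n, drop = FALSE]; dim(V) <- c(Tn, dh)
      S <- (Q %*% t(K)) * scale
      E <- exp(S - S[cbind(seq_len(Tn), max.col(S, ties.method = "first"))])
      A <- E / rowSums(E)
      A_store[[(n - 1L) * heads + h]] <- A
      out[, idx, n] <- (A * masks[[h]]) %*% V
    }
  }
  ag_record(out, list(q, k, v), function(g) {
    gq <- array(0, dim = d); gk <- array(0, dim = d); gv <- array(0, dim = d)
    for (n in seq_len(N)) {
      for (h in seq_len(heads)) {
        idx <- (h - 1L) * dh + seq_len(dh)
        Q <- qv[, idx, n, drop = FALSE]; dim(Q) <- c(Tn, dh)
        K <- kv[, idx, n, drop = FALSE]; dim(K) <- c(Tn, dh)
        V <- vv[, idx, n, drop = FALSE]; dim(V) <- c(Tn, dh)
        A <- A_store[[(n - 1L) * heads + h]]
        dO <- g[, idx, n, drop = FALSE]; dim(dO) <- c(Tn, dh)
        Am <- A * masks[[h]]
        gv[, idx, n] <- t(Am) %*% dO
        dA <- (dO %*% t(V)) * masks[[h]]
        dS <- A * (dA - rowSums(dA * A))
        gq[, idx, n] <- (dS %*% K) * scale
        gk[, idx, n] <- (t(dS) %*% Q) * scale
      }
    }
    list(gq, gk, gv)
  })
}

#' Manhattan self-attention forward pass
#'
#' Per head h: `out_h = (Softmax(Q_h K_h^T / sqrt(d_h)) * D(gamma_h)) V_h`
#' on row-major flattened tokens; heads are concatenated, linearly projected
#' and reshaped back to the feature-map layout.
#'
#' @param x Feature map tensor [N,C,H,W].
#' @param p Parameters from [masa_params()].
#' @return Feature map tensor of the same shape.
#' @export
masa_forward <- function(x, p) {
  v <- check_feature_map(x)
  C <- dim(v)[2L]; H <- dim(v)[3L]; W <- dim(v)[4L]
  if (C != p$channels)
    hemf_stop_config("MaSA channel mismatch")
  dh <- C %/% p$heads
  dist <- manhattan_distance_matrix(H, W)
  masks <- lapply(p$gammas, function(g) g^dist)
  q <- ag_to_tokens(fwd_conv(x, p$q_proj))
  k <- ag_to_tokens(fwd_conv(x, p$k_proj))
  vt <- ag_to_tokens(fwd_conv(x, p$v_proj))
  o <- ag_decay_attention(q, k, vt, masks, p$heads, 1 / sqrt(dh))
  fwd_conv(ag_from_tokens(o, H, W), p$out_proj)
}

#' Conditional position embedding
#'
#' Residual depthwise 3x3 convolution: `x + dw3x3(x)`. Applied once per
#' stage, before the first EGF block.
#'
#' @param x Feature map tensor [N,C,H,W].
#' @param dw Depthwise convolution parameters (from `nn_conv` with
#'   `groups = channels`).
#' @return Feature map tensor of the same shape.
#' @export
conditional_pos_embed <- function(x, dw) {
  v <- check_feature_map(x)
  C <- dim(v)[2L]
  if (dim(ag_value(dw$w))[1L] != C)
    hemf_stop_config("position-embedding channel mismatch")
  ag_add(x, ag_conv2d(x, dw$w, dw$b, pad = 1L, groups = C))
}

#' Parameters of one EGF block
#' @param channels Channel count.
#' @param heads Attention heads.
#' @param gammas Optional per-head decay values.
#' @return Named list of layer parameters.
#' @export
egf_block_params <- function(channels, heads, gammas = NULL) {
  list(
    channels = channels,
    masa = masa_params(channels, heads, gammas),
    ln1 = nn_ln(channels),
    linear = nn_conv(channels, channels, 1L),
    ln2 = nn_ln(channels)
  )
}

#' Forward pass of one EGF block
#' @param x Feature map tensor [N,C,H,W].
#' @param p Parameters from [egf_block_params()].
#' @param apply_pos Apply the position embedding before attention?
#' @param pos Position-embedding parameters (stage-level; required when
#'   `apply_pos` is TRUE).
#' @return Feature map tensor of the same shape.
#' @export
egf_block_forward <- function(x, p, apply_pos = FALSE, pos = NULL) {
  t <- if (apply_pos) conditional_pos_embed(x, pos) else x
  g <- fwd_ln(ag_add(masa_forward(t, p$masa), t), p$ln1)
  fwd_ln(ag_add(fwd_conv(g, p$linear), g), p$ln2)
}

#' Parameters of an EGF stage
#' @param channels Channel count.
#' @param heads Attention heads.
#' @param n_blocks Number of stacked blocks (default 3).
#' @param gammas Optional per-head decay values.
#' @return Named list with `entry_ln`, `pos` and `blocks`.
#' @export
egf_stage_params <- function(channels, heads, n_blocks = 3L, gammas = NULL) {
  if (n_blocks < 1L) hemf_stop_config("EGF stage needs at least one block")
  list(
    channels = channels,
    entry_ln = nn_ln(channels),
    pos = nn_conv(channels, channels, 3L, groups = channels),
    blocks = lapply(seq_len(n_blocks),
                    function(i) egf_block_params(channels, heads, gammas))
  )
}

#' Forward pass of an EGF stage
#'
#' Stage-entry layer normalization, then the block stack; the position
#' embedding is applied only in the first block.
#'
#' @param x Feature map tensor [N,C,H,W].
#' @param stage Parameters from [egf_stage_params()].
#' @return Feature map tensor of the same shape.
#' @export
egf_stage_forward <- function(x, stage) {
  if (length(stage$blocks) == 0L)
    hemf_stop_config("EGF stage has no blocks")
  h <- fwd_ln(x, stage$entry_ln)
  for (i in seq_along(stage$blocks)) {
    h <- egf_block_forward(h, stage$blocks[[i]], apply_pos = (i == 1L),
                           pos = stage$pos)
  }
  h
}
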