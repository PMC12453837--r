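# Mixed attention: multi-head external attention followed by spatial and
# channel gates, with multiplicative skip connections.
#
#   m_x = LN(MHEA(LN(x)) * LN(x))       (one shared LN(x), evaluated once)
#   m_y = m_x * SA(m_x)                 (gate broadcast over channels)
#   out = m_y * CA(m_y)                 (gate broadcast over space)
#
# External attention scores tokens against small learnable memory matrices
# M_k, M_v (shared across samples) and normalizes them by double
# normalization: softmax over the token axis per memory slot, then L1 over
# the memory axis per token. Each output token is therefore a convex
# combination of the rows of M_v.

#' Parameters of a spatial attention gate
#' @param kernel Convolution kernel size (default 7, padding kernel %/% 2).
#' @return Named list with the 2-to-1-channel convolution.
#' @export
spatial_attention_params <- function(kernel = 7L) {
  list(kernel = kernel, conv = nn_conv(2L, 1L, kernel))
}

#' Spatial attention gate
#'
#' `Sigmoid(conv(concat[channel-mean(x), channel-max(x)]))`, a one-channel
#' map in (0,1) highlighting salient spatial regions.
#'
#' @param x Feature map tensor [N,C,H,W].
#' @param p Parameters from [spatial_attention_params()].
#' @return Gate tensor [N,1,H,W].
#' @export
spatial_attention <- function(x, p) {
  check_feature_map(x)
  pooled <- ag_concat_ch(list(ag_mean_ch(x), ag_max_ch(x)))
  ag_sigmoid(fwd_conv(pooled, p$conv, pad = p$kernel %/% 2L))
}

#' Parameters of a channel attention gate
#' @param channels Channel count.
#' @param reduction Bottleneck reduction ratio (must divide `channels`).
#' @return Named list with the shared two-layer MLP.
#' @export
channel_attention_params <- function(channels, reduction = 16L) {
  if (channels %% reduction != 0L)
    hemf_stop_config("reduction ratio must divide channel count")
  list(
    channels = channels,
    fc1 = nn_linear(channels, channels %/% reduction),
    fc2 = nn_linear(channels %/% reduction, channels)
  )
}

#' Channel attention gate
#'
#' `Sigmoid(MLP(avgpool(x)) + MLP(maxpool(x)))` with a shared
#' C -> C/r -> C perceptron; a per-channel weight in (0,1).
#'
#' @param x Feature map tensor [N,C,H,W].
#' @param p Parameters from [channel_attention_params()].
#' @return Gate tensor [N,C,1,1].
#' @export
channel_attention <- function(x, p) {
  v <- check_feature_map(x)
  if (dim(v)[2L] != p$channels)
    hemf_stop_config("channel attention channel mismatch")
  mlp <- function(z) ag_linear(ag_relu(ag_linear(z, p$fc1$w, p$fc1$b)),
                               p$fc2$w, p$fc2$b)
  s <- ag_sigmoid(ag_add(mlp(ag_gap(x)), mlp(ag_gmp(x))))
  ag_reshape(s, c(dim(v)[1L], dim(v)[2L], 1L, 1L))
}

#' Parameters of one external-attention memory
#' @param d Per-head channel dimension.
#' @param memory Number of memory slots S.
#' @return Named list with `m_k` and `m_v` (S x d tensors).
#' @export
external_memory_params <- function(d, memory = 64L) {
  if (memory < 1L || d < 1L)
    hemf_stop_config("memory size and head dimension must be >= 1")
  list(
    m_k = ag_param(matrix(stats::rnorm(memory * d, 0, init_sd), memory, d)),
    m_v = ag_param(matrix(stats::rnorm(memory * d, 0, init_sd), memory, d))
  )
}

#' Single-head external attention on a token matrix
#'
#' Scores `tokens %*% t(M_k)` are double-normalized (softmax over the token
#' axis per memory slot, then L1 over the memory axis per token) and applied
#' to `M_v`. Each output row is a convex combination of the rows of `M_v`.
#'
#' @param tokens Matrix tensor [n_tokens, d].
#' @param mem Parameters from [external_memory_params()].
#' @return Matrix tensor [n_tokens, d].
#' @export
external_attention_head <- function(tokens, mem) {
  tv <- ag_value(tokens)
  if (nrow(tv) == 0L)
    hemf_stop_validation("external attention needs at least one token")
  if (ncol(tv) != ncol(ag_value(mem$m_k)))
    hemf_stop_config("token dimension does not match memory")
  scores <- ag_matmul(tokens, ag_record(t(ag_value(mem$m_k)), list(mem$m_k),
                                        function(g) list(t(g))))
  alpha <- ag_l1norm_rows(ag_softmax_cols(scores))
  ag_matmul(alpha, mem$m_v)
}

# Composite multi-head external attention on a token array [T, C, N].
# One tape entry; stores the column-softmax matrices for backward.
ag_mhea <- function(tokens, mems, heads) {
  tv <- ag_value(tokens)
  d3 <- dim(tv)
  Tn <- d3[1L]; C <- d3[2L]; N <- d3[3L]
  dh <- C %/% heads
  out <- array(0, dim = d3)
  A_store <- vector("list", N * heads)
  for (n in seq_len(N)) {
    for (h in seq_len(heads)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      X <- tv[, idx, n, drop = FALSE]; dim(X) <- c(Tn, dh)
      Mk <- ag_value(mems[[h]]$m_k); Mv <- ag_value(mems[[h]]$m_v)
      S <- X %*% t(Mk)                           # T x S
      E <- exp(sweep(S, 2L, apply(S, 2L, max)))
      A <- sweep(E, 2L, colSums(E), "/")         # softmax over tokens
      A_store[[(n - 1L) * heads + h]] <- A
      alpha <- A / rowSums(A)                    # L1 over memory slots
      out[, idx, n] <- alpha %*% Mv
    }
  }
  inputs <- c(list(tokens),
              lapply(mems, `[[`, "m_k"),
              lapply(mems, `[[`, "m_v"))
  ag_record(out, inputs, function(g) {
    gt <- array(0, dim = d3)
    gmk <- lapply(mems, function(m) 0 * ag_value(m$m_k))
    gmv <- lapply(mems, function(m) 0 * ag_value(m$m_v))
    for (n in seq_len(N)) {
      for (h in seq_len(heads)) {
        idx <- (h - 1L) * dh + seq_len(dh)
        X <- tv[, idx, n, drop = FALSE]; dim(X) <- c(Tn, dh)
        Mk <- ag_value(mems[[h]]$m_k); Mv <- ag_value(mems[[h]]$m_v)
        A <- A_store[[(n - 1L) * heads + h]]
        r <- rowSums(A)
        alpha <- A / r
        dO <- g[, idx, n, drop = FALSE]; dim(dO) <- c(Tn, dh)
        gmv[[h]] <- gmv[[h]] + t(alpha) %*% dO
        dalpha <- dO %*% t(Mv)
        dA <- dalpha / r - rowSums(dalpha * A) / r^2
        dS <- A * sweep(dA, 2L, colSums(dA * A))
        gt[, idx, n] <- dS %*% Mk
        gmk[[h]] <- gmk[[h]] + t(dS) %*% X
      }
    }
    c(list(gt), gmk, gmv)
  })
}

#' Parameters of a multi-head external attention layer
#' @param channels Channel count.
#' @param heads Number of heads (must divide `channels`).
#' @param memory Memory slots per head.
#' @return Named list with per-head memories.
#' @export
mhea_params <- function(channels, heads, memory = 64L) {
  if (channels %% heads != 0L)
    hemf_stop_config("head count must divide channel count")
  list(
    channels = channels, heads = heads, memory = memory,
    memories = lapply(seq_len(heads), function(h)
      external_memory_params(channels %/% heads, memory))
  )
}

#' Multi-head external attention forward pass
#'
#' Channels are split into head groups; each group attends to its own
#' memory via [external_attention_head()] semantics; results are
#' concatenated and reshaped back to the feature-map layout.
#'
#' @param x Feature map tensor [N,C,H,W].
#' @param p Parameters from [mhea_params()].
#' @return Feature map tensor of the same shape.
#' @export
mhea_forward <- function(x, p) {
  v <- check_feature_map(x)
  if (dim(v)[2L] != p$channels)
    hemf_stop_config("MHEA channel mismatch")
  o <- ag_mhea(ag_to_tokens(x), p$memories, p$heads)
  ag_from_tokens(o, dim(v)[3L], dim(v)[4L])
}

#' Parameters of a mixed attention module
#' @param channels Channel count.
#' @param heads External-attention heads.
#' @param memory Memory slots per head.
#' @param reduction Channel-attention reduction ratio.
#' @return Named list of sub-module parameters.
#' @export
mixed_attention_params <- function(channels, heads, memory = 64L,
                                   reduction = 16L) {
  list(
    channels = channels,
    ln_in = nn_ln(channels),
    ln_out = nn_ln(channels),
    mhea = mhea_params(channels, heads, memory),
    sa = spatial_attention_params(),
    ca = channel_attention_params(channels, reduction)
  )
}

#' Mixed attention forward pass
#' @param x Feature map tensor [N,C,H,W].
#' @param p Parameters from [mixed_attention_params()].
#' @return Feature map tensor of the same shape.
#' @export
mixed_attention_forward <- function(x, p) {
  lnx <- fwd_ln(x, p$ln_in)
  m_x <- fwd_ln(ag_mul(mhea_forward(lnx, p$mhea), lnx), p$ln_out)
  m_y <- ag_mul_spatialgate(m_x, spatial_attention(m_x, p$sa))
  ag_mul_changate(m_y, channel_attention(m_y, p$ca))
}
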