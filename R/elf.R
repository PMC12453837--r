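# Enhanced local feature (ELF) branch.
#
# Each block refines a feature map with a 3x3 standard convolution followed
# by channel-wise layer normalization, a 3x3 depthwise + 1x1 pointwise pair,
# a GELU, and an identity skip from the block input:
#
#   l   = LN(conv3x3(x))
#   out = GELU(pw1x1(dw3x3(l))) + x
#
# All convolutions preserve the channel count and (with padding 1 on the 3x3
# kernels) the spatial size, so the skip connection is always well-typed.
# A stage applies one shared layer normalization at entry and then a stack
# of blocks.

#' Parameters of one ELF block
#' @param channels Channel count the block operates on.
#' @return Named list of layer parameters.
#' @export
elf_block_params <- function(channels) {
  list(
    channels = channels,
    std_conv = nn_conv(channels, channels, 3L),
    ln = nn_ln(channels),
    dw_conv = nn_conv(channels, channels, 3L, groups = channels),
    pw_conv = nn_conv(channels, channels, 1L)
  )
}

#' Forward pass of one ELF block
#' @param x Feature map tensor [N,C,H,W].
#' @param p Parameters from [elf_block_params()].
#' @return Feature map tensor of the same shape.
#' @export
elf_block_forward <- function(x, p) {
  v <- check_feature_map(x)
  if (dim(v)[2L] != p$channels)
    hemf_stop_config(sprintf("ELF block built for %d channels, got %d",
                             p$channels, dim(v)[2L]))
  l <- fwd_ln(fwd_conv(x, p$std_conv, pad = 1L), p$ln)
  z <- fwd_conv(fwd_conv(l, p$dw_conv, pad = 1L, groups = p$channels), p$pw_conv)
  ag_add(ag_gelu(z), x)
}

#' Parameters of an ELF stage (entry LN + stacked blocks)
#' @param channels Channel count.
#' @param n_blocks Number of stacked blocks (default 4).
#' @return Named list with `entry_ln` and `blocks`.
#' @export
elf_stage_params <- function(channels, n_blocks = 4L) {
  if (n_blocks < 1L) hemf_stop_config("ELF stage needs at least one block")
  list(
    channels = channels,
    entry_ln = nn_ln(channels),
    blocks = lapply(seq_len(n_blocks), function(i) elf_block_params(channels))
  )
}

#' Forward pass of an ELF stage
#'
#' Applies the stage-entry layer normalization, then the block stack in
#' sequence.
#'
#' @param x Feature map tensor [N,C,H,W].
#' @param stage Parameters from [elf_stage_params()].
#' @return Feature map tensor of the same shape.
#' @export
elf_stage_forward <- function(x, stage) {
  if (length(stage$blocks) == 0L)
    hemf_stop_config("ELF stage has no blocks")
  h <- fwd_ln(x, stage$entry_ln)
  for (b in stage$blocks) h <- elf_block_forward(h, b)
  h
}
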