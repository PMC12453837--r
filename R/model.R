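# Full model assembly: stem, four dual-branch stages with per-stage fusion,
# classification head, and the parameter/FLOP accounting that mirrors the
# forward pass.
#
# Geometry for a 224x224x3 input: the 4x4/stride-4 stem emits 96 channels at
# 56x56; each later stage halves the spatial side (area /4) and doubles the
# channels, ending at 7x7x768 before global average pooling, layer
# normalization and the linear head.

#' Model configuration
#'
#' @param num_classes Number of output classes (>= 2).
#' @param input_size Square input resolution; must be divisible by 32.
#' @param in_channels Image channels (3 for RGB).
#' @param stem_width Stem output channels; must equal `stage_widths[1]`.
#' @param stage_widths Channel widths of the four stages; each entry must
#'   double the previous one.
#' @param elf_blocks_per_stage,egf_blocks_per_stage Blocks per stage in the
#'   local and global branches.
#' @param masa_heads,mhea_heads Per-stage head counts for decayed
#'   self-attention and external attention; default `max(1, width/32)`.
#' @param gammas Optional list of per-stage decay-value vectors (one value
#'   per head); defaults to the `1 - 2^-(5+h)` schedule.
#' @param ea_memory External-attention memory slots per head.
#' @param ca_reduction Channel-attention reduction ratio; must divide every
#'   stage width.
#' @param drop_path Stochastic-depth rate; only 0 is supported (the training
#'   recipe fixes it at 0) and the field exists as a forward-compatible hook.
#' @return An object of class `hemf_config`.
#' @export
hemf_config <- function(num_classes,
                        input_size = 224L,
                        in_channels = 3L,
                        stem_width = 96L,
                        stage_widths = c(96L, 192L, 384L, 768L),
                        elf_blocks_per_stage = 4L,
                        egf_blocks_per_stage = 3L,
                        masa_heads = NULL,
                        mhea_heads = NULL,
                        gammas = NULL,
                        ea_memory = 64L,
                        ca_reduction = 16L,
                        drop_path = 0) {
  if (num_classes < 2L) hemf_stop_config("num_classes must be >= 2")
  if (input_size %% 32L != 0L)
    hemf_stop_config("input_size must be divisible by 32")
  if (length(stage_widths) != 4L)
    hemf_stop_config("exactly four stage widths are required")
  if (any(stage_widths[-1L] != 2L * stage_widths[-4L]))
    hemf_stop_config("stage widths must double at each stage")
  if (stem_width != stage_widths[1L])
    hemf_stop_config("stem_width must equal the first stage width")
  if (is.null(masa_heads)) masa_heads <- pmax(1L, stage_widths %/% 32L)
  if (is.null(mhea_heads)) mhea_heads <- pmax(1L, stage_widths %/% 32L)
  if (any(stage_widths %% masa_heads != 0L) ||
      any(stage_widths %% mhea_heads != 0L))
    hemf_stop_config("head counts must divide stage widths")
  if (any(stage_widths %% ca_reduction != 0L))
    hemf_stop_config("ca_reduction must divide every stage width")
  if (!is.null(gammas)) {
    if (!is.list(gammas) || length(gammas) != 4L)
      hemf_stop_config("gammas must be a list of four per-stage vectors")
    for (i in 1:4)
      if (length(gammas[[i]]) != masa_heads[i])
        hemf_stop_config("need one gamma per attention head")
  }
  if (drop_path != 0) hemf_stop_config("only drop_path = 0 is supported")
  structure(list(
    num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    in_channels = as.integer(in_channels),
    stem_width = as.integer(stem_width),
    stage_widths = as.integer(stage_widths),
    elf_blocks_per_stage = as.integer(elf_blocks_per_stage),
    egf_blocks_per_stage = as.integer(egf_blocks_per_stage),
    masa_heads = as.integer(masa_heads),
    mhea_heads = as.integer(mhea_heads),
    gammas = gammas,
    ea_memory = as.integer(ea_memory),
    ca_reduction = as.integer(ca_reduction),
    drop_path = drop_path
  ), class = "hemf_config")
}

#' @export
print.hemf_config <- function(x, ...) {
  cat("hemf model configuration\n")
  cat("  input:", x$input_size, "x", x$input_size, "x", x$in_channels, "\n")
  cat("  stage widths:", paste(x$stage_widths, collapse = "/"),
      " heads:", paste(x$masa_heads, collapse = "/"), "\n")
  cat("  blocks/stage:", x$elf_blocks_per_stage, "local +",
      x$egf_blocks_per_stage, "global\n")
  cat("  classes:", x$num_classes, "\n")
  invisible(x)
}

#' Instantiate the model
#' @param config A `hemf_config`.
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `hemf_model` (nested parameter lists).
#' @export
hemf_model <- function(config, seed = NULL) {
  build <- function() {
    sw <- config$stage_widths
    stages <- vector("list", 4L)
    for (i in 1:4) {
      C <- sw[i]
      gam <- if (is.null(config$gammas)) NULL else config$gammas[[i]]
      stages[[i]] <- list(
        elf = elf_stage_params(C, config$elf_blocks_per_stage),
        egf = egf_stage_params(C, config$masa_heads[i],
                               config$egf_blocks_per_stage, gam),
        hef = hef_params(C, config$mhea_heads[i], config$ea_memory,
                         config$ca_reduction, is_first = (i == 1L))
      )
    }
    ds <- function(C) list(ln = nn_ln(C), conv = nn_conv(C, 2L * C, 2L))
    structure(list(
      config = config,
      stem = list(conv = nn_conv(config$in_channels, config$stem_width, 4L),
                  ln = nn_ln(config$stem_width)),
      stages = stages,
      ds_local = lapply(sw[1:3], ds),
      ds_global = lapply(sw[1:3], ds),
      head = list(ln = nn_ln(sw[4L]), linear = nn_linear(sw[4L], config$num_classes))
    ), class = "hemf_model")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Stem forward pass
#'
#' 4x4 convolution with stride 4 followed by channel layer normalization.
#' @param x Image tensor [N,3,S,S] with S divisible by 4.
#' @param p Stem parameters (`model$stem`).
#' @return Feature map [N, stem_width, S/4, S/4].
#' @export
stem_forward <- function(x, p) {
  v <- check_feature_map(x, "image batch")
  if (dim(v)[3L] %% 4L != 0L || dim(v)[4L] %% 4L != 0L)
    hemf_stop_validation("stem input size must be divisible by 4")
  fwd_ln(fwd_conv(x, p$conv, stride = 4L), p$ln)
}

#' Inter-stage downsampling
#'
#' Layer normalization then a 2x2 stride-2 convolution that doubles the
#' channels and halves each spatial side.
#' @param x Feature map [N,C,H,W] with even H and W.
#' @param p Downsample parameters (`ln` + `conv`).
#' @return Feature map [N,2C,H/2,W/2].
#' @export
downsample_forward <- function(x, p) {
  v <- check_feature_map(x)
  if (dim(v)[3L] %% 2L != 0L || dim(v)[4L] %% 2L != 0L)
    hemf_stop_validation("downsample needs even spatial size")
  fwd_conv(fwd_ln(x, p$ln), p$conv, stride = 2L)
}

#' Full forward pass
#'
#' @param model A `hemf_model`.
#' @param images Numeric array (or tensor) [N, in_channels, S, S] matching
#'   the configured input size.
#' @param return_features Also return the stem output and the four fusion
#'   outputs?
#' @return A logits matrix tensor [N, num_classes]; with
#'   `return_features = TRUE`, a list with elements `logits`, `stem`,
#'   `features`.
#' @export
hemf_forward <- function(model, images, return_features = FALSE) {
  cfg <- model$config
  v <- check_feature_map(images, "image batch")
  if (dim(v)[2L] != cfg$in_channels ||
      dim(v)[3L] != cfg$input_size || dim(v)[4L] != cfg$input_size)
    hemf_stop_config(sprintf(
      "expected [N,%d,%d,%d] input, got [%s]", cfg$in_channels,
      cfg$input_size, cfg$input_size, paste(dim(v), collapse = ",")))
  x <- if (inherits(images, "ag_tensor")) images else ag_tensor(images)
  stem <- stem_forward(x, model$stem)
  local <- stem; global <- stem; prev <- stem
  feats <- vector("list", 4L)
  for (i in 1:4) {
    if (i > 1L) {
      local <- downsample_forward(local, model$ds_local[[i - 1L]])
      global <- downsample_forward(global, model$ds_global[[i - 1L]])
    }
    L <- elf_stage_forward(local, model$stages[[i]]$elf)
    G <- egf_stage_forward(global, model$stages[[i]]$egf)
    fused <- hef_block_forward(L, G, prev, model$stages[[i]]$hef)
    local <- L; global <- G; prev <- fused
    feats[[i]] <- fused
  }
  pooled <- fwd_ln(ag_gap(prev), model$head$ln)
  logits <- ag_linear(pooled, model$head$linear$w, model$head$linear$b)
  if (any(!is.finite(ag_value(logits))))
    hemf_stop_validation("forward pass produced non-finite logits")
  if (return_features) list(logits = logits, stem = stem, features = feats)
  else logits
}

#' Flat list of trainable parameters
#' @param model A `hemf_model`.
#' @return Named list of `ag_tensor` parameters (names are paths).
#' @export
hemf_parameters <- function(model) collect_params(unclass(model))

# ---- accounting ------------------------------------------------------------

mixattn_param_count <- function(C, S, r) {
  # ln_in + ln_out + per-head memories (2*S*C total) + SA conv + CA MLP
  4 * C + 2 * S * C + (2 * 49 + 1) +
    (C * (C / r) + C / r) + ((C / r) * C + C)
}

#' Closed-form trainable parameter count
#'
#' Exact total of trainable scalars, derived analytically from the layer
#' shapes (independently of model construction; the test suite checks it
#' against enumeration of an instantiated model).
#'
#' @param config A `hemf_config`.
#' @return Total parameter count (numeric, integer-valued).
#' @export
count_parameters <- function(config) {
  sw <- config$stage_widths
  S <- config$ea_memory; r <- config$ca_reduction
  K <- config$num_classes
  total <- 0
  # stem: conv 4x4 in->96 + LN
  total <- total + 16 * config$in_channels * config$stem_width +
    config$stem_width + 2 * config$stem_width
  for (i in 1:4) {
    C <- sw[i]
    elf_block <- (9 * C^2 + C) + 2 * C + (9 * C + C) + (C^2 + C)
    total <- total + 2 * C + config$elf_blocks_per_stage * elf_block
    egf_block <- 4 * (C^2 + C) + 2 * C + (C^2 + C) + 2 * C
    total <- total + 2 * C + (9 * C + C) +
      config$egf_blocks_per_stage * egf_block
    prev_in <- if (i == 1L) C else C / 2
    hef <- (prev_in * C + C) + 2 * (C^2 + C) + 6 * C + (3 * C^2 + C) +
      6 * C + 2 * mixattn_param_count(C, S, r) + sirmlp_param_count(C)
    total <- total + hef
    if (i < 4L) total <- total + 2 * (2 * C + 8 * C^2 + 2 * C)  # two streams
  }
  total + 2 * sw[4L] + sw[4L] * K + K
}

#' Closed-form forward-pass FLOP count (multiply-accumulate convention)
#'
#' Counts one MAC per multiply-accumulate: convolutions as
#' `k^2 C_in C_out H_out W_out / groups`, linears as `n d_in d_out`,
#' attention matmuls as `T^2 d` per head for both the score and the value
#' product, external attention as `T S d` per head per matmul. Elementwise
#' operations, normalizations, softmax and pooling are excluded.
#'
#' @param config A `hemf_config`.
#' @param input_size Input resolution (defaults to the configured one).
#' @param batch Batch size (default 1).
#' @return Total MAC count (numeric, integer-valued).
#' @export
count_flops <- function(config, input_size = config$input_size, batch = 1L) {
  if (input_size %% 32L != 0L)
    hemf_stop_config("input_size must be divisible by 32")
  sw <- config$stage_widths
  S <- config$ea_memory; r <- config$ca_reduction
  side <- input_size %/% 4L
  total <- 16 * config$in_channels * config$stem_width * side^2  # stem
  for (i in 1:4) {
    C <- sw[i]
    hw <- side^2
    tok <- hw
    # local branch
    elf_block <- (9 * C^2 + 9 * C + C^2) * hw
    total <- total + config$elf_blocks_per_stage * elf_block
    # global branch: position embedding + blocks
    total <- total + 9 * C * hw
    egf_block <- 4 * C^2 * hw + 2 * tok^2 * C + C^2 * hw
    total <- total + config$egf_blocks_per_stage * egf_block
    # fusion
    mixattn <- 2 * tok * S * C + 49 * 2 * hw + 4 * C^2 / r
    prev_proj <- if (i == 1L) C^2 * hw else (C / 2) * C * (4 * hw)
    total <- total + prev_proj + 2 * C^2 * hw + 3 * C^2 * hw +
      2 * mixattn + sirmlp_flop_count(C, hw)
    # two downsampling streams between stages
    if (i < 4L) total <- total + 2 * (4 * C * 2 * C * (hw / 4))
    side <- side %/% 2L
  }
  total <- total + sw[4L] * config$num_classes  # head
  batch * total
}

#' Per-stage SIRMLP-vs-IRMLP profile and whole-model totals
#'
#' Builds the four-row comparison of fusion-block parameter and MAC counts
#' against the inverted-residual-MLP baseline, plus whole-model totals.
#'
#' @param config A `hemf_config`.
#' @param input_size Input resolution for the FLOP columns.
#' @return An object of class `hemf_profile` with elements `blocks`
#'   (data.frame), `total_params`, `total_flops`.
#' @export
profile_table <- function(config, input_size = config$input_size) {
  sw <- config$stage_widths
  side <- input_size %/% 4L
  rows <- vector("list", 4L)
  for (i in 1:4) {
    C <- sw[i]
    hw <- side^2
    sp <- sirmlp_param_count(C); ip <- irmlp_param_count(C)
    sf <- sirmlp_flop_count(C, hw); iff <- irmlp_flop_count(C, hw)
    rows[[i]] <- data.frame(
      layer = i,
      input_shape = sprintf("[%dx3, %d, %d]", C, side, side),
      sirmlp_params = sp, irmlp_params = ip,
      decline_pct = 100 * (1 - sp / ip),
      sirmlp_flops = sf, irmlp_flops = iff,
      flops_decline_pct = 100 * (1 - sf / iff),
      stringsAsFactors = FALSE
    )
    side <- side %/% 2L
  }
  structure(list(
    blocks = do.call(rbind, rows),
    total_params = count_parameters(config),
    total_flops = count_flops(config, input_size)
  ), class = "hemf_profile")
}

#' @export
print.hemf_profile <- function(x, ...) {
  cat("Per-stage fusion block comparison (params exact, FLOPs = MACs):\n")
  print(x$blocks, row.names = FALSE)
  cat(sprintf("Total parameters: %d (%.2fM)\n", x$total_params,
              x$total_params / 1e6))
  cat(sprintf("Total forward MACs (1 MAC = 1 FLOP): %.0f (%.2fG)\n",
              x$total_flops, x$total_flops / 1e9))
  invisible(x)
}

#' Write a profile report as CSV
#'
#' The first line states the FLOP convention (1 MAC = 1 FLOP), since
#' published counters differ by a factor of two.
#'
#' @param report A `hemf_profile`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# FLOP convention: 1 MAC = 1 FLOP",
               sprintf("# total_params,%d", report$total_params),
               sprintf("# total_flops,%.0f", report$total_flops)), con)
  utils::write.csv(report$blocks, con, row.names = FALSE)
  invisible(path)
}

# ---- checkpoints -----------------------------------------------------------

.ckpt_format <- "hemf_checkpoint"
.ckpt_version <- 1L

#' Save model parameters and configuration
#'
#' The checkpoint is a single versioned binary file whose round trip is
#' bit-exact for every parameter, batch-norm running statistic and
#' configuration field.
#'
#' @param model A `hemf_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  flat <- hemf_parameters(model)
  bn <- collect_bn_states(unclass(model))
  obj <- list(
    format = .ckpt_format,
    version = .ckpt_version,
    config = model$config,
    params = lapply(flat, ag_value),
    bn = lapply(bn, function(e) list(running_mean = e$running_mean,
                                     running_var = e$running_var))
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint
#' @param path Checkpoint file path.
#' @return A `hemf_model` with restored parameters and running statistics.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    hemf_stop_validation(sprintf("cannot read checkpoint '%s': %s",
                                 path, conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, .ckpt_format))
    hemf_stop_validation("not a model checkpoint file")
  if (!identical(obj$version, .ckpt_version))
    hemf_stop_validation(sprintf("unsupported checkpoint version %s",
                                 format(obj$version)))
  model <- hemf_model(obj$config)
  flat <- hemf_parameters(model)
  if (!setequal(names(flat), names(obj$params)))
    hemf_stop_validation("checkpoint parameters do not match the model")
  for (nm in names(flat)) {
    val <- obj$params[[nm]]
    if (!identical(dim(ag_value(flat[[nm]])), dim(val)) ||
        length(ag_value(flat[[nm]])) != length(val))
      hemf_stop_validation(sprintf("checkpoint shape mismatch at '%s'", nm))
    flat[[nm]]$v <- val
  }
  bn <- collect_bn_states(unclass(model))
  for (nm in names(bn)) {
    st <- obj$bn[[nm]]
    if (is.null(st))
      hemf_stop_validation(sprintf("checkpoint missing batch-norm state '%s'", nm))
    bn[[nm]]$running_mean <- st$running_mean
    bn[[nm]]$running_var <- st$running_var
  }
  model
}
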