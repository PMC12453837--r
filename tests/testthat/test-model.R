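# Whole-model assembly: configuration validation, stem/downsample geometry,
# closed-form accounting against enumeration, checkpoint round trips,
# determinism and gradient completeness.

test_that("configuration invariants are enforced", {
  expect_error(hemf_config(num_classes = 1L), class = "hemf_config_error")
  expect_error(hemf_config(num_classes = 2L, input_size = 100L),
               class = "hemf_config_error")
  expect_error(hemf_config(num_classes = 2L,
                           stage_widths = c(96L, 192L, 384L, 700L)),
               class = "hemf_config_error")
  expect_error(hemf_config(num_classes = 2L, stem_width = 48L),
               class = "hemf_config_error")
  expect_error(hemf_config(num_classes = 2L, masa_heads = c(5L, 5L, 5L, 5L)),
               class = "hemf_config_error")
  expect_error(hemf_config(num_classes = 2L, drop_path = 0.1),
               class = "hemf_config_error")
  cfg <- hemf_config(num_classes = 7L)
  expect_identical(cfg$stage_widths, c(96L, 192L, 384L, 768L))
  expect_identical(cfg$masa_heads, c(3L, 6L, 12L, 24L))
})

test_that("stem and downsampling implement the stage geometry arithmetic", {
  set.seed(601)
  stem <- list(conv = hemf:::nn_conv(3L, 8L, 4L), ln = hemf:::nn_ln(8L))
  x <- array(rnorm(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  out <- ag_no_grad(ag_value(stem_forward(ag_tensor(x), stem)))
  expect_identical(dim(out), c(2L, 8L, 16L, 16L))

  zero_all_params(stem)
  z <- ag_no_grad(ag_value(stem_forward(ag_tensor(x), stem)))
  expect_true(all(z == 0))

  ds <- list(ln = hemf:::nn_ln(8L), conv = hemf:::nn_conv(8L, 16L, 2L))
  y <- ag_no_grad(ag_value(downsample_forward(ag_tensor(out), ds)))
  expect_identical(dim(y), c(2L, 16L, 8L, 8L))
  ds2 <- list(ln = hemf:::nn_ln(16L), conv = hemf:::nn_conv(16L, 32L, 2L))
  y2 <- ag_no_grad(ag_value(downsample_forward(ag_tensor(y), ds2)))
  expect_identical(dim(y2), c(2L, 32L, 4L, 4L))

  expect_error(downsample_forward(ag_tensor(array(0, c(1, 8, 5, 5))), ds),
               class = "hemf_validation_error")
  expect_error(stem_forward(ag_tensor(array(0, c(1, 3, 30, 30))), stem),
               class = "hemf_validation_error")
})

test_that("closed-form parameter count equals enumeration over varied configurations", {
  set.seed(602)
  configs <- list(
    tiny_config(),
    hemf_config(num_classes = 3L, input_size = 32L, stem_width = 8L,
                stage_widths = c(8L, 16L, 32L, 64L),
                masa_heads = c(1L, 2L, 2L, 4L), mhea_heads = c(1L, 1L, 2L, 2L),
                ea_memory = 7L, ca_reduction = 8L),
    hemf_config(num_classes = 11L, input_size = 64L, stem_width = 12L,
                stage_widths = c(12L, 24L, 48L, 96L),
                masa_heads = c(1L, 2L, 4L, 4L), mhea_heads = c(2L, 2L, 4L, 8L),
                ea_memory = 5L, ca_reduction = 12L),
    hemf_config(num_classes = 2L, input_size = 32L, stem_width = 16L,
                stage_widths = c(16L, 32L, 64L, 128L),
                elf_blocks_per_stage = 2L, egf_blocks_per_stage = 2L,
                masa_heads = c(1L, 1L, 2L, 4L), mhea_heads = c(1L, 1L, 2L, 4L),
                ea_memory = 16L, ca_reduction = 16L)
  )
  for (cfg in configs) {
    m <- hemf_model(cfg)
    enum <- sum(vapply(hemf_parameters(m), function(p) length(ag_value(p)),
                       numeric(1)))
    expect_equal(count_parameters(cfg), enum)
  }
})

test_that("MAC count matches an independent hand-derived per-layer sum", {
  cfg <- tiny_config(num_classes = 2L, input_size = 32L)
  # independent derivation, layer by layer, for widths 8/16/32/64 at 32x32
  sides <- c(8L, 4L, 2L, 1L)
  widths <- c(8L, 16L, 32L, 64L)
  S <- 4; r <- 4
  ref <- 16 * 3 * 8 * 8^2                       # stem: 4x4/4 conv, 8x8 out
  for (i in 1:4) {
    C <- widths[i]; hw <- sides[i]^2
    ref <- ref + 4 * ((9 * C^2 + 9 * C + C^2) * hw) +         # 4 conv blocks
      9 * C * hw +                                            # pos embed
      3 * (4 * C^2 * hw + 2 * hw^2 * C + C^2 * hw)            # 3 attn blocks
    ma <- 2 * hw * S * C + 98 * hw + 4 * C^2 / r              # mixed attention
    pp <- if (i == 1) C^2 * hw else (C / 2) * C * 4 * hw      # prev projection
    ref <- ref + pp + 2 * C^2 * hw + 3 * C^2 * hw + 2 * ma +
      (11 * C^2 + 9 * C) * hw                                 # fusion + SIRMLP
    if (i < 4)                                                # two 2x2/2 streams
      ref <- ref + 2 * (4 * C * (2 * C) * (sides[i] / 2)^2)
  }
  ref <- ref + 64 * 2                                         # head
  expect_equal(count_flops(cfg), ref)

  # a lone 1x1 convolution 96 -> 96 on a 56x56 map costs 96*96*56*56 MACs
  expect_equal(96 * 96 * 56 * 56, 28901376)
})

test_that("forward pass is deterministic, shape-correct and batch-equivariant", {
  cfg <- tiny_config(num_classes = 3L, input_size = 32L)
  m1 <- hemf_model(cfg, seed = 9L)
  m2 <- hemf_model(cfg, seed = 9L)
  x <- withr::with_seed(10L, array(rnorm(4 * 3 * 32 * 32), c(4, 3, 32, 32)))
  l1 <- ag_no_grad(ag_value(hemf_forward(m1, x)))
  l2 <- ag_no_grad(ag_value(hemf_forward(m2, x)))
  expect_identical(l1, l2)
  expect_identical(dim(l1), c(4L, 3L))

  perm <- c(3L, 1L, 4L, 2L)
  lp <- ag_no_grad(ag_value(hemf_forward(m1, x[perm, , , , drop = FALSE])))
  expect_equal(lp, l1[perm, ], tolerance = 1e-10)

  expect_error(hemf_forward(m1, array(0, c(1, 3, 64, 64))),
               class = "hemf_config_error")
})

test_that("every registered parameter receives a nonzero gradient", {
  # input 64 keeps >= 4 tokens in the last stage; with a single token the
  # attention softmax is constant and Q/K gradients vanish structurally
  cfg <- tiny_config(num_classes = 2L, input_size = 64L)
  m <- hemf_model(cfg, seed = 2L)
  params <- hemf_parameters(m)
  x <- withr::with_seed(3L, array(rnorm(2 * 3 * 64 * 64), c(2, 3, 64, 64)))
  ag_set_training(TRUE)
  ag_tape_reset()
  loss <- ag_cce(hemf_forward(m, x), c(0L, 1L))
  ag_zero_grad(params)
  ag_backward(loss)
  ag_set_training(FALSE)
  dead <- names(params)[vapply(params, function(p)
    is.null(p$g) || all(p$g == 0), logical(1))]
  expect_identical(dead, character(0))
})

test_that("checkpoints round-trip bitwise and reject corrupt files", {
  cfg <- tiny_config(num_classes = 2L, input_size = 32L)
  m <- hemf_model(cfg, seed = 4L)
  x <- withr::with_seed(5L, array(rnorm(1 * 3 * 32 * 32), c(1, 3, 32, 32)))
  before <- ag_no_grad(ag_value(hemf_forward(m, x)))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  after <- ag_no_grad(ag_value(hemf_forward(m2, x)))
  expect_identical(after, before)
  expect_identical(m2$config, m$config)

  # truncated file: an explicit load error, never silent garbage
  raw <- readBin(path, "raw", file.size(path))
  trunc_path <- tempfile(fileext = ".rds")
  writeBin(raw[seq_len(length(raw) %/% 2)], trunc_path)
  expect_error(load_checkpoint(trunc_path), class = "hemf_validation_error")

  # wrong format / version
  other <- tempfile(fileext = ".rds")
  saveRDS(list(format = "something_else"), other)
  expect_error(load_checkpoint(other), class = "hemf_validation_error")
  vfile <- tempfile(fileext = ".rds")
  obj <- readRDS(path); obj$version <- 99L
  saveRDS(obj, vfile)
  expect_error(load_checkpoint(vfile), class = "hemf_validation_error")
})

test_that("profile table mirrors the four fusion widths and totals", {
  cfg <- hemf_config(num_classes = 7L)
  pt <- profile_table(cfg)
  expect_identical(nrow(pt$blocks), 4L)
  expect_identical(pt$blocks$input_shape,
                   c("[96x3, 56, 56]", "[192x3, 28, 28]",
                     "[384x3, 14, 14]", "[768x3, 7, 7]"))
  expect_true(all(pt$blocks$decline_pct >= 84 & pt$blocks$decline_pct <= 86))
  expect_true(all(pt$blocks$flops_decline_pct >= 84 &
                    pt$blocks$flops_decline_pct <= 86))
  expect_identical(pt$total_params, count_parameters(cfg))
  expect_identical(pt$total_flops, count_flops(cfg))

  csv <- tempfile(fileext = ".csv")
  write_profile_csv(pt, csv)
  lines <- readLines(csv)
  expect_match(lines[1], "1 MAC = 1 FLOP")
  tab <- utils::read.csv(csv, comment.char = "#")
  expect_identical(nrow(tab), 4L)
})
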