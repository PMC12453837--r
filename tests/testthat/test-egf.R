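# Global branch: decay masks against brute force, decayed attention against
# an explicit-loop oracle, positional embedding, and block/stage wiring.

test_that("decay mask analytic values and validation", {
  m1 <- manhattan_decay_mask(3L, 2L, 1)
  expect_true(all(m1 == 1))

  m <- manhattan_decay_mask(2L, 2L, 0.5)
  # tokens row-major: 1=(0,0), 2=(1,0), 3=(0,1), 4=(1,1)
  expect_equal(m[1, 4], 0.25)
  expect_equal(m[1, 2], 0.5)
  expect_equal(m[1, 3], 0.5)
  expect_equal(diag(m), rep(1, 4))

  expect_error(manhattan_decay_mask(2L, 2L, 0), class = "hemf_validation_error")
  expect_error(manhattan_decay_mask(2L, 2L, 1.5), class = "hemf_validation_error")
  expect_error(manhattan_decay_mask(0L, 2L, 0.5), class = "hemf_validation_error")
})

test_that("decay masks equal a brute-force pairwise computation up to 5x5", {
  for (h in 1:5) for (w in 1:5) {
    gamma <- 0.9
    m <- manhattan_decay_mask(h, w, gamma)
    Tn <- h * w
    ref <- matrix(0, Tn, Tn)
    for (n in seq_len(Tn)) for (q in seq_len(Tn)) {
      xn <- (n - 1) %% w; yn <- (n - 1) %/% w
      xq <- (q - 1) %% w; yq <- (q - 1) %/% w
      ref[n, q] <- gamma^(abs(xn - xq) + abs(yn - yq))
    }
    expect_equal(unclass(m), ref, tolerance = 1e-14, ignore_attr = TRUE)
    # structural invariants
    expect_equal(m, t(m), ignore_attr = TRUE)
    expect_true(all(diag(m) == 1))
    expect_true(all(m > 0 & m <= 1))
  }
  # strict monotone decay in Manhattan distance (gamma < 1)
  m <- manhattan_decay_mask(5L, 5L, 0.8)
  d <- hemf:::manhattan_distance_matrix(5L, 5L)
  for (dist in 1:7)
    expect_true(max(m[d == dist]) > max(m[d == dist + 1]))
})

test_that("decayed self-attention equals the explicit-loop oracle on all grids up to 4x4", {
  set.seed(301)
  for (h in 1:4) for (w in 1:4) {
    p <- masa_params(4L, 2L)
    x <- array(rnorm(1 * 4 * h * w), c(1, 4, h, w))
    out <- ag_no_grad(ag_value(masa_forward(ag_tensor(x), p)))
    expect_equal(out, oracle_masa(x, p), tolerance = 1e-5,
                 info = sprintf("grid %dx%d", h, w))
  }
})

test_that("gamma = 1 attention degenerates to vanilla softmax attention", {
  set.seed(302)
  p <- masa_params(6L, 3L, gammas = rep(1, 3))
  x <- array(rnorm(1 * 6 * 3 * 3), c(1, 6, 3, 3))
  out <- ag_no_grad(ag_value(masa_forward(ag_tensor(x), p)))
  expect_equal(out, oracle_vanilla_attention(x, p), tolerance = 1e-6)
})

test_that("single-token attention returns the projected values regardless of Q and K", {
  set.seed(303)
  p <- masa_params(4L, 1L)
  x <- array(rnorm(4), c(1, 4, 1, 1))
  # scramble Q/K projections: the softmax over one token is always 1
  p$q_proj$w$v <- p$q_proj$w$v * 100
  p$k_proj$w$v <- p$k_proj$w$v * -50
  out <- ag_no_grad(ag_value(masa_forward(ag_tensor(x), p)))
  v <- conv1x1_as_matrix(p$v_proj) %*% x[1, , 1, 1] + ag_value(p$v_proj$b)
  expected <- conv1x1_as_matrix(p$out_proj) %*% v + ag_value(p$out_proj$b)
  expect_equal(as.numeric(out), as.numeric(expected), tolerance = 1e-10)
})

test_that("attention weights are a proper softmax before masking", {
  set.seed(304)
  # reconstructed from the oracle's intermediates: rows sum to 1, masked
  # weights stay nonnegative
  p <- masa_params(4L, 1L)
  x <- array(rnorm(1 * 4 * 3 * 3), c(1, 4, 3, 3))
  tok <- tokens_of(x, 1L)
  q <- sweep(tok %*% t(conv1x1_as_matrix(p$q_proj)), 2, as.numeric(ag_value(p$q_proj$b)), "+")
  k <- sweep(tok %*% t(conv1x1_as_matrix(p$k_proj)), 2, as.numeric(ag_value(p$k_proj$b)), "+")
  s <- q %*% t(k) / sqrt(4)
  a <- exp(s - apply(s, 1, max)); a <- a / rowSums(a)
  expect_equal(rowSums(a), rep(1, 9), tolerance = 1e-12)
  expect_true(all(a * manhattan_decay_mask(3L, 3L, p$gammas[1]) >= 0))
})

test_that("conditional position embedding is a residual depthwise convolution", {
  set.seed(305)
  dw <- hemf:::nn_conv(3L, 3L, 3L, groups = 3L)
  zero_all_params(dw)
  x <- array(rnorm(1 * 3 * 4 * 4), c(1, 3, 4, 4))
  expect_identical(ag_no_grad(ag_value(conditional_pos_embed(ag_tensor(x), dw))), x)

  # constant input: interior pixels see the full kernel sum s -> c * (1 + s)
  dw2 <- hemf:::nn_conv(1L, 1L, 3L, groups = 1L)
  s <- sum(ag_value(dw2$w))
  cc <- 0.7
  xc <- array(cc, c(1, 1, 5, 5))
  out <- ag_no_grad(ag_value(conditional_pos_embed(ag_tensor(xc), dw2)))
  expect_equal(out[1, 1, 3, 3], cc * (1 + s) + ag_value(dw2$b), tolerance = 1e-12)

  x96 <- array(rnorm(1 * 96 * 8 * 8), c(1, 96, 8, 8))
  dw96 <- hemf:::nn_conv(96L, 96L, 3L, groups = 96L)
  expect_identical(dim(ag_no_grad(ag_value(conditional_pos_embed(ag_tensor(x96), dw96)))),
                   c(1L, 96L, 8L, 8L))
})

test_that("zero-weight EGF block is transparent for channel-normalized input", {
  set.seed(306)
  st <- egf_stage_params(4L, 1L, n_blocks = 3L)
  for (b in st$blocks) {
    zero_all_params(b)
    b$ln1$gamma$v <- rep(1, 4)   # keep the normalizations as near-identities
    b$ln2$gamma$v <- rep(1, 4)
  }
  zero_all_params(st$pos)
  x <- ln_neutral_input(c(2, 4, 3, 3))
  out <- ag_no_grad(ag_value(egf_block_forward(ag_tensor(x), st$blocks[[1]],
                                               apply_pos = TRUE, pos = st$pos)))
  expect_equal(out, x, tolerance = 1e-5)
  # whole zero stage (entry LN re-normalizes, blocks stay transparent)
  outs <- ag_no_grad(ag_value(egf_stage_forward(ag_tensor(x), st)))
  expect_equal(outs, x, tolerance = 1e-5)
})

test_that("an EGF stage composes blocks with position embedding only in the first", {
  set.seed(307)
  st <- egf_stage_params(4L, 2L, n_blocks = 3L)
  x <- array(rnorm(2 * 4 * 3 * 3), c(2, 4, 3, 3))
  out <- ag_no_grad(ag_value(egf_stage_forward(ag_tensor(x), st)))
  manual <- ag_no_grad({
    h <- ag_layernorm(ag_tensor(x), st$entry_ln$gamma, st$entry_ln$beta)
    h <- egf_block_forward(h, st$blocks[[1]], apply_pos = TRUE, pos = st$pos)
    h <- egf_block_forward(h, st$blocks[[2]], apply_pos = FALSE)
    h <- egf_block_forward(h, st$blocks[[3]], apply_pos = FALSE)
    ag_value(h)
  })
  expect_equal(out, manual, tolerance = 1e-12)

  # the pos-embed parameters matter only once: doubling them changes the
  # stage output, while a second application inside later blocks would
  # change `manual` built above -- equality proves single use
  st1 <- egf_stage_params(4L, 2L, n_blocks = 1L)
  out1 <- ag_no_grad(ag_value(egf_stage_forward(ag_tensor(x), st1)))
  manual1 <- ag_no_grad(ag_value(egf_block_forward(
    ag_layernorm(ag_tensor(x), st1$entry_ln$gamma, st1$entry_ln$beta),
    st1$blocks[[1]], apply_pos = TRUE, pos = st1$pos)))
  expect_equal(out1, manual1, tolerance = 1e-12)
})

test_that("attention configuration errors are raised", {
  expect_error(masa_params(5L, 2L), class = "hemf_config_error")
  expect_error(masa_params(4L, 2L, gammas = c(0.5, 1.5)),
               class = "hemf_config_error")
  p <- masa_params(4L, 2L)
  expect_error(masa_forward(ag_tensor(array(0, c(1, 6, 2, 2))), p),
               class = "hemf_config_error")
})
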