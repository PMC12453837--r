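# Mixed attention: gate ranges and scalar oracles, external attention
# double normalization, head decomposition, and the gating topology.

test_that("spatial attention gate range, shape and zero-weight value", {
  set.seed(401)
  p <- spatial_attention_params()
  x <- array(rnorm(2 * 6 * 5 * 5), c(2, 6, 5, 5))
  s <- ag_no_grad(ag_value(spatial_attention(ag_tensor(x), p)))
  expect_identical(dim(s), c(2L, 1L, 5L, 5L))
  expect_true(all(s > 0 & s < 1))

  zero_all_params(p)
  s0 <- ag_no_grad(ag_value(spatial_attention(ag_tensor(x), p)))
  expect_true(all(s0 == 0.5))
})

test_that("spatial attention on one pixel reduces to scalar arithmetic", {
  set.seed(402)
  p <- spatial_attention_params()
  x <- array(c(0.3, -0.9, 0.5), c(1, 3, 1, 1))
  w <- ag_value(p$conv$w)     # [1, 2, 7, 7]; only the center tap sees data
  b <- as.numeric(ag_value(p$conv$b))
  expected <- plogis(w[1, 1, 4, 4] * mean(x) + w[1, 2, 4, 4] * max(x) + b)
  s <- ag_no_grad(ag_value(spatial_attention(ag_tensor(x), p)))
  expect_equal(as.numeric(s), expected, tolerance = 1e-12)
})

test_that("channel attention gate: zero weights, constant input, scalar oracle", {
  set.seed(403)
  p <- channel_attention_params(4L, reduction = 2L)
  x <- array(rnorm(2 * 4 * 3 * 3), c(2, 4, 3, 3))
  s <- ag_no_grad(ag_value(channel_attention(ag_tensor(x), p)))
  expect_identical(dim(s), c(2L, 4L, 1L, 1L))
  expect_true(all(s > 0 & s < 1))

  zero_all_params(p)
  s0 <- ag_no_grad(ag_value(channel_attention(ag_tensor(x), p)))
  expect_true(all(s0 == 0.5))

  # constant per channel: avg pool equals max pool, so the two MLP passes agree
  p2 <- channel_attention_params(2L, reduction = 2L)
  cc <- c(0.4, -1.1)
  xc <- array(0, c(1, 2, 3, 3))
  xc[1, 1, , ] <- cc[1]; xc[1, 2, , ] <- cc[2]
  mlp <- function(v) {
    h <- pmax(ag_value(p2$fc1$w) %*% v + ag_value(p2$fc1$b), 0)
    ag_value(p2$fc2$w) %*% h + ag_value(p2$fc2$b)
  }
  expected <- plogis(2 * mlp(cc))
  s2 <- ag_no_grad(ag_value(channel_attention(ag_tensor(xc), p2)))
  expect_equal(as.numeric(s2), as.numeric(expected), tolerance = 1e-10)
})

test_that("external attention double normalization: degeneracies and hand oracle", {
  set.seed(404)
  mem <- external_memory_params(3L, memory = 5L)
  # zero tokens -> uniform attention -> column mean of M_v
  tok <- matrix(0, 4, 3)
  out <- ag_no_grad(ag_value(external_attention_head(ag_tensor(tok), mem)))
  cm <- colMeans(ag_value(mem$m_v))
  for (i in 1:4) expect_equal(out[i, ], cm, tolerance = 1e-12)

  # a single token: softmax over one token gives 1 per slot, alpha = 1/S
  tok1 <- matrix(rnorm(3), 1, 3)
  out1 <- ag_no_grad(ag_value(external_attention_head(ag_tensor(tok1), mem)))
  expect_equal(as.numeric(out1), cm, tolerance = 1e-12)

  # N = 2, S = 2, d = 1 with small integers, normalized by hand
  mem2 <- list(m_k = ag_param(matrix(c(1, -1), 2, 1)),
               m_v = ag_param(matrix(c(2, 3), 2, 1)))
  tokens <- matrix(c(1, 2), 2, 1)
  s <- tokens %*% t(ag_value(mem2$m_k))          # [[1,-1],[2,-2]]
  a <- apply(s, 2, function(col) exp(col - max(col)) / sum(exp(col - max(col))))
  alpha <- a / rowSums(a)
  expected <- alpha %*% ag_value(mem2$m_v)
  out2 <- ag_no_grad(ag_value(external_attention_head(ag_tensor(tokens), mem2)))
  expect_equal(out2, expected, tolerance = 1e-12)
  expect_equal(rowSums(alpha), c(1, 1), tolerance = 1e-12)
})

test_that("double-normalized attention rows are convex weights on random inputs", {
  set.seed(405)
  for (rep in 1:20) {
    n <- sample(2:8, 1); d <- sample(1:4, 1); S <- sample(2:6, 1)
    mem <- external_memory_params(d, S)
    tok <- matrix(rnorm(n * d, 0, 2), n, d)
    s <- tok %*% t(ag_value(mem$m_k))
    a <- apply(s, 2, function(col) exp(col - max(col)) / sum(exp(col - max(col))))
    if (is.null(dim(a))) a <- matrix(a, nrow = 1)
    alpha <- a / rowSums(a)
    expect_true(all(alpha >= 0))
    expect_equal(rowSums(alpha), rep(1, n), tolerance = 1e-6)
    out <- ag_no_grad(ag_value(external_attention_head(ag_tensor(tok), mem)))
    # rows of the output lie inside the convex hull of the memory rows
    mv <- ag_value(mem$m_v)
    for (i in seq_len(n)) {
      expect_true(all(out[i, ] <= apply(mv, 2, max) + 1e-9))
      expect_true(all(out[i, ] >= apply(mv, 2, min) - 1e-9))
    }
  }
})

test_that("multi-head external attention decomposes into independent heads", {
  set.seed(406)
  p <- mhea_params(4L, 2L, memory = 3L)
  x <- array(rnorm(2 * 4 * 2 * 2), c(2, 4, 2, 2))
  out <- ag_no_grad(ag_value(mhea_forward(ag_tensor(x), p)))
  expect_identical(dim(out), dim(x))
  for (n in 1:2) {
    tok <- tokens_of(x, n)
    for (h in 1:2) {
      idx <- (h - 1) * 2 + 1:2
      ref <- ag_no_grad(ag_value(external_attention_head(
        ag_tensor(tok[, idx, drop = FALSE]), p$memories[[h]])))
      expect_equal(tokens_of(out, n)[, idx], ref, tolerance = 1e-10)
    }
  }

  # H = 1 is exactly a single external attention head
  p1 <- mhea_params(3L, 1L, memory = 4L)
  x1 <- array(rnorm(1 * 3 * 2 * 2), c(1, 3, 2, 2))
  o1 <- ag_no_grad(ag_value(mhea_forward(ag_tensor(x1), p1)))
  ref1 <- ag_no_grad(ag_value(external_attention_head(
    ag_tensor(tokens_of(x1, 1)), p1$memories[[1]])))
  expect_equal(tokens_of(o1, 1), ref1, tolerance = 1e-12)
})

test_that("head groups are equivariant under joint permutation of heads and memories", {
  set.seed(407)
  p <- mhea_params(4L, 2L, memory = 3L)
  x <- array(rnorm(1 * 4 * 2 * 2), c(1, 4, 2, 2))
  out <- ag_no_grad(ag_value(mhea_forward(ag_tensor(x), p)))
  # swap the two channel groups of the input and the two memories
  p2 <- p
  p2$memories <- p$memories[c(2, 1)]
  xs <- x[, c(3, 4, 1, 2), , , drop = FALSE]
  out2 <- ag_no_grad(ag_value(mhea_forward(ag_tensor(xs), p2)))
  expect_equal(out2[, c(3, 4, 1, 2), , , drop = FALSE], out, tolerance = 1e-12)
})

test_that("mixed attention topology: saturated gates and annihilation", {
  set.seed(408)
  p <- mixed_attention_params(4L, 2L, memory = 3L, reduction = 2L)
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))

  # huge gate biases -> SA and CA sigmoids ~ 1 -> output ~ m_x
  p$sa$conv$b$v <- 50
  p$ca$fc2$b$v <- rep(50, 4)
  out <- ag_no_grad(ag_value(mixed_attention_forward(ag_tensor(x), p)))
  m_x <- ag_no_grad({
    lnx <- ag_layernorm(ag_tensor(x), p$ln_in$gamma, p$ln_in$beta)
    ag_value(ag_layernorm(ag_mul(mhea_forward(lnx, p$mhea), lnx),
                          p$ln_out$gamma, p$ln_out$beta))
  })
  expect_equal(out, m_x, tolerance = 1e-6)

  # zero memories annihilate the multiplicative skip: output is exactly 0
  p0 <- mixed_attention_params(4L, 2L, memory = 3L, reduction = 2L)
  for (m in p0$mhea$memories) { m$m_k$v <- 0 * m$m_k$v; m$m_v$v <- 0 * m$m_v$v }
  out0 <- ag_no_grad(ag_value(mixed_attention_forward(ag_tensor(x), p0)))
  expect_true(all(out0 == 0))
})

test_that("mixed attention composes its three oracles step by step", {
  set.seed(409)
  p <- mixed_attention_params(4L, 2L, memory = 3L, reduction = 2L)
  x <- array(rnorm(1 * 4 * 2 * 2), c(1, 4, 2, 2))
  out <- ag_no_grad(ag_value(mixed_attention_forward(ag_tensor(x), p)))
  ref <- ag_no_grad({
    lnx <- ag_layernorm(ag_tensor(x), p$ln_in$gamma, p$ln_in$beta)
    m_x <- ag_layernorm(ag_mul(mhea_forward(lnx, p$mhea), lnx),
                        p$ln_out$gamma, p$ln_out$beta)
    m_y <- ag_mul_spatialgate(m_x, spatial_attention(m_x, p$sa))
    ag_value(ag_mul_changate(m_y, channel_attention(m_y, p$ca)))
  })
  expect_equal(out, ref, tolerance = 1e-12)
  expect_identical(dim(out), dim(x))
})
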