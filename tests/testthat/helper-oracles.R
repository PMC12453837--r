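# Shared helpers: finite-difference gradient checking, independent
# explicit-loop oracles for the attention mechanisms, and brute-force
# metric implementations. Oracles deliberately avoid the package's
# vectorized code paths.

# Relative finite-difference error of the gradients of `fwd()` (a closure
# returning a scalar ag_tensor) with respect to a list of tensors, probing
# `probes` random coordinates per tensor.
fd_check <- function(fwd, tensors, probes = 4L, eps = 1e-6) {
  loss <- fwd()
  ag_backward(loss)
  maxerr <- 0
  for (t in tensors) {
    v <- ag_value(t)
    g <- t$g
    if (is.null(g)) g <- 0 * v
    for (rep in seq_len(min(length(v), probes))) {
      j <- sample.int(length(v), 1L)
      t$v[j] <- v[j] + eps
      lp <- ag_no_grad(ag_value(fwd()))
      t$v[j] <- v[j] - eps
      lm <- ag_no_grad(ag_value(fwd()))
      t$v[j] <- v[j]
      num <- (lp - lm) / (2 * eps)
      maxerr <- max(maxerr, abs(num - g[j]) / max(1, abs(num)))
    }
    t$g <- NULL
  }
  ag_tape_reset()
  maxerr
}

# Set every trainable tensor inside a nested parameter list to zero.
zero_all_params <- function(p) {
  for (t in hemf:::collect_params(p)) t$v <- 0 * t$v
  invisible(p)
}

# Channel-normalize a [N,C,H,W] array at every spatial position (zero mean,
# unit variance across channels) so that layer normalization acts as the
# identity up to its eps.
ln_neutral_input <- function(d, sd = 1) {
  a <- array(rnorm(prod(d), 0, sd), dim = d)
  for (n in seq_len(d[1])) for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
    v <- a[n, , h, w]
    a[n, , h, w] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  a
}

conv1x1_as_matrix <- function(p) {
  w <- ag_value(p$w)
  matrix(w, nrow = dim(w)[1], ncol = dim(w)[2])
}

# Row-major token matrix (x inner, y outer) of sample n.
tokens_of <- function(xv, n = 1L) {
  C <- dim(xv)[2]; H <- dim(xv)[3]; W <- dim(xv)[4]
  tok <- matrix(0, H * W, C)
  for (t in seq_len(H * W)) {
    xi <- (t - 1L) %% W
    yi <- (t - 1L) %/% W
    tok[t, ] <- xv[n, , yi + 1L, xi + 1L]
  }
  tok
}

tokens_to_map <- function(tok, H, W) {
  C <- ncol(tok)
  out <- array(0, dim = c(1, C, H, W))
  for (t in seq_len(H * W)) {
    xi <- (t - 1L) %% W
    yi <- (t - 1L) %/% W
    out[1, , yi + 1L, xi + 1L] <- tok[t, ]
  }
  out
}

# Explicit-loop Manhattan self-attention oracle for a single sample,
# evaluating score, softmax, decay product and value sum term by term.
oracle_masa <- function(xv, p) {
  C <- dim(xv)[2]; H <- dim(xv)[3]; W <- dim(xv)[4]
  Tn <- H * W
  tok <- tokens_of(xv, 1L)
  lin <- function(proj) sweep(tok %*% t(conv1x1_as_matrix(proj)), 2,
                              as.numeric(ag_value(proj$b)), "+")
  q <- lin(p$q_proj); k <- lin(p$k_proj); v <- lin(p$v_proj)
  dh <- C / p$heads
  o <- matrix(0, Tn, C)
  xs <- (seq_len(Tn) - 1L) %% W
  ys <- (seq_len(Tn) - 1L) %/% W
  for (h in seq_len(p$heads)) {
    idx <- (h - 1) * dh + seq_len(dh)
    for (n in seq_len(Tn)) {
      s <- numeric(Tn)
      for (m in seq_len(Tn)) s[m] <- sum(q[n, idx] * k[m, idx]) / sqrt(dh)
      a <- exp(s - max(s)); a <- a / sum(a)
      dec <- p$gammas[h]^(abs(xs[n] - xs) + abs(ys[n] - ys))
      for (m in seq_len(Tn)) o[n, idx] <- o[n, idx] + a[m] * dec[m] * v[m, idx]
    }
  }
  out <- sweep(o %*% t(conv1x1_as_matrix(p$out_proj)), 2,
               as.numeric(ag_value(p$out_proj$b)), "+")
  tokens_to_map(out, H, W)
}

# Plain softmax attention (no decay) oracle, for the gamma = 1 degeneracy.
oracle_vanilla_attention <- function(xv, p) {
  p2 <- p
  p2$gammas <- rep(1, p$heads)
  oracle_masa(xv, p2)
}

# Brute-force one-vs-rest metrics from a confusion matrix.
brute_metrics <- function(cm) {
  C <- nrow(cm); tot <- sum(cm)
  prec <- rec <- f1 <- numeric(C)
  for (k in seq_len(C)) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    prec[k] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[k] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[k] <- if (prec[k] + rec[k] == 0) 0 else
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
  }
  list(accuracy = sum(diag(cm)) / tot, precision = mean(prec),
       recall = mean(rec), f1 = mean(f1))
}

brute_mcc <- function(cm) {
  s <- sum(cm); c0 <- sum(diag(cm))
  tk <- rowSums(cm); pk <- colSums(cm)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  (c0 * s - sum(pk * tk)) / den
}

brute_kappa <- function(cm) {
  s <- sum(cm)
  po <- sum(diag(cm)) / s
  pe <- sum(rowSums(cm) * colSums(cm)) / s^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

# Mann-Whitney AUC (average ranks handle ties like the trapezoid rule).
rank_auc <- function(score, pos) {
  r <- rank(score)
  np <- sum(pos); nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

random_cm <- function(C, n = 200L) {
  m <- matrix(0L, C, C)
  yt <- sample.int(C, n, replace = TRUE)
  yp <- sample.int(C, n, replace = TRUE)
  for (i in seq_len(n)) m[yt[i], yp[i]] <- m[yt[i], yp[i]] + 1L
  m
}

# A tiny model configuration used throughout the unit tests.
tiny_config <- function(num_classes = 2L, input_size = 32L) {
  hemf_config(num_classes = num_classes, input_size = input_size,
              stem_width = 8L, stage_widths = c(8L, 16L, 32L, 64L),
              masa_heads = c(1L, 1L, 2L, 2L), mhea_heads = c(1L, 1L, 2L, 2L),
              ea_memory = 4L, ca_reduction = 4L)
}

# The compact CPU-sized configuration used by the learning smoke test.
smoke_config <- function(num_classes = 2L, input_size = 64L) {
  hemf_config(num_classes = num_classes, input_size = input_size,
              stem_width = 16L, stage_widths = c(16L, 32L, 64L, 128L),
              masa_heads = c(1L, 2L, 4L, 8L), mhea_heads = c(1L, 2L, 4L, 8L),
              ea_memory = 16L, ca_reduction = 16L)
}
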