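# Training recipe: AdamW with decoupled weight decay, linear warmup over
# the first epoch (from 1/100 of the initial rate), then cosine annealing
# from the initial to the final learning rate, categorical cross-entropy
# loss. The defaults reproduce the published recipe field for field:
# lr 1e-4 -> 1e-6, weight decay 0.01, batch size 32, 150 epochs, warmup 1
# epoch, drop path 0.

#' Training configuration
#'
#' @param lr_init,lr_final Initial and final learning rates
#'   (`lr_final < lr_init`).
#' @param optimizer Only `"adamw"` is supported.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param schedule Only `"cosine_annealing"` is supported.
#' @param warmup_epochs Linear warmup length in epochs.
#' @param epochs Number of training epochs.
#' @param batch_size Minibatch size.
#' @param loss Only `"cce"` (categorical cross-entropy) is supported.
#' @param mixed_precision Accepted for interface compatibility; this engine
#'   computes in double precision regardless, and the flag is excluded from
#'   determinism guarantees.
#' @param seed Seed controlling initialization and shuffling.
#' @param device Only `"cpu"` is supported.
#' @return An object of class `hemf_train_config`.
#' @export
train_config <- function(lr_init = 1e-4, lr_final = 1e-6,
                         optimizer = "adamw", weight_decay = 0.01,
                         schedule = "cosine_annealing", warmup_epochs = 1L,
                         epochs = 150L, batch_size = 32L, loss = "cce",
                         mixed_precision = FALSE, seed = 42L,
                         device = "cpu") {
  if (lr_final >= lr_init) hemf_stop_config("lr_final must be below lr_init")
  if (epochs < 1L || batch_size < 1L)
    hemf_stop_config("epochs and batch_size must be >= 1")
  if (!identical(optimizer, "adamw")) hemf_stop_config("optimizer must be 'adamw'")
  if (!identical(schedule, "cosine_annealing"))
    hemf_stop_config("schedule must be 'cosine_annealing'")
  if (!identical(loss, "cce")) hemf_stop_config("loss must be 'cce'")
  if (!identical(device, "cpu")) hemf_stop_config("only device='cpu' is available")
  structure(list(
    lr_init = lr_init, lr_final = lr_final, optimizer = optimizer,
    weight_decay = weight_decay, schedule = schedule,
    warmup_epochs = as.integer(warmup_epochs), epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), loss = loss,
    mixed_precision = isTRUE(mixed_precision), seed = as.integer(seed),
    device = device
  ), class = "hemf_train_config")
}

#' Learning rate at a given optimizer step
#'
#' Steps `0 .. ws-1` (one warmup epoch) ramp linearly from `lr_init/100`
#' to exactly `lr_init`; the remaining steps follow
#' `lr_final + (lr_init - lr_final) * (1 + cos(pi * t)) / 2` with progress
#' `t` in [0, 1], reaching exactly `lr_final` at the last step.
#'
#' @param step 0-based optimizer step.
#' @param steps_per_epoch Optimizer steps per epoch.
#' @param cfg A [train_config()].
#' @param total_steps Total steps of the run (default
#'   `epochs * steps_per_epoch`).
#' @return Learning rate (scalar).
#' @export
lr_schedule <- function(step, steps_per_epoch, cfg,
                        total_steps = cfg$epochs * steps_per_epoch) {
  ws <- cfg$warmup_epochs * steps_per_epoch
  if (step < ws) {
    if (ws == 1L) return(cfg$lr_init)
    return(cfg$lr_init * (0.01 + 0.99 * step / (ws - 1L)))
  }
  span <- total_steps - 1L - ws
  t <- if (span <= 0L) 1 else (step - ws) / span
  t <- min(max(t, 0), 1)
  cfg$lr_final + (cfg$lr_init - cfg$lr_final) * (1 + cos(pi * t)) / 2
}

adamw_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) 0 * ag_value(p))
  st$v <- lapply(params, function(p) 0 * ag_value(p))
  st
}

adamw_step <- function(params, st, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$g
    if (is.null(g)) next
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    p$v <- p$v - lr * ((st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps) +
                         weight_decay * p$v)
  }
  invisible(NULL)
}

checkpoint_build <- function(model) {
  list(format = .ckpt_format, version = .ckpt_version, config = model$config,
       params = lapply(hemf_parameters(model), ag_value),
       bn = lapply(collect_bn_states(unclass(model)),
                   function(e) list(running_mean = e$running_mean,
                                    running_var = e$running_var)))
}

checkpoint_load_into <- function(model, obj) {
  flat <- hemf_parameters(model)
  for (nm in names(flat)) flat[[nm]]$v <- obj$params[[nm]]
  bn <- collect_bn_states(unclass(model))
  for (nm in names(bn)) {
    bn[[nm]]$running_mean <- obj$bn[[nm]]$running_mean
    bn[[nm]]$running_var <- obj$bn[[nm]]$running_var
  }
  model
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

#' Train the classifier
#'
#' Runs AdamW with the configured schedule on a labelled image array.
#' Deterministic given the seed (and `mixed_precision = FALSE`). The best
#' checkpoint is selected by validation accuracy when a validation set is
#' given, otherwise by training loss.
#'
#' @param model A `hemf_model` or a `hemf_config` (instantiated with the
#'   training seed).
#' @param cfg A [train_config()].
#' @param dataset List with `images` ([n, C, S, S], already normalized) and
#'   `labels` (0-based integers).
#' @param val Optional validation dataset in the same format.
#' @param max_steps Optional cap on the number of optimizer steps.
#' @param stop_when_acc Optional early-stopping threshold: training ends
#'   after the first epoch whose training accuracy reaches this value.
#' @param checkpoint_path Optional path where the best checkpoint is saved.
#' @param verbose Log one line per epoch to stderr.
#' @return List with `model` (final parameters), `history` (one row per
#'   epoch: epoch, lr, train_loss, train_acc, val_loss, val_acc), `best`
#'   (checkpoint object of the best epoch) and `best_epoch`.
#' @export
train_model <- function(model, cfg, dataset, val = NULL, max_steps = NULL,
                        stop_when_acc = NULL, checkpoint_path = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(cfg, "hemf_train_config"))
  if (inherits(model, "hemf_config")) model <- hemf_model(model, seed = cfg$seed)
  if (cfg$mixed_precision)
    message("mixed precision requested; this engine computes in double precision")
  n <- length(dataset$labels)
  if (n == 0L) hemf_stop_validation("empty training set")
  if (max(dataset$labels) + 1L > model$config$num_classes)
    hemf_stop_config("labels exceed the configured class count")
  params <- hemf_parameters(model)
  opt <- adamw_init(params)
  spe <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$epochs * spe
  if (!is.null(max_steps)) total_steps <- min(total_steps, max_steps)
  history <- list()
  best <- NULL; best_epoch <- NA_integer_
  best_score <- -Inf
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    if (step >= total_steps) break
    perm <- withr::with_seed(cfg$seed + epoch, sample.int(n))
    ag_set_training(TRUE)
    ep_loss <- 0; ep_correct <- 0L; ep_n <- 0L; lr <- NA_real_
    for (bi in batch_indices(n, cfg$batch_size)) {
      if (step >= total_steps) break
      idx <- perm[bi]
      xb <- dataset$images[idx, , , , drop = FALSE]
      yb <- dataset$labels[idx]
      lr <- lr_schedule(step, spe, cfg, total_steps)
      ag_tape_reset()
      logits <- hemf_forward(model, xb)
      loss <- ag_cce(logits, yb)
      lv <- ag_value(loss)
      if (!is.finite(lv))
        stop(sprintf("training diverged: non-finite loss at step %d", step))
      ag_zero_grad(params)
      ag_backward(loss)
      adamw_step(params, opt, lr, cfg$weight_decay)
      pred <- max.col(ag_value(logits), ties.method = "first") - 1L
      ep_loss <- ep_loss + lv * length(idx)
      ep_correct <- ep_correct + sum(pred == yb)
      ep_n <- ep_n + length(idx)
      step <- step + 1L
    }
    ag_set_training(FALSE)
    row <- data.frame(epoch = epoch, lr = lr,
                      train_loss = ep_loss / ep_n,
                      train_acc = ep_correct / ep_n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val)) {
      ev <- predict_hemf(model, val$images, batch_size = cfg$batch_size)
      row$val_loss <- cce_loss(ev$logits, val$labels)
      row$val_acc <- mean(ev$pred == val$labels)
      score <- row$val_acc
    } else {
      score <- -row$train_loss
    }
    if (score > best_score) {
      best_score <- score
      best <- checkpoint_build(model)
      best_epoch <- epoch
    }
    history[[epoch]] <- row
    if (!is.null(stop_when_acc) && row$train_acc >= stop_when_acc) {
      if (verbose) message(sprintf("early stop at epoch %d (train_acc %.3f)",
                                   epoch, row$train_acc))
      break
    }
    if (verbose)
      message(sprintf("[%s] epoch %d  lr %.2e  loss %.4f  acc %.4f%s",
                      format(Sys.time(), "%H:%M:%S"), epoch, row$lr,
                      row$train_loss, row$train_acc,
                      if (is.null(val)) "" else
                        sprintf("  val_loss %.4f  val_acc %.4f",
                                row$val_loss, row$val_acc)))
  }
  history <- do.call(rbind, history)
  if (!is.null(checkpoint_path)) saveRDS(best, checkpoint_path)
  list(model = model, history = history, best = best, best_epoch = best_epoch)
}

#' Batched inference
#' @param model A `hemf_model`.
#' @param images Array [n, C, S, S] (already normalized).
#' @param batch_size Minibatch size for the forward passes.
#' @return List with `logits`, `probs` (softmax rows) and `pred` (0-based).
#' @export
predict_hemf <- function(model, images, batch_size = 32L) {
  n <- dim(images)[1L]
  logits <- NULL
  ag_set_training(FALSE)
  for (bi in batch_indices(n, batch_size)) {
    lb <- ag_no_grad(ag_value(hemf_forward(model, images[bi, , , , drop = FALSE])))
    logits <- rbind(logits, lb)
  }
  e <- exp(logits - apply(logits, 1L, max))
  probs <- e / rowSums(e)
  list(logits = logits, probs = probs,
       pred = max.col(probs, ties.method = "first") - 1L)
}

resolve_model <- function(x) {
  if (inherits(x, "hemf_model")) return(x)
  if (is.list(x) && identical(x$format, .ckpt_format))
    return(checkpoint_load_into(hemf_model(x$config), x))
  if (is.character(x) && length(x) == 1L) return(load_checkpoint(x))
  hemf_stop_validation("expected a model, checkpoint object or checkpoint path")
}

#' Evaluate a model or checkpoint on a dataset
#'
#' With a protocol, the dataset is split by [make_splits()] and the model
#' is evaluated on each test portion (for `kfold2`, on both folds, with
#' metrics averaged arithmetically). Batch norm runs in evaluation mode.
#'
#' @param x A `hemf_model`, checkpoint object or checkpoint file path.
#' @param dataset List with `images` and `labels`.
#' @param protocol Optional split protocol (see [make_splits()]).
#' @param seed Split seed.
#' @param batch_size Inference batch size.
#' @return A `hemf_metrics` report.
#' @export
evaluate_model <- function(x, dataset, protocol = NULL, seed = 1L,
                           batch_size = 32L) {
  model <- resolve_model(x)
  C <- model$config$num_classes
  if (max(dataset$labels) + 1L > C)
    hemf_stop_config("dataset class count exceeds the checkpoint's")
  eval_subset <- function(idx) {
    pr <- predict_hemf(model, dataset$images[idx, , , , drop = FALSE],
                       batch_size)
    metrics_report(dataset$labels[idx], pr$pred, scores = pr$probs, C = C)
  }
  if (is.null(protocol)) return(eval_subset(seq_along(dataset$labels)))
  sp <- make_splits(dataset$labels, protocol, seed)
  switch(protocol,
    holdout_70_30 = eval_subset(sp$test),
    three_way_60_15_25 = eval_subset(sp$test),
    kfold2 = average_metrics(list(eval_subset(sp$fold1),
                                  eval_subset(sp$fold2))))
}
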