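# Parameter constructors for the layers used across the network, plus the
# error classes shared by every module. Weights are drawn from N(0, 0.02^2)
# (the usual init for LN-based conv/transformer hybrids); biases start at 0,
# normalization scales at 1.

hemf_stop <- function(msg, class) {
  stop(structure(class = c(class, "hemf_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

hemf_stop_config <- function(msg) hemf_stop(msg, "hemf_config_error")
hemf_stop_validation <- function(msg) hemf_stop(msg, "hemf_validation_error")

check_feature_map <- function(x, what = "input") {
  v <- ag_value(x)
  if (length(dim(v)) != 4L)
    hemf_stop_validation(sprintf("%s must be a rank-4 [N,C,H,W] array", what))
  if (anyNA(v) || any(is.infinite(v)))
    hemf_stop_validation(sprintf("%s contains non-finite values", what))
  invisible(v)
}

init_sd <- 0.02

nn_conv <- function(cin, cout, k, groups = 1L, sd = init_sd) {
  if (cin %% groups != 0L || cout %% groups != 0L)
    hemf_stop_config("channels not divisible by groups")
  list(
    w = ag_param(array(stats::rnorm(cout * (cin / groups) * k * k, 0, sd),
                       dim = c(cout, cin / groups, k, k))),
    b = ag_param(numeric(cout))
  )
}

nn_linear <- function(din, dout, sd = init_sd) {
  list(
    w = ag_param(matrix(stats::rnorm(dout * din, 0, sd), nrow = dout, ncol = din)),
    b = ag_param(numeric(dout))
  )
}

nn_ln <- function(C) {
  list(gamma = ag_param(rep(1, C)), beta = ag_param(numeric(C)))
}

nn_bn <- function(C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  list(gamma = ag_param(rep(1, C)), beta = ag_param(numeric(C)), state = st)
}

fwd_conv <- function(x, p, stride = 1L, pad = 0L, groups = 1L) {
  ag_conv2d(x, p$w, p$b, stride = stride, pad = pad, groups = groups)
}

fwd_ln <- function(x, p) ag_layernorm(x, p$gamma, p$beta)

fwd_bn <- function(x, p) ag_batchnorm(x, p$gamma, p$beta, p$state)

# Recursively collect every trainable tensor (named by its path) from a
# nested parameter list.
collect_params <- function(x, path = character()) {
  if (inherits(x, "ag_tensor")) {
    out <- list(x)
    names(out) <- paste(path, collapse = ".")
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_params(x[[i]], c(path, nm)))
    }
    return(out)
  }
  list()
}

# Collect batch-norm running-statistic environments, named by path.
collect_bn_states <- function(x, path = character()) {
  if (is.environment(x) && !inherits(x, "ag_tensor")) {
    out <- list(x)
    names(out) <- paste(path, collapse = ".")
    return(out)
  }
  if (is.list(x) && !inherits(x, "ag_tensor")) {
    out <- list()
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_bn_states(x[[i]], c(path, nm)))
    }
    return(out)
  }
  list()
}
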