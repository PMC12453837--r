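# Multiclass evaluation metrics derived from the confusion matrix, plus
# one-vs-rest ROC/AUC and the categorical cross-entropy loss.
#
# Per-class precision/recall/F1 use the one-vs-rest collapse of the
# confusion matrix and are macro-averaged (unweighted class mean). MCC uses
# the standard multi-category generalization computed from the full
# matrix (it reduces to the familiar binary formula for C = 2), and kappa
# is the usual chance-corrected agreement (P_o - P_e) / (1 - P_e).

#' Confusion matrix
#' @param y_true,y_pred Integer class labels in `[0, C)`.
#' @param C Number of classes.
#' @return C x C integer matrix; rows are true classes, columns predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, C) {
  if (length(y_true) != length(y_pred))
    hemf_stop_validation("label vectors must have equal length")
  if (any(y_true < 0L) || any(y_true >= C) || any(y_pred < 0L) || any(y_pred >= C))
    hemf_stop_validation("labels out of range [0, C)")
  cm <- matrix(0L, C, C)
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

ovr_counts <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("zero denominator in %s; contributing 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Accuracy and macro precision/recall/F1 from a confusion matrix
#'
#' @param cm Confusion matrix (rows true, columns predicted).
#' @return List with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1` and a per-class data frame `per_class`.
#' @export
classification_metrics <- function(cm) {
  if (sum(cm) == 0) hemf_stop_validation("empty confusion matrix")
  C <- nrow(cm)
  pc <- t(vapply(seq_len(C), function(k) {
    n <- ovr_counts(cm, k)
    p <- safe_div(n["tp"], n["tp"] + n["fp"], sprintf("precision of class %d", k - 1L))
    r <- safe_div(n["tp"], n["tp"] + n["fn"], sprintf("recall of class %d", k - 1L))
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = unname(p), recall = unname(r), f1 = unname(f))
  }, numeric(3)))
  list(
    accuracy = sum(diag(cm)) / sum(cm),
    macro_precision = mean(pc[, "precision"]),
    macro_recall = mean(pc[, "recall"]),
    macro_f1 = mean(pc[, "f1"]),
    per_class = data.frame(class = seq_len(C) - 1L, pc)
  )
}

#' Matthews correlation coefficient
#'
#' Binary confusion matrices use
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; larger matrices
#' use the multi-category generalization computed from the full matrix.
#' A zero denominator yields 0.
#'
#' @param cm Confusion matrix.
#' @return Value in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  if (sum(cm) == 0) hemf_stop_validation("empty confusion matrix")
  s <- sum(cm)
  c0 <- sum(diag(cm))
  tk <- rowSums(cm)   # true occurrences
  pk <- colSums(cm)   # predicted occurrences
  num <- c0 * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Cohen's kappa
#'
#' `(P_o - P_e) / (1 - P_e)` with observed agreement `P_o = trace/total`
#' and chance agreement `P_e = sum_k row_k * col_k / total^2`.
#'
#' @param cm Confusion matrix.
#' @return Value in `(-1, 1]`; a degenerate single-cell matrix yields 0
#'   with a warning.
#' @export
kappa <- function(cm) {
  if (sum(cm) == 0) hemf_stop_validation("empty confusion matrix")
  s <- sum(cm)
  po <- sum(diag(cm)) / s
  pe <- sum(rowSums(cm) * colSums(cm)) / s^2
  if (pe == 1) {
    warning("degenerate margins (P_e = 1); kappa defined as 0", call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' One-vs-rest ROC curve and AUC
#'
#' For each class, samples are sorted by that class's score; thresholds
#' sweep the grouped unique scores (ties move as one block) and the area
#' under the (FPR, TPR) polyline is accumulated by the trapezoidal rule.
#'
#' @param scores n x C matrix of class scores (higher = more confident).
#' @param y_true Integer labels in `[0, C)`.
#' @return List with `auc` (per-class, NA for classes absent from
#'   `y_true`), `macro_auc` (mean over present classes) and `roc`
#'   (per-class data frames of FPR/TPR points).
#' @export
roc_auc <- function(scores, y_true) {
  if (any(!is.finite(scores))) hemf_stop_validation("non-finite scores")
  C <- ncol(scores)
  aucs <- rep(NA_real_, C)
  curves <- vector("list", C)
  for (k in seq_len(C)) {
    pos <- y_true == (k - 1L)
    np <- sum(pos); nn <- sum(!pos)
    if (np == 0L || nn == 0L) {
      warning(sprintf("class %d absent from one side; excluded from AUC", k - 1L),
              call. = FALSE)
      next
    }
    s <- scores[, k]
    ord <- order(s, decreasing = TRUE)
    sp <- s[ord]; lp <- pos[ord]
    grp <- cumsum(!duplicated(sp))          # tie groups
    tp <- c(0, cumsum(tapply(lp, grp, sum)))
    fp <- c(0, cumsum(tapply(!lp, grp, sum)))
    tpr <- tp / np; fpr <- fp / nn
    aucs[k] <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    curves[[k]] <- data.frame(fpr = fpr, tpr = tpr)
  }
  list(auc = aucs, macro_auc = mean(aucs, na.rm = TRUE), roc = curves)
}

#' Categorical cross-entropy from logits (numeric convenience form)
#'
#' Mean negative log softmax probability of the true class, evaluated with
#' the log-sum-exp stabilization.
#'
#' @param logits n x C numeric matrix.
#' @param y_true Integer labels in `[0, C)`.
#' @return Nonnegative scalar.
#' @export
cce_loss <- function(logits, y_true) {
  if (any(is.na(logits))) hemf_stop_validation("NaN logits")
  n <- nrow(logits)
  stopifnot(length(y_true) == n)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[cbind(seq_len(n), y_true + 1L)])
}

#' Full metrics report
#'
#' @param y_true Integer labels in `[0, C)`.
#' @param y_pred Predicted labels.
#' @param scores Optional n x C score matrix (enables AUC columns).
#' @param C Number of classes (default inferred).
#' @return An object of class `hemf_metrics`: accuracy, macro
#'   precision/recall/F1, MCC, kappa, per-class and macro AUC, and the
#'   confusion matrix.
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL, C = NULL) {
  if (is.null(C)) C <- max(y_true, y_pred) + 1L
  cm <- confusion_matrix(y_true, y_pred, C)
  base <- classification_metrics(cm)
  rep <- list(
    accuracy = base$accuracy,
    macro_precision = base$macro_precision,
    macro_recall = base$macro_recall,
    macro_f1 = base$macro_f1,
    mcc = mcc(cm),
    kappa = kappa(cm),
    per_class = base$per_class,
    confusion = cm
  )
  if (!is.null(scores)) {
    ra <- roc_auc(scores, y_true)
    rep$auc <- ra$auc
    rep$macro_auc <- ra$macro_auc
    rep$roc <- ra$roc
  }
  structure(rep, class = "hemf_metrics")
}

#' @export
print.hemf_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  macro P %.4f  R %.4f  F1 %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  cat(sprintf("MCC %.4f  kappa %.4f", x$mcc, x$kappa))
  if (!is.null(x$macro_auc)) cat(sprintf("  macro AUC %.4f", x$macro_auc))
  cat("\n")
  invisible(x)
}

#' Average metrics reports across cross-validation folds
#' @param reports List of `hemf_metrics` objects.
#' @return A `hemf_metrics` with arithmetic-mean scalar fields and the
#'   summed confusion matrix.
#' @export
average_metrics <- function(reports) {
  stopifnot(length(reports) >= 1L)
  fields <- c("accuracy", "macro_precision", "macro_recall", "macro_f1",
              "mcc", "kappa", "macro_auc")
  out <- list()
  for (f in fields) {
    vals <- vapply(reports, function(r) if (is.null(r[[f]])) NA_real_ else r[[f]],
                   numeric(1))
    if (!all(is.na(vals))) out[[f]] <- mean(vals, na.rm = TRUE)
  }
  out$confusion <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  out$folds <- length(reports)
  structure(out, class = "hemf_metrics")
}

#' Write a metrics report to CSV and/or JSON
#' @param report A `hemf_metrics`.
#' @param csv,json Optional output paths for the scalar metrics.
#' @param roc_csv Optional output path for the per-class ROC points
#'   (columns class, fpr, tpr); requires a report built with scores.
#' @return Invisibly, the report.
#' @export
write_metrics <- function(report, csv = NULL, json = NULL, roc_csv = NULL) {
  if (!is.null(roc_csv)) {
    if (is.null(report$roc))
      hemf_stop_validation("report has no ROC curves (no scores given)")
    pts <- do.call(rbind, lapply(seq_along(report$roc), function(k) {
      r <- report$roc[[k]]
      if (is.null(r)) return(NULL)
      cbind(class = k - 1L, r)
    }))
    utils::write.csv(pts, roc_csv, row.names = FALSE)
  }
  scal <- report[vapply(report, function(v) is.numeric(v) && length(v) == 1L,
                        logical(1))]
  if (!is.null(csv)) {
    utils::write.csv(data.frame(metric = names(scal),
                                value = unlist(scal, use.names = FALSE)),
                     csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(scal, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
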