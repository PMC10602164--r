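# Hard-label evaluation: confusion-matrix metrics, the stepped single-point
# ROC and its AUC, and the repeated train/test protocol.

#' Confusion-matrix metrics for hard 0/1 predictions
#'
#' @param y_true Integer vector of true labels (both classes present).
#' @param y_pred Integer vector of predicted labels, same length.
#' @return List: `TP`, `FP`, `TN`, `FN`, `sensitivity`, `specificity`,
#'   `precision`, `F1`. With no predicted positives, precision is `NA` and
#'   F1 is 0 (with a warning).
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0 or 1")
  }
  if (length(unique(y_true)) < 2L) {
    stop("y_true must contain both classes")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  precision <- if (tp + fp == 0) {
    warning("no predicted positives; precision undefined, F1 set to 0")
    NA_real_
  } else tp / (tp + fp)
  list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = precision,
    F1 = if (tp + fp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  )
}

#' AUC of a hard-label (stepped) ROC
#'
#' A classifier that emits only 0/1 labels has a single operating point; its
#' ROC is the polyline (0,0) -> (1-specificity, sensitivity) -> (1,1) and the
#' trapezoidal area under it reduces to `(sensitivity + specificity) / 2`.
#'
#' @param sensitivity,specificity Rates in \[0, 1\].
#' @return The AUC.
#' @export
#' @examples
#' binary_auc(0.85, 0.75)
binary_auc <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 1)) {
    stop("rates must lie in [0, 1]")
  }
  (sensitivity + specificity) / 2
}

#' Vertices of the stepped ROC polyline
#'
#' @param sensitivity,specificity Rates in \[0, 1\].
#' @return A 3x2 matrix of (FPR, TPR) vertices.
#' @export
roc_points <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 1)) {
    stop("rates must lie in [0, 1]")
  }
  m <- rbind(c(0, 0), c(1 - specificity, sensitivity), c(1, 1))
  dimnames(m) <- list(NULL, c("fpr", "tpr"))
  m
}

#' Repeated down-sample / split / augment / train / test protocol
#'
#' Runs the full pipeline `n_repeats` times. Repeat `r` (zero-based) re-draws
#' the majority-class down-sampling, the train/test split and the cross-class
#' pair sample with seed `base_seed + r`, and trains with model seed
#' `config$seed + r`. Per-repeat confusion metrics and stepped-ROC AUC are
#' collected and averaged (unweighted arithmetic mean).
#'
#' @param records Labeled, filtered data frame (see [label_records()] and
#'   [filter_by_word_count()]).
#' @param store An `embedding_store` covering every record id.
#' @param n_repeats Number of repeats; default 10.
#' @param base_seed Integer base seed for the data draws.
#' @param train_per_class Training narratives per class; default 170.
#' @param config A [model_config()]; its `input_dim` must match the store.
#' @param neg_ratio Cross-class pair ratio; default 2.
#' @return An `evaluation_report`: `per_repeat` data frame, `aggregate`
#'   named numeric vector, and `roc` (list of per-repeat ROC vertex
#'   matrices).
#' @export
run_repeats <- function(records, store, n_repeats = 10L, base_seed = 1L,
                        train_per_class = 170L, config = model_config(),
                        neg_ratio = 2) {
  stopifnot(n_repeats >= 1L)
  per <- vector("list", n_repeats)
  roc <- vector("list", n_repeats)
  for (r in seq_len(n_repeats) - 1L) {
    res <- tryCatch({
      s <- as.integer(base_seed) + r
      balanced <- balance_downsample(records, seed = s)
      split <- split_train_test(balanced, train_per_class = train_per_class,
                                seed = base_seed, repeat_index = r)
      train_set <- build_training_set(split, store, seed = s,
                                      neg_ratio = neg_ratio)
      cfg <- config
      cfg$seed <- config$seed + r
      model <- train_model(train_set, cfg)
      preds <- classify_test_set(split, model, store)
      met <- confusion_metrics(preds$true_label, preds$predicted)
      met$auc <- binary_auc(met$sensitivity, met$specificity)
      met
    }, error = function(e) {
      stop("repeat ", r, " failed: ", conditionMessage(e), call. = FALSE)
    })
    roc[[r + 1L]] <- roc_points(res$sensitivity, res$specificity)
    per[[r + 1L]] <- data.frame(
      repeat_index = r, TP = res$TP, FP = res$FP, TN = res$TN, FN = res$FN,
      sensitivity = res$sensitivity, specificity = res$specificity,
      precision = res$precision, F1 = res$F1, auc = res$auc
    )
  }
  per_repeat <- do.call(rbind, per)
  metric_cols <- c("sensitivity", "specificity", "precision", "F1", "auc")
  aggregate <- colMeans(per_repeat[, metric_cols, drop = FALSE])
  structure(list(per_repeat = per_repeat, aggregate = aggregate, roc = roc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cat("evaluation_report:", nrow(x$per_repeat), "repeat(s)\n")
  print(round(x$per_repeat, digits))
  cat("aggregate (mean across repeats):\n")
  print(round(x$aggregate, digits))
  invisible(x)
}
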