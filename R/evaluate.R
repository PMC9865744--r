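# Classifier evaluation: per-class precision/recall/F1, macro-average F1,
# accuracy, and the row-normalized confusion matrix.

#' Evaluate a classifier on labeled data
#'
#' @param model A `conformo_cnn`.
#' @param x Normalized feature matrix.
#' @param y True states aligned with the rows of `x`.
#' @return Object of class `conformo_eval`: list with `confusion` (raw
#'   counts, rows = true, columns = predicted, in [state_levels()] order),
#'   `confusion_normalized` (rows summing to 1), `metrics` (tibble
#'   `class,precision,recall,f1,support`), `macro_f1` (unweighted mean of
#'   the per-class F1), and `accuracy`.
#' @export
evaluate_model <- function(model, x, y) {
  if (length(y) == 0 || nrow(as.matrix(x)) == 0) abort("empty evaluation set")
  pred <- predict(model, x)
  eval_report(truth = y, estimate = pred,
              class_levels = model$class_levels)
}

#' Build an evaluation report from predictions
#'
#' The computation behind [evaluate_model()], usable with any predictions.
#'
#' @param truth,estimate Character/factor vectors of true and predicted
#'   states.
#' @param class_levels Class order (default [state_levels()]).
#' @return A `conformo_eval` (see [evaluate_model()]).
#' @export
eval_report <- function(truth, estimate, class_levels = state_levels()) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate lengths differ")
  }
  truth <- factor(as.character(truth), levels = class_levels)
  estimate <- factor(as.character(estimate), levels = class_levels)
  conf <- table(truth = truth, predicted = estimate)
  conf <- matrix(as.integer(conf), nrow = length(class_levels),
                 dimnames = list(truth = class_levels,
                                 predicted = class_levels))
  tp <- diag(conf)
  support <- rowSums(conf)
  pred_n <- colSums(conf)
  precision <- ifelse(pred_n > 0, tp / pred_n, NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  metrics <- tibble(class = class_levels, precision = unname(precision),
                    recall = unname(recall), f1 = unname(f1),
                    support = as.integer(unname(support)))
  norm <- conf / ifelse(support > 0, support, 1)
  structure(list(confusion = conf, confusion_normalized = norm,
                 metrics = metrics, macro_f1 = mean(f1, na.rm = TRUE),
                 accuracy = sum(tp) / sum(conf)),
            class = "conformo_eval")
}

#' @export
print.conformo_eval <- function(x, ...) {
  cat("Classification report\n")
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 4)
  cat(sprintf("macro-avg F1: %.4f   accuracy: %.4f\n", x$macro_f1,
              x$accuracy))
  invisible(x)
}

#' Write the confusion matrix (and metrics) as CSV
#' @param report A `conformo_eval`.
#' @param path CSV path for the row-normalized confusion matrix; per-class
#'   metrics go to `<path base>_metrics.csv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  cm <- as_tibble(report$confusion_normalized, rownames = "truth")
  readr::write_csv(cm, path, progress = FALSE)
  readr::write_csv(report$metrics,
                   sub("(\\.csv)?$", "_metrics.csv", path, perl = TRUE),
                   progress = FALSE)
  invisible(path)
}
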