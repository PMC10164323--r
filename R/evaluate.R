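# Validation protocol: subset-correctness, the two accuracies, and the
# under/overestimated one-vs-rest ROC AUC and MCC conventions for
# multilabel molecules classified with a single argmax set.

truth_sets <- function(predictions, truth) {
  sets <- truth$descriptors[match(predictions$id, truth$id)]
  if (any(vapply(sets, is.null, logical(1)))) {
    abort("`truth` must contain every predicted molecule id")
  }
  sets
}

#' Mark predictions as correct, incorrect, or not assessable
#'
#' A prediction is correct iff the molecule was predictable and the
#' predicted set is a subset of the true descriptor set.  Unpredictable
#' molecules are neither correct nor incorrect (`NA`), but still count in
#' the overall-accuracy denominator.
#'
#' @param predictions Prediction tibble from [predict.owsum_model()].
#' @param truth Molecule tibble with true `descriptors`.
#' @return `predictions` with an added logical `correct` column.
#' @export
is_correct <- function(predictions, truth) {
  sets <- truth_sets(predictions, truth)
  correct <- map_lgl(seq_len(nrow(predictions)), function(k) {
    if (predictions$status[k] != "predicted") return(NA)
    length(predictions$predicted[[k]]) > 0 &&
      all(predictions$predicted[[k]] %in% sets[[k]])
  })
  mutate(predictions, correct = correct)
}

#' Overall and predicted accuracy
#'
#' Overall accuracy divides correct predictions by all tested molecules
#' (unpredictable ones included); predicted accuracy divides by the
#' predictable molecules only.  Both are reported as percentages.
#'
#' @inheritParams is_correct
#' @return One-row tibble: `overall_accuracy`, `predicted_accuracy`
#'   (`NA` when nothing was predictable), `nonpredictable_pct`, `n`,
#'   `n_predictable`, `n_correct`.
#' @export
accuracies <- function(predictions, truth) {
  marked <- is_correct(predictions, truth)
  n <- nrow(marked)
  n_pred <- sum(marked$status == "predicted")
  n_corr <- sum(marked$correct, na.rm = TRUE)
  tibble(
    overall_accuracy = 100 * n_corr / n,
    predicted_accuracy = if (n_pred > 0) 100 * n_corr / n_pred else NA_real_,
    nonpredictable_pct = 100 * (n - n_pred) / n,
    n = n, n_predictable = n_pred, n_correct = n_corr
  )
}

#' One-vs-rest label vectors under the two multilabel conventions
#'
#' For a focus class, the predicted bit is 1 iff the class is in the
#' predicted set (unpredictable molecules contribute 0).  The true bit is
#' the class membership, except for a molecule that carries the focus
#' class along with other true labels and whose prediction hit one of the
#' others: `underestimated` keeps true = 1 (scoring the hit as a miss for
#' the focus class, a lower bound), `overestimated` reassigns the molecule
#' to the rest class, true = 0 (an upper bound).
#'
#' @inheritParams is_correct
#' @param class Focus class label.
#' @param mode `"underestimated"` or `"overestimated"`.
#' @return Tibble `id`, `true`, `pred` of 0/1 bits.
#' @export
one_vs_rest_labels <- function(predictions, truth, class,
                               mode = c("underestimated", "overestimated")) {
  mode <- match.arg(mode)
  sets <- truth_sets(predictions, truth)
  pred_bit <- map_int(predictions$predicted, function(p) {
    as.integer(class %in% p)
  })
  true_bit <- map_int(seq_len(nrow(predictions)), function(k) {
    tr <- sets[[k]]
    if (!class %in% tr) return(0L)
    hit_other <- pred_bit[k] == 0L &&
      length(intersect(predictions$predicted[[k]], setdiff(tr, class))) > 0
    if (hit_other && mode == "overestimated") 0L else 1L
  })
  tibble(id = predictions$id, true = true_bit, pred = pred_bit)
}

#' Rank-based binary ROC AUC for hard predictions
#'
#' Treats the 0/1 predicted labels as scores and computes the rank-based
#' area under the ROC curve (ties count one half).  A constant truth
#' vector has no defined AUC and yields `NA`.
#'
#' @param true,pred Equal-length 0/1 vectors.
#' @return AUC in \[0, 1\], or `NA` when truth is constant.
#' @export
roc_auc_binary <- function(true, pred) {
  if (length(true) != length(pred)) abort("`true` and `pred` lengths differ")
  if (length(unique(true)) < 2L) return(NA_real_)
  r <- pROC::roc(response = true, predictor = as.numeric(pred),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Matthews correlation for binary predictions
#'
#' Standard MCC from the 2x2 confusion table, with two conventions for
#' degenerate tables: if truth and prediction are both all zeros the MCC
#' is defined as 1 (a vacuously perfect rest-class assignment, arising
#' only under the overestimated convention); any other zero-denominator
#' case yields 0.
#'
#' @inheritParams roc_auc_binary
#' @return MCC in \[-1, 1\].
#' @export
mcc_binary <- function(true, pred) {
  if (length(true) != length(pred)) abort("`true` and `pred` lengths differ")
  true <- as.integer(true); pred <- as.integer(pred)
  if (all(true == 0L) && all(pred == 0L)) return(1)
  tp <- sum(true == 1 & pred == 1)
  tn <- sum(true == 0 & pred == 0)
  fp <- sum(true == 0 & pred == 1)
  fn <- sum(true == 1 & pred == 0)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Full multilabel evaluation of a set of predictions
#'
#' Combines the accuracies with per-class underestimated and
#' overestimated one-vs-rest ROC AUC and MCC, plus their class means
#' (classes with undefined AUC are excluded from the mean).
#'
#' @inheritParams is_correct
#' @param classes Class set to evaluate over; defaults to all descriptors
#'   in `truth`.
#' @return List of class `owsum_eval`: `accuracy` (one-row tibble),
#'   `per_class` (tibble of per-class metrics), `means` (one-row tibble).
#' @export
evaluate_multilabel <- function(predictions, truth, classes = NULL) {
  classes <- classes %||% sort(unique(unlist(truth$descriptors)))
  per_class <- dplyr::bind_rows(lapply(classes, function(cl) {
    un <- one_vs_rest_labels(predictions, truth, cl, "underestimated")
    ov <- one_vs_rest_labels(predictions, truth, cl, "overestimated")
    tibble(
      class = cl,
      auc_under = roc_auc_binary(un$true, un$pred),
      auc_over = roc_auc_binary(ov$true, ov$pred),
      mcc_under = mcc_binary(un$true, un$pred),
      mcc_over = mcc_binary(ov$true, ov$pred)
    )
  }))
  means <- summarise(
    per_class,
    mean_auc_under = mean(.data$auc_under, na.rm = TRUE),
    mean_auc_over = mean(.data$auc_over, na.rm = TRUE),
    mean_mcc_under = mean(.data$mcc_under, na.rm = TRUE),
    mean_mcc_over = mean(.data$mcc_over, na.rm = TRUE)
  )
  structure(list(
    accuracy = accuracies(predictions, truth),
    per_class = per_class,
    means = means
  ), class = "owsum_eval")
}

#' @export
print.owsum_eval <- function(x, ...) {
  a <- x$accuracy
  cat(sprintf(
    "Overall accuracy %.1f%% | predicted accuracy %s | non-predictable %.1f%%\n",
    a$overall_accuracy,
    if (is.na(a$predicted_accuracy)) "undefined"
    else sprintf("%.1f%%", a$predicted_accuracy),
    a$nonpredictable_pct))
  m <- x$means
  cat(sprintf("Mean ROC AUC under/over: %.2f / %.2f | mean MCC under/over: %.2f / %.2f\n",
              m$mean_auc_under, m$mean_auc_over,
              m$mean_mcc_under, m$mean_mcc_over))
  invisible(x)
}
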