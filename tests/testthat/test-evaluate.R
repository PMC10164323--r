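# hand-built prediction tibbles; no chemistry required
pred_tbl <- function(ids, status, predicted) {
  tibble::tibble(id = ids, status = status, predicted = predicted)
}

test_that("a predicted subset of the true labels is correct", {
  truth <- tibble::tibble(id = c("a", "b", "c"),
                          descriptors = list(c("floral", "perfumery"),
                                             "medicinal", "woody"))
  pred <- pred_tbl(c("a", "b", "c"),
                   c("predicted", "predicted", "unpredictable"),
                   list("floral", "floral", character()))
  marked <- is_correct(pred, truth)
  expect_equal(marked$correct, c(TRUE, FALSE, NA))
})

test_that("overall and predicted accuracies divide by the right counts", {
  # 10 tested, 8 predictable, 6 correct -> 60% overall, 75% predicted
  truth <- tibble::tibble(id = paste0("m", 1:10),
                          descriptors = rep(list("x"), 10))
  status <- c(rep("predicted", 8), rep("unpredictable", 2))
  predicted <- c(rep(list("x"), 6), rep(list("y"), 2),
                 rep(list(character()), 2))
  acc <- accuracies(pred_tbl(paste0("m", 1:10), status, predicted), truth)
  expect_equal(acc$overall_accuracy, 60)
  expect_equal(acc$predicted_accuracy, 75)
  expect_equal(acc$nonpredictable_pct, 20)
})

test_that("without unpredictable molecules the two accuracies coincide", {
  truth <- tibble::tibble(id = c("a", "b"), descriptors = list("x", "y"))
  pred <- pred_tbl(c("a", "b"), c("predicted", "predicted"),
                   list("x", "x"))
  acc <- accuracies(pred, truth)
  expect_equal(acc$overall_accuracy, acc$predicted_accuracy)
})

test_that("all-unpredictable data has undefined predicted accuracy", {
  truth <- tibble::tibble(id = "a", descriptors = list("x"))
  pred <- pred_tbl("a", "unpredictable", list(character()))
  acc <- accuracies(pred, truth)
  expect_equal(acc$overall_accuracy, 0)
  expect_true(is.na(acc$predicted_accuracy))
})

test_that("one-vs-rest bits follow the two multilabel conventions", {
  # molecule with true {floral, perfumery}, predicted {floral}:
  # focus perfumery -> under (1, 0), over (0, 0)
  truth <- tibble::tibble(id = "a", descriptors = list(c("floral",
                                                         "perfumery")))
  pred <- pred_tbl("a", "predicted", list("floral"))
  un <- one_vs_rest_labels(pred, truth, "perfumery", "underestimated")
  expect_equal(c(un$true, un$pred), c(1L, 0L))
  ov <- one_vs_rest_labels(pred, truth, "perfumery", "overestimated")
  expect_equal(c(ov$true, ov$pred), c(0L, 0L))
  # focus floral: the hit itself is (1, 1) under both conventions
  for (mode in c("underestimated", "overestimated")) {
    fl <- one_vs_rest_labels(pred, truth, "floral", mode)
    expect_equal(c(fl$true, fl$pred), c(1L, 1L))
  }
  # an unpredictable molecule contributes predicted = 0
  pred_u <- pred_tbl("a", "unpredictable", list(character()))
  uu <- one_vs_rest_labels(pred_u, truth, "floral", "underestimated")
  expect_equal(c(uu$true, uu$pred), c(1L, 0L))
})

test_that("a genuinely wrong prediction stays a miss in both conventions", {
  truth <- tibble::tibble(id = "a", descriptors = list(c("floral",
                                                         "perfumery")))
  pred <- pred_tbl("a", "predicted", list("woody"))
  for (mode in c("underestimated", "overestimated")) {
    b <- one_vs_rest_labels(pred, truth, "floral", mode)
    expect_equal(c(b$true, b$pred), c(1L, 0L))
  }
})

test_that("hard-label AUC matches pair enumeration on worked examples", {
  expect_equal(roc_auc_binary(c(1, 0, 0, 1), c(1, 0, 0, 0)), 0.75)
  expect_equal(roc_auc_binary(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(roc_auc_binary(c(1, 0, 1, 0), c(0, 0, 0, 0)), 0.5)
  expect_true(is.na(roc_auc_binary(c(1, 1), c(1, 0))))
  expect_error(roc_auc_binary(c(1, 0), c(1, 0, 0)), "length")
})

test_that("MCC follows the confusion table and its conventions", {
  expect_equal(mcc_binary(c(0, 0, 0), c(0, 0, 0)), 1)    # vacuous rest class
  expect_equal(mcc_binary(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_equal(mcc_binary(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(mcc_binary(c(1, 0), c(0, 1)), -1)
  expect_equal(mcc_binary(c(1, 1, 1, 1), c(1, 1, 1, 1)), 0)  # zero denominator
  expect_error(mcc_binary(c(1, 0), c(1)), "length")
})

test_that("overall accuracy equals predicted accuracy times coverage", {
  set.seed(9)
  for (r in 1:10) {
    inst <- random_instance(10, 3, 3)
    truth <- as_truth_tbl(inst$labels)
    fit <- owsum_fit(as_feature_tbl(inst$occ), as_label_tbl(inst$labels),
                     variant = "same_weighted", feature_selection = FALSE)
    pred <- predict(fit, as_feature_tbl(inst$occ))
    acc <- accuracies(pred, truth)
    if (!is.na(acc$predicted_accuracy)) {
      expect_equal(acc$overall_accuracy,
                   acc$predicted_accuracy *
                     (100 - acc$nonpredictable_pct) / 100)
    }
  }
})
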