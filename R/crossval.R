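#' k-fold cross-validation of an OWSum model
#'
#' Shuffles molecules with an explicit seed, splits them into `k`
#' near-equal folds, refits the model on each training complement
#' (conditional probabilities, idf and the feature-selection mask are all
#' recomputed per fold) and predicts the held-out fold.  The feature
#' catalog itself is fixed across folds; held-out molecules whose only
#' informative features were unseen in a fold's training data simply find
#' no usable features there.  Metrics are computed on the pooled held-out
#' predictions of all folds and averaged across classes, or per fold when
#' `per_fold = TRUE`.
#'
#' @param molecules Labeled molecule tibble.
#' @param catalog SMARTS catalog; ignored when `features` is supplied.
#' @param features Optional precomputed occurrence tibble for `molecules`.
#' @inheritParams owsum_fit
#' @param k Number of folds (>= 2); `k = nrow(molecules)` gives
#'   leave-one-out.
#' @param seed Integer seed controlling the shuffle.
#' @param stratified Deal molecules of each primary (first-listed)
#'   descriptor round-robin across folds instead of a plain shuffle.
#' @param per_fold Average per-class metrics over folds instead of
#'   pooling all held-out predictions.
#' @return An object of class `owsum_cv`: the pooled `predictions` (with
#'   fold ids), the `evaluation` (`owsum_eval`), the fold assignment and
#'   the resolved configuration.
#' @examples
#' sim <- simulate_molecules(n_per_class = 5, seed = 1)
#' cv <- owsum_crossval(sim, simulated_catalog(sim), k = 5, seed = 1)
#' glance(cv)
#' @export
owsum_crossval <- function(molecules, catalog = NULL, features = NULL,
                           k = 5, seed = 1, variant = "tfidf_weighted",
                           feature_selection = TRUE, log_base = exp(1),
                           stratified = FALSE, per_fold = FALSE) {
  n <- nrow(molecules)
  if (k < 2) abort("`k` must be >= 2")
  if (n < k) abort("need at least `k` molecules")
  if (is.null(features)) {
    if (is.null(catalog)) abort("supply `catalog` or `features`")
    features <- occurrence_table(molecules, catalog)
  }
  labels_all <- label_table(molecules)
  classes <- setdiff(names(labels_all), "id")

  fold <- with_seed(seed, {
    perm <- sample.int(n)
    if (stratified) {
      primary <- map_chr(molecules$descriptors, function(d) {
        if (length(d)) d[1] else ""
      })
      ord <- perm[order(primary[perm])]
      f <- integer(n)
      f[ord] <- rep_len(seq_len(k), n)
      f
    } else {
      f <- integer(n)
      f[perm] <- rep_len(seq_len(k), n)
      f
    }
  })

  preds <- dplyr::bind_rows(lapply(seq_len(k), function(fi) {
    tr <- fold != fi
    mols_tr <- molecules[tr, , drop = FALSE]
    train_classes <- sort(unique(unlist(mols_tr$descriptors)))
    if (length(train_classes) < length(classes)) {
      warn(paste0("fold ", fi, ": class(es) absent from training split: ",
                  paste(setdiff(classes, train_classes), collapse = ", ")))
    }
    fit <- owsum_fit(features[tr, , drop = FALSE],
                     label_table(mols_tr, classes = train_classes),
                     variant = variant, feature_selection = feature_selection,
                     log_base = log_base)
    mutate(predict(fit, features[!tr, , drop = FALSE]), fold = fi)
  }))
  preds <- preds[match(molecules$id, preds$id), , drop = FALSE]

  evaluation <- if (per_fold) {
    per <- lapply(seq_len(k), function(fi) {
      evaluate_multilabel(filter(preds, .data$fold == fi), molecules,
                          classes = classes)
    })
    pooled <- evaluate_multilabel(preds, molecules, classes = classes)
    pooled$means <- dplyr::bind_rows(lapply(per, function(e) e$means)) |>
      summarise(dplyr::across(dplyr::everything(),
                              ~ mean(.x, na.rm = TRUE)))
    pooled
  } else {
    evaluate_multilabel(preds, molecules, classes = classes)
  }

  structure(list(
    predictions = preds,
    evaluation = evaluation,
    folds = tibble(id = molecules$id, fold = fold),
    config = list(k = k, seed = seed, variant = variant,
                  feature_selection = feature_selection,
                  log_base = log_base, stratified = stratified,
                  per_fold = per_fold, n = n, classes = classes)
  ), class = "owsum_cv")
}

#' @export
print.owsum_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s, seed %d, n = %d)\n",
              x$config$k, x$config$variant, x$config$seed, x$config$n))
  print(x$evaluation)
  invisible(x)
}

#' Per-class cross-validation metrics in long form
#'
#' @param x An `owsum_cv` object.
#' @param ... Unused.
#' @export
tidy.owsum_cv <- function(x, ...) {
  tidyr::pivot_longer(x$evaluation$per_class, -"class",
                      names_to = "metric", values_to = "value")
}

#' One-row cross-validation summary
#'
#' @param x An `owsum_cv` object.
#' @param ... Unused.
#' @export
glance.owsum_cv <- function(x, ...) {
  dplyr::bind_cols(x$evaluation$accuracy, x$evaluation$means,
                   tibble(k = x$config$k, seed = x$config$seed,
                          variant = x$config$variant))
}

#' Dot plot of per-class cross-validation metrics
#'
#' @param object An `owsum_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.owsum_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$class,
                                   colour = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "metric value", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a cross-validation report as JSON
#'
#' Serializes accuracies, per-class and mean metrics, the fold assignment
#' and the resolved configuration so a run is fully reproducible from its
#' report.
#'
#' @param cv An `owsum_cv` object.
#' @param path Output path.
#' @export
write_cv_report <- function(cv, path) {
  jsonlite::write_json(list(
    config = cv$config,
    accuracy = cv$evaluation$accuracy,
    per_class = cv$evaluation$per_class,
    means = cv$evaluation$means,
    folds = cv$folds
  ), path, auto_unbox = TRUE, digits = 10, na = "null")
  invisible(path)
}
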