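#' Score and classify molecules with a fitted OWSum model
#'
#' Each class score is the sum of the influences of the selected, trained
#' features present in the molecule.  The predicted set is the argmax of
#' the scores; a molecule whose argmax spans every class — in particular
#' one with no usable features — is `unpredictable` and gets an empty
#' predicted set.  Features the model never saw in training contribute
#' nothing.
#'
#' @param object A fitted `owsum_model`.
#' @param new_data A molecule tibble (with a `smiles` column; featurized
#'   against the model's patterns) or an occurrence tibble that contains a
#'   column for every model pattern.
#' @param ... Unused.
#' @return Tibble with one row per molecule: `id`, `status` (`"predicted"`
#'   or `"unpredictable"`), `predicted` (list-column of class labels,
#'   empty when unpredictable; ties return every tied class),
#'   `used_features`, and one `score_<class>` column per class.
#' @examples
#' toy <- toy_fixture()
#' fit <- owsum(toy$molecules, toy$catalog)
#' predict(fit, toy$molecules)
#' @export
predict.owsum_model <- function(object, new_data, ...) {
  if ("smiles" %in% names(new_data)) {
    features <- occurrence_table(new_data, object$patterns)
  } else {
    missing <- setdiff(object$patterns, names(new_data))
    if (length(missing)) {
      abort(paste0("occurrence table lacks model pattern(s): ",
                   paste(missing, collapse = "  ")))
    }
    features <- new_data[, c("id", object$patterns)]
  }
  X <- occ_matrix(features)
  usable <- object$patterns[object$selected[object$patterns]]
  Xu <- X[, usable, drop = FALSE]
  S <- Xu %*% t(object$influence[, usable, drop = FALSE])
  used <- as.integer(rowSums(Xu))
  n_class <- length(object$classes)

  rows <- lapply(seq_len(nrow(X)), function(k) {
    amax <- argmax_set(S[k, ])
    if (used[k] == 0L || length(amax) == n_class) {
      list(status = "unpredictable", predicted = character())
    } else {
      list(status = "predicted", predicted = object$classes[amax])
    }
  })
  scores <- as.data.frame(S)
  names(scores) <- paste0("score_", object$classes)
  dplyr::bind_cols(
    tibble(id = features$id,
           status = map_chr(rows, "status"),
           predicted = map(rows, "predicted"),
           used_features = used),
    as_tibble(scores)
  )
}

#' Per-class influence ranking of features
#'
#' Orders the selected features of one class by decreasing influence, the
#' model's native interpretation device: the top patterns are the
#' substructures that push a molecule hardest toward that odor.  Equal
#' influences are grouped by a shared dense rank, and `n_at_influence`
#' counts the features tied at each value.
#'
#' @param model A fitted `owsum_model`.
#' @param class One class label present in the model.
#' @return Tibble `rank`, `pattern`, `influence`, `n_at_influence`, sorted
#'   by decreasing influence.
#' @export
rank_features <- function(model, class) {
  if (!class %in% model$classes) {
    abort(paste0("unknown class: ", class))
  }
  pats <- model$patterns[model$selected[model$patterns]]
  inf <- model$influence[class, pats]
  out <- tibble(pattern = pats, influence = unname(inf)) |>
    arrange(desc(.data$influence), .data$pattern) |>
    mutate(rank = dense_rank(desc(.data$influence)))
  out |>
    group_by(.data$influence) |>
    mutate(n_at_influence = dplyr::n()) |>
    ungroup() |>
    select("rank", "pattern", "influence", "n_at_influence")
}

#' Signed influence differences between two classes
#'
#' For every selected feature, `influence(class_a) - influence(class_b)`:
#' positive values mark substructures that pull toward `class_a`,
#' negative toward `class_b`.  Passing the same class twice returns all
#' zeros (a valid degenerate comparison).
#'
#' @param model A fitted `owsum_model`.
#' @param class_a,class_b Class labels present in the model.
#' @return Tibble `pattern`, `influence_a`, `influence_b`, `difference`,
#'   sorted by decreasing difference.
#' @export
influence_difference <- function(model, class_a, class_b) {
  for (cl in c(class_a, class_b)) {
    if (!cl %in% model$classes) abort(paste0("unknown class: ", cl))
  }
  pats <- model$patterns[model$selected[model$patterns]]
  tibble(
    pattern = pats,
    influence_a = unname(model$influence[class_a, pats]),
    influence_b = unname(model$influence[class_b, pats])
  ) |>
    mutate(difference = .data$influence_a - .data$influence_b) |>
    arrange(desc(.data$difference), .data$pattern)
}
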