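# Model and prediction serialization.  A model file is a single TSV with
# a JSON header line (prefixed "#") carrying everything the matrices do
# not: variant, class sizes, log base, selection flag, training size and
# a hash of the catalog, so a saved model predicts without retraining.

#' Write a fitted OWSum model to TSV
#'
#' @param model An `owsum_model`.
#' @param path Output path.
#' @export
write_owsum <- function(model, path) {
  header <- jsonlite::toJSON(list(
    variant = model$variant,
    feature_selection = model$feature_selection,
    log_base = model$log_base,
    n_train = model$n_train,
    class_sizes = as.list(model$class_sizes),
    untrained = model$untrained,
    catalog_hash = rlang::hash(model$patterns)
  ), auto_unbox = TRUE, digits = NA)
  body <- tidy(model) |>
    select(class = "class", smarts = "pattern", G = "g", idf = "idf",
           tfidf = "tf_idf", a = "weighting", influence = "influence",
           selected = "selected")
  writeLines(paste0("#", header), path)
  readr::write_tsv(body, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a fitted OWSum model written by [write_owsum()]
#'
#' @param path Model TSV path.
#' @return An `owsum_model` ready for prediction.
#' @export
read_owsum <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) abort("not an OWSum model file (no JSON header)")
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  # skip the JSON header line; `comment = "#"` would truncate the SMARTS
  # atomic-number primitive [#6]
  body <- readr::read_tsv(path, skip = 1, show_col_types = FALSE,
                          progress = FALSE)
  classes <- unique(body$class)
  patterns <- unique(body$smarts)
  as_mat <- function(col) {
    m <- matrix(body[[col]], nrow = length(classes), byrow = TRUE,
                dimnames = list(classes, patterns))
    m
  }
  class_sizes <- unlist(meta$class_sizes)[classes]
  idf <- setNames(body$idf[seq_along(patterns)], patterns)
  selected <- setNames(as.logical(body$selected[seq_along(patterns)]),
                       patterns)
  structure(list(
    classes = classes, patterns = patterns, class_sizes = class_sizes,
    n_train = meta$n_train,
    G = as_mat("G"), idf = idf, tfidf = as_mat("tfidf"), a = as_mat("a"),
    influence = as_mat("influence"), selected = selected,
    untrained = as.character(meta$untrained %||% character()),
    variant = meta$variant, feature_selection = meta$feature_selection,
    log_base = meta$log_base
  ), class = "owsum_model")
}

#' Write predictions as CSV
#'
#' Flat prediction export: `id,status,predicted,score_<class>...` with
#' multi-class predictions joined by `;`.
#'
#' @param predictions Prediction tibble from [predict.owsum_model()].
#' @param path Output path.
#' @param sep Join separator for multi-class predictions.
#' @export
write_predictions <- function(predictions, path, sep = ";") {
  out <- mutate(predictions,
                predicted = map_chr(.data$predicted, paste, collapse = sep))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
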