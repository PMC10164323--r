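#' @export
print.owsum_model <- function(x, ...) {
  cat("OWSum model (", x$variant, ")\n", sep = "")
  cat("  classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  cat(sprintf("  features: %d trained (%d selected, %d untrained dropped)\n",
              length(x$patterns), sum(x$selected), length(x$untrained)))
  cat(sprintf("  trained on %d molecules; feature selection %s; log base %.4g\n",
              x$n_train, if (x$feature_selection) "on" else "off",
              x$log_base))
  invisible(x)
}

#' Tidy an OWSum model into one row per class/feature pair
#'
#' @param x An `owsum_model`.
#' @param ... Unused.
#' @return Tibble `class`, `pattern`, `g`, `idf`, `tf_idf`, `weighting`,
#'   `influence`, `selected`.
#' @export
tidy.owsum_model <- function(x, ...) {
  tibble(
    class = rep(x$classes, each = length(x$patterns)),
    pattern = rep(x$patterns, times = length(x$classes)),
    g = as.vector(t(x$G)),
    idf = rep(unname(x$idf), times = length(x$classes)),
    tf_idf = as.vector(t(x$tfidf)),
    weighting = as.vector(t(x$a)),
    influence = as.vector(t(x$influence)),
    selected = rep(unname(x$selected), times = length(x$classes))
  )
}

#' One-row summary of an OWSum model
#'
#' @param x An `owsum_model`.
#' @param ... Unused.
#' @export
glance.owsum_model <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_features = length(x$patterns),
    n_selected = sum(x$selected),
    n_untrained = length(x$untrained),
    n_train = x$n_train,
    variant = x$variant,
    feature_selection = x$feature_selection,
    log_base = x$log_base
  )
}

#' Bar chart of the most influential features per class
#'
#' @param object An `owsum_model`.
#' @param top_n Features shown per class.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.owsum_model <- function(object, top_n = 8, ...) {
  df <- dplyr::bind_rows(lapply(object$classes, function(cl) {
    mutate(head(rank_features(object, cl), top_n), class = cl)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$influence,
                                   stats::reorder(.data$pattern,
                                                  .data$influence))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "influence", y = NULL) +
    ggplot2::theme_minimal()
}
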