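# Descriptor overlap: how interchangeable two odor labels are on a dataset.

descriptor_sets <- function(molecules) {
  classes <- sort(unique(unlist(molecules$descriptors)))
  sets <- lapply(classes, function(cl) {
    molecules$id[map_lgl(molecules$descriptors, function(d) cl %in% d)]
  })
  setNames(sets, classes)
}

#' Overlap between two descriptors
#'
#' The number of molecules carrying both descriptors divided by the
#' molecule count of the rarer descriptor.  1 means the rarer descriptor's
#' molecules are contained in the other's; 0 means no molecule carries
#' both.
#'
#' @param molecules Molecule tibble with descriptor sets.
#' @param desc1,desc2 Descriptor labels; each must describe at least one
#'   molecule.
#' @return A single value in \[0, 1\].
#' @export
descriptor_overlap <- function(molecules, desc1, desc2) {
  sets <- descriptor_sets(molecules)
  for (d in c(desc1, desc2)) {
    if (is.null(sets[[d]]) || length(sets[[d]]) == 0L) {
      abort(paste0("descriptor has no molecules: ", d))
    }
  }
  length(intersect(sets[[desc1]], sets[[desc2]])) /
    min(length(sets[[desc1]]), length(sets[[desc2]]))
}

#' Pairwise descriptor-overlap matrix
#'
#' @param molecules Molecule tibble with at least two distinct descriptors.
#' @return A symmetric numeric matrix (class `owsum_overlap`) with unit
#'   diagonal; descriptors ordered alphabetically.
#' @examples
#' toy <- toy_fixture()
#' overlap_matrix(toy$molecules)
#' @export
overlap_matrix <- function(molecules) {
  sets <- descriptor_sets(molecules)
  if (length(sets) < 2L) abort("need at least 2 descriptors")
  k <- length(sets)
  m <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      v <- length(intersect(sets[[i]], sets[[j]])) /
        min(length(sets[[i]]), length(sets[[j]]))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("owsum_overlap", "matrix", "array"))
}

#' Mean overlap of each descriptor with all others
#'
#' The screening statistic used to drop broad-spectrum, non-selective
#' descriptors: the arithmetic mean of a descriptor's overlaps with every
#' other descriptor, self excluded.
#'
#' @param x An `owsum_overlap` matrix or a molecule tibble.
#' @return Tibble `descriptor`, `mean_overlap`.
#' @export
mean_overlap <- function(x) {
  if (is.data.frame(x)) x <- overlap_matrix(x)
  if (nrow(x) < 2L) abort("need at least 2 descriptors")
  mo <- vapply(seq_len(nrow(x)), function(i) mean(x[i, -i]), numeric(1))
  tibble(descriptor = rownames(x), mean_overlap = mo)
}

#' Overlap edge list for chord-diagram rendering
#'
#' @param molecules Molecule tibble.
#' @return Tibble `desc1`, `desc2`, `shared_count`, `overlap` over all
#'   unordered descriptor pairs.
#' @export
overlap_edges <- function(molecules) {
  sets <- descriptor_sets(molecules)
  if (length(sets) < 2L) abort("need at least 2 descriptors")
  pairs <- combn(names(sets), 2)
  tibble(
    desc1 = pairs[1, ],
    desc2 = pairs[2, ],
    shared_count = map_int(seq_len(ncol(pairs)), function(p) {
      length(intersect(sets[[pairs[1, p]]], sets[[pairs[2, p]]]))
    })
  ) |>
    mutate(overlap = .data$shared_count /
             unname(pmin(lengths(sets)[.data$desc1],
                         lengths(sets)[.data$desc2])))
}

#' @export
print.owsum_overlap <- function(x, digits = 2, ...) {
  cat("Descriptor overlap matrix (", nrow(x), " descriptors)\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Tidy a descriptor-overlap matrix into long form
#'
#' @param x An `owsum_overlap` matrix.
#' @param ... Unused.
#' @export
tidy.owsum_overlap <- function(x, ...) {
  m <- unclass(x)
  tibble(desc1 = rep(rownames(m), times = ncol(m)),
         desc2 = rep(colnames(m), each = nrow(m)),
         overlap = as.vector(m))
}

#' Heat-map of a descriptor-overlap matrix
#'
#' @param object An `owsum_overlap` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.owsum_overlap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$desc1, .data$desc2,
                                   fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "overlap") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Export an overlap matrix as square CSV
#'
#' @param x An `owsum_overlap` matrix.
#' @param path Output path.
#' @export
write_overlap <- function(x, path) {
  df <- as.data.frame(unclass(x), check.names = FALSE)
  df <- cbind(descriptor = rownames(df), df)
  readr::write_csv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}
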