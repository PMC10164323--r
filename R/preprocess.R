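#' Turn raw panel applicability data into a selective multilabel dataset
#'
#' Applies, in order, the filters that reduce a molecules-by-descriptors
#' percent-applicability table to a dataset fit for training:
#' \enumerate{
#'   \item assign a descriptor to a molecule iff its applicability is at
#'     least `applicability_min` percent;
#'   \item keep only descriptors with at least `min_molecules` molecules;
#'   \item drop descriptors whose mean overlap with the survivors exceeds
#'     `mean_overlap_max` (computed once on the post-stage-2 set, or
#'     recomputed after each drop when `iterative = TRUE`);
#'   \item drop the `manual_drop` labels;
#'   \item drop molecules left without any descriptor.
#' }
#' Thresholds follow the literal reading: "at least" is inclusive,
#' "over" is strict.
#'
#' @param raw A data frame whose first column (or the column named by
#'   `id_col`) holds molecule ids and whose remaining numeric columns are
#'   descriptors with percent applicability in \[0, 100\].
#' @param applicability_min Percent threshold for assigning a descriptor.
#' @param min_molecules Minimum molecule count for a descriptor to survive.
#' @param mean_overlap_max Mean-overlap exclusion threshold (fraction).
#' @param manual_drop Descriptor labels to remove unconditionally.
#' @param iterative Recompute mean overlaps after each exclusion instead
#'   of a single pass.
#' @param id_col Name of the id column; defaults to the first column.
#' @return A list of class `owsum_panel` with `molecules` (id/descriptor
#'   tibble; `smiles` is absent since panel data carries none) and
#'   `report`, a tibble of molecule/descriptor counts after every stage.
#' @export
preprocess_panel <- function(raw, applicability_min = 25, min_molecules = 10,
                             mean_overlap_max = 0.49,
                             manual_drop = character(),
                             iterative = FALSE, id_col = NULL) {
  if (!is.numeric(applicability_min) || applicability_min < 0 ||
      applicability_min > 100) {
    abort("`applicability_min` must be a percentage in [0, 100]")
  }
  if (!is.numeric(min_molecules) || min_molecules < 1) {
    abort("`min_molecules` must be >= 1")
  }
  assert_fraction(mean_overlap_max, "mean_overlap_max")
  raw <- as_tibble(raw)
  id_col <- id_col %||% names(raw)[1]
  ids <- as.character(raw[[id_col]])
  vals <- as.matrix(raw[, setdiff(names(raw), id_col), drop = FALSE])
  if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
    abort("applicability values must lie in [0, 100]")
  }
  vals[is.na(vals)] <- 0
  rownames(vals) <- ids

  report <- list()
  log_stage <- function(stage, memb, dropped = character()) {
    report[[length(report) + 1]] <<- tibble(
      stage = stage,
      n_molecules = sum(rowSums(memb) > 0),
      n_descriptors = ncol(memb),
      dropped = paste(dropped, collapse = ";")
    )
  }

  # stage 1: binarize at the applicability threshold
  memb <- (vals >= applicability_min) * 1L
  log_stage("applicability_threshold", memb)

  # stage 2: descriptor support filter
  weak <- colnames(memb)[colSums(memb) < min_molecules]
  memb <- memb[, setdiff(colnames(memb), weak), drop = FALSE]
  log_stage("min_molecule_filter", memb, weak)

  # stage 3: mean-overlap screen
  overlap_dropped <- character()
  repeat {
    if (ncol(memb) < 2L) break
    mols <- membership_to_molecules(memb)
    mo <- mean_overlap(overlap_matrix(mols))
    high <- mo$descriptor[mo$mean_overlap > mean_overlap_max]
    if (!length(high)) break
    if (iterative) {
      # drop only the worst offender, then rescreen
      worst <- mo$descriptor[which.max(mo$mean_overlap)]
      overlap_dropped <- c(overlap_dropped, worst)
      memb <- memb[, setdiff(colnames(memb), worst), drop = FALSE]
    } else {
      overlap_dropped <- high
      memb <- memb[, setdiff(colnames(memb), high), drop = FALSE]
      break
    }
  }
  log_stage("mean_overlap_screen", memb, overlap_dropped)

  # stage 4: manual exclusions
  hit <- intersect(manual_drop, colnames(memb))
  memb <- memb[, setdiff(colnames(memb), manual_drop), drop = FALSE]
  log_stage("manual_drop", memb, hit)

  # stage 5: molecules with no remaining descriptor
  orphan <- rownames(memb)[rowSums(memb) == 0]
  memb <- memb[rowSums(memb) > 0, , drop = FALSE]
  log_stage("drop_unlabeled_molecules", memb, orphan)

  structure(list(
    molecules = membership_to_molecules(memb),
    report = dplyr::bind_rows(report)
  ), class = "owsum_panel")
}

# 0/1 membership matrix -> id/descriptors tibble (no smiles: panel data)
membership_to_molecules <- function(memb) {
  tibble(
    id = rownames(memb) %||% character(),
    descriptors = lapply(seq_len(nrow(memb)), function(i) {
      colnames(memb)[memb[i, ] == 1]
    })
  )
}

#' @export
print.owsum_panel <- function(x, ...) {
  cat("Panel preprocessing result:", nrow(x$molecules), "molecules,",
      length(unique(unlist(x$molecules$descriptors))), "descriptors\n")
  print(x$report)
  invisible(x)
}

#' Default preprocessing thresholds for Dravnieks-atlas-shaped panels
#'
#' The standard recipe for percent-applicability atlases: 25%
#' applicability, 10-molecule descriptor support, 0.49 mean-overlap
#' ceiling, and removal of the inter-individually inconsistent labels
#' `heavy` and `light`.
#'
#' @return Named list of arguments for [preprocess_panel()].
#' @export
dravnieks_recipe <- function() {
  list(applicability_min = 25, min_molecules = 10,
       mean_overlap_max = 0.49, manual_drop = c("heavy", "light"))
}
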