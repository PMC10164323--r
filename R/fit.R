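# OWSum model fitting: conditional-probability weights, idf/tf-idf,
# weighting variants and feature selection.

owsum_variants <- c("same_weighted", "tfidf_weighted",
                    "tfidf_over_prfc", "tfidf_over_prfc_times_prcf")

# shared count machinery: aligns an occurrence tibble and a label tibble
# and returns the matrices every estimator is built from
owsum_counts <- function(features, labels) {
  if (!identical(features$id, labels$id)) {
    labels <- labels[match(features$id, labels$id), , drop = FALSE]
    if (anyNA(labels$id)) {
      abort("`features` and `labels` must cover the same molecule ids")
    }
  }
  X <- occ_matrix(features)            # objects x features, 0/1
  Y <- label_matrix(labels)            # objects x classes, 0/1
  class_sizes <- colSums(Y)
  if (any(class_sizes == 0)) {
    abort(paste0("class(es) with no training molecules: ",
                 paste(colnames(Y)[class_sizes == 0], collapse = ", ")))
  }
  nFC <- t(Y) %*% X                    # classes x features joint counts
  list(X = X, Y = Y, nFC = nFC, nF = colSums(X), class_sizes = class_sizes,
       classes = colnames(Y), patterns = colnames(X))
}

#' Conditional-probability feature weights
#'
#' The weight of feature j for class i is the conditional probability
#' `Pr(F_j | C_i)`, estimated by counting: the fraction of class-i training
#' molecules that contain the feature.  A multilabel molecule contributes
#' to every class it belongs to.
#'
#' @param features Occurrence tibble from [occurrence_table()].
#' @param labels Label tibble from [label_table()] over the same ids.
#' @return Long tibble with columns `class`, `pattern`, `g`.
#' @examples
#' toy <- toy_fixture()
#' occ <- occurrence_table(toy$molecules, toy$catalog)
#' compute_weights(occ, label_table(toy$molecules))
#' @export
compute_weights <- function(features, labels) {
  cnt <- owsum_counts(features, labels)
  G <- sweep(cnt$nFC, 1, cnt$class_sizes, "/")
  tibble(class = rep(rownames(G), each = ncol(G)),
         pattern = rep(colnames(G), times = nrow(G)),
         g = as.vector(t(G)))
}

#' Inverse document frequency of features over classes
#'
#' `idf(j) = log(|C| / #{classes with at least one member containing j})`.
#' A feature present in every class scores 0 (maximally unspecific); one
#' confined to a single class scores `log |C|`.  Features absent from all
#' training molecules have no defined idf and are flagged untrained.
#'
#' @inheritParams compute_weights
#' @param log_base Base of the logarithm (natural log by default; the
#'   choice provably never changes a prediction, see the package vignette).
#' @return Tibble with `pattern`, `n_classes_present`, `idf`, `untrained`.
#' @export
compute_idf <- function(features, labels, log_base = exp(1)) {
  cnt <- owsum_counts(features, labels)
  present <- colSums(cnt$nFC > 0)
  idf <- ifelse(present > 0,
                log(length(cnt$classes) / pmax(present, 1), base = log_base),
                NA_real_)
  tibble(pattern = cnt$patterns,
         n_classes_present = as.integer(unname(present)),
         idf = unname(idf),
         untrained = unname(cnt$nF == 0))
}

#' tf-idf of features per class
#'
#' The term frequency of feature j in class i is the within-class
#' occurrence fraction `#(F_j, C_i) / len(C_i)`, which coincides with the
#' conditional-probability weight; tf-idf is its product with the idf.
#'
#' @inheritParams compute_idf
#' @return Long tibble with `class`, `pattern`, `tf`, `idf`, `tf_idf`.
#' @export
compute_tfidf <- function(features, labels, log_base = exp(1)) {
  g <- compute_weights(features, labels)
  idf <- compute_idf(features, labels, log_base)
  g |>
    left_join(select(idf, "pattern", "idf"), by = "pattern") |>
    mutate(tf = .data$g, tf_idf = .data$tf * .data$idf) |>
    select("class", "pattern", "tf", "idf", "tf_idf")
}

#' Fit an OWSum model
#'
#' Trains the weighted-sum classifier on an occurrence table and a label
#' table: conditional-probability weights G, per-feature idf, the
#' variant-specific weighting factor a, and the influence matrix
#' `I = a * G` that scoring sums over.  With `feature_selection = TRUE`
#' (the default), features with idf = 0 — present in every class, hence
#' uninformative — are dropped from scoring.  Features never seen in
#' training are excluded from the model entirely.
#'
#' @inheritParams compute_idf
#' @param variant Weighting variant: `"same_weighted"` (a = 1),
#'   `"tfidf_weighted"` (a = tf-idf), `"tfidf_over_prfc"`
#'   (a = tf-idf / Pr(F|C), so I = tf-idf), or
#'   `"tfidf_over_prfc_times_prcf"` (additionally multiplied by Pr(C|F)).
#' @param feature_selection Drop idf-zero features from scoring?
#' @return An object of class `owsum_model`.
#' @examples
#' toy <- toy_fixture()
#' occ <- occurrence_table(toy$molecules, toy$catalog)
#' fit <- owsum_fit(occ, label_table(toy$molecules), variant = "tfidf_weighted")
#' tidy(fit)
#' @export
owsum_fit <- function(features, labels, variant = "tfidf_weighted",
                      feature_selection = TRUE, log_base = exp(1)) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% owsum_variants) {
    abort(paste0("unknown variant; must be one of: ",
                 paste(owsum_variants, collapse = ", ")))
  }
  cnt <- owsum_counts(features, labels)
  untrained <- cnt$patterns[cnt$nF == 0]
  keep <- cnt$nF > 0
  nFC <- cnt$nFC[, keep, drop = FALSE]
  nF <- cnt$nF[keep]
  patterns <- cnt$patterns[keep]
  classes <- cnt$classes
  class_sizes <- cnt$class_sizes

  G <- sweep(nFC, 1, class_sizes, "/")
  present <- colSums(nFC > 0)
  idf <- log(length(classes) / present, base = log_base)
  tfidf <- sweep(G, 2, idf, "*")
  PrCF <- sweep(nFC, 2, nF, "/")

  a <- switch(variant,
    same_weighted = matrix(1, nrow(G), ncol(G), dimnames = dimnames(G)),
    tfidf_weighted = tfidf,
    # a = tf-idf / G has a removable singularity at G = 0: the influence
    # a * G equals tf-idf there in the limit, i.e. 0
    tfidf_over_prfc = ifelse(G > 0, tfidf / G, 0),
    tfidf_over_prfc_times_prcf = ifelse(G > 0, tfidf * PrCF / G, 0)
  )
  influence <- a * G

  structure(list(
    classes = classes,
    patterns = patterns,
    class_sizes = class_sizes,
    n_train = nrow(cnt$X),
    G = G, idf = idf, tfidf = tfidf, a = a, influence = influence,
    selected = setNames(if (feature_selection) unname(idf > 0)
                        else rep(TRUE, length(idf)), patterns),
    untrained = untrained,
    variant = variant,
    feature_selection = feature_selection,
    log_base = log_base
  ), class = "owsum_model")
}

#' Fit an OWSum model straight from molecules
#'
#' Convenience front end: featurizes a molecule table against a SMARTS
#' catalog, derives the label table from the `descriptors` column and
#' calls [owsum_fit()].
#'
#' @param molecules Molecule tibble with non-empty descriptor sets.
#' @param catalog SMARTS patterns (character vector or catalog tibble).
#' @inheritParams owsum_fit
#' @return An `owsum_model`.
#' @export
owsum <- function(molecules, catalog, variant = "tfidf_weighted",
                  feature_selection = TRUE, log_base = exp(1)) {
  features <- occurrence_table(molecules, catalog)
  labels <- label_table(molecules)
  owsum_fit(features, labels, variant = variant,
            feature_selection = feature_selection, log_base = log_base)
}
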