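# Independent oracles used across the suite.  Everything here is
# deliberately written as naive loops over definitions (counting,
# pair enumeration, confusion tables) and never calls into the package's
# own estimation code paths.

# counting oracle for the full model: occ and labels are plain 0/1
# matrices (objects x features, objects x classes)
oracle_model <- function(occ, labels, variant = "tfidf_weighted",
                         feature_selection = TRUE, log_base = exp(1)) {
  classes <- colnames(labels)
  feats <- colnames(occ)
  G <- matrix(0, length(classes), length(feats),
              dimnames = list(classes, feats))
  PrCF <- G
  for (ci in classes) {
    members <- which(labels[, ci] == 1)
    for (fj in feats) {
      G[ci, fj] <- sum(occ[members, fj]) / length(members)
      nF <- sum(occ[, fj])
      PrCF[ci, fj] <- if (nF > 0) sum(occ[members, fj]) / nF else 0
    }
  }
  idf <- vapply(feats, function(fj) {
    n_cl <- 0
    for (ci in classes) {
      if (any(occ[labels[, ci] == 1, fj] == 1)) n_cl <- n_cl + 1
    }
    if (n_cl == 0) NA_real_ else log(length(classes) / n_cl, base = log_base)
  }, numeric(1))
  trained <- !is.na(idf)
  tfidf <- G
  for (ci in classes) for (fj in feats) {
    tfidf[ci, fj] <- G[ci, fj] * idf[fj]
  }
  infl <- G
  for (ci in classes) for (fj in feats) {
    a <- switch(variant,
      same_weighted = 1,
      tfidf_weighted = tfidf[ci, fj],
      tfidf_over_prfc = if (G[ci, fj] > 0) tfidf[ci, fj] / G[ci, fj] else 0,
      tfidf_over_prfc_times_prcf =
        if (G[ci, fj] > 0) tfidf[ci, fj] * PrCF[ci, fj] / G[ci, fj] else 0)
    infl[ci, fj] <- a * G[ci, fj]
  }
  selected <- if (feature_selection) trained & idf > 0 else trained
  list(G = G, idf = idf, tfidf = tfidf, influence = infl,
       selected = selected, trained = trained, classes = classes)
}

# score + argmax prediction by direct summation
oracle_predict <- function(om, occ_row) {
  usable <- names(which(om$selected))
  scores <- setNames(numeric(length(om$classes)), om$classes)
  used <- 0
  for (fj in usable) {
    if (occ_row[fj] == 1) {
      used <- used + 1
      for (ci in om$classes) scores[ci] <- scores[ci] + om$influence[ci, fj]
    }
  }
  amax <- which(scores == max(scores))
  if (used == 0 || length(amax) == length(om$classes)) {
    list(status = "unpredictable", predicted = character(), scores = scores)
  } else {
    list(status = "predicted", predicted = om$classes[amax], scores = scores)
  }
}

# rank-based AUC by exhaustive positive/negative pair enumeration
brute_auc <- function(true, pred) {
  pos <- pred[true == 1]
  neg <- pred[true == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# confusion-table MCC with the all-zeros and zero-denominator conventions
brute_mcc <- function(true, pred) {
  if (all(true == 0) && all(pred == 0)) return(1)
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (k in seq_along(true)) {
    if (true[k] == 1 && pred[k] == 1) tp <- tp + 1
    if (true[k] == 0 && pred[k] == 0) tn <- tn + 1
    if (true[k] == 0 && pred[k] == 1) fp <- fp + 1
    if (true[k] == 1 && pred[k] == 0) fn <- fn + 1
  }
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# random multilabel instance; every class is guaranteed a member and
# every object at least one label
random_instance <- function(n_obj, n_feat, n_class) {
  repeat {
    occ <- matrix(rbinom(n_obj * n_feat, 1, 0.5), n_obj, n_feat,
                  dimnames = list(paste0("o", seq_len(n_obj)),
                                  paste0("f", seq_len(n_feat))))
    labels <- matrix(rbinom(n_obj * n_class, 1, 0.4), n_obj, n_class,
                     dimnames = list(paste0("o", seq_len(n_obj)),
                                     LETTERS[seq_len(n_class)]))
    for (k in seq_len(n_obj)) {
      if (sum(labels[k, ]) == 0) labels[k, sample(n_class, 1)] <- 1
    }
    if (all(colSums(labels) > 0)) break
  }
  list(occ = occ, labels = labels)
}

as_feature_tbl <- function(occ) {
  dplyr::bind_cols(tibble::tibble(id = rownames(occ)),
                   tibble::as_tibble(as.data.frame(occ, check.names = FALSE)))
}

as_label_tbl <- as_feature_tbl

# molecules tibble matching a label matrix (ids + descriptor sets only)
as_truth_tbl <- function(labels) {
  tibble::tibble(
    id = rownames(labels),
    descriptors = lapply(seq_len(nrow(labels)), function(k) {
      colnames(labels)[labels[k, ] == 1]
    })
  )
}
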