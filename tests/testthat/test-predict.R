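toy <- toy_fixture()
toy_occ <- occurrence_table(toy$molecules, toy$catalog)
toy_lab <- label_table(toy$molecules)

test_that("scores sum influences of present, selected features only", {
  fit <- owsum_fit(toy_occ, toy_lab, variant = "tfidf_weighted")
  pred <- predict(fit, toy$molecules)
  # M1 has the ester and the ring; the ring is deselected (idf = 0)
  expect_equal(pred$score_A[1], log(2))
  expect_equal(pred$score_B[1], 0)
  expect_equal(pred$used_features[1], 1L)
  expect_equal(pred$predicted[[1]], "A")
})

test_that("molecules with no usable features are unpredictable", {
  fit <- owsum_fit(toy_occ, toy_lab, variant = "tfidf_weighted")
  pred <- predict(fit, molecule_table("hexane", "CCCCCC"))
  expect_equal(pred$status, "unpredictable")
  expect_equal(pred$predicted[[1]], character())
  expect_equal(unname(unlist(pred[1, c("score_A", "score_B")])), c(0, 0))
})

test_that("a tie across all classes is unpredictable", {
  # same-weighted without selection: the shared ring feature scores
  # 0.5 for both classes
  fit <- owsum_fit(toy_occ, toy_lab, variant = "same_weighted",
                   feature_selection = FALSE)
  ring_only <- molecule_table("benzene", "c1ccccc1")
  pred <- predict(fit, ring_only)
  expect_equal(pred$status, "unpredictable")
})

test_that("higher score wins and proper-subset ties return all tied classes", {
  fit <- owsum_fit(toy_occ, toy_lab, variant = "same_weighted",
                   feature_selection = FALSE)
  # ester + sulfur: A gets 1.0 + 0, B gets 0 + 1.0 -> two-way tie over the
  # full class set -> unpredictable; with 3 classes the same tie would be
  # a proper subset, so build one
  mols3 <- molecule_table(
    c("M1", "M2", "M3", "M4", "M5"),
    c("CC(=O)Oc1ccccc1", "CCOC(C)=O", "Sc1ccccc1", "CCS", "CCCO"),
    c("A", "A", "B", "B", "Z")
  )
  occ3 <- occurrence_table(mols3, c(toy$catalog, oh = "[OX2H1]"))
  fit3 <- owsum_fit(occ3, label_table(mols3), variant = "same_weighted",
                    feature_selection = FALSE)
  probe <- molecule_table("p", "CC(=O)OCCS")   # ester + sulfur, no OH
  pred <- predict(fit3, probe)
  expect_equal(pred$status, "predicted")
  expect_setequal(pred$predicted[[1]], c("A", "B"))
})

test_that("untrained features contribute nothing at prediction", {
  fit <- owsum_fit(toy_occ, toy_lab, variant = "tfidf_weighted")
  # thiophene-like probe: sulfur trained, ring deselected, nitrogen unseen
  with_n <- molecule_table("probe", "NCCS")
  pred <- predict(fit, with_n)
  expect_equal(pred$score_B[1], log(2))  # only the sulfur feature counts
})

test_that("removing a feature lowers each class score by its influence", {
  sim <- simulate_molecules(n_per_class = 5, seed = 11)
  fit <- owsum(sim, simulated_catalog(sim))
  occ <- occurrence_table(sim, simulated_catalog(sim))
  row <- occ[3, ]
  present <- names(row)[-1][unlist(row[-1]) == 1]
  present <- intersect(present, names(which(fit$selected)))
  pred_full <- predict(fit, row)
  drop1 <- row
  drop1[[present[1]]] <- 0L
  pred_drop <- predict(fit, drop1)
  for (cl in fit$classes) {
    expect_equal(pred_full[[paste0("score_", cl)]] -
                   pred_drop[[paste0("score_", cl)]],
                 unname(fit$influence[cl, present[1]]))
  }
})

test_that("feature ranking orders by influence with grouped ties", {
  fit <- owsum_fit(toy_occ, toy_lab, variant = "tfidf_weighted")
  rk <- rank_features(fit, "A")
  expect_equal(rk$pattern[1], toy$catalog[["f1"]])
  expect_equal(rk$influence[1], log(2))
  expect_equal(rk$rank, c(1L, 2L))          # f2 deselected; f3 at zero
  expect_error(rank_features(fit, "C"), "unknown class")
})

test_that("influence differences are signed and antisymmetric", {
  fit <- owsum_fit(toy_occ, toy_lab, variant = "tfidf_weighted")
  d <- influence_difference(fit, "A", "B")
  expect_equal(d$difference[d$pattern == toy$catalog[["f1"]]], log(2))
  expect_equal(d$difference[d$pattern == toy$catalog[["f3"]]], -log(2))
  rev <- influence_difference(fit, "B", "A")
  expect_equal(
    rev$difference[match(d$pattern, rev$pattern)], -d$difference)
  same <- influence_difference(fit, "A", "A")
  expect_true(all(same$difference == 0))
})

test_that("rank lists are identical for classes with identical membership", {
  mols <- molecule_table(
    c("m1", "m2", "m3"), c("CCOC(C)=O", "CCS", "CCO"),
    c("X;Y", "X;Y", "X;Y"))
  occ <- occurrence_table(mols, toy$catalog)
  fit <- owsum_fit(occ, label_table(mols), feature_selection = FALSE)
  expect_equal(rank_features(fit, "X"), rank_features(fit, "Y"))
})
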