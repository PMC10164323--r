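test_that("the shared two-carbon chain is found between ethanol and propane", {
  cat <- build_catalog_mcs(c("CCO", "CCC"), min_atoms = 2)
  expect_equal(nrow(cat), 1)
  expect_equal(cat$n_atoms, 2L)
  occ <- occurrence_table(c("CCO", "CCC"), cat)
  expect_equal(unname(unlist(occ[, 2])), c(1L, 1L))
})

test_that("identical molecules give a pattern matching the full molecule", {
  cat <- build_catalog_mcs(c("CCO", "CCO"))
  expect_equal(cat$n_atoms, 3L)
  expect_equal(unname(match_features("CCO", cat$pattern)), 1L)
})

test_that("catalog construction is deterministic", {
  corpus <- bundled_corpus()
  c1 <- build_catalog_mcs(corpus)
  c2 <- build_catalog_mcs(corpus)
  expect_identical(c1, c2)
  path1 <- withr::local_tempfile(); path2 <- withr::local_tempfile()
  write_catalog(c1, path1); write_catalog(c2, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("every emitted pattern matches both molecules of its source pair", {
  # soundness over all 45 pairs of the bundled corpus: recompute per pair
  # and check the pattern against both parents
  corpus <- bundled_corpus()
  pairs <- combn(nrow(corpus), 2)
  for (p in seq_len(ncol(pairs))) {
    two <- corpus[pairs[, p], ]
    cat <- build_catalog_mcs(two, min_atoms = 2)
    if (nrow(cat) == 0) next
    occ <- occurrence_table(two, cat$pattern)
    expect_true(all(occ[[cat$pattern]] == 1L),
                info = paste(two$id, collapse = " vs "))
  }
})

test_that("pairwise MCS sizes agree with an independent implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  corpus <- bundled_corpus()
  script <- '
import sys, json
from rdkit import Chem
from rdkit.Chem import rdFMCS
smiles = json.load(sys.stdin)
mols = [Chem.MolFromSmiles(s) for s in smiles]
out = []
for i in range(len(mols)):
    for j in range(i + 1, len(mols)):
        res = rdFMCS.FindMCS([mols[i], mols[j]],
                             atomCompare=rdFMCS.AtomCompare.CompareElements,
                             bondCompare=rdFMCS.BondCompare.CompareOrder,
                             maximizeBonds=False, timeout=5)
        out.append({"i": i + 1, "j": j + 1, "atoms": res.numAtoms})
json.dump(out, sys.stdout)
'
  sfile <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sfile)
  ref <- jsonlite::fromJSON(system2(
    "python", sfile, input = as.character(jsonlite::toJSON(corpus$smiles)),
    stdout = TRUE))
  skip_if(length(ref) == 0, "reference MCS implementation unavailable")
  sdf <- parse_molecules(corpus)
  graphs <- lapply(seq_len(nrow(corpus)), function(i) owsum:::mol_graph(sdf[[i]]))
  ours <- vapply(seq_len(nrow(ref)), function(k) {
    fr <- owsum:::mcs_pair_graph(graphs[[ref$i[k]]], graphs[[ref$j[k]]])
    if (is.null(fr)) 0L else length(fr$elem)
  }, integer(1))
  expect_equal(ours, ref$atoms)
})

test_that("catalog size equals the count of distinct pairwise patterns", {
  corpus <- bundled_corpus()
  cat <- build_catalog_mcs(corpus, min_atoms = 2)
  pairs <- combn(nrow(corpus), 2)
  seen <- character()
  for (p in seq_len(ncol(pairs))) {
    two <- build_catalog_mcs(corpus[pairs[, p], ], min_atoms = 2)
    seen <- union(seen, two$pattern)
  }
  expect_setequal(cat$pattern, seen)
})

test_that("min_atoms filters small fragments and tiny corpora error", {
  expect_error(build_catalog_mcs(c("CCO")), "at least 2")
  big_only <- build_catalog_mcs(c("CCO", "CCC"), min_atoms = 3)
  expect_equal(nrow(big_only), 0)
})

test_that("aromatic-ring patterns match both kekulized parents", {
  cat <- build_catalog_mcs(c("Cc1ccccc1O", "CCc1ccc(O)cc1"), min_atoms = 4)
  occ <- occurrence_table(c("Cc1ccccc1O", "CCc1ccc(O)cc1"), cat$pattern)
  expect_true(all(as.matrix(occ[, -1]) == 1L))
})

test_that("disjoint element sets yield an empty catalog", {
  expect_equal(nrow(build_catalog_mcs(c("CCC", "OO"), min_atoms = 1)), 0)
})
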