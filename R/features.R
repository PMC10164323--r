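#' Binary occurrence table of SMARTS features
#'
#' Matches every catalog pattern against every molecule and records
#' presence only: a cell is 1 if the molecular graph contains at least
#' one subgraph satisfying the pattern, 0 otherwise.  Match multiplicity
#' is deliberately discarded so that small, frequently repeated fragments
#' are not over-represented.
#'
#' @param molecules A molecule tibble (see [molecule_table()]) or a
#'   character vector of SMILES.
#' @param catalog Character vector of SMARTS patterns or a catalog tibble.
#' @return A wide tibble: `id` plus one 0/1 integer column per pattern
#'   (column names are the SMARTS strings, in catalog order).
#' @examples
#' toy <- toy_fixture()
#' occurrence_table(toy$molecules, toy$catalog)
#' @export
occurrence_table <- function(molecules, catalog) {
  patterns <- catalog_patterns(catalog)
  validate_smarts(patterns)
  sdf <- parse_molecules(molecules)
  ids <- if (is.character(molecules)) ChemmineR::cid(sdf) else molecules$id
  cols <- lapply(patterns, function(p) {
    hits <- ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = FALSE)
    as.integer(hits > 0)
  })
  names(cols) <- patterns
  dplyr::bind_cols(tibble(id = ids),
                   tibble::new_tibble(cols, nrow = length(ids)))
}

#' Match catalog features in a single molecule
#'
#' @param smiles One SMILES string.
#' @param catalog SMARTS patterns.
#' @return Named 0/1 integer vector, one element per pattern.
#' @export
match_features <- function(smiles, catalog) {
  occ <- occurrence_table(c(m = as.character(smiles)[1]), catalog)
  unlist(occ[1, -1, drop = FALSE])
}

# occurrence tibble -> 0/1 matrix with molecule ids as rownames
occ_matrix <- function(features) {
  m <- as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- features$id
  m
}

# label tibble -> 0/1 matrix
label_matrix <- function(labels) {
  m <- as.matrix(labels[, setdiff(names(labels), "id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- labels$id
  m
}

#' Write an occurrence table in sparse coordinate form
#'
#' On-disk format: a TSV of `object_id<TAB>feature_index<TAB>1` rows (1-based
#' feature indices, only nonzero cells) plus a JSON sidecar
#' (`<path>.meta.json`) listing the full id and pattern order, so all-zero
#' rows and all-zero columns survive the round trip.
#'
#' @param features Occurrence tibble from [occurrence_table()].
#' @param path Output TSV path.
#' @export
write_occurrence <- function(features, path) {
  m <- occ_matrix(features)
  nz <- which(m == 1L, arr.ind = TRUE)
  coords <- tibble(
    object_id = rownames(m)[nz[, 1]],
    feature_index = as.integer(nz[, 2]),
    value = 1L
  ) |> arrange(match(.data$object_id, rownames(m)), .data$feature_index)
  readr::write_tsv(coords, path, progress = FALSE)
  jsonlite::write_json(
    list(object_ids = rownames(m), patterns = colnames(m)),
    paste0(path, ".meta.json"))
  invisible(path)
}

#' Read a sparse occurrence table written by [write_occurrence()]
#'
#' @param path TSV path (its `.meta.json` sidecar must sit next to it).
#' @return Occurrence tibble identical to the one written.
#' @export
read_occurrence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  coords <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- matrix(0L, nrow = length(meta$object_ids),
              ncol = length(meta$patterns),
              dimnames = list(meta$object_ids, meta$patterns))
  if (nrow(coords)) {
    m[cbind(match(coords$object_id, meta$object_ids),
            coords$feature_index)] <- 1L
  }
  dplyr::bind_cols(
    tibble(id = meta$object_ids),
    as_tibble(as.data.frame(m, check.names = FALSE))
  )
}
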