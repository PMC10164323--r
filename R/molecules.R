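#' Build a molecule table
#'
#' The central input container: one row per molecule with an opaque `id`,
#' a SMILES string (canonicalized on ingest through OpenBabel), and a
#' list-column of odor descriptor labels.  Molecules whose SMILES does not
#' parse are rejected immediately, with every failing id named.
#'
#' @param id Character vector of unique molecule identifiers.
#' @param smiles Character vector of SMILES strings.
#' @param descriptors Optional list of character vectors (one per molecule)
#'   or a single character vector of `sep`-separated labels.  Labels are
#'   trimmed and de-duplicated; empty sets are allowed (unlabeled
#'   prediction inputs).
#' @param sep Separator used when `descriptors` is a plain character vector.
#' @return A tibble with columns `id`, `smiles` (canonical) and
#'   `descriptors` (list-column of character vectors).
#' @examples
#' molecule_table(c("m1", "m2"), c("CCO", "c1ccccc1O"),
#'                c("floral", "medicinal;floral"))
#' @export
molecule_table <- function(id, smiles, descriptors = NULL, sep = ";") {
  id <- as.character(id)
  smiles <- as.character(smiles)
  if (length(id) != length(smiles)) {
    abort("`id` and `smiles` must have the same length")
  }
  if (anyDuplicated(id)) {
    abort(paste0("duplicate molecule id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  canon <- canonical_smiles(smiles)
  if (anyNA(canon)) {
    abort(paste0("SMILES failed to parse for molecule(s): ",
                 paste(id[is.na(canon)], collapse = ", ")))
  }
  if (is.null(descriptors)) {
    descriptors <- rep(list(character()), length(id))
  } else if (is.character(descriptors)) {
    descriptors <- strsplit(descriptors, sep, fixed = TRUE)
  }
  if (length(descriptors) != length(id)) {
    abort("`descriptors` must have one entry per molecule")
  }
  descriptors <- map(descriptors, normalize_descriptors)
  tibble(id = id, smiles = canon, descriptors = descriptors)
}

#' Canonicalize SMILES strings
#'
#' Round-trips each SMILES through OpenBabel's canonical writer so that
#' equal molecular graphs compare equal as strings.  Invalid SMILES map
#' to `NA`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = s),
                    error = function(e) "")
    out <- strsplit(out, "[ \t\n]")[[1]]
    if (length(out) == 0L || !nzchar(out[1])) NA_character_ else out[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Parse molecules into an SDF set
#'
#' Thin wrapper over [ChemmineR::smiles2sdf()] that names each entry by
#' molecule id and rejects unparsable records.
#'
#' @param molecules A molecule table (see [molecule_table()]) or a
#'   character vector of SMILES.
#' @return A `ChemmineR::SDFset` with one entry per molecule.
#' @export
parse_molecules <- function(molecules) {
  if (is.character(molecules)) {
    molecules <- molecule_table(
      id = if (is.null(names(molecules))) paste0("m", seq_along(molecules))
           else names(molecules),
      smiles = molecules
    )
  }
  smi <- setNames(molecules$smiles, molecules$id)
  sdf <- ChemmineR::smiles2sdf(smi)
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) {
    abort(paste0("SMILES failed to parse for molecule(s): ",
                 paste(molecules$id[!ok], collapse = ", ")))
  }
  sdf
}

#' Read a molecule table from CSV/TSV or SDF
#'
#' CSV/TSV files must carry the header columns `id,smiles,descriptors`
#' with descriptor labels separated by `sep` (default `;`).  SDF input is
#' read with ids taken from the molecule block titles and descriptors from
#' a named data field.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"sdf"`.
#' @param sep Descriptor separator inside the descriptor column/field.
#' @param descriptor_field Name of the SDF data field holding descriptors.
#' @return A molecule tibble (see [molecule_table()]).
#' @export
read_molecules <- function(path, format = c("auto", "csv", "tsv", "sdf"),
                           sep = ";", descriptor_field = "descriptors") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     sdf = "sdf", mol = "sdf",
                     abort(paste0("cannot infer format from extension .", ext)))
  }
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdf)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    desc <- map_chr(seq_along(sdf), function(i) {
      db <- ChemmineR::datablock(sdf[[i]])
      if (descriptor_field %in% names(db)) db[[descriptor_field]] else ""
    })
    return(molecule_table(ids, smi, desc, sep = sep))
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "smiles")
  if (!all(need %in% names(tab))) {
    abort("molecule file must have columns `id` and `smiles`")
  }
  desc <- if ("descriptors" %in% names(tab)) {
    dplyr::coalesce(as.character(tab$descriptors), "")
  } else {
    rep("", nrow(tab))
  }
  molecule_table(tab$id, tab$smiles, desc, sep = sep)
}

#' Write a molecule table to CSV
#'
#' Inverse of [read_molecules()]; descriptor sets are joined with `sep`.
#'
#' @inheritParams read_molecules
#' @param molecules A molecule tibble.
#' @export
write_molecules <- function(molecules, path, sep = ";") {
  out <- tibble(
    id = molecules$id,
    smiles = molecules$smiles,
    descriptors = map_chr(molecules$descriptors, paste, collapse = sep)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Binary class-membership table
#'
#' Expands the `descriptors` list-column into a wide 0/1 membership
#' tibble, one column per class, mirroring the objects-by-classes half of
#' the training input.
#'
#' @param molecules A molecule tibble.
#' @param classes Optional class ordering/subset; defaults to all labels
#'   seen, sorted.
#' @return Tibble with `id` plus one 0/1 integer column per class.
#' @export
label_table <- function(molecules, classes = NULL) {
  seen <- sort(unique(unlist(molecules$descriptors)))
  classes <- classes %||% seen
  cols <- lapply(classes, function(cl) {
    as.integer(map_lgl(molecules$descriptors, function(d) cl %in% d))
  })
  names(cols) <- classes
  dplyr::bind_cols(tibble(id = molecules$id),
                   tibble::new_tibble(cols, nrow = nrow(molecules)))
}
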