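#' Read a SMARTS feature catalog
#'
#' Plain-text format: one SMARTS pattern per line, `#` starts a comment,
#' blank lines ignored.  Every pattern is validated against the SMARTS
#' parser at load time, so malformed patterns fail here and never at
#' match time.  Duplicate strings are collapsed, keeping first occurrence.
#'
#' @param path Path to the catalog file.
#' @return Character vector of SMARTS patterns.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # `#` opens a comment only at line start or after whitespace: the bare
  # `#` inside brackets is SMARTS's atomic-number primitive (e.g. [#6])
  lines <- sub("(^|\\s)#.*$", "", lines)
  lines <- trimws(lines)
  patterns <- unique(lines[nzchar(lines)])
  validate_smarts(patterns)
  patterns
}

#' Write a SMARTS feature catalog
#'
#' @param catalog Character vector of SMARTS patterns, or a catalog tibble
#'   from [build_catalog_mcs()].
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  writeLines(catalog_patterns(catalog), path)
  invisible(path)
}

# accept either a plain character vector or a tibble with a `pattern` column
catalog_patterns <- function(catalog) {
  if (is.data.frame(catalog)) {
    if (!"pattern" %in% names(catalog)) {
      abort("catalog tibble must have a `pattern` column")
    }
    catalog <- catalog$pattern
  }
  patterns <- unique(as.character(catalog))
  if (length(patterns) == 0L) abort("catalog is empty")
  patterns
}

#' Validate SMARTS patterns
#'
#' Runs each pattern against a probe molecule so that invalid SMARTS is a
#' configuration error at catalog load, not a matching-time failure.
#'
#' @param patterns Character vector of SMARTS.
#' @return Invisibly, the patterns; aborts naming every invalid pattern.
#' @export
validate_smarts <- function(patterns) {
  probe <- ChemmineR::smiles2sdf(c(probe = "OCC=CSN"))
  bad <- patterns[!map_lgl(patterns, function(p) {
    ok <- tryCatch({
      ChemmineR::smartsSearchOB(probe, p, uniqueMatches = FALSE)
      TRUE
    }, error = function(e) FALSE)
    ok
  })]
  if (length(bad)) {
    abort(paste0("invalid SMARTS pattern(s): ", paste(bad, collapse = "  ")))
  }
  invisible(patterns)
}
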