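# Synthetic molecule datasets with planted structure-odor associations.
# The generator is a test scaffold emulating the qualitative findings that
# motivate the classifier (esters <-> fruity, sulfur <-> sickening, ...):
# each class has one diagnostic fragment that every one of its molecules
# contains, diluted with shared decoy fragments, optional label noise and
# optional multilabel assignment.  No claim of chemical realism is made.

#' Planted odor-motif library
#'
#' Six odor classes, each with a diagnostic SMILES fragment and the SMARTS
#' pattern that detects it.  Fragments are written so that concatenating
#' `decoy fragments + motif fragment` into a SMILES string keeps each
#' motif detectable by its own SMARTS and by no other class's.
#'
#' @return Tibble `class`, `fragment` (SMILES suffix), `smarts`.
#' @export
odor_motifs <- function() {
  tibble(
    class = c("fruity", "sickening", "medicinal",
              "floral", "woody", "perfumery"),
    fragment = c("C(=O)OC", "SC", "c1ccc(O)cc1",
                 "C=C", "C(C)(C)C", "C(=O)O"),
    smarts = c("[CX3](=[OX1])[OX2][#6]",   # ester
               "[#16X2]([#6])[#6]",        # thioether
               "[OX2H1][c]",               # phenol
               "[CX3]=[CX3]",              # aliphatic C=C
               "[CX4]([#6])([#6])([#6])[#6]",  # quaternary carbon
               "[CX3](=[OX1])[OX2H1]")     # carboxylic acid
  )
}

# decoy fragments shared across all classes; none matches any motif SMARTS
# and none ends in a heteroatom (so appending the motif never mutates it)
.decoy_fragments <- c("C", "CC", "CCC", "C(O)C", "C(OC)C")
.decoy_smarts <- c("[CX4]", "[CX4][CX4]", "[CX4][CX4][CX4]",
                   "[#6][OX2H1]", "[CX4][OX2][CX4]")

#' Generate a synthetic molecule dataset with planted motifs
#'
#' Each molecule is assembled as a valid SMILES from 1-3 random decoy
#' fragments followed by its class's motif fragment, so at label-noise 0
#' every molecule provably contains exactly its class motif.  With
#' probability `noise` the label is replaced by a uniformly random other
#' class (the structure keeps the original motif); with probability
#' `multilabel` a second class label is added.  Output is fully
#' determined by `seed`.
#'
#' @param n_per_class Molecules per class.
#' @param classes Subset of [odor_motifs()] classes; default all six.
#' @param noise Label-noise rate in \[0, 1\].
#' @param multilabel Probability of adding a second label.
#' @param seed Integer seed.
#' @return Molecule tibble with attributes `motifs` (named SMARTS vector,
#'   the ground-truth map), `decoys` (decoy SMARTS) and `true_class`
#'   column recording the structural class before label noise.
#' @examples
#' sim <- simulate_molecules(n_per_class = 3, seed = 7)
#' table(unlist(sim$descriptors))
#' @export
simulate_molecules <- function(n_per_class = 10, classes = NULL, noise = 0,
                               multilabel = 0, seed = 1) {
  assert_fraction(noise, "noise")
  assert_fraction(multilabel, "multilabel")
  motifs <- odor_motifs()
  classes <- classes %||% motifs$class
  if (!all(classes %in% motifs$class)) {
    abort(paste0("unknown class(es): ",
                 paste(setdiff(classes, motifs$class), collapse = ", ")))
  }
  if (length(classes) < 2L) abort("need at least 2 classes")
  motifs <- motifs[match(classes, motifs$class), , drop = FALSE]

  with_seed(seed, {
    rows <- list()
    for (ci in seq_along(classes)) {
      for (mi in seq_len(n_per_class)) {
        n_dec <- sample(1:3, 1)
        decs <- sample(.decoy_fragments, n_dec, replace = TRUE)
        smiles <- paste0(paste(decs, collapse = ""), motifs$fragment[ci])
        lab <- classes[ci]
        if (noise > 0 && stats::runif(1) < noise) {
          lab <- sample(setdiff(classes, lab), 1)
        }
        labs <- lab
        if (multilabel > 0 && stats::runif(1) < multilabel) {
          labs <- c(labs, sample(setdiff(classes, labs), 1))
        }
        rows[[length(rows) + 1]] <- tibble(
          id = sprintf("%s_%02d", classes[ci], mi),
          smiles = smiles,
          descriptors = list(labs),
          true_class = classes[ci]
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    canon <- canonical_smiles(out$smiles)
    if (anyNA(canon)) abort("internal error: generated SMILES failed to parse")
    out$smiles <- canon
    attr(out, "motifs") <- setNames(motifs$smarts, motifs$class)
    attr(out, "decoys") <- .decoy_smarts
    out
  })
}

#' Feature catalog matching a simulated dataset
#'
#' The planted motif SMARTS plus the shared decoy SMARTS — the catalog a
#' planted-motif recovery experiment trains on.
#'
#' @param data Output of [simulate_molecules()].
#' @return Character vector of SMARTS patterns.
#' @export
simulated_catalog <- function(data) {
  motifs <- attr(data, "motifs")
  if (is.null(motifs)) abort("`data` was not produced by simulate_molecules()")
  unname(c(motifs, attr(data, "decoys")))
}

#' Ground-truth motif map of a simulated dataset
#'
#' @param data Output of [simulate_molecules()].
#' @return Named character vector: class -> planted SMARTS.
#' @export
motif_map <- function(data) {
  motifs <- attr(data, "motifs")
  if (is.null(motifs)) abort("`data` was not produced by simulate_molecules()")
  motifs
}

#' The four-molecule worked example
#'
#' A deterministic toy set realizing the simplified worked scheme used
#' throughout the documentation and tests: two ester molecules labelled
#' `A`, two sulfur molecules labelled `B`, and three features (ester,
#' benzene ring, sulfur) whose occurrence matrix is exactly
#' `[[1,1,0],[1,0,0],[0,1,1],[0,0,1]]`.
#'
#' @return List with `molecules` (tibble: phenyl acetate, ethyl acetate,
#'   thiophenol, ethanethiol) and `catalog` (3 SMARTS patterns).
#' @export
toy_fixture <- function() {
  list(
    molecules = molecule_table(
      id = c("M1", "M2", "M3", "M4"),
      smiles = c("CC(=O)Oc1ccccc1", "CCOC(C)=O", "Sc1ccccc1", "CCS"),
      descriptors = c("A", "A", "B", "B")
    ),
    catalog = c(f1 = "[CX3](=[OX1])[OX2][#6]",
                f2 = "c1ccccc1",
                f3 = "[#16]")
  )
}
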