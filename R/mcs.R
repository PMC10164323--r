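# Maximum-common-substructure feature catalogs.
#
# No installed R package exposes pairwise MCS, so it is computed here as a
# maximum common induced subgraph: compatible atom pairs (same element)
# form the vertices of a modular-product graph whose maximum cliques are
# the maximum common mappings; the largest connected component of the best
# mapping is emitted as a SMARTS pattern.  Atoms are compared at element
# level and bonds by order, the defaults a practitioner would pick for
# fragment catalogs.

# molecular graph from one SDF entry: heavy-atom elements + bond list
mol_graph <- function(sdf1) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  elem <- sub("_.*$", "", rownames(ab))
  edges <- if (nrow(bb)) {
    matrix(as.integer(as.matrix(bb[, 1:3, drop = FALSE])), ncol = 3)
  } else {
    matrix(integer(), ncol = 3)
  }
  list(elem = elem, edges = edges)
}

bond_adjacency <- function(g) {
  n <- length(g$elem)
  A <- matrix(0L, n, n)
  if (nrow(g$edges)) {
    A[g$edges[, 1:2, drop = FALSE]] <- g$edges[, 3]
    A[g$edges[, 2:1, drop = FALSE]] <- g$edges[, 3]
  }
  A
}

# maximum common induced subgraph of two molecular graphs; returns the
# largest connected common fragment as (elements, edge list with orders,
# ring flags) or NULL when no two atoms can be mapped
mcs_pair_graph <- function(g1, g2) {
  pairs <- which(outer(g1$elem, g2$elem, "=="), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(NULL)
  A1 <- bond_adjacency(g1)
  A2 <- bond_adjacency(g2)
  B1 <- A1[pairs[, 1], pairs[, 1], drop = FALSE]
  B2 <- A2[pairs[, 2], pairs[, 2], drop = FALSE]
  D <- outer(pairs[, 1], pairs[, 1], "!=") & outer(pairs[, 2], pairs[, 2], "!=")
  compat <- (B1 == B2) & D
  nv <- nrow(pairs)
  idx <- which(compat & upper.tri(compat), arr.ind = TRUE)
  pg <- igraph::make_empty_graph(nv, directed = FALSE)
  if (nrow(idx)) pg <- igraph::add_edges(pg, t(idx))
  cliques <- igraph::largest_cliques(pg)
  if (!length(cliques)) return(NULL)

  best <- NULL
  for (cl in cliques) {
    v <- sort(as.integer(cl))
    atoms1 <- pairs[v, 1]
    sub <- A1[atoms1, atoms1, drop = FALSE]
    # connectivity over real bonds within the mapped set
    cg <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected")
    comp <- igraph::components(cg)
    take <- which(comp$membership == which.max(comp$csize))
    cand <- list(atoms = atoms1[take],
                 sub = sub[take, take, drop = FALSE])
    nb <- sum(cand$sub > 0) / 2
    if (is.null(best) ||
        length(cand$atoms) > length(best$atoms) ||
        (length(cand$atoms) == length(best$atoms) && nb > best$n_bonds)) {
      best <- cand
      best$n_bonds <- nb
    }
  }
  if (is.null(best) || length(best$atoms) == 0L) return(NULL)
  el <- which(best$sub > 0 & upper.tri(best$sub), arr.ind = TRUE)
  fg <- igraph::graph_from_adjacency_matrix(best$sub > 0, mode = "undirected")
  bridge_ids <- igraph::bridges(fg)
  em <- igraph::as_edgelist(fg)
  in_ring <- rep(TRUE, nrow(em))
  if (length(bridge_ids)) in_ring[as.integer(bridge_ids)] <- FALSE
  orders <- best$sub[em]
  list(
    elem = g1$elem[best$atoms],
    edges = cbind(em, orders),
    in_ring = in_ring
  )
}

# deterministic DFS SMARTS writer for a connected fragment.
# Atoms are written as [#Z]; acyclic bonds carry their exact order symbol,
# ring bonds additionally allow the aromatic alternative so that patterns
# derived from kekulized structures still match aromatic perception.
fragment_smarts <- function(frag) {
  n <- length(frag$elem)
  atom_expr <- paste0("[#", atomic_number(frag$elem), "]")
  if (n == 1L) return(atom_expr[1])
  sym <- c("-", "=", "#", ":")[pmin(frag$edges[, 3], 4L)]
  ring_alt <- frag$in_ring & sym != ":"
  sym[ring_alt] <- paste0(sym[ring_alt], ",:")
  adj <- vector("list", n)
  for (k in seq_len(nrow(frag$edges))) {
    i <- frag$edges[k, 1]; j <- frag$edges[k, 2]
    adj[[i]] <- c(adj[[i]], setNames(j, k))
    adj[[j]] <- c(adj[[j]], setNames(i, k))
  }
  # deterministic root/neighbor order: by element number then index
  z <- atomic_number(frag$elem)
  root <- order(z, seq_len(n))[1]
  visited <- rep(FALSE, n)
  used_edge <- rep(FALSE, nrow(frag$edges))
  ring_open <- list()          # vertex -> closure digits to print
  ring_count <- 0L
  # pass 1: DFS to find back edges and assign ring-closure numbers
  find_backedges <- function(v) {
    visited[v] <<- TRUE
    nbrs <- adj[[v]]
    ord <- order(z[nbrs], nbrs)
    for (ix in ord) {
      u <- nbrs[ix]; e <- as.integer(names(nbrs)[ix])
      if (used_edge[e]) next
      used_edge[e] <<- TRUE
      if (visited[u]) {
        ring_count <<- ring_count + 1L
        lab <- if (ring_count < 10) as.character(ring_count)
               else paste0("%", ring_count)
        b <- sym[e]
        ring_open[[as.character(v)]] <<-
          c(ring_open[[as.character(v)]], paste0(b, lab))
        ring_open[[as.character(u)]] <<-
          c(ring_open[[as.character(u)]], paste0(b, lab))
      } else {
        find_backedges(u)
      }
    }
  }
  find_backedges(root)
  # pass 2: rebuild the string along the same traversal
  visited <- rep(FALSE, n)
  used_edge <- rep(FALSE, nrow(frag$edges))
  build <- function(v) {
    visited[v] <<- TRUE
    out <- paste0(atom_expr[v],
                  paste(ring_open[[as.character(v)]] %||% character(),
                        collapse = ""))
    nbrs <- adj[[v]]
    ord <- order(z[nbrs], nbrs)
    children <- character()
    for (ix in ord) {
      u <- nbrs[ix]; e <- as.integer(names(nbrs)[ix])
      if (used_edge[e]) next
      used_edge[e] <<- TRUE
      if (!visited[u]) {
        children <- c(children, paste0(sym[e], build(u)))
      }
    }
    if (length(children) > 1L) {
      out <- paste0(out,
                    paste0("(", children[-length(children)], ")",
                           collapse = ""),
                    children[length(children)])
    } else if (length(children) == 1L) {
      out <- paste0(out, children)
    }
    out
  }
  build(root)
}

#' Build a SMARTS feature catalog by pairwise maximum common substructure
#'
#' For every unordered pair of corpus molecules the maximum common
#' substructure is computed (element-level atom comparison, bond-order
#' comparison) and, when its largest connected fragment has at least
#' `min_atoms` atoms, emitted as a SMARTS pattern.  Duplicate patterns are
#' collapsed and the catalog is sorted, so the same corpus and parameters
#' always give a byte-identical catalog.  A pair whose computation exceeds
#' `pair_timeout` seconds is skipped with a warning, never fatally.
#'
#' @param corpus Molecule tibble or character vector of SMILES; at least
#'   two molecules.
#' @param min_atoms Minimum fragment size (atoms) for a pattern to enter
#'   the catalog.
#' @param pair_timeout Per-pair time budget in seconds.
#' @return Tibble with columns `pattern` (SMARTS), `n_atoms`, `n_bonds`
#'   and `n_pairs` (how many corpus pairs produced the pattern), sorted by
#'   decreasing size then pattern.
#' @examples
#' build_catalog_mcs(c("CCO", "CCC", "CC(C)O"))
#' @export
build_catalog_mcs <- function(corpus, min_atoms = 2, pair_timeout = 5) {
  if (is.character(corpus)) {
    corpus <- molecule_table(paste0("m", seq_along(corpus)), corpus)
  }
  if (nrow(corpus) < 2L) abort("corpus must contain at least 2 molecules")
  if (min_atoms < 1L) abort("`min_atoms` must be >= 1")
  sdf <- parse_molecules(corpus)
  graphs <- lapply(seq_along(corpus$id), function(i) mol_graph(sdf[[i]]))
  found <- list()
  pair_idx <- combn(length(graphs), 2)
  for (p in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, p]; j <- pair_idx[2, p]
    frag <- tryCatch({
      setTimeLimit(elapsed = pair_timeout, transient = TRUE)
      mcs_pair_graph(graphs[[i]], graphs[[j]])
    }, error = function(e) {
      warn(paste0("MCS pair (", corpus$id[i], ", ", corpus$id[j],
                  ") skipped: ", conditionMessage(e)))
      NULL
    })
    setTimeLimit(elapsed = Inf)
    if (is.null(frag) || length(frag$elem) < min_atoms) next
    pat <- fragment_smarts(frag)
    if (is.null(found[[pat]])) {
      found[[pat]] <- list(n_atoms = length(frag$elem),
                           n_bonds = nrow(frag$edges), n_pairs = 1L)
    } else {
      found[[pat]]$n_pairs <- found[[pat]]$n_pairs + 1L
    }
  }
  if (!length(found)) {
    return(tibble(pattern = character(), n_atoms = integer(),
                  n_bonds = integer(), n_pairs = integer()))
  }
  out <- tibble(
    pattern = names(found),
    n_atoms = unname(map_int(found, function(x) as.integer(x$n_atoms))),
    n_bonds = unname(map_int(found, function(x) as.integer(x$n_bonds))),
    n_pairs = unname(map_int(found, function(x) x$n_pairs))
  )
  arrange(out, desc(.data$n_atoms), desc(.data$n_bonds), .data$pattern)
}

#' Bundled reference corpus
#'
#' A small built-in corpus of odor-relevant molecules (esters, alcohols,
#' thiols, aromatics) for demonstrating catalog construction without any
#' external download.  Real studies substitute a large purchasable-compound
#' corpus here.
#'
#' @return A molecule tibble.
#' @export
bundled_corpus <- function() {
  path <- system.file("extdata", "reference_corpus.csv", package = "owsum")
  read_molecules(path, format = "csv")
}
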