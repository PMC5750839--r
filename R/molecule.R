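# Molecular data model: an ordered atom list with one or more conformers,
# a bond table, per-conformer provenance and carried SDF properties.

#' Construct a molecule
#'
#' The central container of the package: an ordered list of atoms with 3D
#' coordinates (one or more conformers), a bond table and free-form string
#' properties. Hydrogens are kept in the model (they count towards molecular
#' weight) but are excluded from all shape mathematics downstream.
#'
#' @param id Non-empty molecule identifier.
#' @param elements Character vector of element symbols, one per atom.
#' @param conformers A single n x 3 coordinate matrix (Angstrom) or a list of
#'   such matrices.
#' @param bonds Matrix or data frame with columns `from`, `to`, `order`
#'   (1-based atom indices); may have zero rows.
#' @param provenance `"experimental"` or `"generated"`, recycled to one flag
#'   per conformer.
#' @param properties Named list of string properties (carried SDF tags).
#' @return An object of class `molecule`.
#' @export
molecule <- function(id, elements, conformers, bonds = NULL,
                     provenance = "generated", properties = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("molecule id must be a non-empty string")
  }
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("molecule must have at least one atom")
  if (is.matrix(conformers)) conformers <- list(conformers)
  if (!is.list(conformers) || length(conformers) < 1L) {
    stop("at least one conformer is required")
  }
  conformers <- lapply(conformers, function(x) {
    x <- as.matrix(x)
    if (nrow(x) != n || ncol(x) != 3L) {
      stop("every conformer needs one coordinate triple per atom")
    }
    if (!all(is.finite(x))) stop("conformer coordinates must be finite")
    storage.mode(x) <- "double"
    dimnames(x) <- NULL
    x
  })
  if (is.null(bonds) || (is.data.frame(bonds) && nrow(bonds) == 0L)) {
    bonds <- data.frame(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("from", "to", "order")
    bonds$from <- as.integer(bonds$from)
    bonds$to <- as.integer(bonds$to)
    bonds$order <- as.integer(bonds$order)
    if (nrow(bonds) &&
        (any(bonds$from < 1L) || any(bonds$to < 1L) ||
         any(bonds$from > n) || any(bonds$to > n))) {
      stop("bond indices out of range for molecule '", id, "'")
    }
  }
  provenance <- match.arg(provenance, c("experimental", "generated"),
                          several.ok = TRUE)
  provenance <- rep_len(provenance, length(conformers))
  is_heavy <- elements != "H"
  vdw <- suppressWarnings(vdw_radius(elements))
  structure(list(
    id = id,
    elements = elements,
    vdw = vdw,
    is_heavy = is_heavy,
    bonds = bonds,
    conformers = conformers,
    provenance = provenance,
    properties = properties
  ), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms (%d heavy), %d bonds, %d conformer(s)>\n",
              x$id, length(x$elements), sum(x$is_heavy), nrow(x$bonds),
              length(x$conformers)))
  invisible(x)
}

n_conformers <- function(mol) length(mol$conformers)

get_conformer <- function(mol, i = 1L) {
  if (i < 1L || i > length(mol$conformers)) {
    stop("molecule '", mol$id, "' has no conformer ", i)
  }
  mol$conformers[[i]]
}

#' Number of non-hydrogen atoms
#'
#' @param mol A [molecule()].
#' @return Integer heavy-atom count.
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  sum(mol$is_heavy)
}

#' Implicit hydrogen count per atom
#'
#' Derived from typical neutral valences minus the sum of bond orders
#' (aromatic bonds, order 4 in SDF, count 1.5). Explicit hydrogens in the
#' atom list reduce the implicit count through their single bonds.
#'
#' @param mol A [molecule()].
#' @return Integer vector, one entry per atom.
#' @export
implicit_hydrogens <- function(mol) {
  n <- length(mol$elements)
  bosum <- numeric(n)
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds$order == 4L, 1.5, as.numeric(mol$bonds$order))
    for (k in seq_len(nrow(mol$bonds))) {
      bosum[mol$bonds$from[k]] <- bosum[mol$bonds$from[k]] + ord[k]
      bosum[mol$bonds$to[k]] <- bosum[mol$bonds$to[k]] + ord[k]
    }
  }
  v <- element_valence(mol$elements)
  h <- pmax(0, round(v - bosum))
  h[mol$elements == "H"] <- 0
  as.integer(h)
}

#' Molecular weight in Dalton
#'
#' Sum of standard atomic masses over all atoms, counting implicit as well
#' as explicit hydrogens.
#'
#' @param mol A [molecule()].
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  sum(atomic_mass(mol$elements)) +
    sum(implicit_hydrogens(mol)) * .ATOMIC_MASSES[["H"]]
}

# Subset a molecule to a set of atom indices (all conformers), reindexing
# bonds. Used by largest_fragment.
subset_molecule <- function(mol, idx) {
  idx <- sort(unique(as.integer(idx)))
  map <- integer(length(mol$elements))
  map[idx] <- seq_along(idx)
  keep <- mol$bonds$from %in% idx & mol$bonds$to %in% idx
  bonds <- mol$bonds[keep, , drop = FALSE]
  if (nrow(bonds)) {
    bonds$from <- map[bonds$from]
    bonds$to <- map[bonds$to]
  }
  molecule(
    id = mol$id,
    elements = mol$elements[idx],
    conformers = lapply(mol$conformers, function(x) x[idx, , drop = FALSE]),
    bonds = bonds,
    provenance = mol$provenance,
    properties = mol$properties
  )
}

fragment_indices <- function(mol) {
  n <- length(mol$elements)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$from, mol$bonds$to))
  }
  comp <- igraph::components(g)
  split(seq_len(n), comp$membership)
}

#' Keep the largest connected fragment (counter-ion stripping)
#'
#' Salt forms carry charge-balancing counter ions as disconnected
#' fragments; similarity is computed on the bioactive component only. The
#' fragment with the most heavy atoms is kept; ties are broken by larger
#' molecular weight, then by first occurrence in the atom list.
#'
#' @param mol A [molecule()], possibly with several disconnected components.
#' @return A [molecule()] containing a single connected component.
#' @export
largest_fragment <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  frags <- fragment_indices(mol)
  if (length(frags) == 1L) return(mol)
  heavy <- vapply(frags, function(ix) sum(mol$is_heavy[ix]), numeric(1))
  mw <- vapply(frags, function(ix) {
    sub <- subset_molecule(mol, ix)
    molecular_weight(sub)
  }, numeric(1))
  first <- vapply(frags, min, numeric(1))
  ord <- order(-heavy, -mw, first)
  subset_molecule(mol, frags[[ord[1L]]])
}

n_fragments <- function(mol) length(fragment_indices(mol))
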