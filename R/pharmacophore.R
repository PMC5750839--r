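# Pharmacophore ("static") typing and feature overlap.
#
# Atoms and groups are mapped to typed feature points by a versioned,
# user-overridable rule file. Each rule line pairs one of the six
# conventional feature types with a named structural detector evaluated on
# the molecular graph (see feature_detectors below). Feature points are
# idealized: a fixed radius, unit weight, same Gaussian closed form as the
# shape overlap, and only same-type pairs contribute.

FEATURE_TYPES <- c("donor", "acceptor", "cation", "anion", "hydrophobe",
                   "aromatic")

#' Read a pharmacophore rule file
#'
#' Line-oriented text: `feature_type <TAB> DETECTOR_NAME`; `#` starts a
#' comment. A `# version:` comment line tags the ruleset version, which is
#' carried into every feature model and result sidecar so outputs can cite
#' the typing scheme they used.
#'
#' @param path Path to a rule file; default: the ruleset shipped with the
#'   package.
#' @return Object of class `feature_rules`.
#' @export
read_feature_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feature_rules.tsv", package = "shapefish")
  }
  if (!file.exists(path)) stop("feature rule file not found: ", path)
  lines <- readLines(path)
  version <- "unversioned"
  vline <- grep("^#\\s*version:", lines, value = TRUE)
  if (length(vline)) {
    version <- trimws(sub("^#\\s*version:", "", vline[1]))
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed rule line(s): ", paste(lines[bad], collapse = "; "))
  rules <- data.frame(type = vapply(parts, `[[`, "", 1L),
                      detector = vapply(parts, `[[`, "", 2L))
  if (!all(rules$type %in% FEATURE_TYPES)) {
    stop("unknown feature type(s): ",
         paste(setdiff(rules$type, FEATURE_TYPES), collapse = ", "))
  }
  known <- names(feature_detectors())
  if (!all(rules$detector %in% known)) {
    stop("unknown detector(s): ",
         paste(setdiff(rules$detector, known), collapse = ", "))
  }
  structure(list(version = version, rules = rules), class = "feature_rules")
}

#' @export
print.feature_rules <- function(x, ...) {
  cat(sprintf("<feature_rules version %s: %d rule(s)>\n", x$version,
              nrow(x$rules)))
  invisible(x)
}

#' The shipped pharmacophore ruleset (cached)
#'
#' @return A `feature_rules` object, read once per session.
#' @export
default_feature_rules <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_feature_rules()
    cache
  }
})

# ---- molecular graph perception -------------------------------------------

mol_graph_info <- function(mol) {
  n <- length(mol$elements)
  el <- mol$elements
  nbrs <- vector("list", n)
  bond_order <- list()
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$from[k]; j <- mol$bonds$to[k]; o <- mol$bonds$order[k]
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
      bond_order[[paste(min(i, j), max(i, j))]] <- o
    }
  }
  order_of <- function(i, j) bond_order[[paste(min(i, j), max(i, j))]]
  imp_h <- implicit_hydrogens(mol)
  exp_h <- vapply(seq_len(n), function(i) sum(el[nbrs[[i]]] == "H"), integer(1))
  list(n = n, el = el, nbrs = nbrs, order_of = order_of,
       total_h = imp_h + exp_h,
       heavy_nbrs = lapply(seq_len(n), function(i) {
         v <- nbrs[[i]]; v[el[v] != "H"]
       }),
       rings = find_rings(mol))
}

# Fundamental cycles from a spanning tree; adequate for the simple mono-
# and fused-ring systems this package handles (size capped at 8).
find_rings <- function(mol, max_size = 8L) {
  n <- length(mol$elements)
  if (!nrow(mol$bonds)) return(list())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(mol$bonds$from, mol$bonds$to))
  tree <- igraph::mst(g)
  all_e <- igraph::as_edgelist(g)
  tree_e <- igraph::as_edgelist(tree)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  extra <- which(!(key(all_e) %in% key(tree_e)))
  rings <- list()
  for (k in extra) {
    u <- all_e[k, 1]; v <- all_e[k, 2]
    p <- suppressWarnings(igraph::shortest_paths(tree, from = u, to = v))
    vp <- as.integer(p$vpath[[1]])
    if (length(vp) >= 3L && length(vp) <= max_size) {
      rings[[length(rings) + 1L]] <- vp
    }
  }
  rings
}

ring_is_aromatic <- function(ring, info) {
  m <- length(ring)
  orders <- vapply(seq_len(m), function(k) {
    i <- ring[k]; j <- ring[if (k == m) 1L else k + 1L]
    o <- info$order_of(i, j)
    if (is.null(o)) NA_integer_ else o
  }, integer(1))
  if (anyNA(orders)) return(FALSE)
  if (all(orders == 4L)) return(TRUE)
  if (m %% 2L != 0L) return(FALSE)
  if (!all(info$el[ring] == "C")) return(FALSE)
  # Kekule check: alternating single/double around the ring
  all(orders %in% c(1L, 2L)) &&
    all(abs(diff(c(orders, orders[1]))) == 1L)
}

# ---- detectors ------------------------------------------------------------

# Each detector maps the graph to feature centers for a given conformer.
# Returns a list of atom-index vectors; the feature center is the centroid
# of the indexed atoms.
feature_detectors <- function() {
  list(
    # N or O carrying at least one hydrogen
    NH_OH = function(info) {
      idx <- which(info$el %in% c("N", "O") & info$total_h >= 1L)
      lapply(idx, identity)
    },
    # any N or O lone-pair bearer
    N_O_LONEPAIR = function(info) {
      idx <- which(info$el %in% c("N", "O"))
      lapply(idx, identity)
    },
    # aliphatic amine N: protonatable at physiological pH; all-single
    # bonds, carbon-only heavy neighbours none of which is a carbonyl
    ALIPHATIC_AMINE = function(info) {
      out <- list()
      in_aromatic <- rep(FALSE, info$n)
      for (r in info$rings) if (ring_is_aromatic(r, info)) in_aromatic[r] <- TRUE
      for (i in which(info$el == "N")) {
        if (in_aromatic[i]) next
        hn <- info$heavy_nbrs[[i]]
        if (length(hn) == 0L || any(info$el[hn] != "C")) next
        if (any(vapply(hn, function(j) info$order_of(i, j) != 1L, logical(1)))) next
        carbonyl <- vapply(hn, function(c) {
          any(vapply(info$heavy_nbrs[[c]], function(k) {
            info$el[k] %in% c("O", "N") && k != i &&
              identical(info$order_of(c, k), 2L)
          }, logical(1)))
        }, logical(1))
        if (any(carbonyl)) next
        out[[length(out) + 1L]] <- i
      }
      out
    },
    # carboxylic acid / carboxylate: deprotonated at physiological pH;
    # feature centred between the two oxygens
    CARBOXYLATE = function(info) {
      out <- list()
      for (c in which(info$el == "C")) {
        osv <- info$heavy_nbrs[[c]]
        osv <- osv[info$el[osv] == "O"]
        if (length(osv) != 2L) next
        ords <- vapply(osv, function(o) info$order_of(c, o), integer(1))
        if (sort(ords)[1] == 1L && sort(ords)[2] == 2L) {
          out[[length(out) + 1L]] <- osv
        }
      }
      out
    },
    AROMATIC_RING = function(info) {
      Filter(Negate(is.null), lapply(info$rings, function(r) {
        if (ring_is_aromatic(r, info)) r else NULL
      }))
    },
    # maximal connected groups (>= 3 atoms) of carbons with no polar
    # neighbour
    CARBON_GROUP = function(info) {
      ok <- info$el == "C" & vapply(seq_len(info$n), function(i) {
        !any(info$el[info$nbrs[[i]]] %in% c("N", "O", "S", "P", "F", "Cl",
                                            "Br", "I"))
      }, logical(1))
      idx <- which(ok)
      if (!length(idx)) return(list())
      g <- igraph::make_empty_graph(n = info$n, directed = FALSE)
      ed <- NULL
      for (i in idx) {
        for (j in info$nbrs[[i]]) if (j > i && ok[j]) ed <- c(ed, i, j)
      }
      if (!is.null(ed)) g <- igraph::add_edges(g, ed)
      comp <- igraph::components(g)
      grps <- split(seq_len(info$n), comp$membership)
      grps <- lapply(grps, function(v) v[ok[v]])
      grps <- grps[lengths(grps) >= 3L]
      unname(grps)
    }
  )
}

#' Assign pharmacophore features to a conformer
#'
#' Feature types and counts depend only on the molecular graph; centers are
#' atom positions or group centroids in the requested conformer.
#'
#' @param mol A [molecule()].
#' @param conformer Conformer index.
#' @param rules A `feature_rules` object; default: shipped ruleset.
#' @param radius Feature radius in Angstrom (idealized, uniform).
#' @param p Gaussian prefactor used for feature overlap.
#' @return Object of class `feature_model` with a `features` data frame
#'   (`type`, `x`, `y`, `z`), per-type Gaussian sets and the cached
#'   same-type self-overlap.
#' @export
assign_features <- function(mol, conformer = 1L, rules = default_feature_rules(),
                            radius = 1.0, p = 2.7) {
  stopifnot(inherits(mol, "molecule"), radius > 0)
  info <- mol_graph_info(mol)
  coords <- get_conformer(mol, conformer)
  dets <- feature_detectors()
  rows <- list()
  for (k in seq_len(nrow(rules$rules))) {
    type <- rules$rules$type[k]
    hits <- dets[[rules$rules$detector[k]]](info)
    for (h in hits) {
      ctr <- colMeans(coords[h, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(type = type, x = ctr[1],
                                              y = ctr[2], z = ctr[3])
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), x = numeric(), y = numeric(), z = numeric())
  fm <- structure(list(features = features, radius = radius, p = p,
                       version = rules$version), class = "feature_model")
  fm$by_type <- feature_gaussians(fm)
  fm$self_overlap <- feature_overlap(fm, fm)
  fm
}

feature_gaussians <- function(fm) {
  out <- list()
  for (type in unique(fm$features$type)) {
    sel <- fm$features$type == type
    out[[type]] <- atom_gaussians(
      as.matrix(fm$features[sel, c("x", "y", "z")]),
      radii = fm$radius, p = fm$p)
  }
  out
}

#' @export
print.feature_model <- function(x, ...) {
  counts <- table(x$features$type)
  cat(sprintf("<feature_model (rules %s): %d feature(s)%s>\n", x$version,
              nrow(x$features),
              if (length(counts)) paste0(" [",
                paste(names(counts), counts, sep = ":", collapse = ", "), "]")
              else ""))
  invisible(x)
}

n_features <- function(fm) nrow(fm$features)

#' Pharmacophore feature overlap
#'
#' Gaussian overlap volume summed over feature pairs of the same type;
#' cross-type pairs contribute nothing. Both models must be in a common
#' frame unless a transform for `F_B` is given.
#'
#' @param F_A,F_B `feature_model` objects.
#' @param transform Optional [rigid_transform()] applied to `F_B`.
#' @return Overlap volume in cubic Angstrom.
#' @export
feature_overlap <- function(F_A, F_B, transform = NULL) {
  total <- 0
  for (type in intersect(names(F_A$by_type), names(F_B$by_type))) {
    ga <- F_A$by_type[[type]]
    gb <- F_B$by_type[[type]]
    cb <- gb$centers
    if (!is.null(transform)) cb <- apply_transform(cb, transform)
    total <- total + sum(pair_overlap_matrix(ga, gb, cb = cb, cutoff = TRUE))
  }
  total
}
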