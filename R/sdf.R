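# SDF input/output, backed by ChemmineR. One SDF record maps to one
# single-conformer molecule; multi-conformer molecules are written as
# repeated records sharing a LIGAND_ID tag and regrouped on read by
# group_conformers().

sdf_element <- function(atom_names) sub("_\\d+$", "", atom_names)

sdf_to_molecule <- function(sdf, fallback_id) {
  ab <- ChemmineR::atomblock(sdf)
  coords <- unname(ab[, 1:3, drop = FALSE])
  elements <- sdf_element(rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (is.null(bb) || nrow(bb) == 0L) NULL else
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  db <- ChemmineR::datablock(sdf)
  props <- as.list(db)
  # ChemmineR folds header fields into the datablock on some paths; keep
  # user tags only.
  props <- props[setdiff(names(props),
                         c("Molecule_Name", "Source", "Comment", "Counts_Line"))]
  id <- props[["LIGAND_ID"]]
  if (is.null(id) || !nzchar(id)) {
    hdr <- ChemmineR::header(sdf)
    id <- if (nzchar(hdr[["Molecule_Name"]])) hdr[["Molecule_Name"]] else fallback_id
  }
  prov <- props[["SOURCE"]]
  prov <- if (!is.null(prov) && prov %in% c("experimental", "generated"))
    prov else "generated"
  molecule(id = id, elements = elements, conformers = coords, bonds = bonds,
           provenance = prov, properties = props)
}

#' Read molecules from an SDF file
#'
#' Each record becomes one single-conformer [molecule()]; SDF data fields
#' are preserved in `properties`. Records with unparsable MOL blocks are
#' skipped with a warning rather than aborting the read, because database
#' builds ingest thousands of records.
#'
#' @param path Path to an SDF/MOL file (V2000).
#' @return List of [molecule()] objects (possibly empty, with a warning).
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("SDF file not found: ", path)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) NULL
  )
  if (is.null(sdfset) || length(sdfset) == 0L) {
    warning("no parseable SDF records in ", path)
    return(list())
  }
  ok <- ChemmineR::validSDF(sdfset)
  if (any(!ok)) {
    warning(sum(!ok), " unparsable SDF record(s) skipped in ", path)
  }
  mols <- vector("list", sum(ok))
  j <- 0L
  for (i in which(ok)) {
    m <- tryCatch(sdf_to_molecule(sdfset[[i]], fallback_id = paste0("MOL", i)),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning("SDF record ", i, " skipped: could not build molecule")
      next
    }
    j <- j + 1L
    mols[[j]] <- m
  }
  mols[seq_len(j)]
}

molecule_to_sdf <- function(mol, conf = 1L, extra_props = character()) {
  coords <- get_conformer(mol, conf)
  n <- nrow(coords)
  ab <- cbind(coords, matrix(0, n, 12))
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  rownames(ab) <- paste(mol$elements, seq_len(n), sep = "_")
  nb <- nrow(mol$bonds)
  if (nb) {
    bb <- cbind(mol$bonds$from, mol$bonds$to, mol$bonds$order, 0)
  } else {
    bb <- matrix(0, 0, 4)
  }
  colnames(bb) <- paste0("C", 1:4)
  rownames(bb) <- if (nb) as.character(seq_len(nb)) else character()
  header <- c(
    Molecule_Name = mol$id,
    Source = "  shapefish",
    Comment = "",
    Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  )
  props <- mol$properties
  props[["LIGAND_ID"]] <- mol$id
  props[["SOURCE"]] <- mol$provenance[conf]
  for (nm in names(extra_props)) props[[nm]] <- extra_props[[nm]]
  db <- vapply(props, function(v) paste(as.character(v), collapse = " "),
               character(1))
  methods::new("SDF", header = header, atomblock = ab, bondblock = bb,
               datablock = db)
}

#' Write molecules to an SDF file
#'
#' Multi-conformer molecules are written as one record per conformer, all
#' sharing the molecule's `LIGAND_ID` tag and carrying a per-conformer
#' `SOURCE` (experimental|generated) tag. Properties become SDF data fields.
#'
#' @param mols A [molecule()] or list of molecules.
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  records <- list()
  for (mol in mols) {
    stopifnot(inherits(mol, "molecule"))
    for (k in seq_len(n_conformers(mol))) {
      records[[length(records) + 1L]] <- molecule_to_sdf(mol, k)
    }
  }
  if (length(records) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write SDF file: ", path)
    return(invisible(0L))
  }
  sdfset <- methods::new("SDFset", SDF = records,
                         ID = paste0("CMP", seq_along(records)))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(length(records))
}

#' Group single-conformer molecules into multi-conformer molecules
#'
#' Records sharing an id (the `LIGAND_ID` tag as read by [read_sdf()]) are
#' merged into one molecule whose conformers appear experimental-first, in
#' file order within each provenance class, so that downstream exact-tie
#' breaking by conformer index prefers experimentally determined poses.
#'
#' @param mols List of single-conformer molecules.
#' @return Named list of multi-conformer molecules keyed by id.
#' @export
group_conformers <- function(mols) {
  ids <- vapply(mols, function(m) m$id, character(1))
  out <- list()
  for (id in unique(ids)) {
    grp <- mols[ids == id]
    prov <- vapply(grp, function(m) m$provenance[1L], character(1))
    ord <- order(prov != "experimental", seq_along(grp))
    grp <- grp[ord]
    base <- grp[[1L]]
    confs <- unlist(lapply(grp, function(m) m$conformers), recursive = FALSE)
    nat <- vapply(grp, function(m) length(m$elements), integer(1))
    if (length(unique(nat)) != 1L) {
      warning("conformer records for '", id,
              "' differ in atom count; keeping the first record only")
      confs <- base$conformers
      grp <- grp[1L]
    }
    out[[id]] <- molecule(
      id = id, elements = base$elements, conformers = confs,
      bonds = base$bonds,
      provenance = vapply(grp, function(m) m$provenance[1L], character(1))[
        rep(seq_along(grp), vapply(grp, n_conformers, integer(1)))],
      properties = base$properties
    )
  }
  out
}
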