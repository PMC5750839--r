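# Deterministic synthetic-data generation: toy molecules with standard
# bond geometry, planted scaffold-family target databases in the on-disk
# database layout, and grid-integration oracles for the Gaussian closed
# forms. Everything is reproducible from a single seed.

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Build a synthetic toy molecule
#'
#' Deterministic generators for the geometries the tests and fixtures use:
#' zig-zag carbon chains and planar rings with exact 1.5 Angstrom bond
#' lengths, free-floating fused-sphere systems, and decorated scaffolds
#' (chain or ring cores with heteroatom substituents at 1.4 Angstrom).
#'
#' @param kind `"linear_chain"`, `"ring"`, `"fused_spheres"` or
#'   `"decorated_scaffold"`.
#' @param n Number of core atoms.
#' @param id Molecule id.
#' @param bond_length Core bond length (Angstrom).
#' @param d Sphere separation for `"fused_spheres"`.
#' @param elements Optional element vector for the core (default carbon).
#' @param decorations Data frame with columns `site` (core atom index) and
#'   `element`, for `"decorated_scaffold"`.
#' @param seed Optional seed (only relevant when callers add randomness).
#' @return A [molecule()].
#' @export
make_toy_molecule <- function(kind, n = 6L, id = kind, bond_length = 1.5,
                              d = 1.0, elements = NULL, decorations = NULL,
                              seed = NULL) {
  build <- function() {
    switch(kind,
      linear_chain = toy_chain(n, id, bond_length, elements),
      ring = toy_ring(n, id, bond_length, elements),
      fused_spheres = toy_fused(n, id, d, elements),
      decorated_scaffold = toy_decorated(n, id, bond_length, elements,
                                         decorations),
      stop("unknown toy molecule kind: ", kind)
    )
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

toy_chain <- function(n, id, L, elements) {
  stopifnot(n >= 1L)
  angle <- 112 * pi / 180
  a <- (pi - angle) / 2
  coords <- matrix(0, n, 3)
  for (i in seq_len(n - 1L)) {
    dir <- c(cos(a), if (i %% 2L == 1L) sin(a) else -sin(a), 0)
    coords[i + 1L, ] <- coords[i, ] + L * dir
  }
  coords <- sweep(coords, 2, colMeans(coords))
  el <- if (is.null(elements)) rep("C", n) else rep_len(elements, n)
  bonds <- if (n > 1L)
    data.frame(from = seq_len(n - 1L), to = 2:n, order = 1L) else NULL
  molecule(id, el, coords, bonds)
}

toy_ring <- function(n, id, L, elements) {
  stopifnot(n >= 3L)
  r <- L / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  coords <- cbind(r * cos(th), r * sin(th), 0)
  coords <- sweep(coords, 2, colMeans(coords))
  el <- if (is.null(elements)) rep("C", n) else rep_len(elements, n)
  ord <- if (n %% 2L == 0L) rep(c(1L, 2L), n / 2) else rep(1L, n)
  bonds <- data.frame(from = seq_len(n), to = c(2:n, 1L), order = ord)
  molecule(id, el, coords, bonds)
}

toy_fused <- function(n, id, d, elements) {
  stopifnot(n >= 1L)
  coords <- cbind((seq_len(n) - 1L) * d, 0, 0)
  coords <- sweep(coords, 2, colMeans(coords))
  el <- if (is.null(elements)) rep("C", n) else rep_len(elements, n)
  bonds <- if (n > 1L)
    data.frame(from = seq_len(n - 1L), to = 2:n, order = 1L) else NULL
  molecule(id, el, coords, bonds)
}

toy_decorated <- function(n, id, L, elements, decorations) {
  core <- if (n >= 5L && n %% 2L == 0L) toy_ring(n, id, L, elements)
          else toy_chain(n, id, L, elements)
  if (is.null(decorations) || nrow(decorations) == 0L) return(core)
  coords <- core$conformers[[1L]]
  el <- core$elements
  bonds <- core$bonds
  centroid <- colMeans(coords)
  for (k in seq_len(nrow(decorations))) {
    site <- as.integer(decorations$site[k])
    stopifnot(site >= 1L, site <= n)
    out_dir <- coords[site, ] - centroid
    nrm <- sqrt(sum(out_dir^2))
    dir <- if (nrm > 1e-9) out_dir / nrm else c(0, 0, 1)
    # push decorations off-plane so successive ones at one site separate
    dir <- dir + c(0, 0, 0.35 * k)
    dir <- dir / sqrt(sum(dir^2))
    coords <- rbind(coords, coords[site, ] + 1.4 * dir)
    el <- c(el, as.character(decorations$element[k]))
    bonds <- rbind(bonds, data.frame(from = site, to = nrow(coords),
                                     order = 1L))
  }
  molecule(id, el, coords, bonds)
}

# Rotate all atoms past bond (pivot, pivot+1) of a chain-like molecule
# about that bond axis.
perturb_torsion <- function(coords, pivot, angle) {
  n <- nrow(coords)
  if (pivot >= n - 1L) return(coords)
  axis <- coords[pivot + 1L, ] - coords[pivot, ]
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  moving <- (pivot + 2L):n
  origin <- coords[pivot + 1L, ]
  coords[moving, ] <- sweep(sweep(coords[moving, , drop = FALSE], 2, origin) %*%
                              t(R), 2, origin, "+")
  coords
}

#' Fixture-database specification
#'
#' Conditions for the planted scaffold-family database: each synthetic
#' target owns one scaffold family (shared core plus fixed heteroatom
#' decorations); members differ by coordinate jitter and torsion-perturbed
#' extra conformers; activities are log-uniform over \[0.001, 100\] uM so
#' the 50 uM curation filter and 10/20/50 uM tailoring both have events on
#' either side.
#'
#' @param seed RNG seed driving all generation.
#' @param n_targets Number of synthetic targets (= scaffold families).
#' @param ligands_per_target Ligands per family.
#' @param sigma Coordinate jitter standard deviation (Angstrom).
#' @param frac_experimental Fraction of ligands whose first conformer is
#'   flagged experimental.
#' @param max_decorations Maximum heteroatom decorations per family.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1337L, n_targets = 5L, ligands_per_target = 5L,
                         sigma = 0.1, frac_experimental = 0.3,
                         max_decorations = 3L) {
  stopifnot(n_targets >= 1L, ligands_per_target >= 1L, sigma >= 0)
  structure(list(seed = as.integer(seed), n_targets = as.integer(n_targets),
                 ligands_per_target = as.integer(ligands_per_target),
                 sigma = sigma, frac_experimental = frac_experimental,
                 max_decorations = as.integer(max_decorations)),
            class = "fixture_spec")
}

# Family scaffold palette: visibly different shapes so between-family
# similarity stays well below within-family similarity.
family_definition <- function(k, max_decorations) {
  palette <- list(
    list(kind = "linear_chain", n = 5L),
    list(kind = "ring", n = 6L),
    list(kind = "linear_chain", n = 9L),
    list(kind = "ring", n = 9L),
    list(kind = "linear_chain", n = 7L)
  )
  base <- palette[[(k - 1L) %% length(palette) + 1L]]
  base$n <- base$n + 2L * ((k - 1L) %/% length(palette))
  ndec <- sample.int(max_decorations + 1L, 1L) - 1L
  dec <- if (ndec > 0L) {
    data.frame(site = sample.int(base$n, ndec),
               element = sample(c("N", "O"), ndec, replace = TRUE))
  } else NULL
  list(kind = base$kind, n = base$n, decorations = dec)
}

# One family member: base geometry + Gaussian jitter; chains get one
# torsion-perturbed extra conformer.
make_family_member <- function(fam, id, sigma, provenance = "generated") {
  core <- if (fam$kind == "ring") toy_ring(fam$n, id, 1.5, NULL)
          else toy_chain(fam$n, id, 1.5, NULL)
  base <- toy_decorated_on(core, fam$decorations, id)
  nat <- length(base$elements)
  confs <- list(base$conformers[[1L]] + matrix(stats::rnorm(nat * 3, 0, sigma),
                                               nat, 3))
  prov <- provenance
  if (fam$kind == "linear_chain" && fam$n >= 4L) {
    pivot <- max(2L, fam$n %/% 2L)
    ang <- stats::runif(1, pi / 6, pi / 2)
    confs[[2L]] <- perturb_torsion(confs[[1L]], pivot, ang)
    prov <- c(provenance, "generated")
  }
  molecule(id, base$elements, confs, base$bonds, provenance = prov)
}

toy_decorated_on <- function(core, decorations, id) {
  if (is.null(decorations) || nrow(decorations) == 0L) return(core)
  coords <- core$conformers[[1L]]
  el <- core$elements
  bonds <- core$bonds
  centroid <- colMeans(coords)
  for (k in seq_len(nrow(decorations))) {
    site <- as.integer(decorations$site[k])
    out_dir <- coords[site, ] - centroid
    nrm <- sqrt(sum(out_dir^2))
    dir <- if (nrm > 1e-9) out_dir / nrm else c(0, 0, 1)
    dir <- dir + c(0, 0, 0.35 * k)
    dir <- dir / sqrt(sum(dir^2))
    coords <- rbind(coords, coords[site, ] + 1.4 * dir)
    el <- c(el, as.character(decorations$element[k]))
    bonds <- rbind(bonds, data.frame(from = site, to = nrow(coords),
                                     order = 1L))
  }
  molecule(id, el, coords, bonds)
}

#' Generate a planted scaffold-family target database
#'
#' Writes raw (pre-curation) database inputs in the on-disk layout consumed
#' by [build_database()] — `ligands.sdf`, `activities.tsv`, `targets.tsv`,
#' `valid_uniprot.txt` — plus `ground_truth.tsv` mapping every ligand to
#' its family target. Fully deterministic from `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with file paths, the family definitions and
#'   the ground-truth table.
#' @export
make_fixture_database <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, {
    families <- lapply(seq_len(spec$n_targets), family_definition,
                       max_decorations = spec$max_decorations)
    mols <- list()
    act <- list()
    gt <- list()
    targets <- data.frame(
      uniprot_id = sprintf("P%05d", 10000L + seq_len(spec$n_targets)),
      name = sprintf("Synthetic target %d", seq_len(spec$n_targets)),
      organism = "Synthetic construct",
      gene = sprintf("SYN%d", seq_len(spec$n_targets)),
      chembl_id = "", ttd_id = ""
    )
    for (k in seq_len(spec$n_targets)) {
      for (m in seq_len(spec$ligands_per_target)) {
        lid <- sprintf("FAM%02d_LIG%02d", k, m)
        prov <- if (stats::runif(1) < spec$frac_experimental)
          "experimental" else "generated"
        mol <- make_family_member(families[[k]], lid, spec$sigma, prov)
        mols[[lid]] <- mol
        n_act <- sample.int(3L, 1L)
        act[[length(act) + 1L]] <- data.frame(
          ligand_id = lid,
          uniprot_id = targets$uniprot_id[k],
          activity_type = sample(c("IC50", "Ki", "Kd"), n_act, replace = TRUE),
          value = signif(10^stats::runif(n_act, -3, 2), 6),
          units = "uM",
          reference = "synthetic"
        )
        gt[[length(gt) + 1L]] <- data.frame(
          ligand_id = lid, target_uniprot = targets$uniprot_id[k],
          family_id = sprintf("FAM%02d", k))
      }
    }
    activities <- do.call(rbind, act)
    ground_truth <- do.call(rbind, gt)
    paths <- list(
      ligands = file.path(out_dir, "ligands.sdf"),
      activities = file.path(out_dir, "activities.tsv"),
      targets = file.path(out_dir, "targets.tsv"),
      valid_uniprot = file.path(out_dir, "valid_uniprot.txt"),
      ground_truth = file.path(out_dir, "ground_truth.tsv")
    )
    write_sdf(mols, paths$ligands)
    write_tsv_plain(activities, paths$activities)
    write_tsv_plain(targets, paths$targets)
    writeLines(targets$uniprot_id, paths$valid_uniprot)
    write_tsv_plain(ground_truth, paths$ground_truth)
    invisible(list(paths = paths, families = families, targets = targets,
                   activities = activities, ground_truth = ground_truth,
                   molecules = mols, spec = spec))
  })
}

#' Generate a held-out query from a fixture family
#'
#' A fresh member of family `k` (same scaffold and decorations, new jitter
#' and torsions), for planted-recovery experiments.
#'
#' @param fix Result of [make_fixture_database()].
#' @param k Family index.
#' @param seed Seed for the member's jitter.
#' @return A [molecule()].
#' @export
fixture_query <- function(fix, k, seed) {
  with_seed(seed, make_family_member(fix$families[[k]],
                                     sprintf("QUERY_FAM%02d", k),
                                     fix$spec$sigma))
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

# ---- grid oracles ---------------------------------------------------------

grid_axes <- function(lo, hi, step) {
  lapply(1:3, function(a) seq(lo[a], hi[a], by = step))
}

gaussian_density_on_grid <- function(g, ax) {
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  dens <- numeric(nx * ny * nz)
  X <- rep(ax[[1]], times = ny * nz)
  Y <- rep(rep(ax[[2]], each = nx), times = nz)
  Z <- rep(ax[[3]], each = nx * ny)
  for (i in seq_len(nrow(g$centers))) {
    d2 <- (X - g$centers[i, 1])^2 + (Y - g$centers[i, 2])^2 +
      (Z - g$centers[i, 3])^2
    dens <- dens + g$weights[i] * g$p[i] * exp(-g$alpha[i] * d2)
  }
  dens
}

#' Grid-integration oracle for Gaussian overlap volumes
#'
#' Independent Riemann-sum check of the closed-form overlaps: integrates
#' the product of the two (weighted) sum-of-Gaussians densities over a box
#' extending `margin_radii` maximum radii beyond all centers.
#'
#' @param ga,gb Gaussian sets from [atom_gaussians()].
#' @param step Grid step in Angstrom (<= 0.1 recommended).
#' @param margin_radii Box margin in units of the largest radius.
#' @return Overlap volume estimate in cubic Angstrom.
#' @export
grid_overlap_oracle <- function(ga, gb, step = 0.1, margin_radii = 4) {
  radius_of <- function(g) sqrt(pi * (3 * g$p / (4 * pi))^(2 / 3) / g$alpha)
  rmax <- max(radius_of(ga), radius_of(gb))
  allc <- rbind(ga$centers, gb$centers)
  lo <- apply(allc, 2, min) - margin_radii * rmax
  hi <- apply(allc, 2, max) + margin_radii * rmax
  ax <- grid_axes(lo, hi, step)
  da <- gaussian_density_on_grid(ga, ax)
  db <- gaussian_density_on_grid(gb, ax)
  sum(da * db) * step^3
}

#' Voxelized hard-sphere union volume
#'
#' Counts grid points inside at least one sphere; the reference the
#' weighted first-order volume is calibrated against.
#'
#' @param centers n x 3 matrix of sphere centers.
#' @param radii Sphere radii (recycled).
#' @param step Voxel edge (Angstrom).
#' @return Union volume in cubic Angstrom.
#' @export
union_volume_grid <- function(centers, radii, step = 0.05) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  radii <- rep_len(radii, nrow(centers))
  lo <- apply(centers - radii, 2, min) - step
  hi <- apply(centers + radii, 2, max) + step
  ax <- grid_axes(lo, hi, step)
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  X <- rep(ax[[1]], times = ny * nz)
  Y <- rep(rep(ax[[2]], each = nx), times = nz)
  Z <- rep(ax[[3]], each = nx * ny)
  inside <- logical(nx * ny * nz)
  for (i in seq_len(nrow(centers))) {
    d2 <- (X - centers[i, 1])^2 + (Y - centers[i, 2])^2 + (Z - centers[i, 3])^2
    inside <- inside | (d2 <= radii[i]^2)
  }
  sum(inside) * step^3
}

#' The 20-molecule calibration fixture set
#'
#' Chains, rings, fused-sphere systems and decorated scaffolds spanning the
#' element palette (C/N/O), used to calibrate the weighted first-order
#' volume against voxelized hard-sphere union volumes.
#'
#' @return Named list of 20 [molecule()] objects.
#' @export
calibration_molecules <- function() {
  mols <- list()
  for (n in 2:8) {
    el <- rep(c("C", "N", "O"), length.out = n)
    mols[[paste0("chain", n)]] <-
      make_toy_molecule("linear_chain", n, id = paste0("chain", n),
                        elements = if (n %% 2L == 0L) NULL else el)
  }
  for (n in 3:8) {
    mols[[paste0("ring", n)]] <-
      make_toy_molecule("ring", n, id = paste0("ring", n))
  }
  for (d in c(0.8, 1.2, 1.6)) {
    mols[[paste0("fused", d)]] <-
      make_toy_molecule("fused_spheres", 2L, id = paste0("fused", d), d = d)
  }
  dec1 <- data.frame(site = c(1L, 3L), element = c("O", "N"))
  mols[["dec_chain6"]] <- make_toy_molecule("decorated_scaffold", 7L,
                                            id = "dec_chain6",
                                            decorations = dec1)
  dec2 <- data.frame(site = c(2L, 5L), element = c("N", "O"))
  mols[["dec_ring6"]] <- make_toy_molecule("decorated_scaffold", 6L,
                                           id = "dec_ring6",
                                           decorations = dec2)
  dec3 <- data.frame(site = 1L, element = "O")
  mols[["dec_chain5"]] <- make_toy_molecule("decorated_scaffold", 5L,
                                            id = "dec_chain5",
                                            decorations = dec3)
  dec4 <- data.frame(site = c(1L, 4L, 8L), element = c("N", "O", "N"))
  mols[["dec_ring8"]] <- make_toy_molecule("decorated_scaffold", 8L,
                                           id = "dec_ring8",
                                           decorations = dec4)
  mols
}
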