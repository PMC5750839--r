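# Target-annotated ligand database: ingest, curation, persistence, load.
#
# Curation applies, in order: (1) drop activities annotated to accessions
# outside the supplied valid-UniProt list; (2) strip counter ions (keep the
# largest fragment of each ligand); (3) drop activity records less potent
# than the cutoff (strictly greater than 50 uM by default); (4) drop
# ligands with fewer than 6 heavy atoms or molecular weight above 1000 Da
# (measured after stripping). Ligands left without activities are dropped.

DB_LAYOUT_VERSION <- "1"

ACTIVITY_TYPES <- c("IC50", "Ki", "Kd")

#' Read an activities table
#'
#' Tab-separated with columns `ligand_id`, `uniprot_id`, `activity_type`,
#' `value`, `units`, `reference`. Values are normalized to micromolar at
#' ingest (`nM` / 1000, `uM` as-is, `M` x 1e6).
#'
#' @param path TSV path.
#' @return Data frame with a `value_uM` column.
#' @export
read_activities <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("ligand_id", "uniprot_id", "activity_type", "value", "units")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("activities file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"reference" %in% names(df)) df$reference <- ""
  if (nrow(df) == 0L) {
    df$value_uM <- numeric()
    return(df)
  }
  bad_type <- !df$activity_type %in% ACTIVITY_TYPES
  if (any(bad_type)) {
    stop("unknown activity_type value(s): ",
         paste(unique(df$activity_type[bad_type]), collapse = ", "))
  }
  value <- as.numeric(df$value)
  factor <- c(nM = 1e-3, uM = 1, M = 1e6)[df$units]
  if (anyNA(factor)) {
    stop("unknown units value(s): ",
         paste(unique(df$units[is.na(factor)]), collapse = ", "),
         " (expected nM, uM or M)")
  }
  df$value_uM <- value * unname(factor)
  if (any(!is.finite(df$value_uM) | df$value_uM <= 0)) {
    stop("activity values must be positive numbers")
  }
  df
}

read_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("uniprot_id", "name", "organism", "gene")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("targets file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (opt in c("chembl_id", "ttd_id")) if (!opt %in% names(df)) df[[opt]] <- ""
  if (anyDuplicated(df$uniprot_id)) {
    stop("duplicate uniprot_id entries in ", path)
  }
  df
}

curation_report <- function(lig_input, lig_kept, lig_drops, act_input,
                            act_kept, act_drops, modifications, dropped_ids,
                            params) {
  structure(list(
    ligands = c(input = lig_input, kept = lig_kept),
    ligand_drops = lig_drops,
    activities = c(input = act_input, kept = act_kept),
    activity_drops = act_drops,
    modifications = modifications,
    dropped_ligand_ids = dropped_ids,
    params = params
  ), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  ligands:    %d in, %d kept (dropped: %s)\n",
              x$ligands["input"], x$ligands["kept"],
              paste(names(x$ligand_drops), x$ligand_drops, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  activities: %d in, %d kept (dropped: %s)\n",
              x$activities["input"], x$activities["kept"],
              paste(names(x$activity_drops), x$activity_drops, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  modifications: counter_ion_stripped=%d\n",
              x$modifications["counter_ion_stripped"]))
  invisible(x)
}

#' Does a curation report reconcile?
#'
#' Checks input = kept + sum(drops) at both the ligand and the activity
#' level (counter-ion stripping is a modification, counted separately).
#'
#' @param report A `curation_report`.
#' @return `TRUE` or `FALSE`.
#' @export
report_reconciles <- function(report) {
  lig_ok <- report$ligands["input"] ==
    report$ligands["kept"] + sum(report$ligand_drops)
  act_ok <- report$activities["input"] ==
    report$activities["kept"] + sum(report$activity_drops)
  unname(lig_ok && act_ok)
}

#' Curate ligands and activities
#'
#' @param ligands Named list of [molecule()] objects (multi-conformer),
#'   names = ligand ids.
#' @param activities Data frame from [read_activities()] (must carry
#'   `value_uM`).
#' @param valid_targets Character vector of valid UniProt accessions.
#' @param activity_cutoff_uM Potency cutoff; records strictly above it are
#'   dropped (50 uM keeps a 50 uM record).
#' @param min_heavy_atoms,max_mw Size filters applied after counter-ion
#'   stripping.
#' @return List with `ligands`, `activities` and `report`.
#' @export
curate <- function(ligands, activities, valid_targets,
                   activity_cutoff_uM = 50, min_heavy_atoms = 6L,
                   max_mw = 1000) {
  if (is.null(names(ligands))) {
    names(ligands) <- vapply(ligands, function(m) m$id, character(1))
  }
  act_input <- nrow(activities)
  lig_input <- length(ligands)
  drops <- c(unknown_ligand = 0L, obsolete_target = 0L,
             over_activity_cutoff = 0L, duplicate = 0L, ligand_dropped = 0L)

  known <- activities$ligand_id %in% names(ligands)
  drops["unknown_ligand"] <- sum(!known)
  if (any(!known)) {
    message(sum(!known), " activity record(s) referenced unknown ligand ids")
  }
  activities <- activities[known, , drop = FALSE]

  valid <- activities$uniprot_id %in% valid_targets
  drops["obsolete_target"] <- sum(!valid)
  activities <- activities[valid, , drop = FALSE]

  stripped <- 0L
  ligands <- lapply(ligands, function(m) {
    if (n_fragments(m) > 1L) {
      stripped <<- stripped + 1L
      largest_fragment(m)
    } else m
  })

  weak <- activities$value_uM > activity_cutoff_uM
  drops["over_activity_cutoff"] <- sum(weak)
  activities <- activities[!weak, , drop = FALSE]

  # duplicate (ligand, target, type): keep the most potent record
  if (nrow(activities)) {
    key <- paste(activities$ligand_id, activities$uniprot_id,
                 activities$activity_type)
    ord <- order(key, activities$value_uM)
    activities <- activities[ord, , drop = FALSE]
    dup <- duplicated(key[ord])
    drops["duplicate"] <- sum(dup)
    if (any(dup)) {
      message(sum(dup), " duplicate activity record(s) resolved to the most",
              " potent value")
    }
    activities <- activities[!dup, , drop = FALSE]
  }

  lig_drops <- c(too_small = 0L, too_large = 0L, no_activity = 0L)
  dropped_ids <- data.frame(ligand_id = character(), reason = character())
  keep <- logical(length(ligands))
  for (i in seq_along(ligands)) {
    m <- ligands[[i]]
    reason <- NULL
    if (heavy_atom_count(m) < min_heavy_atoms) {
      reason <- "too_small"
    } else if (molecular_weight(m) > max_mw) {
      reason <- "too_large"
    } else if (!any(activities$ligand_id == m$id)) {
      reason <- "no_activity"
    }
    if (is.null(reason)) {
      keep[i] <- TRUE
    } else {
      lig_drops[reason] <- lig_drops[reason] + 1L
      dropped_ids <- rbind(dropped_ids,
                           data.frame(ligand_id = m$id, reason = reason))
    }
  }
  size_dropped <- names(ligands)[!keep]
  orphan <- activities$ligand_id %in% size_dropped
  drops["ligand_dropped"] <- sum(orphan)
  activities <- activities[!orphan, , drop = FALSE]
  ligands <- ligands[keep]

  report <- curation_report(
    lig_input, length(ligands), lig_drops, act_input, nrow(activities), drops,
    c(counter_ion_stripped = stripped), dropped_ids,
    params = list(activity_cutoff_uM = activity_cutoff_uM,
                  min_heavy_atoms = min_heavy_atoms, max_mw = max_mw)
  )
  rownames(activities) <- NULL
  list(ligands = ligands, activities = activities, report = report)
}

#' Build a persisted target-ligand database
#'
#' Reads raw inputs, curates them and writes the on-disk layout:
#' `ligands.sdf` (multi-conformer via repeated records sharing
#' `LIGAND_ID`), `activities.tsv` (values in uM), `targets.tsv`,
#' `curation_report.json` and `manifest.tsv` (layout version, md5
#' checksums, curation parameters).
#'
#' @param ligands_sdf Path to the raw structures SDF.
#' @param activities_tsv Path to the activities TSV.
#' @param targets_tsv Path to the target metadata TSV.
#' @param valid_uniprot Character vector of valid accessions, or a path to
#'   a one-per-line text file.
#' @param out_dir Output directory (created).
#' @param activity_cutoff_uM,min_heavy_atoms,max_mw Curation parameters.
#' @return Invisibly, a list with `dir` and the `curation_report`.
#' @export
build_database <- function(ligands_sdf, activities_tsv, targets_tsv,
                           valid_uniprot, out_dir, activity_cutoff_uM = 50,
                           min_heavy_atoms = 6L, max_mw = 1000) {
  records <- read_sdf(ligands_sdf)
  ligands <- group_conformers(records)
  activities <- read_activities(activities_tsv)
  targets <- read_targets(targets_tsv)
  if (length(valid_uniprot) == 1L && file.exists(valid_uniprot)) {
    valid_uniprot <- readLines(valid_uniprot)
  }
  cur <- curate(ligands, activities, valid_uniprot,
                activity_cutoff_uM = activity_cutoff_uM,
                min_heavy_atoms = min_heavy_atoms, max_mw = max_mw)
  if (nrow(cur$activities) == 0L) {
    warning("curated database is empty")
  }
  targets <- targets[targets$uniprot_id %in% cur$activities$uniprot_id, ,
                     drop = FALSE]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f_lig <- file.path(out_dir, "ligands.sdf")
  f_act <- file.path(out_dir, "activities.tsv")
  f_tar <- file.path(out_dir, "targets.tsv")
  write_sdf(unname(cur$ligands), f_lig)
  out_act <- cur$activities
  out_act$value <- if (nrow(out_act)) {
    format(out_act$value_uM, trim = TRUE, scientific = FALSE, digits = 10)
  } else character()
  out_act$units <- rep("uM", nrow(out_act))
  write_tsv_plain(out_act[, c("ligand_id", "uniprot_id", "activity_type",
                              "value", "units", "reference")], f_act)
  write_tsv_plain(targets, f_tar)
  jsonlite::write_json(
    list(ligands = as.list(cur$report$ligands),
         ligand_drops = as.list(cur$report$ligand_drops),
         activities = as.list(cur$report$activities),
         activity_drops = as.list(cur$report$activity_drops),
         modifications = as.list(cur$report$modifications),
         params = cur$report$params),
    file.path(out_dir, "curation_report.json"), auto_unbox = TRUE)
  sums <- tools::md5sum(c(f_lig, f_act, f_tar))
  manifest <- data.frame(
    key = c("layout_version", "activity_cutoff_uM", "min_heavy_atoms",
            "max_mw", paste0("md5:", basename(names(sums)))),
    value = c(DB_LAYOUT_VERSION, as.character(activity_cutoff_uM),
              as.character(min_heavy_atoms), as.character(max_mw),
              unname(sums))
  )
  write_tsv_plain(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(dir = out_dir, report = cur$report))
}

#' Load a persisted database
#'
#' Verifies the manifest (layout version, md5 checksums) and reads the
#' records back, precomputing shape and feature models for every conformer
#' of every ligand (eager by default).
#'
#' @param dir Directory produced by [build_database()].
#' @param params [shape_params()].
#' @param rules Feature ruleset used for precomputed feature models.
#' @param precompute Precompute per-conformer models now (`TRUE`) or on
#'   first use (`FALSE`).
#' @return Object of class `target_db`.
#' @export
load_database <- function(dir, params = shape_params(),
                          rules = default_feature_rules(), precompute = TRUE) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop("not a database directory (no manifest): ", dir)
  manifest <- utils::read.delim(man_path, stringsAsFactors = FALSE,
                                colClasses = "character")
  mget <- function(k) manifest$value[manifest$key == k]
  ver <- mget("layout_version")
  if (!identical(ver, DB_LAYOUT_VERSION)) {
    stop("database layout version mismatch: found ", ver, ", expected ",
         DB_LAYOUT_VERSION)
  }
  for (f in c("ligands.sdf", "activities.tsv", "targets.tsv")) {
    expected <- mget(paste0("md5:", f))
    actual <- unname(tools::md5sum(file.path(dir, f)))
    if (!identical(expected, actual)) {
      stop("checksum mismatch for ", f, " in ", dir)
    }
  }
  ligands <- group_conformers(read_sdf(file.path(dir, "ligands.sdf")))
  activities <- read_activities(file.path(dir, "activities.tsv"))
  targets <- read_targets(file.path(dir, "targets.tsv"))
  models <- if (precompute) {
    lapply(ligands, prepare_conformer_models, params = params, rules = rules)
  } else NULL
  structure(list(dir = dir, ligands = ligands, activities = activities,
                 targets = targets, models = models, params = params,
                 rules = rules,
                 curation = c(activity_cutoff_uM = as.numeric(mget("activity_cutoff_uM")))),
            class = "target_db")
}

#' @export
print.target_db <- function(x, ...) {
  cat(sprintf("<target_db: %d ligand(s), %d target(s), %d activity record(s)%s>\n",
              length(x$ligands), nrow(x$targets), nrow(x$activities),
              if (is.null(x$models)) "" else ", models precomputed"))
  invisible(x)
}

db_models_for <- function(db, ligand_id) {
  if (!is.null(db$models)) return(db$models[[ligand_id]])
  prepare_conformer_models(db$ligands[[ligand_id]], db$params, db$rules)
}
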