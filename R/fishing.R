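# End-to-end target fishing: score the query against every database
# ligand, keep ligand evidence above the similarity threshold, keep
# (ligand, target) evidence whose best recorded potency passes the activity
# threshold, aggregate to targets by the maximum supporting-ligand score,
# rank and export.

#' Fishing run configuration
#'
#' @param mode Similarity mode: `"shape"`, `"feature"` or `"combo"` (the
#'   combined mode is the most stringent).
#' @param similarity_threshold Minimum ligand similarity counted as
#'   evidence; ligands below it show low similarity to the query
#'   (default 0.6).
#' @param activity_threshold_uM Potency cutoff on a template ligand's best
#'   recorded activity, e.g. 10, 20 or 50 uM (default 50).
#' @param top_k Number of top-ranked targets to export aligned poses for.
#' @param extra_starts Additional seeded random alignment starts.
#' @return List of class `fishing_config`.
#' @export
fishing_config <- function(mode = c("combo", "shape", "feature"),
                           similarity_threshold = 0.6,
                           activity_threshold_uM = 50,
                           top_k = 10L, extra_starts = 0L) {
  mode <- match.arg(mode)
  stopifnot(similarity_threshold >= 0, similarity_threshold <= 1,
            activity_threshold_uM > 0, top_k >= 0L)
  structure(list(mode = mode, similarity_threshold = similarity_threshold,
                 activity_threshold_uM = activity_threshold_uM,
                 top_k = as.integer(top_k),
                 extra_starts = as.integer(extra_starts)),
            class = "fishing_config")
}

#' Score a query against one database ligand
#'
#' Delegates to [align_and_score()] with the template fixed (its frame is
#' preserved) and the query moving, over all conformer pairs. Database
#' conformers are ordered experimental-first, so exact ties prefer
#' experimentally determined template poses.
#'
#' @param query Query [molecule()].
#' @param db A `target_db`.
#' @param ligand_id Template ligand id.
#' @param config [fishing_config()].
#' @param models_query Optional precomputed query models.
#' @return A `similarity_result`; `transform` maps the query onto the
#'   template frame; `conformer_a` is the winning template conformer,
#'   `conformer_b` the winning query conformer.
#' @export
score_ligand <- function(query, db, ligand_id, config = fishing_config(),
                         models_query = NULL) {
  align_and_score(db$ligands[[ligand_id]], query, mode = config$mode,
                  params = db$params, rules = db$rules,
                  extra_starts = config$extra_starts,
                  models_a = db_models_for(db, ligand_id),
                  models_b = models_query)
}

#' Predict protein targets for a query compound
#'
#' Scores every database ligand, discards ligand evidence below the
#' similarity threshold and (ligand, target) evidence whose most potent
#' recorded activity exceeds the activity threshold, scores each remaining
#' target by its best supporting ligand, and ranks targets by score
#' (descending; ties broken by UniProt accession). Targets sharing their
#' best supporting evidence with other predictions are flagged, since such
#' co-ranked predictions carry no extra significance.
#'
#' @param query Query [molecule()] (single- or multi-conformer).
#' @param db A `target_db` from [load_database()].
#' @param config A [fishing_config()].
#' @param seed Optional seed (only relevant with `extra_starts > 0`).
#' @return Data frame of class `target_predictions` with columns `rank`,
#'   `uniprot_id`, `name`, `organism`, `gene`, `score`, `best_ligand_id`,
#'   `best_activity_uM`, `n_support`, `shared_evidence`; per-target support
#'   tables in `attr(, "support")`, per-ligand similarity results in
#'   `attr(, "results")`.
#' @export
fish_targets <- function(query, db, config = fishing_config(), seed = NULL) {
  stopifnot(inherits(db, "target_db"), inherits(config, "fishing_config"))
  empty <- data.frame(rank = integer(), uniprot_id = character(),
                      name = character(), organism = character(),
                      gene = character(), score = numeric(),
                      best_ligand_id = character(),
                      best_activity_uM = numeric(), n_support = integer(),
                      shared_evidence = logical())
  finish <- function(df, support, results) {
    attr(df, "support") <- support
    attr(df, "results") <- results
    attr(df, "config") <- config
    attr(df, "query_id") <- query$id
    class(df) <- c("target_predictions", class(df))
    df
  }
  if (length(db$ligands) == 0L) {
    warning("empty database: no predictions")
    return(finish(empty, list(), list()))
  }
  run <- function() {
    need_feat <- config$mode %in% c("feature", "combo")
    models_q <- prepare_conformer_models(query, db$params, db$rules,
                                         features = need_feat)
    results <- list()
    for (lid in names(db$ligands)) {
      res <- tryCatch(
        score_ligand(query, db, lid, config, models_query = models_q),
        error = function(e) {
          message("ligand ", lid, " skipped: ", conditionMessage(e))
          NULL
        })
      if (!is.null(res)) results[[lid]] <- res
    }
    scores <- vapply(results, function(r) r$score, numeric(1))
    evident <- names(scores)[scores >= config$similarity_threshold]
    act <- db$activities
    act <- act[act$ligand_id %in% evident, , drop = FALSE]
    if (nrow(act)) {
      key <- paste(act$ligand_id, act$uniprot_id)
      best_act <- tapply(act$value_uM, key, min)
      pairs <- unique(act[, c("ligand_id", "uniprot_id")])
      pairs$best_uM <- unname(best_act[paste(pairs$ligand_id,
                                             pairs$uniprot_id)])
      pairs <- pairs[pairs$best_uM <= config$activity_threshold_uM, ,
                     drop = FALSE]
    } else {
      pairs <- data.frame(ligand_id = character(), uniprot_id = character(),
                          best_uM = numeric())
    }
    if (nrow(pairs) == 0L) return(finish(empty, list(), results))
    pairs$score <- scores[pairs$ligand_id]
    support <- split(pairs[, c("ligand_id", "score", "best_uM")],
                     pairs$uniprot_id)
    rows <- lapply(names(support), function(up) {
      s <- support[[up]]
      s <- s[order(-s$score, s$ligand_id), , drop = FALSE]
      ti <- db$targets[db$targets$uniprot_id == up, , drop = FALSE]
      data.frame(
        uniprot_id = up,
        name = if (nrow(ti)) ti$name else NA_character_,
        organism = if (nrow(ti)) ti$organism else NA_character_,
        gene = if (nrow(ti)) ti$gene else NA_character_,
        score = s$score[1L],
        best_ligand_id = s$ligand_id[1L],
        best_activity_uM = s$best_uM[1L],
        n_support = nrow(s)
      )
    })
    df <- do.call(rbind, rows)
    df <- df[order(-df$score, df$uniprot_id), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    # best template also supporting another predicted target?
    df$shared_evidence <- vapply(seq_len(nrow(df)), function(i) {
      lid <- df$best_ligand_id[i]
      any(vapply(names(support), function(up) {
        up != df$uniprot_id[i] && lid %in% support[[up]]$ligand_id
      }, logical(1)))
    }, logical(1))
    df <- df[, c("rank", "uniprot_id", "name", "organism", "gene", "score",
                 "best_ligand_id", "best_activity_uM", "n_support",
                 "shared_evidence")]
    rownames(df) <- NULL
    finish(df, support, results)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.target_predictions <- function(x, ...) {
  cat(sprintf("Target predictions for query '%s' (%s mode): %d target(s)\n",
              attr(x, "query_id"), attr(x, "config")$mode, nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Export a fishing run to disk
#'
#' Writes `predictions.tsv` (one row per predicted target), a `run.json`
#' metadata sidecar (mode, thresholds, feature-rule version, seed), and,
#' for each of the `top_k` targets, an SDF containing the query posed by
#' the winning transform next to the best template ligand in the
#' template's original frame.
#'
#' @param predictions Result of [fish_targets()].
#' @param out_dir Output directory (created).
#' @param query The query [molecule()].
#' @param db The `target_db` used.
#' @param config The [fishing_config()] used.
#' @param seed Seed recorded in the sidecar.
#' @return Invisibly, the paths written.
#' @export
export_results <- function(predictions, out_dir, query, db,
                           config = attr(predictions, "config"),
                           seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  pred_path <- file.path(out_dir, "predictions.tsv")
  df <- as.data.frame(predictions)
  if (nrow(df)) {
    df$score <- sprintf("%.6f", df$score)
    df$best_activity_uM <- sprintf("%.6g", df$best_activity_uM)
    df$shared_evidence <- ifelse(df$shared_evidence, "true", "false")
  }
  write_tsv_plain(df, pred_path)
  results <- attr(predictions, "results")
  pose_paths <- character()
  n_pose <- min(nrow(predictions), config$top_k)
  for (i in seq_len(n_pose)) {
    lid <- predictions$best_ligand_id[i]
    res <- results[[lid]]
    template <- db$ligands[[lid]]
    tmpl_one <- template
    tmpl_one$conformers <- template$conformers[res$conformer_a]
    tmpl_one$provenance <- template$provenance[res$conformer_a]
    tmpl_one$properties <- c(template$properties,
                             list(ROLE = "template",
                                  TARGET = predictions$uniprot_id[i]))
    posed <- query
    posed$conformers <- list(apply_transform(
      query$conformers[[res$conformer_b]], res$transform))
    posed$provenance <- query$provenance[res$conformer_b]
    posed$properties <- c(query$properties, list(
      ROLE = "query", TARGET = predictions$uniprot_id[i],
      MODE = res$mode, SCORE = sprintf("%.6f", res$score),
      SHAPE_TANIMOTO = sprintf("%.6f", res$shape_tanimoto),
      FEATURE_TANIMOTO = if (is.na(res$feature_tanimoto)) "NA" else
        sprintf("%.6f", res$feature_tanimoto)))
    pp <- file.path(out_dir, sprintf("pose_rank%02d_%s.sdf", i,
                                     predictions$uniprot_id[i]))
    write_sdf(list(tmpl_one, posed), pp)
    pose_paths <- c(pose_paths, pp)
  }
  run_path <- file.path(out_dir, "run.json")
  jsonlite::write_json(list(
    query_id = query$id,
    mode = config$mode,
    similarity_threshold = config$similarity_threshold,
    activity_threshold_uM = config$activity_threshold_uM,
    top_k = config$top_k,
    extra_starts = config$extra_starts,
    feature_rules_version = db$rules$version,
    seed = if (is.null(seed)) NA else seed,
    n_predictions = nrow(predictions),
    package_version = as.character(utils::packageVersion("shapefish"))
  ), run_path, auto_unbox = TRUE, null = "null")
  invisible(list(predictions = pred_path, run = run_path, poses = pose_paths))
}
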