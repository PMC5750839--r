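# Database curation, persistence and loading.

test_that("curation drops exactly the planted violations and reconciles", {
  inp <- planted_curation_inputs()
  cur <- suppressMessages(curate(inp$ligands, inp$activities, inp$valid))
  expect_setequal(names(cur$ligands),
                  c("ok1", "ok2", "benzoate_na", "boundary"))
  # boundary: the rule is strictly greater than 50 uM
  expect_true("boundary" %in% cur$activities$ligand_id)
  expect_false("weak" %in% cur$activities$ligand_id)
  # counter ion stripped, not dropped
  expect_equal(unname(cur$report$modifications["counter_ion_stripped"]), 1L)
  expect_equal(heavy_atom_count(cur$ligands$benzoate_na), 9L)
  # per-rule drop accounting
  expect_equal(unname(cur$report$ligand_drops["too_small"]), 1L)
  expect_equal(unname(cur$report$ligand_drops["too_large"]), 1L)
  expect_equal(unname(cur$report$activity_drops["obsolete_target"]), 1L)
  expect_equal(unname(cur$report$activity_drops["over_activity_cutoff"]), 1L)
  expect_equal(unname(cur$report$activity_drops["unknown_ligand"]), 1L)
  expect_true(report_reconciles(cur$report))
})

test_that("curation is idempotent and monotone in the activity cutoff", {
  inp <- planted_curation_inputs()
  cur <- suppressMessages(curate(inp$ligands, inp$activities, inp$valid))
  again <- curate(cur$ligands, cur$activities, inp$valid)
  expect_equal(sum(again$report$ligand_drops), 0L)
  expect_equal(sum(again$report$activity_drops), 0L)
  expect_equal(unname(again$report$modifications["counter_ion_stripped"]), 0L)

  kept <- sapply(c(50, 20, 10, 1), function(cut) {
    nrow(suppressMessages(
      curate(inp$ligands, inp$activities, inp$valid,
             activity_cutoff_uM = cut))$activities)
  })
  expect_true(all(diff(kept) <= 0))
})

test_that("duplicate activities resolve to the most potent record", {
  ligs <- list(a = make_toy_molecule("linear_chain", 7, id = "a"))
  act <- data.frame(ligand_id = "a", uniprot_id = "P1",
                    activity_type = "Ki", value_uM = c(5, 2, 9),
                    reference = "")
  cur <- suppressMessages(curate(ligs, act, "P1"))
  expect_equal(nrow(cur$activities), 1L)
  expect_equal(cur$activities$value_uM, 2)
  expect_equal(unname(cur$report$activity_drops["duplicate"]), 2L)
  expect_true(report_reconciles(cur$report))
})

test_that("activity ingestion validates columns and converts units", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("ligand_id\tuniprot_id\tactivity_type\tvalue\tunits\treference",
                     "a\tP1\tIC50\t2500\tnM\tx",
                     "b\tP1\tKi\t0.5\tuM\tx",
                     "c\tP2\tKd\t0.000001\tM\tx"), collapse = "\n"), f)
  act <- read_activities(f)
  expect_equal(act$value_uM, c(2.5, 0.5, 1))
  writeLines("ligand_id\tuniprot_id\tvalue\tunits", f)
  expect_error(read_activities(f), "activity_type")
  writeLines(c("ligand_id\tuniprot_id\tactivity_type\tvalue\tunits",
               "a\tP1\tIC50\t1\tpM"), f)
  expect_error(read_activities(f), "units")
})

test_that("build/load round-trips the fixture database", {
  env <- fixture_db_dir()
  db <- fixture_db()
  expect_s3_class(db, "target_db")
  expect_equal(nrow(db$targets), 5L)
  expect_true(all(db$activities$value_uM <= 50))
  expect_true(all(db$activities$ligand_id %in% names(db$ligands)))
  # loads are idempotent
  db2 <- load_database(env$dir, precompute = FALSE)
  expect_identical(names(db$ligands), names(db2$ligands))
  expect_identical(db$activities, db2$activities)
  # conformers come back experimental-first
  for (m in db$ligands) {
    prov <- m$provenance
    expect_true(all(diff(prov == "experimental") <= 0))
  }
})

test_that("a tampered database file fails its checksum on load", {
  env <- fixture_db_dir()
  tampered <- file.path(tempdir(), "shapefish_tampered")
  unlink(tampered, recursive = TRUE)
  dir.create(tampered)
  file.copy(list.files(env$dir, full.names = TRUE), tampered)
  cat("x\n", file = file.path(tampered, "activities.tsv"), append = TRUE)
  expect_error(load_database(tampered), "checksum")
  # and a wrong layout version is refused
  man <- file.path(tampered, "manifest.tsv")
  tab <- utils::read.delim(man, colClasses = "character")
  tab$value[tab$key == "layout_version"] <- "99"
  utils::write.table(tab, man, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_database(tampered), "version")
})

test_that("an empty activities file builds an empty database with a warning", {
  raw <- file.path(tempdir(), "shapefish_empty")
  unlink(raw, recursive = TRUE); dir.create(raw)
  write_sdf(list(make_toy_molecule("linear_chain", 7, id = "x")),
            file.path(raw, "ligands.sdf"))
  writeLines("ligand_id\tuniprot_id\tactivity_type\tvalue\tunits\treference",
             file.path(raw, "activities.tsv"))
  writeLines(c("uniprot_id\tname\torganism\tgene", "P1\tT\tHuman\tG"),
             file.path(raw, "targets.tsv"))
  expect_warning(
    build_database(file.path(raw, "ligands.sdf"),
                   file.path(raw, "activities.tsv"),
                   file.path(raw, "targets.tsv"),
                   "P1", file.path(raw, "db")),
    "empty")
  db <- suppressWarnings(load_database(file.path(raw, "db")))
  expect_length(db$ligands, 0L)
})
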