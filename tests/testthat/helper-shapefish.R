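# Shared fixtures, built in code and cached for the duration of one test
# run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# methanol with explicit geometry (C-O 1.43 A)
methanol_molecule <- function() {
  molecule("methanol", c("C", "O"),
           matrix(c(0, 0, 0, 1.43, 0, 0), 2, 3, byrow = TRUE),
           bonds = data.frame(from = 1, to = 2, order = 1))
}

benzene_molecule <- function() {
  make_toy_molecule("ring", 6, id = "benzene", bond_length = 1.39)
}

# benzoate + sodium counter ion (two fragments)
benzoate_salt_molecule <- function() {
  ring <- benzene_molecule()
  coords <- ring$conformers[[1]]
  # carboxylate C on ring atom 1, two oxygens
  cpos <- coords[1, ] * 2.1
  o1 <- cpos + c(0.6, 1.0, 0)
  o2 <- cpos + c(0.6, -1.0, 0)
  na <- c(6, 6, 0)
  molecule("benzoate_na", c(ring$elements, "C", "O", "O", "Na"),
           rbind(coords, cpos, o1, o2, na),
           bonds = rbind(ring$bonds,
                         data.frame(from = c(1, 7, 7), to = c(7, 8, 9),
                                    order = c(1L, 2L, 1L))))
}

# a 1-record methane SDF (5 atoms incl. H)
methane_sdf_lines <- function(tag = "LIG1") {
  c("methane", "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300    0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300   -0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300    0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300   -0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END", "> <LIGAND_ID>", tag, "", "$$$$")
}

# glucose connectivity (C6H12O6): pyranose ring + hydroxyls, rough 3D
glucose_molecule <- function() {
  ring <- make_toy_molecule("ring", 6, id = "glucose_ring", bond_length = 1.5)
  coords <- ring$conformers[[1]]
  el <- c(rep("C", 5), "O")            # ring atoms 1-5 C, atom 6 ring O
  bonds <- ring$bonds
  bonds$order <- 1L
  # exocyclic C6 on ring C5, hydroxyl O on ring C1-C4 and on C6
  c6 <- coords[5, ] * 1.9 + c(0, 0, 1)
  coords <- rbind(coords, c6)
  el <- c(el, "C")
  bonds <- rbind(bonds, data.frame(from = 5, to = 7, order = 1L))
  for (i in 1:4) {
    coords <- rbind(coords, coords[i, ] * 1.9 + c(0, 0, -1))
    el <- c(el, "O")
    bonds <- rbind(bonds, data.frame(from = i, to = nrow(coords), order = 1L))
  }
  coords <- rbind(coords, c6 + c(0, 0, 1.4))
  el <- c(el, "O")
  bonds <- rbind(bonds, data.frame(from = 7, to = nrow(coords), order = 1L))
  molecule("glucose", el, coords, bonds)
}

# curation inputs with planted violations of every filter rule
planted_curation_inputs <- function() {
  mk_chain <- function(n, id) make_toy_molecule("linear_chain", n, id = id)
  ligs <- list(
    ok1 = mk_chain(7, "ok1"),
    ok2 = mk_chain(8, "ok2"),
    small = mk_chain(5, "small"),                  # < 6 heavy atoms
    big = mk_chain(90, "big"),                     # C90H182, MW > 1000
    benzoate_na = benzoate_salt_molecule(),        # counter ion to strip
    weak = mk_chain(7, "weak"),                    # only a 60 uM record
    obsolete = mk_chain(7, "obsolete"),            # target not in valid set
    boundary = mk_chain(7, "boundary")             # exactly 50 uM record
  )
  act <- data.frame(
    ligand_id = c("ok1", "ok2", "small", "big", "benzoate_na", "weak",
                  "obsolete", "boundary", "ghost"),
    uniprot_id = c("P1", "P2", "P1", "P2", "P1", "P1", "P9", "P2", "P1"),
    activity_type = "IC50",
    value_uM = c(1, 0.5, 2, 3, 4, 60, 1, 50, 1),
    reference = ""
  )
  list(ligands = ligs, activities = act, valid = c("P1", "P2"))
}

# fixture database (seed 1337) shared across target_db/fishing tests;
# built once into a per-run temp dir
fixture_db_dir <- function() {
  cached("fixture_db_dir", {
    raw <- file.path(tempdir(), "shapefish_fix_raw")
    out <- file.path(tempdir(), "shapefish_fix_db")
    fix <- make_fixture_database(fixture_spec(seed = 1337L), raw)
    suppressMessages(build_database(fix$paths$ligands, fix$paths$activities,
                                    fix$paths$targets, fix$paths$valid_uniprot,
                                    out))
    list(fix = fix, dir = out)
  })
}

fixture_db <- function() {
  cached("fixture_db", load_database(fixture_db_dir()$dir))
}
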