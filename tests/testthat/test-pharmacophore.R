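# Pharmacophore typing and feature overlap.

test_that("textbook molecules are typed as expected", {
  fb <- assign_features(benzene_molecule())
  tab <- table(fb$features$type)
  expect_equal(unname(tab["aromatic"]), 1L)
  expect_gte(unname(tab["hydrophobe"]), 1L)
  expect_false(any(c("donor", "acceptor", "cation", "anion") %in%
                     names(tab)))
  # aromatic centroid at the ring-atom mean
  ctr <- as.numeric(fb$features[fb$features$type == "aromatic",
                                c("x", "y", "z")])
  expect_lt(max(abs(ctr - colMeans(benzene_molecule()$conformers[[1]]))), 1e-6)

  fm <- assign_features(methanol_molecule())
  expect_setequal(fm$features$type, c("donor", "acceptor"))
  expect_equal(sum(fm$features$type == "donor"), 1L)

  fh <- assign_features(make_toy_molecule("linear_chain", 6, id = "hexane"))
  expect_false(any(c("donor", "acceptor", "cation", "anion") %in%
                     fh$features$type))

  # carboxylate and aliphatic amine typing
  acid <- molecule("acetate", c("C", "C", "O", "O"),
                   rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.0, 0),
                         c(2.1, -1.0, 0)),
                   bonds = data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                                      order = c(1L, 2L, 1L)))
  expect_true("anion" %in% assign_features(acid)$features$type)
  amine <- molecule("methylamine", c("C", "N"),
                    rbind(c(0, 0, 0), c(1.47, 0, 0)),
                    bonds = data.frame(from = 1, to = 2, order = 1L))
  expect_true("cation" %in% assign_features(amine)$features$type)
})

test_that("typing is conformer-independent in type and count", {
  m <- calibration_molecules()[["dec_chain6"]]
  m$conformers[[2]] <- m$conformers[[1]] + 3
  f1 <- assign_features(m, 1)
  f2 <- assign_features(m, 2)
  expect_identical(sort(f1$features$type), sort(f2$features$type))
})

test_that("feature overlap: self, type mismatch, brute force, invariance", {
  m <- calibration_molecules()[["dec_ring6"]]
  F1 <- assign_features(m)
  expect_equal(feature_overlap(F1, F1), F1$self_overlap, tolerance = 1e-12)

  donor_only <- methanol_molecule()     # donor+acceptor on the O
  # restrict rule file to donor vs a cation-only ruleset via two molecules
  amine <- molecule("amine", c("C", "N"), rbind(c(0, 0, 0), c(1.47, 0, 0)),
                    bonds = data.frame(from = 1, to = 2, order = 1L))
  f_meoh <- assign_features(donor_only)
  f_amine <- assign_features(amine)
  # shared types only: amine N is donor+acceptor+cation; shift far away so
  # a genuinely disjoint-type comparison is the hexane one
  hex <- assign_features(make_toy_molecule("linear_chain", 6, id = "hex"))
  expect_identical(feature_overlap(f_meoh, hex), 0)

  # brute-force same-type pair enumeration on a 2-feature toy
  two <- data.frame(type = c("donor", "acceptor"),
                    x = c(0, 1), y = 0, z = 0)
  FA <- structure(list(features = two, radius = 1, p = 2.7), class = "feature_model")
  FA$by_type <- shapefish:::feature_gaussians(FA)
  FB <- FA
  manual <- 0
  for (ty in c("donor", "acceptor")) {
    ga <- FA$by_type[[ty]]
    manual <- manual + pair_overlap(ga, ga)
  }
  expect_equal(feature_overlap(FA, FB), manual, tolerance = 1e-12)

  # rigid invariance of the overlap under a common motion
  set.seed(5)
  m2 <- calibration_molecules()[["dec_chain5"]]
  F2 <- assign_features(m2)
  base <- feature_overlap(F1, F2)
  tr <- random_rigid_transform(4)
  F1t <- assign_features(transform_molecule(m, tr))
  F2t <- assign_features(transform_molecule(m2, tr))
  expect_equal(feature_overlap(F1t, F2t), base, tolerance = 1e-9 * max(base, 1))
})

test_that("removing a feature type never increases remaining overlap", {
  rules <- read_feature_rules()
  m1 <- calibration_molecules()[["dec_ring6"]]
  m2 <- calibration_molecules()[["dec_chain6"]]
  full <- feature_overlap(assign_features(m1), assign_features(m2))
  for (drop in unique(rules$rules$type)) {
    sub <- rules
    sub$rules <- sub$rules[sub$rules$type != drop, , drop = FALSE]
    part <- feature_overlap(assign_features(m1, rules = sub),
                            assign_features(m2, rules = sub))
    expect_lte(part, full + 1e-12)
  }
})

test_that("rule files are versioned and validated", {
  rules <- read_feature_rules()
  expect_identical(rules$version, "1")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# version: test2", "donor\tNH_OH"), f)
  custom <- read_feature_rules(f)
  expect_identical(custom$version, "test2")
  fm <- assign_features(methanol_molecule(), rules = custom)
  expect_identical(unique(fm$features$type), "donor")
  writeLines("donor\tNOPE", f)
  expect_error(read_feature_rules(f), "unknown detector")
  writeLines("sparkle\tNH_OH", f)
  expect_error(read_feature_rules(f), "unknown feature type")
})
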