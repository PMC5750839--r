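# Gaussian shape core: normalization, closed-form overlaps vs grid
# integration, weights, gradients.

test_that("atomic Gaussians integrate to their hard-sphere volume", {
  for (R in c(1.2, 1.52, 1.55, 1.70, 1.80)) {
    g <- atom_gaussians(matrix(0, 1, 3), R)
    analytic <- g$p * (pi / g$alpha)^1.5
    expect_equal(analytic, 4 / 3 * pi * R^3, tolerance = 1e-9)
  }
  g <- atom_gaussians(matrix(0, 1, 3), 1.70)
  expect_equal(g$hard_volume, 20.58, tolerance = 1e-3)
})

test_that("pair_overlap matches the grid oracle and is symmetric", {
  radii <- c(1.2, 1.55, 1.70, 1.80)
  for (R1 in radii) {
    for (R2 in radii[radii >= R1]) {
      for (d in seq(0, 2 * (R1 + R2), length.out = 5)) {
        gi <- atom_gaussians(matrix(0, 1, 3), R1)
        gj <- atom_gaussians(matrix(c(d, 0, 0), 1, 3), R2)
        closed <- pair_overlap(gi, gj)
        expect_identical(closed, pair_overlap(gj, gi))
        oracle <- grid_overlap_oracle(gi, gj, step = 0.1)
        expect_equal(closed, oracle, tolerance = 0.01)
      }
    }
  }
  # vanishing at large separation
  gi <- atom_gaussians(matrix(0, 1, 3), 1.7)
  gj <- atom_gaussians(matrix(c(100, 0, 0), 1, 3), 1.7)
  expect_lt(pair_overlap(gi, gj), 1e-300)
  # identical Gaussians at d = 0: p^2 (pi/2a)^(3/2)
  expect_equal(pair_overlap(gi, gi),
               gi$p[1]^2 * (pi / (2 * gi$alpha[1]))^1.5, tolerance = 1e-12)
})

test_that("molecular_overlap equals the cutoff-free brute-force double loop", {
  set.seed(7)
  for (rep in 1:5) {
    ca <- matrix(runif(15, -2, 2), 5, 3)
    cb <- matrix(runif(15, -2, 2), 5, 3)
    A <- structure(atom_gaussians(ca, runif(5, 1.2, 1.8),
                                  weights = runif(5, 0.5, 1)),
                   class = "shape_model")
    B <- structure(atom_gaussians(cb, runif(5, 1.2, 1.8),
                                  weights = runif(5, 0.5, 1)),
                   class = "shape_model")
    brute <- 0
    for (i in 1:5) {
      for (j in 1:5) {
        gi <- atom_gaussians(ca[i, , drop = FALSE], 1)
        gi$alpha <- A$alpha[i]; gi$p <- A$p[i]
        gj <- atom_gaussians(cb[j, , drop = FALSE], 1)
        gj$alpha <- B$alpha[j]; gj$p <- B$p[j]
        brute <- brute + A$weights[i] * B$weights[j] * pair_overlap(gi, gj)
      }
    }
    expect_equal(molecular_overlap(A, B, cutoff = FALSE), brute,
                 tolerance = 1e-9)
    expect_equal(molecular_overlap(A, B), molecular_overlap(B, A),
                 tolerance = 1e-12)
  }
})

test_that("self-overlap decomposes over distant fragments", {
  near <- make_toy_molecule("fused_spheres", 2, d = 1.0)
  far_coords <- rbind(c(0, 0, 0), c(100, 0, 0))
  far <- molecule("far", c("C", "C"), far_coords)
  m_far <- make_shape_model(far)
  single <- make_shape_model(molecule("one", "C", matrix(0, 1, 3)))
  expect_equal(m_far$self_overlap, 2 * single$self_overlap,
               tolerance = 1e-6)
  # disjoint molecules overlap below 1e-9
  A <- make_shape_model(molecule("a", "C", matrix(0, 1, 3)))
  B <- make_shape_model(molecule("b", "C", matrix(c(100, 0, 0), 1, 3)))
  expect_lt(molecular_overlap(A, B), 1e-9)
  expect_gt(near$conformers[[1]][2, 1] - near$conformers[[1]][1, 1], 0)
})

test_that("weights: isolated atoms get 1, superimposed atoms less", {
  iso <- atom_gaussians(rbind(c(0, 0, 0), c(100, 0, 0)), 1.7)
  expect_equal(assign_weights(iso), c(1, 1))
  dup <- atom_gaussians(rbind(c(0, 0, 0), c(0, 0, 0)), 1.7)
  w <- assign_weights(dup)
  expect_true(all(w < 1))
  expect_true(all(w > 0))
  expect_equal(assign_weights(dup, scheme = "unit"), c(1, 1))
})

test_that("weighted first-order volume tracks the hard-sphere union volume", {
  # spot-check two shapes here; the full 20-molecule sweep runs in the
  # acceptance suite
  for (nm in c("fused1.2", "ring6")) {
    m <- calibration_molecules()[[nm]]
    sm <- make_shape_model(m)
    heavy <- m$is_heavy
    uv <- union_volume_grid(m$conformers[[1]][heavy, , drop = FALSE],
                            m$vdw[heavy], step = 0.05)
    expect_equal(weighted_volume(sm), uv, tolerance = 0.05)
  }
})

test_that("analytic overlap gradient matches central finite differences", {
  set.seed(11)
  mA <- make_toy_molecule("linear_chain", 3, id = "a")
  mB <- make_toy_molecule("linear_chain", 3, id = "b")
  A <- make_shape_model(mA)
  B <- make_shape_model(mB)
  for (rep in 1:10) {
    tr <- rigid_transform(rnorm(4), runif(3, -1.5, 1.5))
    res <- overlap_gradient(A, B, tr)
    th <- c(tr$q, tr$t)
    fd <- vapply(1:7, function(i) {
      h <- 1e-5
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (overlap_gradient(A, B, rigid_transform(tp[1:4], tp[5:7]))$value -
         overlap_gradient(A, B, rigid_transform(tm[1:4], tm[5:7]))$value) /
        (2 * h)
    }, numeric(1))
    expect_equal(res$grad, fd, tolerance = 1e-4)
  }
  # stationary at the self-overlap optimum
  g0 <- overlap_gradient(A, A, rigid_transform())
  expect_lt(sqrt(sum(g0$grad^2)), 1e-6)
  # translation gradient opposes increasing separation
  sep <- rigid_transform(t = c(2, 0, 0))
  gx <- overlap_gradient(A, B, sep)$grad[5]
  expect_lt(gx, 0)
})

test_that("overlap is invariant under a common rigid motion", {
  set.seed(3)
  m1 <- calibration_molecules()[["dec_chain6"]]
  m2 <- calibration_molecules()[["ring6"]]
  A <- make_shape_model(m1)
  B <- make_shape_model(m2)
  base <- molecular_overlap(A, B)
  for (rep in 1:5) {
    tr <- random_rigid_transform(5)
    A2 <- make_shape_model(transform_molecule(m1, tr))
    B2 <- make_shape_model(transform_molecule(m2, tr))
    expect_equal(molecular_overlap(A2, B2), base, tolerance = 1e-9)
  }
})
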