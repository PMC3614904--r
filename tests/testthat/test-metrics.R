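test_that("kabsch superposition handles exact and rigidly moved sets", {
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)
  sup <- kabsch_superpose(A, A)
  expect_equal(sup$rmsd, 0, tolerance = 1e-12)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  B <- random_rigid(A, seed = 2)
  expect_lt(kabsch_superpose(A, B)$rmsd, 1e-9)
})

test_that("kabsch rmsd matches the quaternion oracle on random instances", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    A <- matrix(rnorm(3 * n, sd = 3), n, 3)
    B <- A + matrix(rnorm(3 * n, sd = 0.5), n, 3)
    sup <- kabsch_superpose(A, B)
    expect_equal(sup$rmsd, quaternion_rmsd(A, B), tolerance = 1e-9)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  }
})

test_that("kabsch rejects mismatched and degenerate inputs", {
  A <- matrix(rnorm(9), 3, 3)
  expect_error(kabsch_superpose(A, A[1:2, ]), "matched")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 0.0), "collinear")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "3 non-collinear|matched")
})

test_that("structure RMSDs are zero under identity and rigid motion", {
  s <- suite_cached()$helix_clean
  expect_equal(rmsd_all_atom(s, s), 0, tolerance = 1e-12)
  s2 <- s
  s2$xyz <- random_rigid(s$xyz, seed = 5)
  expect_lt(rmsd_all_atom(s, s2), 1e-9)
  expect_lt(rmsd_ca(s, s2), 1e-9)
  s3 <- poly("AAAA")
  expect_error(rmsd_all_atom(s, s3), "differ")
})

test_that("a single perturbed atom contributes ~ delta/sqrt(N)", {
  s <- poly("ADELKSLIGELLKESAADEL") # 20 residues, >100 atoms
  n <- nrow(s$xyz)
  delta <- 0.2
  s2 <- s
  s2$xyz[37, ] <- s2$xyz[37, ] + c(delta, 0, 0)
  expect_equal(rmsd_all_atom(s, s2), delta / sqrt(n), tolerance = 0.02)
})

test_that("aggregation takes per-structure medians then the mean", {
  one <- aggregate_replicates("x", list(c(0.3)), list(c(-1.2)))
  expect_equal(one$mean_rmsd, 0.3)
  expect_equal(one$mean_energy_per_residue, -1.2)
  rob <- aggregate_replicates("x", list(c(1, 2, 100)), list(c(1, 2, 100)))
  expect_equal(rob$mean_rmsd, 2) # median shrugs off the outlier
  multi <- aggregate_replicates(
    "x", list(0.1, 0.2, 0.3), list(-1, -2, -3)
  )
  expect_equal(multi$mean_rmsd, 0.2)
  expect_equal(multi$mean_energy_per_residue, -2)
  # permutation invariance in replicates and structures
  a <- aggregate_replicates("x", list(c(3, 1, 2), c(5, 4)), list(c(1, 2, 3), c(4, 5)))
  b <- aggregate_replicates("x", list(c(4, 5), c(2, 3, 1)), list(c(5, 4), c(3, 1, 2)))
  expect_equal(a$mean_rmsd, b$mean_rmsd)
  expect_equal(a$mean_energy_per_residue, b$mean_energy_per_residue)
  expect_error(aggregate_replicates("x", list(), list()), "at least one")
})

test_that("pareto front matches the brute-force dominance oracle", {
  single <- data.frame(mean_rmsd = 1, mean_energy_per_residue = 1)
  expect_equal(nrow(pareto_front(single)), 1)
  two <- data.frame(
    mean_rmsd = c(1, 2), mean_energy_per_residue = c(1, 2)
  )
  f2 <- pareto_front(two)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$mean_rmsd, 1)

  set.seed(7)
  for (i in 1:25) {
    n <- 50
    # include ties with positive probability
    x <- round(runif(n, 0, 1), 1)
    y <- round(runif(n, 0, 1), 1)
    pts <- data.frame(mean_rmsd = x, mean_energy_per_residue = y)
    got <- attr(pareto_front(pts), "all")$dominated
    expect_identical(got, brute_force_dominated(x, y))
  }
})
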