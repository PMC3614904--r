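test_that("relax configuration validates its schedules", {
  expect_error(relax_config(rep_schedule = c(0.5, 0.25, 1)), "increasing")
  expect_error(relax_config(rep_schedule = c(0.1, 0.5)), "end at 1")
  expect_error(
    relax_config(
      ramp_constraints = TRUE,
      restraint_schedule = c(0.1, 0.5, 0.7, 1)
    ),
    "non-increasing"
  )
  expect_error(relax_config(n_cycles = 0), "at least 1")
})

test_that("repacking leaves chi-free structures untouched", {
  g <- poly("GGGGG")
  r <- repack(g, seed = 3)
  expect_identical(r$xyz, g$xyz)
})

test_that("repacking returns an off-well rotamer to a staggered well", {
  spec <- fixture_spec("AVA", "helix",
    defects = list(list(res = 2, kind = "chi_offset", deg = 30))
  )
  s <- plant_defects(build_peptide(spec), spec)
  r <- repack(s, seed = 1)
  chi <- structure_torsions(r)$chi[[2]]
  expect_true(min(abs(c(chi - c(-60, 60, 180), chi + 180))) < 1e-6)
  expect_lt(score(r)$total, score(s)$total)
})

test_that("the final greedy sweep never accepts uphill moves", {
  for (seed in c(1, 9)) {
    for (nm in c("helix_clash", "helix_chi", "strand_noise")) {
      s <- suite_cached()[[nm]]
      r <- repack(s, seed = seed)
      expect_lte(score(r)$total, score(s)$total + 1e-9)
    }
  }
})

test_that("minimization is a descent and restores a displaced restrained atom", {
  # pure restraint objective: a chi rotation is pulled back to the anchor
  s <- suite_cached()$helix_clean
  rset <- build_coordinate_restraints(s, "all_heavy", sd = 0.5)
  ns <- getNamespace("scaffrelax")
  s2 <- ns$.set_residue_chi(s, 7, structure_torsions(s)$chi[[7]] + c(25, 0))
  w0 <- energy_weights(w_rep = 0, w_atr = 0, w_rot = 0, w_cst = 1)
  m <- minimize(s2, w0, rset, relax_config())
  expect_lt(rmsd_all_atom(m, s), 0.02)

  # a structure at a local minimum stays put (within the convergence
  # tolerance of the minimizer)
  m2 <- minimize(m, w0, rset, relax_config())
  expect_lt(max(abs(m2$xyz - m$xyz)), 0.01)

  # descent on a clash fixture under the full energy
  cl <- suite_cached()$helix_clash
  expect_lte(score(minimize(cl))$total, score(cl)$total + 1e-9)
})

test_that("fast relax is deterministic and records its schedule", {
  s <- suite_cached()$helix_clash
  rset <- build_coordinate_restraints(s, "all_heavy", sd = 0.5)
  cfg <- relax_config(seed = 11)
  r1 <- fast_relax(s, rset, cfg)
  r2 <- fast_relax(s, rset, cfg)
  expect_identical(r1$final$xyz, r2$final$xyz)
  expect_identical(r1$trajectory, r2$trajectory)

  tr <- r1$trajectory
  expect_equal(nrow(tr), 5 * 4)
  expect_equal(unique(tr$w_rep), c(0.02, 0.25, 0.55, 1.0))
  # without ramping, restraints stay at weight 1 at every stage
  expect_true(all(tr$w_cst == 1))
  # final stage runs at full repulsive weight
  expect_equal(tr$w_rep[nrow(tr)], 1.0)
  # stored final score matches a fresh recomputation
  expect_equal(score(r1$final)$total, r1$final_score$total, tolerance = 1e-6)

  ramped <- fast_relax(
    s, rset,
    relax_config(seed = 11, ramp_constraints = TRUE)
  )
  expect_equal(
    unique(ramped$trajectory$w_cst), c(1.0, 0.7, 0.3, 0.0)
  )
})

test_that("restrained relax relieves strain while staying near the input", {
  s <- suite_cached()$helix_clash
  rset <- build_coordinate_restraints(s, "all_heavy", sd = 0.5)
  res <- fast_relax(s, rset, relax_config(seed = 5))
  free <- fast_relax(s, NULL, relax_config(seed = 5))
  expect_lt(res$final_score$total, score(s)$total)
  expect_lt(res$rmsd_to_input, free$rmsd_to_input)
})

test_that("near-zero restraint width pins the structure to the input", {
  s <- suite_cached()$helix_clash
  rset <- build_coordinate_restraints(s, "all_heavy", sd = 1e-6)
  res <- fast_relax(s, rset, relax_config(seed = 2))
  expect_lte(res$rmsd_to_input, 0.01)
})

test_that("backbone-only restraints allow sidechain drift", {
  s <- suite_cached()$helix_chi # perturbed sidechains
  bb <- fast_relax(
    s, build_coordinate_restraints(s, "backbone_heavy", sd = 0.5),
    relax_config(seed = 4)
  )
  aa <- fast_relax(
    s, build_coordinate_restraints(s, "all_heavy", sd = 0.5),
    relax_config(seed = 4)
  )
  expect_gt(bb$rmsd_to_input, aa$rmsd_to_input)
})

test_that("relax configurations round-trip through the key-value file", {
  cfg <- relax_config(
    n_cycles = 3, ramp_constraints = TRUE,
    restraint_schedule = c(1, 0.5, 0.2, 0), min_tolerance = 1e-3, seed = 9
  )
  f <- withr::local_tempfile(fileext = ".cfg")
  write_relax_config(cfg, f)
  back <- read_relax_config(f)
  expect_equal(back, cfg)
})

test_that("replicate summaries follow their definitions", {
  s <- suite_cached()$strand_clean
  rset <- build_coordinate_restraints(s, "all_heavy", sd = 0.5)
  one <- relax_replicates(s, rset, relax_config(), seeds = 4)
  expect_equal(
    one$summary$median_rmsd, one$results[[1]]$rmsd_to_input
  )
  expect_equal(one$summary$rmsd_range, 0)
  expect_error(
    relax_replicates(s, rset, relax_config(), seeds = c(1, 1)),
    "distinct"
  )
})

test_that("H/N/Q flips give the packer access to lower-energy states", {
  # under restraints the protocol converges tightly, so the enlarged
  # candidate set shows up directly in the final energy
  s <- suite_cached()$helix_hnq
  rset <- build_coordinate_restraints(s, "all_heavy", sd = 0.5)
  with_flip <- fast_relax(
    s, rset, relax_config(seed = 6, flip_hnq = TRUE)
  )$final_score$total
  without <- fast_relax(
    s, rset, relax_config(seed = 6, flip_hnq = FALSE)
  )$final_score$total
  expect_lte(with_flip, without + 1e-6)
})
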