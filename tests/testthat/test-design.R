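test_that("shell detection partitions residues by site distance", {
  s <- suite_cached()$helix_long
  centre <- colMeans(s$xyz)
  big <- detect_design_shell(s, shell_definition(matrix(centre, 1, 3), 60, 60))
  expect_setequal(big$designable, seq_along(s$resname))
  expect_length(big$repackable, 0)

  tiny <- detect_design_shell(
    s, shell_definition(matrix(centre + 500, 1, 3), 6, 12)
  )
  expect_length(tiny$designable, 0)
  expect_length(tiny$repackable, 0)

  mid <- detect_design_shell(s, shell_definition(matrix(centre, 1, 3), 8, 16))
  expect_length(intersect(mid$designable, mid$repackable), 0)
  expect_setequal(
    c(mid$designable, mid$repackable, mid$fixed), seq_along(s$resname)
  )
  # monotone shell growth
  mid2 <- detect_design_shell(s, shell_definition(matrix(centre, 1, 3), 12, 16))
  expect_true(all(mid$designable %in% mid2$designable))

  expect_error(shell_definition(integer(0)), "empty")
  expect_error(shell_definition(1, cut_design = 10, cut_repack = 5), "cut_design")
})

test_that("distance thresholds assign constructed positions exactly", {
  # point site at a known distance pattern: use CB atoms of an extended
  # chain and verify against independently computed minimum distances
  s <- poly("ADELKSLIGE", "extended")
  site <- matrix(s$xyz[which(s$atom$res == 1 & s$atom$name == "CA"), ], 1, 3)
  sh <- detect_design_shell(s, shell_definition(site, 6, 12))
  dmin <- vapply(seq_along(s$resname), function(r) {
    idx <- which(s$atom$res == r)
    min(sqrt(rowSums(sweep(s$xyz[idx, , drop = FALSE], 2, site[1, ])^2)))
  }, 0)
  expect_setequal(sh$designable, which(dmin <= 6))
  expect_setequal(sh$repackable, setdiff(which(dmin <= 12), which(dmin <= 6)))
})

test_that("design keeps the backbone fixed and respects the alphabet", {
  cs <- case_study_fixture(1)
  shells <- detect_design_shell(cs$s, cs$shell)
  d <- design(cs$s, shells, design_config(n_runs = 1), seed = 21)
  bb_in <- cs$s$xyz[cs$s$atom$is_bb, ]
  bb_out <- d$structure$xyz[d$structure$atom$is_bb, ]
  expect_identical(bb_out, bb_in)

  # native-only alphabet forces full recovery
  restricted <- design(
    cs$s, shells,
    design_config(
      allowed_aas = character(0), n_runs = 1 # native is always allowed
    ),
    seed = 23
  )
  expect_equal(restricted$recovery, 1.0)

  # no designable positions -> structure unchanged, recovery undefined
  none <- design(
    cs$s, list(designable = integer(0), repackable = integer(0)),
    design_config(n_runs = 1),
    seed = 5
  )
  expect_true(is.na(none$recovery))
  expect_identical(none$structure$aa, cs$s$aa)
})

test_that("recovery experiments report the identity pretreatment at zero RMSD", {
  s <- suite_cached()$helix_clash
  shell <- shell_definition(
    s$xyz[which(s$atom$res == 8 & s$atom$name == "CB"), ], 6, 12
  )
  tab <- recovery_experiment(
    s, c("none"), shell,
    design_config(n_runs = 2, seed = 2)
  )
  expect_equal(tab$rmsd[tab$protocol == "none"], 0)
  expect_true(tab$seq_recovery >= 0 && tab$seq_recovery <= 1)
  expect_error(
    recovery_experiment(s, character(0), shell, design_config(n_runs = 1)),
    "at least one"
  )
})
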