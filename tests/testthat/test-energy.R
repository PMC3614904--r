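test_that("scoring is deterministic and conserves its decomposition", {
  for (s in suite_cached()[c("helix_clash", "strand_noise", "helix_hnq")]) {
    b1 <- score(s)
    b2 <- score(s)
    expect_identical(b1$total, b2$total)
    expect_identical(b1$by_residue, b2$by_residue)
    expect_equal(sum(b1$by_residue$total), b1$total, tolerance = 1e-6)
    expect_equal(sum(b1$by_term), b1$total, tolerance = 1e-6)
  }
})

test_that("repulsive term is non-negative and zero without close contacts", {
  for (s in suite_cached()[c("helix_clean", "strand_clean")]) {
    b <- score(s)
    expect_equal(b$by_term[["rep"]], 0)
    expect_equal(b$by_term[["rot"]], 0, tolerance = 1e-12)
  }
  for (s in suite_cached()) {
    expect_gte(score(s)$by_term[["rep"]], 0)
  }
})

test_that("repulsive energy matches an O(n^2) brute-force oracle", {
  for (nm in c("helix_clash", "helix_mixed", "strand_noise")) {
    s <- suite_cached()[[nm]]
    b <- score(s)
    expect_equal(b$by_term[["rep"]], brute_force_rep(s), tolerance = 1e-8)
  }
})

test_that("a single ideal residue has zero rotamer strain", {
  s <- poly("V", "extended")
  expect_equal(score(s)$by_term[["rot"]], 0, tolerance = 1e-12)
})

test_that("soft repulsive mode never scores above standard mode", {
  for (s in suite_cached()[c("helix_clash", "strand_noise", "helix_long")]) {
    std <- score(s, energy_weights(rep_mode = "standard"))$by_term[["rep"]]
    soft <- score(s, energy_weights(rep_mode = "soft"))$by_term[["rep"]]
    expect_lte(soft, std + 1e-12)
  }
})

test_that("non-finite coordinates are rejected", {
  s <- poly("AAA")
  s$xyz[4, 2] <- NaN
  expect_error(score(s), "finite")
})

test_that("per-residue deltas rank the most-improved residue first", {
  s <- suite_cached()$helix_clash
  before <- score(s)
  expect_equal(per_residue_deltas(before, before)$delta, rep(0, 16))

  rset <- build_coordinate_restraints(s, "all_heavy", sd = 0.5)
  after <- fast_relax(s, rset, relax_config(seed = 3))$final_score
  d <- per_residue_deltas(before, after, term = "rep")
  # the planted clash residue must top the repulsive-improvement ranking
  expect_true(d$res[1] %in% high_energy_residues(before, 5))
  expect_true(all(diff(d$delta) >= 0))
  # truncation caps at the residue count
  expect_equal(nrow(per_residue_deltas(before, after, top = 10)), 10)
  expect_equal(nrow(per_residue_deltas(
    score(poly("AAAAA")), score(poly("AAAAA")),
    top = 10
  )), 5)
  expect_error(per_residue_deltas(before, score(poly("AAA"))), "differ")
})

test_that("high-energy residue sets follow the threshold", {
  s <- suite_cached()$helix_clash
  b <- score(s)
  hi <- high_energy_residues(b, 5)
  expect_true(all(b$by_residue$total[hi] > 5))
  expect_true(all(b$by_residue$total[-hi] <= 5))
  clean <- score(suite_cached()$helix_clean)
  expect_length(high_energy_residues(clean, 5), 0)
  expect_length(high_energy_residues(clean, -1e9), 16)
})

test_that("score tables serialize with one row per residue", {
  s <- poly("ADEL")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(score(s), f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("res", "aa", "rep", "atr", "rot", "cst", "total"))
})
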