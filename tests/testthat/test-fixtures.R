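test_that("ideal peptides have the expected composition and no strain", {
  s <- build_peptide(fixture_spec("AAAAAAAAAA", "helix"))
  expect_equal(length(s$resname), 10)
  expect_equal(nrow(s$atom), 50)
  expect_equal(score(s)$by_term[["rep"]], 0)

  g <- build_peptide(fixture_spec("G", "extended"))
  expect_equal(nrow(g$atom), 4)

  expect_error(build_peptide(fixture_spec("AXB", "helix")), "unknown amino-acid")
})

test_that("peptide construction is deterministic", {
  a <- build_peptide(fixture_spec("ADELKS", "helix"))
  b <- build_peptide(fixture_spec("ADELKS", "helix"))
  expect_identical(a$xyz, b$xyz)
})

test_that("chi offsets enter the rotamer term quadratically", {
  spec <- fixture_spec("AVA", "helix",
    defects = list(list(res = 2, kind = "chi_offset", deg = 40))
  )
  s <- plant_defects(build_peptide(spec), spec)
  b <- score(s)
  expect_equal(b$by_residue$rot[2], (40 / 20)^2, tolerance = 1e-6)
})

test_that("defects on residues without chi torsions are rejected", {
  spec <- fixture_spec("AGA", "helix",
    defects = list(list(res = 2, kind = "clash_rotamer"))
  )
  expect_error(plant_defects(build_peptide(spec), spec), "chi")
})

test_that("an empty defect list leaves the structure unchanged", {
  spec <- fixture_spec("ADEL", "helix")
  s <- build_peptide(spec)
  expect_identical(plant_defects(s, spec)$xyz, s$xyz)
})

test_that("the fixture suite is deterministic and strictly strained", {
  suite1 <- fixture_suite(1)
  suite2 <- fixture_suite(1)
  expect_gte(length(suite1), 8)
  for (nm in names(suite1)) {
    expect_identical(suite1[[nm]]$xyz, suite2[[nm]]$xyz)
    parent <- attr(suite1[[nm]], "parent")
    if (!is.null(parent)) {
      expect_gt(score(suite1[[nm]])$total, score(parent)$total)
    }
  }
  # sizes span small to medium chains
  sizes <- vapply(suite1, function(s) length(s$resname), 0L)
  expect_lte(min(sizes), 12)
  expect_gte(max(sizes), 30)
})

test_that("a planted clash flags exactly the defective region", {
  suite <- suite_cached()
  hi <- high_energy_residues(score(suite$helix_clash), 5)
  expect_true(8 %in% hi) # the planted residue
  expect_lte(length(hi), 3) # only the clash neighborhood
})
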