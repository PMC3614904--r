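test_that("PDB write/read round trip preserves coordinates to PDB precision", {
  s2 <- poly("AA")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s2, f)
  r <- clean_structure(read_pdb(f))
  expect_equal(nrow(r$atom), 10) # 5 heavy atoms per ALA
  expect_equal(r$aa, c("A", "A"))
  expect_lt(max(abs(r$xyz - s2$xyz)), 0.001 + 1e-12)

  s30 <- poly("ADELKSLIGELLKESAADELKSLIGELLKE")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s30, f2)
  r30 <- clean_structure(read_pdb(f2))
  expect_lt(max(abs(r30$xyz - s30$xyz)), 0.001 + 1e-12)
  expect_identical(r30$resname, s30$resname)
})

test_that("oversized coordinates are rejected by the fixed-width writer", {
  s <- poly("AA")
  s$xyz[1, 1] <- 12345.0
  expect_error(write_pdb(s, tempfile()), "fixed-width")
})

test_that("altLoc resolution keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.999   9.999   9.999  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.421   0.000  1.00  0.00           C",
    "END"
  ), f)
  s <- read_pdb(f)
  ca <- s$xyz[s$atom$name == "CA", , drop = FALSE]
  expect_equal(nrow(ca), 1)
  expect_equal(as.numeric(ca), c(1.458, 0, 0))
})

test_that("cleaning removes waters, hydrogens and non-canonical residues", {
  s <- poly("ALAG")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  extra <- c(
    "ATOM     99  O   HOH A  90      20.000  20.000  20.000  1.00  0.00           O",
    "ATOM     98  O   HOH A  91      24.000  20.000  20.000  1.00  0.00           O",
    "ATOM     97  H   ALA A   1       0.500   0.500   0.500  1.00  0.00           H"
  )
  lines <- readLines(f)
  writeLines(c(extra, lines), f)
  raw <- read_pdb(f)
  expect_warning(cl <- clean_structure(raw), NA) # waters drop silently
  expect_equal(.subset2(cl, "aa"), c("A", "L", "A", "G"))
  expect_false(any(cl$atom$el %in% c("H", "D")))

  # non-canonical residues are dropped with a warning
  mse <- c(
    "ATOM     90  N   MSE A  50      30.000  30.000  30.000  1.00  0.00           N",
    "ATOM     91  CA  MSE A  50      31.400  30.000  30.000  1.00  0.00           C"
  )
  writeLines(c(readLines(f), mse), f)
  raw2 <- read_pdb(f)
  expect_warning(cl2 <- clean_structure(raw2), "MSE")
  expect_equal(length(cl2$resname), 4)
})

test_that("clean_structure is idempotent and errors on empty results", {
  s <- suite_cached()$helix_clean
  expect_identical(clean_structure(s)$xyz, s$xyz)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  N   ALA A   2       0.000   0.000   0.000  1.00  0.00           N",
    "END"
  ), f)
  # the lone ALA is incomplete -> missing-atom error
  expect_error(clean_structure(read_pdb(f)), "missing heavy atom")
})

test_that("read_pdb rejects missing files, empty and malformed records", {
  expect_error(read_pdb(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(read_pdb(f), "no ATOM records")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   xxx     0.000  1.00  0.00           N"
  ), f)
  expect_error(read_pdb(f), "line 1")
})

test_that("multi-chain files raise a clear error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  N   ALA B   1       8.000   0.000   0.000  1.00  0.00           N"
  ), f)
  expect_error(read_pdb(f), "multi-chain")
})

test_that("atom selections have the expected sizes and partition the atoms", {
  s10 <- poly("AAAAAAAAAA")
  expect_equal(nrow(select_atoms(s10, "backbone_heavy")), 40)
  expect_equal(nrow(select_atoms(s10, "sidechain_heavy")), 10)
  expect_equal(nrow(select_atoms(s10, "ca")), 10)
  g <- poly("G")
  expect_equal(nrow(select_atoms(g, "sidechain_heavy")), 0)
  expect_error(select_atoms(s10, "everything"))

  for (s in suite_cached()[c("helix_clean", "strand_noise", "helix_mixed")]) {
    bb <- select_atoms(s, "backbone_heavy")$idx
    sc <- select_atoms(s, "sidechain_heavy")$idx
    all <- select_atoms(s, "all_heavy")$idx
    expect_length(intersect(bb, sc), 0)
    expect_setequal(c(bb, sc), all)
  }
})

test_that("measured torsions reproduce the construction values", {
  s <- poly("ADELKS")
  tor <- structure_torsions(s)
  expect_equal(tor$phi[2:6], rep(-57, 5), tolerance = 1e-8)
  expect_equal(tor$psi[1:5], rep(-47, 5), tolerance = 1e-8)
  # every chi sits at a well
  wells <- c(-60, 60, 180, -180)
  for (chis in tor$chi) {
    for (x in chis) expect_true(min(abs(x - wells)) < 1e-6)
  }
})
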