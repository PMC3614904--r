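test_that("harmonic restraint formula is exact", {
  expect_equal(harmonic_energy(0, 0.5), 0)
  expect_equal(harmonic_energy(0.5, 0.5), 1)
  expect_equal(harmonic_energy(2, 2), 1)
  expect_equal(harmonic_energy(1.0, 0.5), 4.0)
  expect_error(harmonic_energy(1, 0), "positive")
})

test_that("bounded restraint has flat bottom, quadratic transition, 1/sd tail", {
  sd <- 0.8
  w <- 0.4
  # zero inside the flat bottom
  expect_equal(bounded_energy(seq(0, w, by = 0.05), sd, w), rep(0, 9))
  # 0.25 at the quadratic/linear junction
  expect_equal(bounded_energy(w + 0.5 * sd, sd, w), 0.25)
  # asymptotic slope 1/sd by central finite differences
  h <- 1e-6
  for (d in c(w + sd, w + 3 * sd, w + 10 * sd)) {
    slope <- (bounded_energy(d + h, sd, w) - bounded_energy(d - h, sd, w)) / (2 * h)
    expect_equal(slope, 1 / sd, tolerance = 1e-5)
  }
  # continuity and C1 at both junctions
  for (j in c(w, w + 0.5 * sd)) {
    expect_equal(bounded_energy(j - h, sd, w), bounded_energy(j + h, sd, w),
      tolerance = 1e-5
    )
    sl <- (bounded_energy(j + h, sd, w) - bounded_energy(j - h, sd, w)) / (2 * h)
    sr <- (bounded_energy(j + 2 * h, sd, w) - bounded_energy(j, sd, w)) / (2 * h)
    expect_equal(sl, sr, tolerance = 1e-3)
  }
  expect_error(bounded_energy(1, -1, 0), "positive")
})

test_that("bounded with zero width matches harmonic on the shared segment", {
  sd <- 0.5
  d <- seq(0, 0.5 * sd, length.out = 20)
  expect_equal(bounded_energy(d, sd, 0), harmonic_energy(d, sd))
})

test_that("restraint penalties are non-increasing in sd (looser is cheaper)", {
  sds <- c(0.1, 0.3, 0.5, 1, 2, 5)
  for (d in c(0.2, 1, 3)) {
    eh <- harmonic_energy(d, sds)
    expect_true(all(diff(eh) <= 1e-12))
    eb <- bounded_energy(d, sds, 0.1)
    expect_true(all(diff(eb) <= 1e-12))
  }
})

test_that("coordinate restraint builders count atoms and anchor at zero", {
  s <- poly("AAAAAAAAAA")
  r_all <- build_coordinate_restraints(s, "all_heavy", sd = 0.5)
  expect_equal(nrow(r_all$coord), 50)
  r_bb <- build_coordinate_restraints(s, "backbone_heavy", sd = 0.5)
  expect_equal(nrow(r_bb$coord), 40)
  expect_equal(restraint_energy(r_all, s), 0)
  expect_error(
    build_coordinate_restraints(s, "all_heavy", form = "harmonic", width = 1),
    "width"
  )
})

test_that("sidechain-sidechain restraints enumerate close pairs once", {
  g <- poly("GGGGGG")
  r <- build_scsc_restraints(g, cutoff = 6)
  expect_null(r$dist) # glycine has no sidechain heavy atoms
  expect_equal(nrow(r$coord), 24) # backbone restraints remain

  s <- suite_cached()$helix_clean
  r5 <- build_scsc_restraints(s, cutoff = 5)
  # brute-force pair enumeration oracle
  sc <- select_atoms(s, "sidechain_heavy")
  cnt <- 0
  for (i in seq_len(nrow(sc) - 1)) {
    for (j in (i + 1):nrow(sc)) {
      if (sc$res[i] == sc$res[j]) next
      d <- sqrt(sum((s$xyz[sc$idx[i], ] - s$xyz[sc$idx[j], ])^2))
      if (d <= 5) cnt <- cnt + 1
    }
  }
  expect_equal(nrow(r5$dist), cnt)
  expect_true(all(r5$dist$sd == 2.0))
  r8 <- build_scsc_restraints(s, cutoff = 8)
  r3 <- build_scsc_restraints(s, cutoff = 3)
  n_of <- function(r) if (is.null(r$dist)) 0L else nrow(r$dist)
  expect_gte(n_of(r8), n_of(r5))
  expect_gte(n_of(r5), n_of(r3))
  # reference distances equal current distances -> zero energy
  expect_equal(restraint_energy(r8, s), 0, tolerance = 1e-20)
})

test_that("restraint energy follows the documented closed forms", {
  s <- poly("AAA")
  rset <- build_coordinate_restraints(s, "all_heavy", sd = 0.5)
  # displace a single restrained atom by 0.5 A
  s2 <- s
  s2$xyz[3, ] <- s2$xyz[3, ] + c(0.5, 0, 0)
  expect_equal(restraint_energy(rset, s2), 1.0, tolerance = 1e-10)
  rset0 <- rset
  rset0$weight <- 0
  expect_equal(restraint_energy(rset0, s2), 0)
})

test_that("distance restraints are rigid-motion invariant, coordinate ones not", {
  s <- suite_cached()$helix_clean
  rd <- build_scsc_restraints(s, cutoff = 8)
  rd$coord <- NULL # distance restraints only
  rc <- build_coordinate_restraints(s, "all_heavy", sd = 0.5)
  s_rot <- s
  s_rot$xyz <- random_rigid(s$xyz, seed = 99)
  expect_equal(restraint_energy(rd, s_rot), 0, tolerance = 1e-9)
  expect_gt(restraint_energy(rc, s_rot), 1)
})

test_that("restraint sets round-trip through the plain-text format", {
  s <- suite_cached()$helix_hnq
  for (rset in list(
    build_coordinate_restraints(s, "all_heavy", sd = 0.5),
    build_scsc_restraints(s, cutoff = 6)
  )) {
    f <- withr::local_tempfile(fileext = ".cst")
    write_restraints(rset, f)
    back <- read_restraints(f)
    expect_equal(back$weight, rset$weight)
    expect_equal(back$coord, rset$coord, tolerance = 1e-6)
    expect_equal(back$dist, rset$dist, tolerance = 1e-6)
  }
})
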