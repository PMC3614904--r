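# Deterministic generator of ideal-geometry mini-proteins with planted
# strain (clashing rotamers, off-well chi angles, sidechain coordinate
# noise).  These emulate the handful of high-energy residues found in
# crystal structures and make every other module testable without any
# structure downloads.

.SECONDARY_TORSIONS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -120, psi = 120),
  extended = c(phi = 180, psi = 180)
)

#' Fixture specification
#'
#' @param sequence One-letter amino-acid sequence (canonical 20).
#' @param secondary `"helix"`, `"strand"` or `"extended"`.
#' @param defects List of defects, each a list with `res` and `kind`
#'   (`"clash_rotamer"`, `"chi_offset"` with `deg`, or `"coord_noise"`
#'   with `sigma` in Angstrom).
#' @param seed Integer seed (used by `coord_noise`).
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(sequence, secondary = c("helix", "strand", "extended"),
                         defects = list(), seed = 1L) {
  secondary <- match.arg(secondary)
  aa1 <- strsplit(sequence, "")[[1]]
  .aa1_to_aa3(aa1) # validates
  for (d in defects) {
    if (is.null(d$res) || d$res < 1 || d$res > length(aa1)) {
      stop("defect residue index outside the sequence")
    }
    if (!d$kind %in% c("clash_rotamer", "chi_offset", "coord_noise")) {
      stop("unknown defect kind: ", d$kind)
    }
    if (d$kind == "coord_noise" && (is.null(d$sigma) || d$sigma < 0)) {
      stop("coord_noise needs sigma >= 0")
    }
  }
  structure(
    list(
      sequence = sequence, secondary = secondary, defects = defects,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Build an ideal-geometry peptide
#'
#' Constructs a chain from the residue templates at the secondary
#' structure's phi/psi (helix: -57/-47) with every sidechain at its
#' default chi well, so clean fixtures carry no repulsive or rotamer
#' strain.  Deterministic given the fixture specification.
#'
#' @param spec A [fixture_spec()] (defects are NOT applied here; see
#'   [plant_defects()]).
#' @param id Structure label.
#' @return A cleaned `scaffold` structure.
#' @export
build_peptide <- function(spec, id = "peptide") {
  stopifnot(inherits(spec, "fixture_spec"))
  aa1 <- strsplit(spec$sequence, "")[[1]]
  aa3 <- .aa1_to_aa3(aa1)
  n <- length(aa3)
  tor <- .SECONDARY_TORSIONS[[spec$secondary]]
  chi <- lapply(aa3, .default_chi)
  .structure_from_torsions(
    id, aa3,
    phi = rep(tor["phi"], n), psi = rep(tor["psi"], n), chi = chi
  )
}

# set the chi vector of one residue (rotating the existing sidechain)
.set_residue_chi <- function(s, res, chi) {
  ptr <- .sys_from_structure(s)
  .sys_set_chi(ptr, as.integer(res), chi)
  .structure_from_sys(ptr, s)
}

#' Plant strain defects into a structure
#'
#' `clash_rotamer` sets the residue's chis to the well combination that
#' maximizes the repulsive energy; `chi_offset` adds the stated offset
#' to chi1; `coord_noise` adds zero-mean Gaussian displacement (per
#' coordinate) to the residue's sidechain heavy atoms.  The planted
#' structure must score strictly higher than the input (an error
#' otherwise); the clean input is attached as attribute `"parent"`.
#'
#' @param s A cleaned `scaffold` structure (typically from
#'   [build_peptide()]).
#' @param spec The [fixture_spec()] carrying the defect list and seed.
#' @return The defective structure.
#' @export
plant_defects <- function(s, spec) {
  .ensure_cleaned(s)
  stopifnot(inherits(spec, "fixture_spec"))
  if (length(spec$defects) == 0) {
    return(s)
  }
  parent <- s
  tmpl <- .aa_templates()
  e_before <- score(s)$total
  set.seed(spec$seed)
  for (d in spec$defects) {
    tp <- tmpl[[s$resname[d$res]]]
    if (d$kind %in% c("clash_rotamer", "chi_offset") && tp$nchi == 0) {
      stop(sprintf(
        "residue %d (%s) has no chi torsions to perturb",
        d$res, s$resname[d$res]
      ))
    }
    if (d$kind == "clash_rotamer") {
      combos <- as.matrix(expand.grid(
        rep(list(.CHI_WELLS), tp$nchi)
      ))
      best <- NULL
      best_rep <- -Inf
      ptr <- .sys_from_structure(s)
      for (i in seq_len(nrow(combos))) {
        .sys_set_chi(ptr, as.integer(d$res), combos[i, ])
        rep_e <- .sys_score(ptr)$raw_terms[["rep"]]
        if (rep_e > best_rep) {
          best_rep <- rep_e
          best <- combos[i, ]
        }
      }
      s <- .set_residue_chi(s, d$res, best)
    } else if (d$kind == "chi_offset") {
      cur <- structure_torsions(s)$chi[[d$res]]
      cur[1] <- cur[1] + d$deg
      s <- .set_residue_chi(s, d$res, cur)
    } else { # coord_noise
      idx <- which(s$atom$res == d$res & !s$atom$is_bb)
      if (length(idx) > 0) {
        s$xyz[idx, ] <- s$xyz[idx, ] +
          matrix(stats::rnorm(3 * length(idx), 0, d$sigma), ncol = 3)
      }
    }
  }
  e_after <- score(s)$total
  if (!(e_after > e_before)) {
    stop(sprintf(
      "defect list did not increase the energy (%.4f -> %.4f)",
      e_before, e_after
    ))
  }
  attr(s, "parent") <- parent
  attr(s, "cleaned") <- TRUE
  s
}

# one fixture = clean peptide + optional defects
.make_fixture <- function(id, sequence, secondary, defects = list(),
                          seed = 1L) {
  spec <- fixture_spec(sequence, secondary, defects, seed)
  clean <- build_peptide(spec, id = id)
  if (length(defects) == 0) {
    return(clean)
  }
  plant_defects(clean, spec)
}

#' Deterministic fixture suite
#'
#' A named set of mini-proteins spanning clean and defective helices and
#' strands, 12 to 34 residues, including His/Asn/Gln residues for flip
#' tests.  Defective fixtures carry their strain-free parent as
#' attribute `"parent"`.  Deterministic given the seed.
#'
#' @param seed Integer seed (drives the coordinate-noise defects).
#' @return Named list of cleaned `scaffold` structures.
#' @export
fixture_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  helix16 <- "ADELKSLIGELLKESA"
  helix_hnq <- "AEHLKSNLQELIKHSA"
  strand12 <- "TVTISEVKVTLE"
  helix34 <- "ADELKSLIGELLKESAADELKSLIGELLKESAAS"
  list(
    helix_clean = .make_fixture("helix_clean", helix16, "helix"),
    helix_clash = .make_fixture(
      "helix_clash", helix16, "helix",
      list(list(res = 8, kind = "clash_rotamer")), seed
    ),
    helix_chi = .make_fixture(
      "helix_chi", helix16, "helix",
      list(
        list(res = 5, kind = "chi_offset", deg = 40),
        list(res = 10, kind = "chi_offset", deg = -35),
        list(res = 12, kind = "chi_offset", deg = 45)
      ), seed
    ),
    helix_hnq = .make_fixture(
      "helix_hnq", helix_hnq, "helix",
      list(
        list(res = 7, kind = "chi_offset", deg = 40),
        list(res = 9, kind = "chi_offset", deg = -40)
      ), seed
    ),
    strand_clean = .make_fixture("strand_clean", strand12, "strand"),
    strand_noise = .make_fixture(
      "strand_noise", strand12, "strand",
      list(
        list(res = 4, kind = "coord_noise", sigma = 0.3),
        list(res = 6, kind = "coord_noise", sigma = 0.3),
        list(res = 9, kind = "coord_noise", sigma = 0.3)
      ), seed
    ),
    helix_long = .make_fixture(
      "helix_long", helix34, "helix",
      list(
        list(res = 8, kind = "clash_rotamer"),
        list(res = 20, kind = "chi_offset", deg = 40),
        list(res = 27, kind = "chi_offset", deg = -35)
      ), seed
    ),
    helix_mixed = .make_fixture(
      "helix_mixed", "ADELKSLIGELLKESAQNHA", "helix",
      list(
        list(res = 8, kind = "clash_rotamer"),
        list(res = 11, kind = "chi_offset", deg = 35),
        list(res = 5, kind = "coord_noise", sigma = 0.25)
      ), seed
    )
  )
}

#' Case-study fixture for design after relax
#'
#' A 33-residue helix-hairpin mini-protein with a hydrophobic core.  A
#' clashing rotamer is planted on a core glutamate adjacent to the
#' studied isoleucine, so the pocket is strained: on the raw input every
#' rotamer of the native isoleucine collides with the displaced
#' neighbor, and fixed-backbone design replaces it.  Restrained
#' relaxation relieves the strain with sub-0.1-Angstrom average motions,
#' after which design keeps the native identity.
#'
#' The strained neighbor sits next to the functional site and outside
#' the repack shell, so design cannot repair it --- only the continuous
#' relax can (the role the input-coordinate strain plays for design in
#' real crystal structures).
#'
#' @param seed Integer seed (the fixture itself is deterministic; the
#'   seed is kept for interface symmetry with [fixture_suite()]).
#' @return List with the planted structure (`s`, parent attached as
#'   attribute `"parent"`), the studied residue index (`res`), the
#'   strained neighbor (`strained`), and the [shell_definition()] of the
#'   design experiment.
#' @seealso [case_study_experiment()]
#' @export
case_study_fixture <- function(seed = 1L) {
  aa3 <- .aa1_to_aa3(strsplit(.case_seq, "")[[1]])
  parent <- .structure_from_torsions(
    "case_parent", aa3, .case_phi, .case_psi, .case_chi
  )
  s <- .set_residue_chi(parent, 2L, c(180, -60, -60))
  s$id <- "case_study"
  if (!(score(s)$total > score(parent)$total)) {
    stop("case-study defect failed to strain the structure") # nocov
  }
  attr(s, "parent") <- parent
  # site just outside the studied sidechain, placed so the strained
  # neighbor falls outside both shells (it stays fixed in design)
  cb6 <- s$xyz[.res_atom_idx(s, 6L)[5], ]
  cb2 <- s$xyz[.res_atom_idx(s, 2L)[5], ]
  u <- (cb6 - cb2) / sqrt(sum((cb6 - cb2)^2))
  site <- cb6 + 3.5 * u
  d2 <- min(sqrt(rowSums(
    sweep(s$xyz[s$atom$res == 2L, , drop = FALSE], 2, site)^2
  )))
  list(
    s = s, res = 6L, strained = 2L,
    shell = shell_definition(
      matrix(site, 1, 3),
      cut_design = 6, cut_repack = max(6.5, d2 - 0.5)
    )
  )
}

#' Case-study design experiment
#'
#' Runs the focused design probe of [case_study_fixture()]: `n_runs`
#' single-position designs (full alphabet, one standard-repulsion
#' cycle) at the studied core position, once on the raw strained input
#' and once after all-atom harmonic restrained relax (`sd = 0.5`).
#'
#' @param seed Integer seed driving the relax and design runs.
#' @param n_runs Number of independent design runs per condition.
#' @return List with `native`, `kept_raw`, `kept_relaxed` (counts out of
#'   `n_runs`) and the relax result (`relax`).
#' @export
case_study_experiment <- function(seed = 1L, n_runs = 10L) {
  cs <- case_study_fixture(seed)
  native <- cs$s$aa[cs$res]
  dcfg <- design_config(n_cycles = 1, n_runs = 1, seed = seed)
  shells_of <- function(st) {
    det <- detect_design_shell(st, cs$shell)
    list(
      designable = cs$res,
      repackable = setdiff(c(det$designable, det$repackable), cs$res)
    )
  }
  rr <- fast_relax(
    cs$s, build_coordinate_restraints(cs$s, "all_heavy", sd = 0.5),
    relax_config(seed = seed)
  )
  sh_raw <- shells_of(cs$s)
  sh_rel <- shells_of(rr$final)
  kept_raw <- 0L
  kept_rel <- 0L
  for (i in seq_len(n_runs)) {
    a <- design(cs$s, sh_raw, dcfg, seed = seed + 100L * i)$per_position
    b <- design(rr$final, sh_rel, dcfg, seed = seed + 100L * i)$per_position
    kept_raw <- kept_raw + (a$designed[a$res == cs$res] == native)
    kept_rel <- kept_rel + (b$designed[b$res == cs$res] == native)
  }
  list(
    native = native, kept_raw = kept_raw, kept_relaxed = kept_rel,
    n_runs = n_runs, relax = rr
  )
}
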