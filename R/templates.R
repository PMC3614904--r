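# Amino-acid template machinery.
#
# Each canonical residue carries an ideal-geometry template: the four
# backbone heavy atoms (N, CA, C, O) followed by sidechain heavy atoms in
# a fixed build order.  Sidechain atoms are placed NeRF-style from three
# reference atoms with an ideal bond length and angle; the dihedral is
# either one of the residue's chi torsions (possibly plus a constant
# offset, for branch atoms) or a fixed constant (ring atoms).  The raw
# numeric table lives in aa_templates_data.R.

.BB_ATOMS <- c("N", "CA", "C", "O")
.BB_ELEMENTS <- c("N", "C", "C", "O")

# Per-element contact radii (Angstrom).  sigma_ij = r_i + r_j is the
# distance below which the repulsive term turns on.  Chosen so that
# ideal-geometry secondary structure is strain-free: the closest
# non-excluded contact of an ideal helix (carbonyl O to the next C' at
# 2.90 A) sits just outside sigma.
.EL_RADIUS <- c(C = 1.50, N = 1.34, O = 1.32, S = 1.63)

# Ideal backbone internal coordinates (Engh-Huber-style values).
.BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_o = 1.231, b_c_n = 1.329,
  a_n_ca_c = 111.2, a_ca_c_o = 120.1, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  omega = 180
)

# Discrete chi wells (degrees); also the minima of the rotamer-strain term.
.CHI_WELLS <- c(-60, 60, 180)
.CHI_SIGMA <- 20 # width (degrees) of the rotamer-strain parabola

.tmpl_env <- new.env(parent = emptyenv())

.aa_templates <- function() {
  if (!is.null(.tmpl_env$tmpl)) {
    return(.tmpl_env$tmpl)
  }
  tmpl <- lapply(names(.aa_template_raw), function(aa3) {
    raw <- .aa_template_raw[[aa3]]
    sc_names <- vapply(raw$sc, `[[`, "", "name")
    atoms <- c(.BB_ATOMS, sc_names)
    el <- c(.BB_ELEMENTS, vapply(raw$sc, `[[`, "", "el"))
    nat <- length(atoms)
    aidx <- stats::setNames(seq_len(nat), atoms)

    nchi <- length(raw$chi_defs)
    chi_quads <- if (nchi > 0) {
      t(vapply(raw$chi_defs, function(q) aidx[q], numeric(4)))
    } else {
      matrix(0, 0, 4)
    }

    zmat <- NULL
    if (length(raw$sc) > 0) {
      zmat <- data.frame(
        atom = vapply(raw$sc, `[[`, "", "name"),
        ref1 = vapply(raw$sc, function(a) aidx[[a$refs[1]]], 0),
        ref2 = vapply(raw$sc, function(a) aidx[[a$refs[2]]], 0),
        ref3 = vapply(raw$sc, function(a) aidx[[a$refs[3]]], 0),
        bond = vapply(raw$sc, `[[`, 0, "bond"),
        angle = vapply(raw$sc, `[[`, 0, "angle"),
        dih_chi = vapply(raw$sc, function(a) as.integer(a$dih_chi), 0L),
        dih_off = vapply(raw$sc, `[[`, 0, "dih_off"),
        dih_const = vapply(raw$sc, `[[`, 0, "dih_const")
      )
    }

    # chi dependency closure: sidechain atom X is rotated by chi k if its
    # own dihedral is chi k or any reference atom already depends on chi k
    dep <- matrix(FALSE, nat, max(nchi, 1))
    if (!is.null(zmat)) {
      for (i in seq_len(nrow(zmat))) {
        ai <- 4L + i
        d <- dep[zmat$ref1[i], ] | dep[zmat$ref2[i], ] | dep[zmat$ref3[i], ]
        if (zmat$dih_chi[i] > 0) d[zmat$dih_chi[i]] <- TRUE
        dep[ai, ] <- d
      }
    }

    # intra-residue bond graph (indices), including ring closures
    bonds <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)) # N-CA, CA-C, C-O
    if (!is.null(zmat)) {
      bonds <- rbind(bonds, cbind(zmat$ref3, 4L + seq_len(nrow(zmat))))
    }
    for (eb in raw$extra_bonds) {
      bonds <- rbind(bonds, c(aidx[[eb[1]]], aidx[[eb[2]]]))
    }

    # graph distances, capped at 4 (pairs with distance <= 3 are excluded
    # from the nonbonded terms)
    gd <- matrix(4L, nat, nat)
    diag(gd) <- 0L
    adj <- vector("list", nat)
    for (i in seq_len(nrow(bonds))) {
      adj[[bonds[i, 1]]] <- c(adj[[bonds[i, 1]]], bonds[i, 2])
      adj[[bonds[i, 2]]] <- c(adj[[bonds[i, 2]]], bonds[i, 1])
    }
    for (src in seq_len(nat)) {
      frontier <- src
      for (d in 1:3) {
        frontier <- unique(unlist(adj[frontier]))
        frontier <- frontier[gd[src, frontier] > d]
        if (length(frontier) == 0) break
        gd[src, frontier] <- d
      }
    }

    flip_pairs <- if (length(raw$flip_pairs) > 0) {
      t(vapply(raw$flip_pairs, function(p) aidx[p], numeric(2)))
    } else {
      matrix(0, 0, 2)
    }

    list(
      aa3 = aa3, aa1 = raw$aa1, atoms = atoms, el = el,
      radius = unname(.EL_RADIUS[el]), n_atoms = nat,
      n_sc = nat - 4L, zmat = zmat, nchi = nchi, chi_quads = chi_quads,
      chi_dep = dep, flip_chi = as.integer(raw$flip_chi),
      flip_pairs = flip_pairs, gdist = gd
    )
  })
  names(tmpl) <- names(.aa_template_raw)
  .tmpl_env$tmpl <- tmpl
  tmpl
}

.AA1_TO_AA3 <- NULL # filled lazily

.aa1_to_aa3 <- function(aa1) {
  tmpl <- .aa_templates()
  map <- stats::setNames(names(tmpl), vapply(tmpl, `[[`, "", "aa1"))
  out <- map[aa1]
  if (anyNA(out)) {
    stop("unknown amino-acid code(s): ", paste(aa1[is.na(out)], collapse = ", "))
  }
  unname(out)
}

.aa3_to_aa1 <- function(aa3) {
  tmpl <- .aa_templates()
  vapply(tmpl[aa3], `[[`, "", "aa1")
}

.is_canonical_aa3 <- function(aa3) {
  aa3 %in% names(.aa_template_raw)
}

# Default rotamer (chi values, all at wells) used when building ideal
# peptides; calibrated per residue type so that ideal helix and strand
# geometry stays outside every contact radius.
.DEFAULT_CHI <- list(
  ARG = c(180, 180, -60, 180), ASN = c(180, 60), ASP = c(180, 60),
  CYS = 180, GLN = c(180, 180, -60), GLU = c(180, 180, -60),
  HIS = c(180, 60), ILE = c(-60, -60), LEU = c(180, 60),
  LYS = c(180, 180, -60, -60), MET = c(180, 180, -60), PHE = c(180, 60),
  SER = 180, THR = -60, TRP = c(180, 60), TYR = c(180, 60), VAL = 180
)

.default_chi <- function(aa3) {
  chi <- .DEFAULT_CHI[[aa3]]
  if (is.null(chi)) {
    return(numeric(0))
  }
  chi
}

# Template database in the flat, 0-based form consumed by the C++ core.
.tmpl_db <- function() {
  if (!is.null(.tmpl_env$db)) {
    return(.tmpl_env$db)
  }
  tmpl <- .aa_templates()
  db <- lapply(tmpl, function(tp) {
    zm <- tp$zmat
    list(
      aa1 = tp$aa1,
      n_sc = as.integer(tp$n_sc),
      radius = tp$radius,
      ref1 = if (is.null(zm)) integer(0) else as.integer(zm$ref1 - 1L),
      ref2 = if (is.null(zm)) integer(0) else as.integer(zm$ref2 - 1L),
      ref3 = if (is.null(zm)) integer(0) else as.integer(zm$ref3 - 1L),
      bond = if (is.null(zm)) numeric(0) else zm$bond,
      angle = if (is.null(zm)) numeric(0) else zm$angle,
      dih_chi = if (is.null(zm)) integer(0) else as.integer(zm$dih_chi),
      dih_off = if (is.null(zm)) numeric(0) else zm$dih_off,
      dih_const = if (is.null(zm)) numeric(0) else zm$dih_const,
      nchi = as.integer(tp$nchi),
      chi_quads = matrix(as.integer(tp$chi_quads - 1L), ncol = 4),
      chi_dep = matrix(as.logical(tp$chi_dep), nrow = tp$n_atoms),
      flip_chi = as.integer(tp$flip_chi),
      flip_pairs = matrix(as.integer(tp$flip_pairs - 1L), ncol = 2),
      gdist = tp$gdist
    )
  })
  .tmpl_env$db <- db
  db
}

.aa_order <- function() names(.aa_template_raw)

.aa_code <- function(aa3) {
  match(aa3, .aa_order())
}
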