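# Structure model: an ordered set of residues, each carrying the heavy
# atoms of its amino-acid template in a fixed build order (N, CA, C, O,
# then sidechain).  Coordinates are stored in Cartesian space; torsions
# (phi/psi/chi) are the degrees of freedom used by refinement.

.new_structure <- function(id, aa3, atom, xyz, orig_resno = NULL,
                           cleaned = FALSE) {
  stopifnot(nrow(atom) == nrow(xyz))
  aa <- rep(NA_character_, length(aa3))
  canon <- .is_canonical_aa3(aa3)
  aa[canon] <- .aa3_to_aa1(aa3[canon])
  s <- list(
    id = id,
    resname = aa3,
    aa = aa,
    atom = atom,
    xyz = unname(xyz),
    orig_resno = if (is.null(orig_resno)) seq_along(aa3) else orig_resno
  )
  class(s) <- "scaffold"
  attr(s, "cleaned") <- cleaned
  s
}

.is_cleaned <- function(s) isTRUE(attr(s, "cleaned"))

.ensure_cleaned <- function(s) {
  if (!inherits(s, "scaffold")) stop("not a scaffold structure")
  if (!.is_cleaned(s)) {
    stop("structure must be cleaned first; call clean_structure()")
  }
  invisible(s)
}

.n_res <- function(s) length(s$resname)

# first atom row of each residue plus one-past-the-end sentinel
.res_offsets <- function(s) {
  c(match(seq_len(.n_res(s)), s$atom$res), nrow(s$atom) + 1L)
}

.res_atom_idx <- function(s, r) {
  which(s$atom$res == r)
}

#' @export
print.scaffold <- function(x, ...) {
  cat(
    sprintf(
      "<scaffold> %s: %d residues, %d heavy atoms%s\n",
      x$id, .n_res(x), nrow(x$atom),
      if (.is_cleaned(x)) " (cleaned)" else " (raw)"
    )
  )
  if (.n_res(x) <= 60 && !anyNA(x$aa)) {
    cat("  sequence: ", paste(x$aa, collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

.WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD")

#' Read a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records into a structure with one
#' residue per `(chain, resSeq, iCode)` group.  Hydrogens are dropped at
#' ingestion; alternate locations are resolved by keeping the conformer
#' with the highest occupancy (ties broken by altLoc letter).  Waters,
#' heteroatoms and non-canonical residues are retained in the raw
#' structure and removed by [clean_structure()].
#'
#' Only single-chain files are supported; multi-chain files raise an
#' error.
#'
#' @param path Path to a PDB file.
#' @param id Label for the structure; defaults to the file name.
#' @return A raw `scaffold` structure.
#' @seealso [write_pdb()], [clean_structure()]
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0) stop("no ATOM records in ", path)
  lines <- lines[keep]

  fx <- function(l, a, b) substr(l, a, b)
  name <- trimws(fx(lines, 13, 16))
  altloc <- fx(lines, 17, 17)
  resname <- trimws(fx(lines, 18, 20))
  chain <- fx(lines, 22, 22)
  resseq <- trimws(fx(lines, 23, 26))
  icode <- fx(lines, 27, 27)
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(fx(lines, a, b)))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf(
        "malformed %s field at line %d of %s: '%s'",
        what, keep[bad[1]], path, lines[bad[1]]
      ))
    }
    v
  }
  x <- num(31, 38, "x-coordinate")
  y <- num(39, 46, "y-coordinate")
  z <- num(47, 54, "z-coordinate")
  occ <- suppressWarnings(as.numeric(fx(lines, 55, 60)))
  occ[!is.finite(occ)] <- 1
  el <- trimws(fx(lines, 77, 78))
  infer <- el == ""
  if (any(infer)) {
    # first alphabetic character of the atom name; leading digits (e.g.
    # "1HB") indicate hydrogens
    nm <- gsub("[^A-Za-z].*$", "", sub("^[0-9]*", "", name[infer]))
    el[infer] <- toupper(substr(nm, 1, 1))
  }
  is_h <- toupper(el) %in% c("H", "D")

  df <- data.frame(
    name = name, altloc = altloc, resname = resname, chain = chain,
    resseq = resseq, icode = icode, x = x, y = y, z = z, occ = occ,
    el = toupper(el), stringsAsFactors = FALSE
  )[!is_h, , drop = FALSE]
  if (nrow(df) == 0) stop("no heavy-atom ATOM records in ", path)

  poly <- !(df$resname %in% .WATER_NAMES)
  chains <- unique(df$chain[poly])
  if (length(chains) > 1) {
    stop(
      "multi-chain input not supported (chains: ",
      paste(chains, collapse = ", "), ")"
    )
  }

  # altLoc resolution per (residue, atom name)
  rkey <- paste(df$chain, df$resseq, df$icode, sep = "|")
  akey <- paste(rkey, df$name, sep = "|")
  ord <- order(
    factor(akey, levels = unique(akey)), -df$occ, df$altloc
  )
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resseq, df$icode, df$name,
    sep = "|"
  )), , drop = FALSE]

  rkey <- paste(df$chain, df$resseq, df$icode, sep = "|")
  res <- match(rkey, unique(rkey))
  aa3 <- df$resname[!duplicated(rkey)]
  resno <- suppressWarnings(as.integer(df$resseq[!duplicated(rkey)]))
  resno[is.na(resno)] <- seq_along(resno)[is.na(resno)]

  if (!any(.is_canonical_aa3(aa3))) {
    stop("no canonical amino-acid residues in ", path)
  }

  atom <- data.frame(
    res = res, name = df$name, el = df$el, stringsAsFactors = FALSE
  )
  .new_structure(id, aa3, atom, cbind(df$x, df$y, df$z),
    orig_resno = resno, cleaned = FALSE
  )
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-column `ATOM` records (occupancy 1.00, B-factor
#' 0.00, chain A), followed by `TER` and `END`.  Coordinates round-trip
#' through [read_pdb()] to PDB precision (0.001 Angstrom).
#'
#' @param s A `scaffold` structure.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  if (!inherits(s, "scaffold")) stop("not a scaffold structure")
  if (.n_res(s) == 0 || nrow(s$atom) == 0) stop("empty structure")
  if (any(abs(s$xyz) > 9999.999)) {
    stop("coordinates exceed the fixed-width PDB field (|x| > 9999.999)")
  }
  resno <- s$orig_resno[s$atom$res]
  nm <- s$atom$name
  nm4 <- ifelse(
    nchar(nm) >= 4 | nchar(s$atom$el) > 1,
    formatC(nm, width = -4),
    paste0(" ", formatC(nm, width = -3))
  )
  lines <- sprintf(
    "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(s$atom)), nm4, s$resname[s$atom$res], resno,
    s$xyz[, 1], s$xyz[, 2], s$xyz[, 3], 1, 0, s$atom$el
  )
  n <- .n_res(s)
  ter <- sprintf(
    "TER   %5d      %3s A%4d", nrow(s$atom) + 1L, s$resname[n], s$orig_resno[n]
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, ter, "END"), con)
  invisible(path)
}

#' Clean a structure for refinement
#'
#' Removes waters, heteroatoms, hydrogens and non-canonical residues
#' (with a warning naming them), verifies that every remaining residue
#' carries all heavy atoms of its template, re-orders atoms into template
#' order and re-indexes residues contiguously.  The original residue
#' numbering is retained as metadata.  Idempotent.
#'
#' @param s A `scaffold` structure.
#' @return A cleaned `scaffold` structure.
#' @export
clean_structure <- function(s) {
  if (!inherits(s, "scaffold")) stop("not a scaffold structure")
  tmpl <- .aa_templates()
  keep_res <- which(.is_canonical_aa3(s$resname))
  dropped <- setdiff(seq_len(.n_res(s)), keep_res)
  if (length(dropped) > 0) {
    nc <- setdiff(unique(s$resname[dropped]), .WATER_NAMES)
    if (length(nc) > 0) {
      warning(
        "dropping non-canonical residue(s): ", paste(nc, collapse = ", ")
      )
    }
  }
  if (length(keep_res) == 0) stop("cleaning removed every residue")

  rows <- integer(0)
  res_new <- integer(0)
  for (j in seq_along(keep_res)) {
    r <- keep_res[j]
    tp <- tmpl[[s$resname[r]]]
    ridx <- which(s$atom$res == r & !(toupper(s$atom$el) %in% c("H", "D")))
    pos <- match(tp$atoms, s$atom$name[ridx])
    if (anyNA(pos)) {
      stop(sprintf(
        "residue %d (%s) is missing heavy atom(s): %s",
        s$orig_resno[r], s$resname[r],
        paste(tp$atoms[is.na(pos)], collapse = ", ")
      ))
    }
    rows <- c(rows, ridx[pos])
    res_new <- c(res_new, rep(j, length(pos)))
  }
  atom <- data.frame(
    res = res_new,
    name = s$atom$name[rows],
    el = s$atom$el[rows],
    stringsAsFactors = FALSE
  )
  aa3 <- s$resname[keep_res]
  is_bb <- atom$name %in% .BB_ATOMS
  atom$is_bb <- is_bb
  out <- .new_structure(
    s$id, aa3, atom, s$xyz[rows, , drop = FALSE],
    orig_resno = s$orig_resno[keep_res], cleaned = TRUE
  )
  out
}

#' Select atoms from a cleaned structure
#'
#' Returns atom references in deterministic order (residue index, then
#' template atom order).
#'
#' @param s A cleaned `scaffold` structure.
#' @param selector One of `"backbone_heavy"` (N, CA, C, O per residue),
#'   `"sidechain_heavy"` (CB onward), `"all_heavy"`, or `"ca"`.
#' @return A data frame with columns `idx` (row into the atom table),
#'   `res` and `name`.
#' @export
select_atoms <- function(s,
                         selector = c(
                           "backbone_heavy", "sidechain_heavy",
                           "all_heavy", "ca"
                         )) {
  .ensure_cleaned(s)
  selector <- match.arg(selector)
  bb <- s$atom$name %in% .BB_ATOMS
  idx <- switch(selector,
    backbone_heavy = which(bb),
    sidechain_heavy = which(!bb),
    all_heavy = seq_len(nrow(s$atom)),
    ca = which(s$atom$name == "CA")
  )
  data.frame(
    idx = idx, res = s$atom$res[idx], name = s$atom$name[idx],
    stringsAsFactors = FALSE
  )
}

#' Backbone and sidechain torsions of a structure
#'
#' Measures phi/psi backbone torsions and the chi sidechain torsions of
#' every residue from the current coordinates.  `phi[1]` and `psi[n]`
#' are `NA` (undefined at the chain ends).
#'
#' @param s A cleaned `scaffold` structure.
#' @return A list with numeric vectors `phi` and `psi` (degrees) and a
#'   list `chi` of per-residue chi vectors.
#' @export
structure_torsions <- function(s) {
  .ensure_cleaned(s)
  tmpl <- .aa_templates()
  n <- .n_res(s)
  off <- .res_offsets(s)
  at <- function(r, k) s$xyz[off[r] + k - 1L, ]
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- .dihedral(at(i - 1, 3), at(i, 1), at(i, 2), at(i, 3))
    }
    if (i < n) {
      psi[i] <- .dihedral(at(i, 1), at(i, 2), at(i, 3), at(i + 1, 1))
    }
  }
  chi <- lapply(seq_len(n), function(i) {
    tp <- tmpl[[s$resname[i]]]
    if (tp$nchi == 0) {
      return(numeric(0))
    }
    vapply(seq_len(tp$nchi), function(k) {
      q <- tp$chi_quads[k, ]
      .dihedral(at(i, q[1]), at(i, q[2]), at(i, q[3]), at(i, q[4]))
    }, 0)
  })
  list(phi = phi, psi = psi, chi = chi)
}

# Build an ideal-geometry chain from per-residue torsions.  aa3 is a
# vector of 3-letter codes; chi is a list of per-residue chi vectors.
# Returns the coordinate matrix in template atom order.
.build_chain <- function(aa3, phi, psi, chi, omega = 180) {
  tmpl <- .aa_templates()
  g <- .BB_GEOM
  n <- length(aa3)
  nat <- vapply(tmpl[aa3], `[[`, 0L, "n_atoms")
  off <- cumsum(c(1L, nat))
  xyz <- matrix(NA_real_, sum(nat), 3)

  for (i in seq_len(n)) {
    o <- off[i] - 1L
    if (i == 1) {
      xyz[o + 1L, ] <- c(0, 0, 0)
      xyz[o + 2L, ] <- c(g$b_n_ca, 0, 0)
      xyz[o + 3L, ] <- .place_atom(
        c(0, 1, 0), xyz[o + 1L, ], xyz[o + 2L, ], g$b_ca_c, g$a_n_ca_c, 0
      )
    } else {
      po <- off[i - 1] - 1L
      xyz[o + 1L, ] <- .place_atom(
        xyz[po + 1L, ], xyz[po + 2L, ], xyz[po + 3L, ],
        g$b_c_n, g$a_ca_c_n, psi[i - 1]
      )
      xyz[o + 2L, ] <- .place_atom(
        xyz[po + 2L, ], xyz[po + 3L, ], xyz[o + 1L, ],
        g$b_n_ca, g$a_c_n_ca, omega
      )
      xyz[o + 3L, ] <- .place_atom(
        xyz[po + 3L, ], xyz[o + 1L, ], xyz[o + 2L, ],
        g$b_ca_c, g$a_n_ca_c, phi[i]
      )
    }
    psi_i <- if (i < n) psi[i] else if (is.na(psi[n])) -47 else psi[n]
    xyz[o + 4L, ] <- .place_atom(
      xyz[o + 1L, ], xyz[o + 2L, ], xyz[o + 3L, ],
      g$b_c_o, g$a_ca_c_o, psi_i + 180
    )
    tp <- tmpl[[aa3[i]]]
    if (tp$n_sc > 0) {
      zm <- tp$zmat
      for (j in seq_len(nrow(zm))) {
        dih <- if (zm$dih_chi[j] > 0) {
          chi[[i]][zm$dih_chi[j]] + zm$dih_off[j]
        } else {
          zm$dih_const[j]
        }
        xyz[o + 4L + j, ] <- .place_atom(
          xyz[o + zm$ref1[j], ], xyz[o + zm$ref2[j], ], xyz[o + zm$ref3[j], ],
          zm$bond[j], zm$angle[j], dih
        )
      }
    }
  }
  xyz
}

# Assemble a cleaned scaffold from sequence + torsions.
.structure_from_torsions <- function(id, aa3, phi, psi, chi, omega = 180) {
  tmpl <- .aa_templates()
  xyz <- .build_chain(aa3, phi, psi, chi, omega)
  atom <- do.call(rbind, lapply(seq_along(aa3), function(i) {
    tp <- tmpl[[aa3[i]]]
    data.frame(
      res = i, name = tp$atoms, el = tp$el,
      is_bb = tp$atoms %in% .BB_ATOMS, stringsAsFactors = FALSE
    )
  }))
  .new_structure(id, aa3, atom, xyz, cleaned = TRUE)
}
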