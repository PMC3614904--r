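# Restraint schemes: harmonic and bounded coordinate restraints anchored
# to reference (input) coordinates, and sidechain-sidechain pairwise
# distance restraints.  The restraint energy feeds the cst term of the
# score; the set-level weight implements restraint ramping.

#' Harmonic restraint energy
#'
#' `(d/sd)^2`: smooth, convex, minimum 0 at the reference.
#'
#' @param d Displacement from the reference (Angstrom, `>= 0`).
#' @param sd Width parameter (Angstrom, `> 0`); smaller is stiffer.
#' @return Energy in units.  Vectorized over `d`.
#' @export
harmonic_energy <- function(d, sd) {
  if (any(sd <= 0)) stop("sd must be positive")
  (d / sd)^2
}

#' Bounded (flat-bottom) restraint energy
#'
#' Zero within `width` of the reference, a quadratic transition
#' `((d - width)/sd)^2` up to `width + 0.5*sd`, then linear with slope
#' `1/sd`.  Continuous with continuous first derivative.
#'
#' @param d Displacement from the reference (Angstrom, `>= 0`).
#' @param sd Width parameter (Angstrom, `> 0`).
#' @param width Flat-bottom half-width (Angstrom, `>= 0`).
#' @return Energy in units.  Vectorized over `d`.
#' @export
bounded_energy <- function(d, sd, width = 0) {
  if (any(sd <= 0)) stop("sd must be positive")
  if (any(width < 0)) stop("width must be non-negative")
  t <- pmax(d - width, 0)
  ifelse(t <= 0.5 * sd, (t / sd)^2, 0.25 + (t - 0.5 * sd) / sd)
}

.new_restraint_set <- function(coord, dist, weight = 1) {
  structure(
    list(coord = coord, dist = dist, weight = weight),
    class = "restraint_set"
  )
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf(
    "<restraint_set> %d coordinate, %d distance restraint(s), weight %.2f\n",
    if (is.null(x$coord)) 0L else nrow(x$coord),
    if (is.null(x$dist)) 0L else nrow(x$dist), x$weight
  ))
  invisible(x)
}

#' Coordinate restraints anchored to the current coordinates
#'
#' One restraint per selected atom with the atom's current position as
#' reference.  For histidine, asparagine and glutamine the terminal
#' sidechain atom pairs that are exchanged by a 180-degree flip are
#' paired, and the restraint group scores the closer of the two symmetric
#' target assignments, so a chemically equivalent flip is not penalized.
#'
#' @param s A cleaned `scaffold` structure.
#' @param selection `"all_heavy"` (backbone + sidechain) or
#'   `"backbone_heavy"`.
#' @param form `"harmonic"` or `"bounded"`.
#' @param sd Width parameter (Angstrom).
#' @param width Flat-bottom half-width (bounded form only; must be 0 for
#'   harmonic).
#' @param weight Set-level multiplier (ramped by the relax schedule).
#' @return A `restraint_set`.
#' @export
build_coordinate_restraints <- function(s,
                                        selection = c(
                                          "all_heavy", "backbone_heavy"
                                        ),
                                        form = c("harmonic", "bounded"),
                                        sd = 0.5, width = 0, weight = 1) {
  .ensure_cleaned(s)
  selection <- match.arg(selection)
  form <- match.arg(form)
  if (sd <= 0) stop("sd must be positive")
  if (width < 0) stop("width must be non-negative")
  if (form == "harmonic" && width != 0) {
    stop("width must be 0 for harmonic restraints")
  }
  sel <- select_atoms(s, selection)
  if (nrow(sel) == 0) stop("empty atom selection")
  coord <- data.frame(
    res = sel$res, atom = sel$name,
    x0 = s$xyz[sel$idx, 1], y0 = s$xyz[sel$idx, 2], z0 = s$xyz[sel$idx, 3],
    form = form, sd = sd, width = width, partner = NA_integer_,
    stringsAsFactors = FALSE
  )
  # pair flip-equivalent terminal atoms of H/N/Q
  tmpl <- .aa_templates()
  for (r in seq_len(.n_res(s))) {
    tp <- tmpl[[s$resname[r]]]
    if (nrow(tp$flip_pairs) == 0) next
    for (k in seq_len(nrow(tp$flip_pairs))) {
      nm <- tp$atoms[tp$flip_pairs[k, ]]
      i <- which(coord$res == r & coord$atom == nm[1])
      j <- which(coord$res == r & coord$atom == nm[2])
      if (length(i) == 1 && length(j) == 1) {
        coord$partner[i] <- j
        coord$partner[j] <- i
      }
    }
  }
  .new_restraint_set(coord, NULL, weight)
}

#' Sidechain-sidechain distance restraints
#'
#' One harmonic distance restraint (default `sd = 2.0`) for every
#' unordered pair of sidechain heavy atoms in distinct residues whose
#' current distance is within `cutoff`, plus harmonic coordinate
#' restraints (default `sd = 0.5`) on all backbone heavy atoms.
#'
#' @param s A cleaned `scaffold` structure.
#' @param cutoff Pair inclusion distance (Angstrom, `> 0`).
#' @param sd_dist Width of the distance restraints.
#' @param sd_bb Width of the backbone coordinate restraints.
#' @param weight Set-level multiplier.
#' @return A `restraint_set`.
#' @export
build_scsc_restraints <- function(s, cutoff, sd_dist = 2.0, sd_bb = 0.5,
                                  weight = 1) {
  .ensure_cleaned(s)
  if (cutoff <= 0) stop("cutoff must be positive")
  bb <- build_coordinate_restraints(
    s,
    selection = "backbone_heavy", form = "harmonic", sd = sd_bb
  )
  sc <- select_atoms(s, "sidechain_heavy")
  dist <- NULL
  if (nrow(sc) > 1) {
    d <- as.matrix(stats::dist(s$xyz[sc$idx, , drop = FALSE]))
    pair <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (nrow(pair) > 0) {
      r1 <- sc$res[pair[, 1]]
      r2 <- sc$res[pair[, 2]]
      keep <- r1 != r2
      if (any(keep)) {
        dist <- data.frame(
          res1 = r1[keep], atom1 = sc$name[pair[keep, 1]],
          res2 = r2[keep], atom2 = sc$name[pair[keep, 2]],
          d0 = d[pair[keep, , drop = FALSE]], sd = sd_dist,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  .new_restraint_set(bb$coord, dist, weight)
}

# convert an R restraint_set to the flat form the C++ core consumes
.apply_restraints <- function(ptr, rset, s) {
  stopifnot(inherits(rset, "restraint_set"))
  tmpl <- .aa_templates()
  atom_idx <- function(res, name) {
    vapply(seq_along(res), function(i) {
      tp <- tmpl[[s$resname[res[i]]]]
      k <- match(name[i], tp$atoms)
      if (is.na(k)) {
        stop(sprintf(
          "restraint references missing atom %s in residue %d",
          name[i], res[i]
        ))
      }
      k - 1L
    }, 0L)
  }
  out <- list(weight = rset$weight)
  if (!is.null(rset$coord) && nrow(rset$coord) > 0) {
    cc <- rset$coord
    if (any(cc$res < 1 | cc$res > .n_res(s))) {
      stop("restraint references residue outside the structure")
    }
    out$c_res <- as.integer(cc$res - 1L)
    out$c_atom <- atom_idx(cc$res, cc$atom)
    out$c_x0 <- cbind(cc$x0, cc$y0, cc$z0)
    out$c_form <- ifelse(cc$form == "harmonic", 0L, 1L)
    out$c_sd <- cc$sd
    out$c_width <- cc$width
    out$c_partner <- ifelse(is.na(cc$partner), -1L,
      as.integer(cc$partner - 1L)
    )
  }
  if (!is.null(rset$dist) && nrow(rset$dist) > 0) {
    dd <- rset$dist
    if (any(c(dd$res1, dd$res2) < 1 | c(dd$res1, dd$res2) > .n_res(s))) {
      stop("restraint references residue outside the structure")
    }
    out$d_res1 <- as.integer(dd$res1 - 1L)
    out$d_atom1 <- atom_idx(dd$res1, dd$atom1)
    out$d_res2 <- as.integer(dd$res2 - 1L)
    out$d_atom2 <- atom_idx(dd$res2, dd$atom2)
    out$d_d0 <- dd$d0
    out$d_sd <- dd$sd
  }
  .sys_set_restraints(ptr, out)
  invisible(ptr)
}

#' Restraint energy of a structure
#'
#' `weight * (sum of coordinate terms + sum of distance terms)`; distance
#' terms are harmonic in the deviation from the reference distance.
#'
#' @param rset A `restraint_set`.
#' @param s A cleaned `scaffold` structure containing every referenced
#'   atom.
#' @return Energy in units.
#' @export
restraint_energy <- function(rset, s) {
  ptr <- .sys_from_structure(
    s, energy_weights(w_rep = 0, w_atr = 0, w_rot = 0, w_cst = 1), rset
  )
  unname(.sys_score(ptr)$terms["cst"])
}

#' Write a restraint set to a plain-text file
#'
#' One line per restraint: `COORD res atom x0 y0 z0 form sd width partner`
#' or `DIST res1 atom1 res2 atom2 d0 sd`, preceded by a `WEIGHT` line.
#' Round-trips through [read_restraints()].
#'
#' @param rset A `restraint_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_restraints <- function(rset, path) {
  stopifnot(inherits(rset, "restraint_set"))
  lines <- sprintf("WEIGHT\t%.10g", rset$weight)
  if (!is.null(rset$coord) && nrow(rset$coord) > 0) {
    cc <- rset$coord
    lines <- c(lines, sprintf(
      "COORD\t%d\t%s\t%.6f\t%.6f\t%.6f\t%s\t%.6g\t%.6g\t%s",
      cc$res, cc$atom, cc$x0, cc$y0, cc$z0, cc$form, cc$sd, cc$width,
      ifelse(is.na(cc$partner), ".", as.character(cc$partner))
    ))
  }
  if (!is.null(rset$dist) && nrow(rset$dist) > 0) {
    dd <- rset$dist
    lines <- c(lines, sprintf(
      "DIST\t%d\t%s\t%d\t%s\t%.6f\t%.6g",
      dd$res1, dd$atom1, dd$res2, dd$atom2, dd$d0, dd$sd
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a restraint set written by [write_restraints()]
#'
#' @param path Path to a restraint file.
#' @return A `restraint_set`.
#' @export
read_restraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kinds <- vapply(parts, `[[`, "", 1)
  weight <- 1
  wl <- which(kinds == "WEIGHT")
  if (length(wl) > 0) weight <- as.numeric(parts[[wl[1]]][2])
  coord <- NULL
  ci <- which(kinds == "COORD")
  if (length(ci) > 0) {
    m <- do.call(rbind, parts[ci])
    partner <- rep(NA_integer_, nrow(m))
    has_p <- m[, 10] != "."
    partner[has_p] <- as.integer(m[has_p, 10])
    coord <- data.frame(
      res = as.integer(m[, 2]), atom = m[, 3],
      x0 = as.numeric(m[, 4]), y0 = as.numeric(m[, 5]),
      z0 = as.numeric(m[, 6]), form = m[, 7],
      sd = as.numeric(m[, 8]), width = as.numeric(m[, 9]),
      partner = partner,
      stringsAsFactors = FALSE
    )
  }
  dist <- NULL
  di <- which(kinds == "DIST")
  if (length(di) > 0) {
    m <- do.call(rbind, parts[di])
    dist <- data.frame(
      res1 = as.integer(m[, 2]), atom1 = m[, 3],
      res2 = as.integer(m[, 4]), atom2 = m[, 5],
      d0 = as.numeric(m[, 6]), sd = as.numeric(m[, 7]),
      stringsAsFactors = FALSE
    )
  }
  .new_restraint_set(coord, dist, weight)
}
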