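# Simplified all-atom energy with the decomposition used throughout:
# a clamped Lennard-Jones repulsive term (rep), a short-range attractive
# well (atr), a rotamer-strain term penalizing chi angles away from the
# nearest staggered well (rot), and the restraint energy (cst).  Energies
# are in arbitrary units.

# shared numeric parameters of the energy model
.ENERGY_PARAMS <- list(
  eps_atr = 0.2, # depth of the attractive well (units)
  soft_scale = 0.9, # contact-radius shrink factor in soft repulsive mode
  chi_sigma = 20, # width (degrees) of the rotamer-strain parabola
  sw_on = 4.5, sw_off = 6.0 # attractive switching window (Angstrom)
)

#' Energy weights
#'
#' Term weights for [score()] and the relax protocol.  `w_rep` is the
#' quantity ramped by the relax schedule; `rep_mode = "soft"` shrinks all
#' contact radii by a fixed factor (0.9), the soft-repulsive mode used in
#' the first design cycle.
#'
#' @param w_rep,w_atr,w_rot,w_cst Non-negative term weights.
#' @param rep_mode `"standard"` or `"soft"`.
#' @return An `energy_weights` object.
#' @export
energy_weights <- function(w_rep = 1, w_atr = 1, w_rot = 1, w_cst = 1,
                           rep_mode = c("standard", "soft")) {
  rep_mode <- match.arg(rep_mode)
  w <- c(w_rep, w_atr, w_rot, w_cst)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("energy weights must be finite and non-negative")
  }
  structure(
    list(
      w_rep = w_rep, w_atr = w_atr, w_rot = w_rot, w_cst = w_cst,
      rep_mode = rep_mode
    ),
    class = "energy_weights"
  )
}

# Build the C++ system for a cleaned structure; optionally attach weights
# and restraints.
.sys_from_structure <- function(s, weights = NULL, restraints = NULL) {
  .ensure_cleaned(s)
  if (any(!is.finite(s$xyz))) stop("structure has non-finite coordinates")
  ptr <- .sys_new(
    as.integer(.aa_code(s$resname)), s$xyz, .tmpl_db(), .ENERGY_PARAMS
  )
  if (!is.null(weights)) .apply_weights(ptr, weights)
  if (!is.null(restraints)) .apply_restraints(ptr, restraints, s)
  ptr
}

.apply_weights <- function(ptr, w) {
  stopifnot(inherits(w, "energy_weights"))
  .sys_set_weights(
    ptr, w$w_rep, w$w_atr, w$w_rot, w$w_cst, identical(w$rep_mode, "soft")
  )
}

# refresh an R-side structure from the (possibly mutated) system
.structure_from_sys <- function(ptr, s) {
  aa_code <- .sys_aa(ptr)
  xyz <- .sys_get_xyz(ptr)
  aa3 <- .aa_order()[aa_code]
  if (identical(aa3, s$resname)) {
    s$xyz <- xyz
    return(s)
  }
  tmpl <- .aa_templates()
  atom <- do.call(rbind, lapply(seq_along(aa3), function(i) {
    tp <- tmpl[[aa3[i]]]
    data.frame(
      res = i, name = tp$atoms, el = tp$el,
      is_bb = tp$atoms %in% .BB_ATOMS, stringsAsFactors = FALSE
    )
  }))
  .new_structure(s$id, aa3, atom, xyz,
    orig_resno = s$orig_resno, cleaned = TRUE
  )
}

#' Score a structure
#'
#' Computes the total energy and its decomposition by term and by
#' residue.  Pairwise energies are split half/half between the two
#' residues, so both decompositions sum exactly to the total.
#'
#' @param s A cleaned `scaffold` structure.
#' @param weights An [energy_weights()] object.
#' @param restraints Optional `restraint_set`; contributes the `cst`
#'   term (zero when absent).
#' @return A `score_breakdown`: list with `total`, `by_term` (weighted
#'   term energies), `by_residue` (data frame of per-residue weighted
#'   energies and totals) and `per_residue_mean`.
#' @export
score <- function(s, weights = energy_weights(), restraints = NULL) {
  ptr <- .sys_from_structure(s, weights, restraints)
  res <- .sys_score(ptr)
  pr <- res$by_residue
  df <- data.frame(
    res = seq_len(.n_res(s)), aa = s$aa,
    rep = pr[, "rep"], atr = pr[, "atr"], rot = pr[, "rot"],
    cst = pr[, "cst"], stringsAsFactors = FALSE
  )
  df$total <- df$rep + df$atr + df$rot + df$cst
  structure(
    list(
      total = res$total,
      by_term = res$terms,
      by_residue = df,
      per_residue_mean = res$total / .n_res(s)
    ),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "<score> total %.3f units (%.3f / residue)\n", x$total,
    x$per_residue_mean
  ))
  cat("  terms: ", paste(
    sprintf("%s %.3f", names(x$by_term), x$by_term),
    collapse = ", "
  ), "\n", sep = "")
  invisible(x)
}

#' Per-residue energy changes between two score breakdowns
#'
#' Ranks residues by the change in the given term, most-improved (most
#' negative delta) first; ties are broken by residue index.
#'
#' @param before,after `score_breakdown` objects for the same residues.
#' @param term One of `"total"`, `"rep"`, `"atr"`, `"rot"`, `"cst"`.
#' @param top Optional: keep only the first `top` rows (truncated to the
#'   residue count).
#' @return A data frame with columns `res`, `aa`, `delta`.
#' @export
per_residue_deltas <- function(before, after, term = "total", top = NULL) {
  stopifnot(
    inherits(before, "score_breakdown"), inherits(after, "score_breakdown")
  )
  if (nrow(before$by_residue) != nrow(after$by_residue)) {
    stop("residue counts differ between the two breakdowns")
  }
  term <- match.arg(term, c("total", "rep", "atr", "rot", "cst"))
  delta <- after$by_residue[[term]] - before$by_residue[[term]]
  out <- data.frame(
    res = before$by_residue$res, aa = before$by_residue$aa, delta = delta,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$delta, out$res), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Residues above an energy threshold
#'
#' @param b A `score_breakdown`.
#' @param threshold Energy threshold (units); residues with per-residue
#'   total strictly greater are returned.
#' @return Integer vector of residue indices.
#' @export
high_energy_residues <- function(b, threshold = 5) {
  stopifnot(inherits(b, "score_breakdown"))
  b$by_residue$res[b$by_residue$total > threshold]
}

#' Write a per-residue score table
#'
#' Tab-separated: residue index, amino acid, per-term energies, total.
#'
#' @param b A `score_breakdown`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(b, path) {
  stopifnot(inherits(b, "score_breakdown"))
  utils::write.table(
    b$by_residue, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
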