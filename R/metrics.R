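# RMSD via Kabsch superposition, replicate aggregation and Pareto-front
# analysis of the energy/RMSD trade-off.

#' Kabsch superposition
#'
#' Least-squares superposition of `coords_b` onto `coords_a` over proper
#' rotations and translations (single pass, no outlier rejection).
#'
#' @param coords_a,coords_b Matched n x 3 coordinate matrices.
#' @return A `superposition`: list with `rotation` (3 x 3, determinant
#'   +1), `translation` (so that `coords_b %*% rotation + translation`
#'   best fits `coords_a`) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3) {
    stop("coordinate sets must be matched n x 3 matrices")
  }
  n <- nrow(coords_a)
  if (n < 1) stop("empty coordinate sets")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  if (n >= 3) {
    # guard against (near-)collinear degenerate geometry
    sv <- svd(A)$d
    if (sv[2] < 1e-9 * max(sv[1], 1)) {
      stop("degenerate geometry: points are (nearly) collinear")
    }
  } else {
    stop("at least 3 non-collinear points required")
  }
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fit <- B %*% R
  rmsd <- sqrt(mean(rowSums((fit - A)^2)))
  structure(
    list(
      rotation = R,
      translation = as.numeric(ca - cb %*% R),
      rmsd = rmsd
    ),
    class = "superposition"
  )
}

.matched_xyz <- function(a, b, selector) {
  .ensure_cleaned(a)
  .ensure_cleaned(b)
  if (.n_res(a) != .n_res(b) || !identical(a$aa, b$aa)) {
    stop("structures differ in residue count or sequence")
  }
  sel <- select_atoms(a, selector)
  list(a = a$xyz[sel$idx, , drop = FALSE], b = b$xyz[sel$idx, , drop = FALSE],
       sel = sel)
}

#' All-heavy-atom RMSD after superposition
#'
#' Superposes on all heavy atoms (Kabsch, no outlier pruning) and
#' returns the RMSD.  Symmetric in its arguments.  With
#' `flip_aware = TRUE`, the terminal atom pairs of His/Asn/Gln exchanged
#' by a 180-degree flip are assigned per residue to whichever pairing
#' gives the lower contribution before the RMSD is computed (off by
#' default: the plain value reports flips as deviation).
#'
#' @param a,b Cleaned `scaffold` structures with identical sequences.
#' @param flip_aware Resolve H/N/Q flip ambiguity.
#' @return RMSD in Angstrom.
#' @export
rmsd_all_atom <- function(a, b, flip_aware = FALSE) {
  m <- .matched_xyz(a, b, "all_heavy")
  sup <- kabsch_superpose(m$a, m$b)
  fit <- m$b %*% sup$rotation
  fit <- sweep(fit, 2, sup$translation, `+`)
  dev2 <- rowSums((fit - m$a)^2)
  if (flip_aware) {
    tmpl <- .aa_templates()
    off <- .res_offsets(a)
    for (r in seq_len(.n_res(a))) {
      tp <- tmpl[[a$resname[r]]]
      if (nrow(tp$flip_pairs) == 0) next
      for (k in seq_len(nrow(tp$flip_pairs))) {
        i <- off[r] + tp$flip_pairs[k, 1] - 1L
        j <- off[r] + tp$flip_pairs[k, 2] - 1L
        direct <- dev2[i] + dev2[j]
        swapped <- sum((fit[i, ] - m$a[j, ])^2) +
          sum((fit[j, ] - m$a[i, ])^2)
        if (swapped < direct) {
          dev2[i] <- sum((fit[i, ] - m$a[j, ])^2)
          dev2[j] <- sum((fit[j, ] - m$a[i, ])^2)
        }
      }
    }
  }
  sqrt(mean(dev2))
}

#' Alpha-carbon RMSD after CA superposition
#'
#' @param a,b Cleaned `scaffold` structures with identical sequences.
#' @return RMSD in Angstrom.
#' @export
rmsd_ca <- function(a, b) {
  m <- .matched_xyz(a, b, "ca")
  kabsch_superpose(m$a, m$b)$rmsd
}

#' Aggregate replicate runs into one summary point
#'
#' Per-structure median over replicates, then unweighted mean over
#' structures, for both axes; ranges are the mean over structures of the
#' replicate range (max - min).
#'
#' @param label Parameter-setting name.
#' @param rmsd,energy Lists (one element per structure) of per-replicate
#'   numeric vectors.
#' @return One-row data frame: `label`, `mean_rmsd`,
#'   `mean_energy_per_residue`, `rmsd_range`, `energy_range`.
#' @export
aggregate_replicates <- function(label, rmsd, energy) {
  if (length(rmsd) == 0 || length(energy) == 0) {
    stop("need at least one structure")
  }
  if (length(rmsd) != length(energy)) {
    stop("rmsd and energy must cover the same structures")
  }
  if (any(vapply(rmsd, length, 0L) == 0)) {
    stop("need at least one replicate per structure")
  }
  data.frame(
    label = label,
    mean_rmsd = mean(vapply(rmsd, stats::median, 0)),
    mean_energy_per_residue = mean(vapply(energy, stats::median, 0)),
    rmsd_range = mean(vapply(rmsd, function(x) max(x) - min(x), 0)),
    energy_range = mean(vapply(energy, function(x) max(x) - min(x), 0)),
    stringsAsFactors = FALSE
  )
}

#' Pareto front of energy/RMSD points
#'
#' Both axes are minimized.  A point is dominated iff another point is
#' less than or equal on both axes and strictly less on at least one;
#' ties (equal on both axes) are all retained.
#'
#' @param points Data frame with columns `mean_rmsd` and
#'   `mean_energy_per_residue` (e.g. rows from
#'   [aggregate_replicates()]).
#' @return The input with a logical `dominated` column added, restricted
#'   to the non-dominated subset and sorted by `mean_rmsd`.  The full
#'   annotated set is attached as attribute `"all"`.
#' @export
pareto_front <- function(points) {
  if (nrow(points) < 1) stop("need at least one point")
  x <- points$mean_rmsd
  y <- points$mean_energy_per_residue
  n <- length(x)
  ord <- order(x, y)
  dominated <- logical(n)
  best_before <- Inf # lowest y among points with strictly smaller x
  i <- 1
  while (i <= n) {
    # process groups with equal x together: within a group only a
    # strictly lower y dominates; across groups, y <= suffices
    j <- i
    while (j < n && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    ymin_group <- y[ord[i]]
    for (k in i:j) {
      p <- ord[k]
      dominated[p] <- (best_before <= y[p]) || (y[p] > ymin_group)
    }
    best_before <- min(best_before, ymin_group)
    i <- j + 1
  }
  points$dominated <- dominated
  front <- points[!dominated, , drop = FALSE]
  front <- front[order(front$mean_rmsd), , drop = FALSE]
  rownames(front) <- NULL
  attr(front, "all") <- points
  front
}

# build the restraint set described by a sweep setting
.setting_restraints <- function(s, setting) {
  kind <- setting$restraint
  if (is.null(kind) || kind == "none") {
    return(NULL)
  }
  form <- if (is.null(setting$form)) "harmonic" else setting$form
  width <- if (is.null(setting$width)) 0 else setting$width
  switch(kind,
    bb = build_coordinate_restraints(
      s,
      selection = "backbone_heavy", form = form,
      sd = setting$sd, width = width
    ),
    allatom = build_coordinate_restraints(
      s,
      selection = "all_heavy", form = form,
      sd = setting$sd, width = width
    ),
    scsc = build_scsc_restraints(s, cutoff = setting$cutoff),
    stop("unknown restraint kind: ", kind)
  )
}

#' Sweep relax settings over a structure set
#'
#' Runs [relax_replicates()] for every (structure, setting) pair,
#' aggregates per setting (median over replicates, mean over
#' structures), and flags the Pareto front of the resulting
#' energy/RMSD points.
#'
#' @param structures Named list of cleaned `scaffold` structures.
#' @param settings List of setting lists: `label`, `restraint` (one of
#'   `"none"`, `"bb"`, `"allatom"`, `"scsc"`), and the scheme parameters
#'   `form`, `sd`, `width`, `cutoff` as applicable.
#' @param config A [relax_config()] template.
#' @param seeds Replicate seeds (shared across settings for paired
#'   comparisons).
#' @return Data frame with one row per setting (aggregate axes, ranges,
#'   `on_front`); per-run details in attribute `"runs"`.
#' @export
sweep_protocols <- function(structures, settings,
                            config = relax_config(), seeds = 1:10) {
  if (length(structures) == 0 || length(settings) == 0) {
    stop("need at least one structure and one setting")
  }
  rows <- list()
  runs <- list()
  for (setting in settings) {
    rmsd <- list()
    energy <- list()
    for (nm in names(structures)) {
      s <- structures[[nm]]
      rset <- .setting_restraints(s, setting)
      rep <- relax_replicates(s, rset, config, seeds = seeds)
      rmsd[[nm]] <- vapply(rep$results, function(r) r$rmsd_to_input, 0)
      energy[[nm]] <- vapply(
        rep$results, function(r) r$final_score$per_residue_mean, 0
      )
      runs[[paste(setting$label, nm, sep = " | ")]] <- rep$summary
    }
    rows[[setting$label]] <- aggregate_replicates(
      setting$label, rmsd, energy
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  front <- pareto_front(out)
  out$on_front <- !attr(front, "all")$dominated
  attr(out, "runs") <- runs
  out
}

#' Scatter plot of a sweep (RMSD vs energy per residue)
#'
#' @param sweep Result of [sweep_protocols()].
#' @param file Optional path; when given, a PDF is written there.
#' @return Invisibly, `sweep`.
#' @export
plot_sweep <- function(sweep, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(
    sweep$mean_rmsd, sweep$mean_energy_per_residue,
    pch = ifelse(sweep$on_front, 19, 1),
    xlab = "mean all-atom RMSD to input (Å)",
    ylab = "mean energy per residue (units)",
    main = "restraint-protocol sweep"
  )
  graphics::text(
    sweep$mean_rmsd, sweep$mean_energy_per_residue,
    labels = sweep$label, pos = 4, cex = 0.7
  )
  invisible(sweep)
}
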