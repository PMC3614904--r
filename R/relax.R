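# The relax protocol: cycles of sidechain repacking and torsion-space
# minimization with the repulsive weight ramped up within each cycle.
# Restraints are anchored before the protocol starts and contribute to
# the objective throughout (optionally ramped off as the repulsive weight
# rises).

.REPACK_TEMPS <- c(10, 3, 1, 0.3, 0)

#' Relax protocol configuration
#'
#' @param n_cycles Number of repack/minimize cycles (default 5).
#' @param rep_schedule Repulsive weights per stage within a cycle;
#'   strictly increasing and ending at 1.0.
#' @param ramp_constraints If `TRUE`, the restraint weight follows
#'   `restraint_schedule` (non-increasing) as the repulsive weight rises;
#'   if `FALSE` (default, the restrained-relax convention) restraints
#'   keep weight 1 at every stage.
#' @param restraint_schedule Restraint weight per stage when ramping.
#' @param min_tolerance Projected-gradient stopping threshold for the
#'   minimizer (units/degree).
#' @param max_min_iters Iteration cap per minimization.
#' @param flip_hnq Allow 180-degree flips of the terminal chi of
#'   His/Asn/Gln during repacking.
#' @param extra_rotamers Add +/-10 degree sub-sampling around each chi
#'   well (slower; off by default).
#' @param seed Integer seed; all randomness in the protocol derives from
#'   it.
#' @return A `relax_config` object.
#' @export
relax_config <- function(n_cycles = 5,
                         rep_schedule = c(0.02, 0.25, 0.55, 1.0),
                         ramp_constraints = FALSE,
                         restraint_schedule = c(1.0, 0.7, 0.3, 0.0),
                         min_tolerance = 1e-4,
                         max_min_iters = 500,
                         flip_hnq = TRUE,
                         extra_rotamers = FALSE,
                         seed = 1L) {
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  if (any(diff(rep_schedule) <= 0) ||
    abs(rep_schedule[length(rep_schedule)] - 1.0) > 1e-12) {
    stop("rep_schedule must be strictly increasing and end at 1.0")
  }
  if (ramp_constraints) {
    if (length(restraint_schedule) != length(rep_schedule)) {
      stop("restraint_schedule must match rep_schedule in length")
    }
    if (any(diff(restraint_schedule) > 0)) {
      stop("restraint_schedule must be non-increasing")
    }
  }
  structure(
    list(
      n_cycles = as.integer(n_cycles), rep_schedule = rep_schedule,
      ramp_constraints = isTRUE(ramp_constraints),
      restraint_schedule = restraint_schedule,
      min_tolerance = min_tolerance,
      max_min_iters = as.integer(max_min_iters),
      flip_hnq = isTRUE(flip_hnq),
      extra_rotamers = isTRUE(extra_rotamers),
      seed = as.integer(seed)
    ),
    class = "relax_config"
  )
}

#' Write / read a relax configuration as a plain key-value file
#'
#' One `key = value` line per field; vectors are comma-separated.
#'
#' @param config A [relax_config()].
#' @param path File path.
#' @return `write_relax_config()` returns `path` invisibly;
#'   `read_relax_config()` returns a `relax_config`.
#' @export
write_relax_config <- function(config, path) {
  stopifnot(inherits(config, "relax_config"))
  fmt <- function(v) paste(format(v, digits = 12), collapse = ",")
  lines <- vapply(
    names(config), function(k) sprintf("%s = %s", k, fmt(config[[k]])), ""
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_relax_config
#' @export
read_relax_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(
    lapply(kv, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]]),
    vapply(kv, `[[`, "", 1)
  )
  num <- function(k) as.numeric(vals[[k]])
  lgl <- function(k) as.logical(vals[[k]])
  relax_config(
    n_cycles = as.integer(num("n_cycles")),
    rep_schedule = num("rep_schedule"),
    ramp_constraints = lgl("ramp_constraints"),
    restraint_schedule = num("restraint_schedule"),
    min_tolerance = num("min_tolerance"),
    max_min_iters = as.integer(num("max_min_iters")),
    flip_hnq = lgl("flip_hnq"),
    extra_rotamers = lgl("extra_rotamers"),
    seed = as.integer(num("seed"))
  )
}

# deterministic per-stage seed stream (kept within 32-bit range)
.stage_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 104729) %% 2147483647L) + 1L
}

# internal: run the packer on an existing system
.pack_sys <- function(ptr, nres, seed, flip, ex) {
  .sys_pack(
    ptr, seq_len(nres), integer(0), list(), flip, ex, .REPACK_TEMPS,
    as.integer(seed), numeric(0)
  )
  invisible(ptr)
}

# internal: run the torsion minimizer on an existing system.
# free: optional logical mask over the torsion catalogue.
.minimize_sys <- function(ptr, tol, maxit, free = NULL) {
  theta0 <- .sys_min_begin(ptr)
  n <- length(theta0)
  if (is.null(free)) free <- rep(TRUE, n)
  if (!any(free)) {
    .sys_min_commit(ptr, theta0)
    return(invisible(ptr))
  }
  full <- theta0
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) {
      return(cache$val)
    }
    full[free] <- par
    val <- .sys_energy_grad(ptr, full)
    cache$par <- par
    cache$val <- val
    val
  }
  fit <- try(
    stats::optim(
      theta0[free],
      fn = function(p) eval_at(p)$E,
      gr = function(p) eval_at(p)$grad[free],
      method = "L-BFGS-B",
      control = list(maxit = maxit, pgtol = tol, factr = 1e7)
    ),
    silent = TRUE
  )
  e0 <- .sys_energy_grad(ptr, theta0)$E
  if (!inherits(fit, "try-error") && is.finite(fit$value) &&
    fit$value <= e0 + 1e-9) {
    full[free] <- fit$par
    .sys_min_commit(ptr, full)
  } else {
    .sys_min_commit(ptr, theta0)
  }
  invisible(ptr)
}

#' Repack sidechain rotamers
#'
#' Replaces each residue's sidechain chi angles by the best-scoring
#' candidate among the input rotamer, the staggered chi wells
#' (-60/60/180 per chi) and, for His/Asn/Gln, the 180-degree terminal
#' flip, optimized by simulated annealing over residues with the total
#' energy (including restraints) as objective.  Residue identities and
#' backbone torsions never change.
#'
#' @param s A cleaned `scaffold` structure.
#' @param weights An [energy_weights()] object.
#' @param restraints Optional `restraint_set`.
#' @param seed Integer seed.
#' @param flip_hnq,extra_rotamers See [relax_config()].
#' @return The repacked structure.
#' @export
repack <- function(s, weights = energy_weights(), restraints = NULL,
                   seed = 1L, flip_hnq = TRUE, extra_rotamers = FALSE) {
  ptr <- .sys_from_structure(s, weights, restraints)
  .pack_sys(ptr, .n_res(s), seed, flip_hnq, extra_rotamers)
  .structure_from_sys(ptr, s)
}

#' Minimize torsions
#'
#' Quasi-Newton (L-BFGS-B) minimization of the total energy (score plus
#' restraints) over all phi/psi/chi torsions, with analytic torsion-space
#' gradients.  The returned structure never scores higher than the
#' input.
#'
#' @param s A cleaned `scaffold` structure.
#' @param weights An [energy_weights()] object.
#' @param restraints Optional `restraint_set`.
#' @param config A [relax_config()] (supplies `min_tolerance` and
#'   `max_min_iters`).
#' @param chi_only If `TRUE`, only sidechain chi torsions move (fixed
#'   backbone).
#' @return The minimized structure.
#' @export
minimize <- function(s, weights = energy_weights(), restraints = NULL,
                     config = relax_config(), chi_only = FALSE) {
  ptr <- .sys_from_structure(s, weights, restraints)
  free <- NULL
  if (chi_only) {
    info <- .sys_torsions(ptr)
    free <- info$type == 2
  }
  .minimize_sys(ptr, config$min_tolerance, config$max_min_iters, free)
  .structure_from_sys(ptr, s)
}

#' Cyclic repack-and-minimize relaxation
#'
#' For each of `n_cycles` cycles, for each stage of `rep_schedule`:
#' set the repulsive weight (and the restraint weight, if ramping),
#' repack, then minimize.  The final stage of the final cycle runs at
#' full repulsive weight.  Deterministic given the seed.
#'
#' @param s A cleaned `scaffold` structure.
#' @param restraints Optional `restraint_set` anchored to `s`.
#' @param config A [relax_config()].
#' @param weights Base [energy_weights()]; `w_rep` is overridden by the
#'   schedule stage by stage.
#' @return A `relax_result`: list with the refined structure (`final`),
#'   the per-stage `trajectory` (cycle, stage, weights, objective and
#'   unrestrained total), `final_score` (standard weights, no
#'   restraints), `rmsd_to_input` (all heavy atoms) and `seed`.
#' @export
fast_relax <- function(s, restraints = NULL, config = relax_config(),
                       weights = energy_weights()) {
  .ensure_cleaned(s)
  ptr <- .sys_from_structure(s, weights, restraints)
  n_stage <- length(config$rep_schedule)
  traj <- vector("list", config$n_cycles * n_stage)
  counter <- 0L
  for (cyc in seq_len(config$n_cycles)) {
    for (st in seq_len(n_stage)) {
      counter <- counter + 1L
      w_rep <- config$rep_schedule[st]
      w_cst <- if (config$ramp_constraints) {
        config$restraint_schedule[st]
      } else {
        1.0
      }
      .sys_set_weights(
        ptr, w_rep, weights$w_atr, weights$w_rot, weights$w_cst,
        identical(weights$rep_mode, "soft")
      )
      if (!is.null(restraints)) {
        .sys_set_cst_weight(ptr, restraints$weight * w_cst)
      }
      .pack_sys(
        ptr, .n_res(s), .stage_seed(config$seed, counter),
        config$flip_hnq, config$extra_rotamers
      )
      .minimize_sys(ptr, config$min_tolerance, config$max_min_iters)
      sc <- .sys_score(ptr)
      traj[[counter]] <- data.frame(
        cycle = cyc, stage = st, w_rep = w_rep, w_cst = w_cst,
        objective = sc$total,
        total = sc$total - sc$terms[["cst"]]
      )
    }
  }
  final <- .structure_from_sys(ptr, s)
  final_score <- score(final, energy_weights(
    w_rep = 1, w_atr = weights$w_atr, w_rot = weights$w_rot
  ))
  structure(
    list(
      final = final,
      trajectory = do.call(rbind, traj),
      final_score = final_score,
      rmsd_to_input = rmsd_all_atom(s, final),
      seed = config$seed
    ),
    class = "relax_result"
  )
}

#' @export
print.relax_result <- function(x, ...) {
  cat(sprintf(
    "<relax_result> final %.3f units (%.3f / residue), rmsd to input %.3f A\n",
    x$final_score$total, x$final_score$per_residue_mean, x$rmsd_to_input
  ))
  invisible(x)
}

#' Replicated relax runs with a convergence summary
#'
#' Runs [fast_relax()] once per seed and summarizes the replicate
#' distribution: the median per-residue energy and median RMSD to the
#' input, plus the ranges (max - min) of both.
#'
#' @param s A cleaned `scaffold` structure.
#' @param restraints Optional `restraint_set`.
#' @param config A [relax_config()]; its seed is ignored in favor of
#'   `seeds`.
#' @param seeds Distinct integer seeds, one per replicate.
#' @param weights Base [energy_weights()].
#' @return A list with `results` (one `relax_result` per seed) and
#'   `summary` (median/range of per-residue energy and RMSD).
#' @export
relax_replicates <- function(s, restraints = NULL, config = relax_config(),
                             seeds = 1:10, weights = energy_weights()) {
  if (length(seeds) < 1) stop("at least one seed required")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  results <- lapply(seeds, function(sd) {
    cfg <- config
    cfg$seed <- as.integer(sd)
    fast_relax(s, restraints, cfg, weights)
  })
  e <- vapply(results, function(r) r$final_score$per_residue_mean, 0)
  r <- vapply(results, function(r) r$rmsd_to_input, 0)
  list(
    results = results,
    summary = list(
      median_energy_per_residue = stats::median(e),
      median_rmsd = stats::median(r),
      energy_range = max(e) - min(e),
      rmsd_range = max(r) - min(r),
      n = length(seeds)
    )
  )
}
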