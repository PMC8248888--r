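#' Scenario specification for synthetic P1 crystals
#'
#' Defines the study conditions of a synthetic point-atom crystal of one
#' of the three scatterer classes: `"weak"` (C/N/O only), `"medium"` (S
#' sites among light atoms) and `"strong"` (Fe/Zn sites present).  By
#' default the cubic cell edge is derived from crystal-like packing,
#' `vol_per_atom = 20` Angstrom^3 per non-H atom, which keeps the
#' volume-per-atom invariant (8-30 A^3) that real close-packed
#' structures obey and that the algorithm's operating thresholds were
#' characterized on.
#'
#' @param class_tag `"weak"`, `"medium"` or `"strong"`.
#' @param n_atoms Number of point atoms (default 30 weak / 60 medium /
#'   60 strong).
#' @param heavy_fraction Fraction of heavy sites for the medium (S) and
#'   strong (Fe/Zn) classes; at least one heavy site is always placed.
#' @param vol_per_atom Cell volume per atom in Angstrom^3; must lie in
#'   [8, 30] (crystal-like packing).
#' @param cell Optional [unit_cell()]; overrides `vol_per_atom`, but
#'   must still satisfy the packing invariant.
#' @param d_min Resolution limit (Angstrom); atomic resolution
#'   (<= 1.2 A) is assumed by the phasing residual.
#' @param min_dist Minimum periodic interatomic distance (Angstrom).
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(class_tag = c("weak", "medium", "strong"),
                          n_atoms = NULL, heavy_fraction = NULL,
                          vol_per_atom = 20, cell = NULL,
                          d_min = 1.0, min_dist = 1.5, seed = 1) {
  class_tag <- match.arg(class_tag)
  if (is.null(n_atoms)) n_atoms <- switch(class_tag, weak = 30L, 60L)
  if (is.null(heavy_fraction))
    heavy_fraction <- switch(class_tag, weak = 0, medium = 0.04, strong = 0.03)
  stopifnot(n_atoms >= 2, min_dist > 0, d_min > 0)
  if (is.null(cell)) {
    edge <- (n_atoms * vol_per_atom)^(1 / 3)
    cell <- unit_cell(edge, edge, edge)
  }
  vpa <- cell$volume / n_atoms
  if (vpa < 8 || vpa > 30)
    stop(sprintf(paste0("cell volume per atom is %.1f A^3; crystal-like ",
                        "packing requires 8-30 A^3 (adjust cell or n_atoms)"),
                 vpa), call. = FALSE)
  structure(list(class_tag = class_tag, n_atoms = as.integer(n_atoms),
                 heavy_fraction = heavy_fraction, cell = cell,
                 d_min = d_min, min_dist = min_dist,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate a ground-truth structure from a scenario
#'
#' Places atoms by rejection sampling with a periodic minimum-distance
#' constraint.  Weights: weak sites draw Z from \{6, 7, 8\} (C/N/O in
#' 2:1:1 proportion); the medium class adds S (Z = 16) sites and the
#' strong class Fe or Zn (Z = 26 / 30) sites, heavy sites first.
#'
#' @param spec A [scenario_spec()].
#' @return A [crystal_structure()], reproducible from `spec$seed`.
#' @export
generate_structure <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_atoms
  n_heavy <- if (spec$heavy_fraction > 0)
    max(1L, round(spec$heavy_fraction * n)) else 0L
  withr_seed(spec$seed, {
    w <- sample(c(6, 7, 8), n, replace = TRUE, prob = c(0.5, 0.25, 0.25))
    if (n_heavy > 0) {
      heavy_z <- switch(spec$class_tag,
                        medium = rep(16, n_heavy),
                        strong = sample(c(26, 30), n_heavy, replace = TRUE),
                        stop("weak class has no heavy sites"))
      w[seq_len(n_heavy)] <- heavy_z
    }
    sites <- matrix(NA_real_, n, 3)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 20000L * n
    while (placed < n) {
      p <- stats::runif(3)
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("packing infeasible: could not place ", n, " atoms at min_dist = ",
             spec$min_dist, " A; use a larger cell", call. = FALSE)
      if (placed == 0L ||
          min(periodic_distance(spec$cell, p, sites[seq_len(placed), , drop = FALSE])) >=
            spec$min_dist) {
        placed <- placed + 1L
        sites[placed, ] <- p
      }
    }
    crystal_structure(spec$cell, tibble::tibble(
      x = sites[, 1], y = sites[, 2], z = sites[, 3], w = w,
      label = guess_element(w)))
  })
}

#' Exact |E| dataset from a ground-truth structure
#'
#' Computes structure factors for the full Friedel-unique shell to
#' `d_min` by direct summation, normalizes to point-atom |E| values and
#' splits the result into the blinded engine input (no phase column) and
#' the ground truth (true phases plus the structure), which is consumed
#' only by validation.
#'
#' @param structure A [crystal_structure()].
#' @param d_min Resolution limit in Angstrom (atomic resolution,
#'   <= 1.2 A recommended).
#' @return List with `reflections` (tibble `h`, `k`, `l`, `E`, carrying
#'   attributes `cell`, `d_min`, `mean_E`) and `truth` (list with
#'   `phases` in radians and `structure`).
#' @export
make_dataset <- function(structure, d_min = 1.0) {
  stopifnot(is_crystal_structure(structure))
  idx <- hkl_shell(structure$cell, d_min)
  if (nrow(idx) < 10)
    stop("fewer than 10 reflections; lower d_min or enlarge the cell",
         call. = FALSE)
  f <- direct_structure_factors(structure, idx)
  refl <- tibble::tibble(h = idx[, 1], k = idx[, 2], l = idx[, 3],
                         E = normalize_to_E(f, structure$sites$w))
  attr(refl, "cell") <- structure$cell
  attr(refl, "d_min") <- d_min
  attr(refl, "mean_E") <- mean(refl$E)
  list(reflections = refl,
       truth = list(phases = Arg(f), structure = structure))
}

#' Optional Gaussian perturbation of |E| moduli
#'
#' Multiplies every modulus by `1 + N(0, rel_sd)` (clamped at zero) to
#' emulate measurement scatter for robustness tests; the default
#' synthetic data are exact.
#'
#' @param reflections Reflection tibble.
#' @param rel_sd Relative standard deviation.
#' @param seed Integer seed.
#' @return The perturbed tibble (attributes preserved, `mean_E`
#'   recomputed).
#' @export
perturb_moduli <- function(reflections, rel_sd, seed = 1) {
  stopifnot(rel_sd >= 0)
  E <- withr_seed(seed,
                  pmax(0, reflections$E * (1 + stats::rnorm(nrow(reflections), 0, rel_sd))))
  out <- reflections
  out$E <- E
  attr(out, "mean_E") <- mean(E)
  out
}

#' Expected atom count passed to the engine
#'
#' The peak-preservation count N used by the ipp procedure is the
#' expected number of non-H atoms including solvent.  For synthetic
#' crystals (which have no solvent) the generated atom count is expanded
#' by the empirical solvent factor so the engine operates exactly as it
#' would on deposited data, where N is protein plus water atoms.
#'
#' @param n_atoms Generated atom count.
#' @param factor Expansion factor; defaults to 1.22, the survey average
#'   of (protein + water) / protein atoms (see
#'   [solvent_expansion_factor()]).
#' @return Integer N.
#' @export
expected_atom_count <- function(n_atoms, factor = 1.22) {
  as.integer(round(n_atoms * factor))
}
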