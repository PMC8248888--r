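#' Align a phase set to the ground truth and score it
#'
#' In P1 every origin choice and either enantiomorph is an equally valid
#' solution, so a trial can only be scored after searching all origin
#' shifts and the phase-conjugated (inverted) solution.  The correlation
#' between the test E-map and the true E-map as a function of the shift
#' u is obtained in a single product transform: with T_K = |E| exp(i
#' phi_test) and U_K = |E| exp(i phi_true), the overlap at shift u is
#' the synthesis of T_K Conj(U_K) evaluated at u, normalized by the map
#' norms (Parseval).  The search is voxel-quantized; no sub-voxel
#' refinement is applied.
#'
#' @param test_phases,true_phases Phases (radians) on the same
#'   Friedel-unique reflection set.
#' @param e_moduli The |E| amplitudes of that set.
#' @param indices Integer n x 3 Miller indices.
#' @param dims Grid dimensions for the shift search.
#' @param cell A [unit_cell()].
#' @return An `alignment_result` list: `best_cc` in [-1, 1], `best_shift`
#'   (fractional u*, components in [0, 1)), `inverted` flag, and
#'   `mean_phase_error` in degrees after alignment.
#' @export
align_and_score <- function(test_phases, true_phases, e_moduli, indices,
                            dims, cell) {
  if (is.null(dim(indices))) indices <- matrix(indices, ncol = 3)
  stopifnot(length(test_phases) == nrow(indices),
            length(true_phases) == nrow(indices),
            length(e_moduli) == nrow(indices))
  denom <- 2 * sum(e_moduli^2)           # full-sphere squared norm (both maps)
  best <- list(cc = -Inf, shift = c(0, 0, 0), inverted = FALSE)
  for (inverted in c(FALSE, TRUE)) {
    pt <- if (inverted) -test_phases else test_phases
    prod_coeff <- (e_moduli * exp(1i * pt)) * (e_moduli * exp(-1i * true_phases))
    overlap <- grid_synthesize(prod_coeff, indices, dims, cell)$values *
      cell$volume                         # 2 * Re(sum_unique P_K e(-2pi K.u))
    m <- which.max(overlap)
    cc <- overlap[m] / denom
    if (cc > best$cc) {
      d <- dims
      i <- (m - 1) %% d[1]
      j <- ((m - 1) %/% d[1]) %% d[2]
      k <- (m - 1) %/% (d[1] * d[2])
      best <- list(cc = cc, shift = c(i / d[1], j / d[2], k / d[3]),
                   inverted = inverted)
    }
  }
  aligned <- if (best$inverted) -test_phases else test_phases
  aligned <- aligned - 2 * pi * as.vector(indices %*% best$shift)
  dphi <- (aligned - true_phases + pi) %% (2 * pi) - pi
  structure(list(best_cc = best$cc, best_shift = best$shift,
                 inverted = best$inverted,
                 mean_phase_error = mean(abs(dphi)) * 180 / pi),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> best CC=%.3f at u*=(%.3f,%.3f,%.3f)%s, <|dphi|>=%.1f deg\n",
              x$best_cc, x$best_shift[1], x$best_shift[2], x$best_shift[3],
              if (x$inverted) " (enantiomorph)" else "", x$mean_phase_error))
  invisible(x)
}

#' Classify a trial as a correct solution
#'
#' @param alignment An [align_and_score()] result.
#' @param cc_threshold Aligned-map correlation threshold in (0, 1);
#'   default 0.7 (converged refinements sit well above it, incorrect
#'   ones well below).
#' @return Logical success flag.
#' @export
classify_success <- function(alignment, cc_threshold = 0.7) {
  stopifnot(cc_threshold > 0, cc_threshold < 1)
  alignment$best_cc >= cc_threshold
}

#' Count map peaks above a sigma threshold
#'
#' Applies the 26-neighbour peak search at threshold `n_sigma * sigma`
#' to a map (typically the final E-map of a trial) and returns the peak
#' count, the N_p diagnostic.
#'
#' @param grid A [real_grid()].
#' @param n_sigma Positive sigma multiple.
#' @return Integer peak count.
#' @export
count_peaks_above <- function(grid, n_sigma) {
  nrow(find_peaks(grid, n_sigma))
}

#' Final E-map of a phase set
#'
#' Synthesis with coefficients |E| exp(i phi); at atomic resolution its
#' peaks mark atom positions.
#'
#' @param reflections Reflection tibble with `cell` / `d_min` attributes.
#' @param phases Phases (radians).
#' @param oversample Grid sampling factor.
#' @return A [real_grid()].
#' @export
e_map <- function(reflections, phases, oversample = 3) {
  cell <- attr(reflections, "cell")
  dims <- choose_dims(cell, attr(reflections, "d_min"), oversample)
  grid_synthesize(reflections$E * exp(1i * phases),
                  as.matrix(reflections[, c("h", "k", "l")]),
                  dims, cell, role = "map")
}
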