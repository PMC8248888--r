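#' Structure factors by direct summation
#'
#' Computes complex structure factors F_K = sum_j w_j exp(+2 pi i K.x_j)
#' for point atoms, the brute-force Fourier oracle behind every map
#' synthesis in the package.  Friedel symmetry F_-K = Conj(F_K) holds
#' exactly by construction.
#'
#' @param structure A [crystal_structure()].
#' @param indices Integer n x 3 matrix of Miller indices (or a length-3
#'   vector for a single reflection).
#' @return Complex vector of n structure factors.
#' @export
direct_structure_factors <- function(structure, indices) {
  stopifnot(is_crystal_structure(structure))
  if (nrow(structure$sites) == 0) stop("no atoms", call. = FALSE)
  if (is.null(dim(indices))) indices <- matrix(indices, ncol = 3)
  xyz <- as.matrix(structure$sites[, c("x", "y", "z")])
  ph <- 2 * pi * (indices %*% t(xyz))      # n_ref x n_atom phase angles
  as.vector((cos(ph) + 1i * sin(ph)) %*% structure$sites$w)
}

#' Normalize structure-factor amplitudes to |E| values
#'
#' Point-atom normalization: |E_K| = |F_K| / sqrt(sum_j w_j^2).  For equal
#' point atoms at random positions this gives the Wilson limit
#' mean(|E|^2) -> 1; no resolution-dependent scaling is applied because
#' point-atom data are sharp by construction.
#'
#' @param f Complex (or numeric) structure-factor amplitudes.
#' @param weights The scattering weights of the generating structure.
#' @return Numeric vector of |E| moduli.
#' @export
normalize_to_E <- function(f, weights) {
  s <- sum(weights^2)
  if (s <= 0) stop("all-zero weights", call. = FALSE)
  Mod(f) / sqrt(s)
}

#' Friedel-unique reflections to a resolution limit
#'
#' Enumerates one member of each Friedel pair \{K, -K\} with
#' d(K) >= d_min, excluding (0,0,0).  The canonical hemisphere keeps the
#' index whose first nonzero component is positive; rows are ordered
#' lexicographically by (h, k, l).
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom (> 0).
#' @return Integer matrix with columns h, k, l, one Friedel-unique
#'   reflection per row.  Empty (with a warning) if d_min exceeds the
#'   largest d-spacing.
#' @export
hkl_shell <- function(cell, d_min) {
  stopifnot(is_unit_cell(cell), d_min > 0)
  # |h| <= a/d holds for any cell: h is the projection of the reciprocal
  # vector (length 1/d) onto the direct axis a.
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  g <- as.matrix(expand.grid(l = -lmax:lmax, k = -kmax:kmax, h = -hmax:hmax))
  g <- g[, c("h", "k", "l"), drop = FALSE]
  nonzero <- rowSums(g != 0) > 0
  g <- g[nonzero, , drop = FALSE]
  g <- g[d_spacing(cell, g) >= d_min, , drop = FALSE]
  hemi <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g <- g[hemi, , drop = FALSE]
  if (nrow(g) == 0) {
    warning("no reflections: d_min exceeds the largest d-spacing")
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("h", "k", "l"))))
  }
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  rownames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}
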