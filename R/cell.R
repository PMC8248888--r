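#' Triclinic unit cell
#'
#' Constructs a unit cell from edge lengths (Angstrom) and angles (degrees)
#' and precomputes the direct metric tensor, its inverse (the reciprocal
#' metric tensor) and the cell volume.  All d-spacing and distance
#' calculations in the package go through the metric tensors, so general
#' triclinic cells are supported everywhere.
#'
#' @param a,b,c Cell edges in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#'   Default 90 (orthogonal cell).
#' @return An object of class `unit_cell`: a list with elements `a`, `b`,
#'   `c`, `alpha`, `beta`, `gamma`, `volume` (Angstrom^3), `metric` (3x3
#'   direct metric tensor G) and `metric_inv` (reciprocal metric tensor
#'   G*), such that `1/d^2 = t(K) %*% G* %*% K` for a Miller index K.
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' cell$volume
#' d_spacing(cell, c(1, 0, 0))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  edges  <- c(a = a, b = b, c = c)
  angles <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(edges)) || any(edges <= 0))
    stop("cell edges must be positive and finite", call. = FALSE)
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles >= 180))
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta  * pi / 180)
  cg <- cos(gamma * pi / 180)
  G <- matrix(c(a * a,      a * b * cg, a * c * cb,
                a * b * cg, b * b,      b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  detG <- det(G)
  if (detG <= 0)
    stop("degenerate cell: metric tensor is not positive definite", call. = FALSE)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         volume = sqrt(detG), metric = G, metric_inv = solve(G)),
    class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4g b=%.4g c=%.4g A  alpha=%.4g beta=%.4g gamma=%.4g deg  V=%.4g A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

#' Lattice-plane spacing of Miller indices
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector of length 3, or an n x 3 matrix of Miller
#'   indices (one row per reflection).
#' @return d-spacings in Angstrom (Inf for the zero index).
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(is_unit_cell(cell))
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  q <- rowSums((hkl %*% cell$metric_inv) * hkl)  # 1/d^2
  ifelse(q > 0, 1 / sqrt(q), Inf)
}

#' Minimum-image distance between fractional coordinates
#'
#' Periodic (minimum-image) distance in Angstrom between a point and a set
#' of points, both in fractional coordinates.  Exact for orthogonal cells;
#' for oblique cells the 27 neighbouring lattice translations are scanned.
#'
#' @param cell A [unit_cell()].
#' @param x Fractional coordinate, length 3.
#' @param pts Matrix (n x 3) of fractional coordinates.
#' @return Numeric vector of n distances.
#' @export
periodic_distance <- function(cell, x, pts) {
  stopifnot(is_unit_cell(cell))
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  d <- sweep(pts, 2, x)
  d <- d - round(d)                       # minimum image in fractional space
  if (cell$alpha == 90 && cell$beta == 90 && cell$gamma == 90) {
    sqrt(rowSums(sweep(d, 2, c(cell$a, cell$b, cell$c), `*`)^2))
  } else {
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    best <- rep(Inf, nrow(d))
    for (s in seq_len(nrow(shifts))) {
      ds <- sweep(d, 2, shifts[s, ], `+`)
      best <- pmin(best, rowSums((ds %*% cell$metric) * ds))
    }
    sqrt(best)
  }
}
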