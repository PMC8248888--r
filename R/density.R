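#' Root-mean-square value of a grid
#'
#' The sigma used by every threshold in the algorithm.  It is the RMS
#' about zero, not about the grid mean: all syntheses exclude F(000) and
#' are therefore zero-mean by construction, and fixing the definition
#' makes the `t * sigma` thresholds reproducible.
#'
#' @param grid A [real_grid()] or bare numeric array.
#' @return A list with `sigma` (RMS) and `n_voxels`.
#' @export
grid_sigma <- function(grid) {
  v <- if (is_real_grid(grid)) grid$values else grid
  list(sigma = sqrt(mean(v^2)), n_voxels = length(v))
}

#' Three-valued sign mask of a density
#'
#' Per voxel: +1 where rho > 0; 0 in the shallow-negative band
#' -t_rho*sigma_rho <= rho <= 0; -1 where rho < -t_rho*sigma_rho.
#' Boundaries (rho exactly 0 or exactly -t_rho*sigma_rho) belong to the
#' band.  Multiplying the mask into rho yields |rho|: positive density is
#' kept, deep negative density is flipped, and the shallow band is
#' flattened to zero.
#'
#' @param rho A [real_grid()] holding the current density.
#' @param t_rho Positive threshold factor.  Recommended defaults by
#'   scatterer class: 2.5 (weak), 2.6 (medium), 2.8 (strong).
#' @return A [real_grid()] with role `"mask"` and values in \{-1, 0, +1\}.
#' @export
m_rho_mask <- function(rho, t_rho) {
  stopifnot(is_real_grid(rho), t_rho > 0)
  sig <- grid_sigma(rho)$sigma
  if (sig == 0) stop("flat map", call. = FALSE)
  v <- rho$values
  m <- array(0, dim(v))
  m[v > 0] <- 1
  m[v < -t_rho * sig] <- -1
  real_grid(m, rho$cell, "mask")
}

#' Default mask threshold for a scatterer class
#'
#' @param class_tag `"weak"`, `"medium"` or `"strong"`.
#' @return 2.5, 2.6 or 2.8 respectively.
#' @export
default_t_rho <- function(class_tag) {
  switch(class_tag, weak = 2.5, medium = 2.6, strong = 2.8,
         stop("unknown scatterer class: ", class_tag, call. = FALSE))
}

#' |rho| from a density and its mask
#'
#' Pointwise product `mask * rho`; every output voxel is >= 0 and band
#' voxels are exactly zero.
#'
#' @param rho,mask [real_grid()]s of identical dimensions (mask from
#'   [m_rho_mask()]).
#' @return A [real_grid()] with role `"abs_rho"`.
#' @export
abs_rho <- function(rho, mask) {
  stopifnot(is_real_grid(rho), is_real_grid(mask))
  if (!identical(rho$dims, mask$dims)) stop("dim mismatch", call. = FALSE)
  real_grid(rho$values * mask$values, rho$cell, "abs_rho")
}

#' Density synthesis from |E| moduli and current phases
#'
#' Synthesizes rho with coefficients |E_K| exp(i phi_K) restricted to
#' reflections with |E_K| >= E_min.  The plain S_M variant uses
#' E_min = 0 (all reflections); the ipp variant works better with
#' E_min of about 1.0, i.e. only large and moderate |E| participate.
#'
#' @param reflections Reflection tibble with columns `h`, `k`, `l`, `E`
#'   (see [read_reflections()] / [make_dataset()]).
#' @param phases Numeric vector of phases (radians), one per reflection.
#' @param e_min Modulus cutoff (>= 0).
#' @param dims Grid dimensions.
#' @param cell A [unit_cell()].
#' @return A [real_grid()] with role `"rho"`.
#' @export
rho_synthesis <- function(reflections, phases, e_min, dims, cell) {
  stopifnot(e_min >= 0, length(phases) == nrow(reflections))
  keep <- reflections$E >= e_min
  if (!any(keep)) stop("no reflection survives the |E| cutoff", call. = FALSE)
  grid_synthesize(reflections$E[keep] * exp(1i * phases[keep]),
                  as.matrix(reflections[keep, c("h", "k", "l")]),
                  dims, cell, role = "rho")
}

#' Origin-free difference synthesis delta_M
#'
#' Synthesizes delta with coefficients (|E_K| - <|E|>) exp(i alpha_K)
#' over ALL reflections in the set; <|E|> is the arithmetic mean modulus
#' of the working set, fixed at load time.  With all alpha = 0 this is
#' the origin-free modulus synthesis M, a Patterson-type function.
#'
#' @param reflections Reflection tibble (columns `h`, `k`, `l`, `E`).
#' @param alphas Phases (radians), one per reflection.
#' @param dims Grid dimensions.
#' @param cell A [unit_cell()].
#' @param mean_E Mean modulus; defaults to the `mean_E` attribute of the
#'   reflection set, falling back to `mean(reflections$E)`.
#' @return A [real_grid()] with role `"delta"`, zero-mean.
#' @export
delta_synthesis <- function(reflections, alphas, dims, cell, mean_E = NULL) {
  stopifnot(length(alphas) == nrow(reflections))
  if (is.null(mean_E)) mean_E <- attr(reflections, "mean_E") %||% mean(reflections$E)
  grid_synthesize((reflections$E - mean_E) * exp(1i * alphas),
                  as.matrix(reflections[, c("h", "k", "l")]),
                  dims, cell, role = "delta")
}

#' eta product function
#'
#' Pointwise product of the difference synthesis delta_M and the stored
#' sign mask m_rho.  This is the map that is density-modified (see
#' [preserve_inner_pixels()]) and Fourier-inverted to update phases.
#'
#' @param delta,mask [real_grid()]s with identical dimensions.
#' @return A [real_grid()] with role `"eta"`.
#' @export
eta_product <- function(delta, mask) {
  stopifnot(is_real_grid(delta), is_real_grid(mask))
  if (!identical(delta$dims, mask$dims)) stop("dim mismatch", call. = FALSE)
  real_grid(delta$values * mask$values, delta$cell, "eta")
}

#' Modulus-function correlation CC_M
#'
#' Correlation between the experimental and calculated modulus
#' functions: the normalized inner product (cosine similarity) of the
#' origin-free experimental coefficients \{|E_K| - <|E|>\} with the
#' calculated amplitudes \{|C_K|\} of the |rho| transform, over all
#' reflections.  By Parseval this is, up to the out-of-band variance of
#' |rho|, the map correlation between delta_M and |rho|, which makes
#' maximizing CC_M equivalent to minimizing the phasing residual R_M
#' (the sum of the squared experimental coefficients is fixed, so R_M
#' decreases exactly when the inner product grows).  Scale-free, in
#' [-1, 1]; its sudden jump (typically a few hundredths in a few
#' cycles) signals convergence of a phase refinement.
#'
#' @param e_moduli Experimental |E| values.
#' @param mean_E Their working-set mean.
#' @param c_amplitudes Calculated |C| amplitudes, same ordering.
#' @return A single correlation value.
#' @export
cc_m <- function(e_moduli, mean_E, c_amplitudes) {
  x <- e_moduli - mean_E
  y <- c_amplitudes
  if (sum(x^2) == 0 || sum(y^2) == 0)
    stop("zero-variance input to CC_M", call. = FALSE)
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Phasing residual R_M (diagnostic)
#'
#' Least-squares discrepancy between delta_M and |rho|:
#' k = sum(delta*|rho|) / sum(|rho|^2), residual = sum((delta - k|rho|)^2)
#' over voxels.  Reported for diagnostics only; iteration is driven by
#' the phase update, and minimizing R_M is equivalent to maximizing the
#' modulus correlation.
#'
#' @param delta,absrho [real_grid()]s with identical dimensions;
#'   `absrho` must not be identically zero.
#' @return List with `residual` and scale constant `k`.
#' @export
r_m_residual <- function(delta, absrho) {
  stopifnot(is_real_grid(delta), is_real_grid(absrho))
  if (!identical(delta$dims, absrho$dims)) stop("dim mismatch", call. = FALSE)
  a <- absrho$values
  d <- delta$values
  ss <- sum(a^2)
  if (ss == 0) stop("|rho| is identically zero", call. = FALSE)
  k <- sum(d * a) / ss
  list(residual = sum((d - k * a)^2), k = k)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
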