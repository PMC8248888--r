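#' Periodic real-space grid over the unit cell
#'
#' Thin S3 wrapper around a 3-D numeric array sampling a periodic scalar
#' field over the cell.  Voxel (0,0,0) sits at fractional (0,0,0) and voxel
#' centres are at i/n (0-based indices, periodic wrap along every axis).
#'
#' @param values 3-D numeric array.
#' @param cell A [unit_cell()].
#' @param role Character tag naming what the field is: one of
#'   `"rho"`, `"abs_rho"`, `"delta"`, `"eta"`, `"modulus"`, `"mask"`,
#'   `"map"`.
#' @return A `real_grid` object.
#' @export
real_grid <- function(values, cell, role = "map") {
  stopifnot(is.array(values), length(dim(values)) == 3, is_unit_cell(cell))
  structure(list(values = values, dims = dim(values), cell = cell, role = role),
            class = "real_grid")
}

#' @export
print.real_grid <- function(x, ...) {
  cat(sprintf("<real_grid:%s> %d x %d x %d voxels, sigma=%.4g\n",
              x$role, x$dims[1], x$dims[2], x$dims[3],
              sqrt(mean(x$values^2))))
  invisible(x)
}

is_real_grid <- function(x) inherits(x, "real_grid")

#' FFT-friendly grid dimensions for a resolution limit
#'
#' Each dimension is the smallest integer at least `oversample *
#' (edge / d_min)` whose prime factors are all <= 5, so the FFT stays
#' fast.  `oversample = 3` (the default) gives smooth, well-separated
#' peaks for the 26-neighbour peak search; 2 is the floor for pure
#' transform work.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom.
#' @param oversample Sampling factor (>= 2).
#' @return Integer vector of three dimensions.
#' @export
choose_dims <- function(cell, d_min, oversample = 3) {
  stopifnot(is_unit_cell(cell), d_min > 0)
  if (oversample < 2) stop("oversample must be >= 2", call. = FALSE)
  vapply(c(cell$a, cell$b, cell$c), function(edge) {
    next_smooth(as.integer(ceiling(oversample * edge / d_min)))
  }, integer(1))
}

next_smooth <- function(n) {
  n <- max(n, 2L)
  while (!is_5_smooth(n)) n <- n + 1L
  n
}

is_5_smooth <- function(n) {
  for (p in c(2L, 3L, 5L)) while (n %% p == 0L) n <- n %/% p
  n == 1L
}

check_aliasing <- function(indices, dims) {
  for (ax in 1:3) {
    bad <- which(2L * abs(indices[, ax]) + 1L > dims[ax])
    if (length(bad) > 0)
      stop(sprintf("aliasing: index (%d,%d,%d) does not fit dims (%d,%d,%d)",
                   indices[bad[1], 1], indices[bad[1], 2], indices[bad[1], 3],
                   dims[1], dims[2], dims[3]), call. = FALSE)
  }
  invisible(TRUE)
}

# Linear positions (1-based) of +K and -K inside a dims-shaped array.
hkl_linear_index <- function(indices, dims) {
  pos <- function(M) {
    i1 <- M[, 1] %% dims[1]
    i2 <- M[, 2] %% dims[2]
    i3 <- M[, 3] %% dims[3]
    as.integer(1L + i1 + dims[1] * (i2 + dims[2] * i3))
  }
  list(plus = pos(indices), minus = pos(-indices))
}

#' Fourier synthesis: reflection coefficients to a real grid
#'
#' Evaluates `grid(x) = (1/V) * sum over the full sphere of
#' c_K exp(-2 pi i K.x)` at every voxel, expanding the Friedel-unique
#' input to the full sphere by conjugation.  (0,0,0) is never among the
#' indices, so every synthesized map has zero mean.
#'
#' @param coeff Complex vector of coefficients c_K, one per row of
#'   `indices`.  A coefficient may have any modulus and phase; negative
#'   "amplitudes" are simply coefficients with a phase shift of pi.
#' @param indices Friedel-unique integer n x 3 Miller indices.
#' @param dims Grid dimensions (see [choose_dims()]); every index must
#'   satisfy `2*|h|+1 <= dim` on its axis, otherwise an error names the
#'   offending index.
#' @param cell A [unit_cell()].
#' @param role Role tag for the returned grid.
#' @return A [real_grid()] with real values (the imaginary residue of the
#'   inverse transform is checked to be negligible).
#' @export
grid_synthesize <- function(coeff, indices, dims, cell, role = "map") {
  if (is.null(dim(indices))) indices <- matrix(indices, ncol = 3)
  stopifnot(length(coeff) == nrow(indices))
  check_aliasing(indices, dims)
  arr <- array(0i, dims)
  if (length(coeff) > 0) {
    li <- hkl_linear_index(indices, dims)
    arr[li$plus]  <- coeff
    arr[li$minus] <- Conj(coeff)
  }
  g <- stats::fft(arr) / cell$volume
  re <- Re(g)
  mx <- max(abs(re))
  if (mx > 0 && max(abs(Im(g))) > 1e-8 * mx)
    stop("synthesis produced a non-real grid; coefficients are not Hermitian")
  real_grid(array(re, dims), cell, role)
}

#' Fourier analysis: real grid to reflection coefficients
#'
#' Inverse of [grid_synthesize()]: returns the complex coefficients c_K
#' at the requested Friedel-unique indices, scaled so that
#' analyze(synthesize(c)) recovers c for all in-band coefficients.
#'
#' @param grid A [real_grid()].
#' @param indices Friedel-unique integer n x 3 Miller indices within the
#'   aliasing bound of the grid.
#' @return Complex vector of coefficients, one per index row.
#' @export
grid_analyze <- function(grid, indices) {
  stopifnot(is_real_grid(grid))
  if (is.null(dim(indices))) indices <- matrix(indices, ncol = 3)
  check_aliasing(indices, grid$dims)
  ft <- stats::fft(grid$values, inverse = TRUE) * (grid$cell$volume / prod(grid$dims))
  li <- hkl_linear_index(indices, grid$dims)
  ft[li$plus]
}

#' Write a grid as a CCP4/MRC map (mode 2)
#'
#' Binary export for inspection in standard map viewers; import of
#' arbitrary maps is not supported.
#'
#' @param grid A [real_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccp4_map <- function(grid, path) {
  stopifnot(is_real_grid(grid))
  con <- file(path, "wb")
  on.exit(close(con))
  d <- grid$dims
  v <- grid$values
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # NC NR NS
  wi(2)                      # MODE 2 = float32
  wi(c(0, 0, 0))             # start
  wi(d)                      # intervals
  wf(c(grid$cell$a, grid$cell$b, grid$cell$c,
       grid$cell$alpha, grid$cell$beta, grid$cell$gamma))
  wi(c(1, 2, 3))             # axis order
  wf(c(min(v), max(v), mean(v)))
  wi(1)                      # ISPG = P1
  wi(0)                      # NSYMBT
  wi(rep(0, 25))             # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sqrt(mean((v - mean(v))^2)))
  wi(0)                      # NLABL
  writeBin(raw(800), con)    # labels
  wf(as.vector(v))
  invisible(path)
}
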