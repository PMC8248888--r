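#' Thresholded 26-neighbour peak search on a periodic grid
#'
#' A voxel is a peak when its value exceeds `t_eta * sigma_eta`
#' (sigma from [grid_sigma()]) and is strictly greater than all 26
#' nearest neighbours, with periodic wrap-around at the grid boundaries.
#' Strict inequality excludes plateaus; no interpolation is performed
#' anywhere (accurate peak centres are not needed downstream), so the
#' result carries voxel indices only.
#'
#' @param eta A [real_grid()] (typically the eta product function).
#' @param t_eta Positive threshold factor, normally 3.5-4.0.  t_eta and
#'   the peak count are inversely related.
#' @return A tibble of class `peak_list` with columns `rank`, `i`, `j`,
#'   `k` (0-based voxel indices), `value`, sorted by decreasing value
#'   (ties broken by lexicographic voxel index, smaller first), plus
#'   attributes `threshold`, `sigma` and `dims`.  The row count is
#'   N_eta.
#' @export
find_peaks <- function(eta, t_eta) {
  stopifnot(is_real_grid(eta), t_eta > 0)
  sig <- grid_sigma(eta)$sigma
  if (sig == 0) stop("flat product function", call. = FALSE)
  v <- eta$values
  d <- dim(v)
  thr <- t_eta * sig
  ok <- v > thr
  if (any(ok)) {
    perm <- lapply(d, function(n) list(`-1` = c(n, seq_len(n - 1L)),
                                       `0`  = seq_len(n),
                                       `1`  = c(seq.int(2L, n), 1L)))
    for (s1 in -1:1) for (s2 in -1:1) for (s3 in -1:1) {
      if (s1 == 0 && s2 == 0 && s3 == 0) next
      nb <- v[perm[[1]][[as.character(s1)]],
              perm[[2]][[as.character(s2)]],
              perm[[3]][[as.character(s3)]]]
      ok <- ok & (v > nb)
      if (!any(ok)) break
    }
  }
  lin <- which(ok)
  i <- (lin - 1L) %% d[1]
  j <- ((lin - 1L) %/% d[1]) %% d[2]
  k <- (lin - 1L) %/% (d[1] * d[2])
  val <- v[lin]
  ord <- order(-val, i, j, k)
  out <- tibble::tibble(rank = seq_along(ord),
                        i = as.integer(i[ord]), j = as.integer(j[ord]),
                        k = as.integer(k[ord]), value = val[ord])
  attr(out, "threshold") <- thr
  attr(out, "sigma") <- sig
  attr(out, "dims") <- d
  class(out) <- c("peak_list", class(out))
  out
}

#' Inner-pixel preservation (ipp) density modification
#'
#' Keeps the density values of the 27 inner-peak voxels (peak centre
#' plus its 26 periodic neighbours) of each of the `min(N, N_eta)`
#' highest-ranked peaks, and zeroes every other voxel.  Overlapping
#' neighbourhoods are the set union, so the nonzero-voxel count is at
#' most `27 * min(N, N_eta)`.  Applying the modification twice with the
#' same peaks changes nothing.
#'
#' @param eta A [real_grid()].
#' @param peaks A peak list from [find_peaks()] on the same grid.
#' @param n_keep The expected atom count N (>= 1): the number of peaks
#'   whose neighbourhoods are preserved when more than N are available.
#' @return The modified [real_grid()].  An empty peak list yields an
#'   all-zero grid with a warning (the engine treats that as a stalled
#'   trial).
#' @export
preserve_inner_pixels <- function(eta, peaks, n_keep) {
  stopifnot(is_real_grid(eta), n_keep >= 1)
  d <- eta$dims
  if (nrow(peaks) == 0) {
    warning("empty peak list: eta zeroed everywhere")
    return(real_grid(array(0, d), eta$cell, "eta"))
  }
  top <- peaks[seq_len(min(n_keep, nrow(peaks))), ]
  keep <- array(FALSE, d)
  off <- -1:1
  for (t in seq_len(nrow(top))) {
    keep[(top$i[t] + off) %% d[1] + 1L,
         (top$j[t] + off) %% d[2] + 1L,
         (top$k[t] + off) %% d[3] + 1L] <- TRUE
  }
  real_grid(eta$values * keep, eta$cell, "eta")
}

#' Q statistic for tuning the peak threshold
#'
#' Q = N_eta(2) / N, the peak count at the second iteration of a trial
#' over the expected atom count.  Suitable t_eta values give Q close to
#' (or not much below) 1; t_eta 3.5-4.0 typically maps to Q 1.5-0.7.
#'
#' @param n_eta_iter2 Peak count at iteration 2.
#' @param n_atoms Expected atom count N (> 0).
#' @return The ratio.
#' @export
q_statistic <- function(n_eta_iter2, n_atoms) {
  stopifnot(n_atoms > 0)
  n_eta_iter2 / n_atoms
}

#' Export a peak list as text or dummy-atom PDB records
#'
#' @param peaks A peak list from [find_peaks()].
#' @param path Output path.
#' @param cell A [unit_cell()] (required for `format = "pdb"`).
#' @param format `"table"` (rank, i, j, k, value/sigma) or `"pdb"`
#'   (dummy carbon atoms at voxel centres, for map inspection).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, cell = NULL, format = c("table", "pdb")) {
  format <- match.arg(format)
  if (format == "table") {
    sig <- attr(peaks, "sigma")
    utils::write.table(
      data.frame(rank = peaks$rank, i = peaks$i, j = peaks$j, k = peaks$k,
                 value_over_sigma = peaks$value / sig),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stopifnot(is_unit_cell(cell))
    d <- attr(peaks, "dims")
    frac <- cbind(peaks$i / d[1], peaks$j / d[2], peaks$k / d[3])
    st <- crystal_structure(cell, tibble::tibble(
      x = frac[, 1], y = frac[, 2], z = frac[, 3], w = 6, label = "C"))
    write_structure_pdb(st, path)
  }
  invisible(path)
}
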