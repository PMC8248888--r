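# Independent oracles, written against the definitions and kept free of the
# production code paths (no fft(), no shared index bookkeeping).

# Per-voxel direct summation of a Fourier synthesis over the full sphere.
# Triple loop over voxels; only usable for tiny grids.
oracle_direct_sum_map <- function(coeff, indices, dims, cell) {
  if (is.null(dim(indices))) indices <- matrix(indices, ncol = 3)
  idx_full <- rbind(indices, -indices)
  c_full <- c(coeff, Conj(coeff))
  out <- array(0, dims)
  for (i3 in seq_len(dims[3])) for (i2 in seq_len(dims[2])) for (i1 in seq_len(dims[1])) {
    x <- c((i1 - 1) / dims[1], (i2 - 1) / dims[2], (i3 - 1) / dims[3])
    ph <- -2 * pi * as.vector(idx_full %*% x)
    out[i1, i2, i3] <- Re(sum(c_full * complex(modulus = 1, argument = ph)))
  }
  out / cell$volume
}

# Direct summation reorganized as explicit DFT-matrix contractions along each
# axis (still the defining sum, evaluated exactly; no fft call).  Usable for
# the acceptance-scale grids.
oracle_dft_map <- function(coeff, indices, dims, cell) {
  if (is.null(dim(indices))) indices <- matrix(indices, ncol = 3)
  idx_full <- rbind(indices, -indices)
  c_full <- c(coeff, Conj(coeff))
  rng <- lapply(1:3, function(ax) {
    m <- max(abs(idx_full[, ax]))
    seq.int(-m, m)
  })
  B <- array(0i, vapply(rng, length, integer(1)))
  pos <- cbind(match(idx_full[, 1], rng[[1]]),
               match(idx_full[, 2], rng[[2]]),
               match(idx_full[, 3], rng[[3]]))
  B[pos] <- B[pos] + c_full
  dft <- function(n, hh) {
    jj <- seq_len(n) - 1
    exp(-2i * pi * outer(jj, hh) / n)
  }
  M1 <- dft(dims[1], rng[[1]]); M2 <- dft(dims[2], rng[[2]]); M3 <- dft(dims[3], rng[[3]])
  nh <- dim(B)
  s1 <- M1 %*% matrix(B, nh[1], nh[2] * nh[3])                    # n1 x (nh2*nh3)
  s1 <- array(s1, c(dims[1], nh[2], nh[3]))
  s2 <- M2 %*% matrix(aperm(s1, c(2, 1, 3)), nh[2], dims[1] * nh[3])
  s2 <- aperm(array(s2, c(dims[2], dims[1], nh[3])), c(2, 1, 3))  # n1 x n2 x nh3
  s3 <- M3 %*% matrix(aperm(s2, c(3, 1, 2)), nh[3], dims[1] * dims[2])
  s3 <- aperm(array(s3, c(dims[3], dims[1], dims[2])), c(2, 3, 1))
  Re(s3) / cell$volume
}

# Structure factors by an explicit double loop (reflection by reflection,
# atom by atom).
oracle_structure_factors <- function(structure, indices) {
  if (is.null(dim(indices))) indices <- matrix(indices, ncol = 3)
  xyz <- as.matrix(structure$sites[, c("x", "y", "z")])
  w <- structure$sites$w
  out <- complex(length.out = nrow(indices))
  for (r in seq_len(nrow(indices))) {
    acc <- 0i
    for (a in seq_len(nrow(xyz))) {
      phi <- 2 * pi * sum(indices[r, ] * xyz[a, ])
      acc <- acc + w[a] * complex(modulus = 1, argument = phi)
    }
    out[r] <- acc
  }
  out
}

# Exhaustive 27-point scan for thresholded strict local maxima with periodic
# wrap-around.  Returns 0-based voxel triples ordered like find_peaks().
oracle_peak_scan <- function(v, threshold) {
  d <- dim(v)
  cand <- which(v > threshold)
  hits <- integer(0)
  for (lin in cand) {
    i <- (lin - 1) %% d[1]
    j <- ((lin - 1) %/% d[1]) %% d[2]
    k <- (lin - 1) %/% (d[1] * d[2])
    is_max <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      nb <- v[(i + di) %% d[1] + 1, (j + dj) %% d[2] + 1, (k + dk) %% d[3] + 1]
      if (v[lin] <= nb) { is_max <- FALSE; break }
    }
    if (is_max) hits <- c(hits, lin)
  }
  i <- (hits - 1) %% d[1]
  j <- ((hits - 1) %/% d[1]) %% d[2]
  k <- (hits - 1) %/% (d[1] * d[2])
  val <- v[hits]
  ord <- order(-val, i, j, k)
  data.frame(i = i[ord], j = j[ord], k = k[ord], value = val[ord])
}

# Exhaustive reflection enumeration for hkl_shell on small cells.
oracle_hkl_count <- function(cell, d_min, bound = 25) {
  g <- as.matrix(expand.grid(h = -bound:bound, k = -bound:bound, l = -bound:bound))
  g <- g[rowSums(g != 0) > 0, ]
  d <- d_spacing(cell, g)
  sum(d >= d_min) / 2
}
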