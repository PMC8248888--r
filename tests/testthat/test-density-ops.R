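test_that("grid sigma is the RMS about zero", {
  cell <- unit_cell(8, 8, 8)
  alt <- array(c(1, -1), c(4, 4, 4))
  expect_equal(grid_sigma(real_grid(alt, cell))$sigma, 1)
  expect_equal(grid_sigma(real_grid(array(0, c(4, 4, 4)), cell))$sigma, 0)
  g <- rnd_grid(c(48, 48, 48), sd = 2, seed = 41)
  expect_gt(grid_sigma(g)$sigma, 1.98)
  expect_lt(grid_sigma(g)$sigma, 2.02)
})

test_that("sign mask implements the three-valued rule with closed band", {
  cell <- unit_cell(8, 8, 8)
  sig <- 1  # construct a grid with RMS exactly 1 and probe voxels inside
  v <- array(c(1, -1), c(10, 10, 10))
  v[1:5] <- c(0.5, -1.0, -3.0, 0, -2.5)       # probes, sigma barely moves
  v <- v / sqrt(mean(v^2))                    # force sigma = 1 exactly
  probe <- v[1:5]
  m <- m_rho_mask(real_grid(v, cell), 2.5)
  expect_setequal(unique(as.vector(m$values)), c(-1, 0, 1))
  got <- m$values[1:5]
  expect_equal(got[probe > 0], rep(1, sum(probe > 0)))
  expect_equal(got[probe <= 0 & probe >= -2.5], rep(0, sum(probe <= 0 & probe >= -2.5)))
  expect_equal(got[probe < -2.5], rep(-1, sum(probe < -2.5)))
  # rho = 0 exactly sits in the band
  expect_equal(m$values[which(v == 0)], rep(0, sum(v == 0)))
  expect_error(m_rho_mask(real_grid(array(0, c(4, 4, 4)), cell), 2.5), "flat")
})

test_that("mask-density product is |rho|: nonnegative, band-zeroed", {
  set.seed(42)
  for (rep in 1:20) {
    g <- rnd_grid(c(8, 8, 8))
    t_rho <- runif(1, 1.5, 3.5)
    m <- m_rho_mask(g, t_rho)
    a <- abs_rho(g, m)
    expect_true(all(a$values >= 0))
    expect_true(all(m$values * g$values >= 0))
    expect_true(all(a$values[m$values == 0] == 0))
    expect_equal(a$values, g$values * m$values)
  }
  # everywhere-positive rho is returned unchanged
  gpos <- real_grid(array(abs(rnorm(64)) + 0.1, c(4, 4, 4)), unit_cell(8, 8, 8))
  expect_equal(abs_rho(gpos, m_rho_mask(gpos, 2.5))$values, gpos$values)
  expect_error(abs_rho(gpos, m_rho_mask(rnd_grid(c(6, 6, 6)), 2.5)), "dim")
})

test_that("raising t_rho never increases the count of -1 voxels", {
  g <- rnd_grid(c(10, 10, 10), seed = 43)
  counts <- vapply(seq(0.5, 3.5, by = 0.5),
                   function(t) sum(m_rho_mask(g, t)$values == -1), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rho synthesis honours the |E| cutoff", {
  ds <- cached("tiny12", tiny_dataset())
  refl <- ds$reflections
  dims <- choose_dims(attr(refl, "cell"), attr(refl, "d_min"), 3)
  cell <- attr(refl, "cell")
  ph <- ds$truth$phases
  # E_min = 0 uses every reflection: equals the plain synthesis of all coeffs
  g_all <- rho_synthesis(refl, ph, 0, dims, cell)
  g_ref <- grid_synthesize(refl$E * exp(1i * ph),
                           as.matrix(refl[, c("h", "k", "l")]), dims, cell)
  expect_equal(g_all$values, g_ref$values)
  # counting: a 2-reflection set with E_min = 1 uses exactly one coefficient
  two <- tibble::tibble(h = c(1L, 2L), k = 0L, l = 0L, E = c(1.2, 0.8))
  attr(two, "cell") <- cell
  g2 <- rho_synthesis(two, c(0, 0), 1.0, dims, cell)
  g1 <- grid_synthesize(1.2 + 0i, c(1, 0, 0), dims, cell)
  expect_equal(g2$values, g1$values)
  expect_error(rho_synthesis(refl, ph, max(refl$E) + 1, dims, cell), "cutoff")
})

test_that("delta synthesis is origin-free and matches the oracle", {
  ds <- cached("tiny12", tiny_dataset())
  refl <- ds$reflections
  cell <- attr(refl, "cell")
  dims <- c(12L, 12L, 12L)
  idx20 <- as.matrix(refl[1:20, c("h", "k", "l")])
  sub <- refl[1:20, ]
  attr(sub, "mean_E") <- NULL

  # all moduli equal -> all coefficients zero -> zero grid
  eq <- sub; eq$E <- 1
  g0 <- delta_synthesis(eq, rep(0.3, 20), dims, cell)
  expect_true(all(abs(g0$values) < 1e-14))

  # all alpha = 0 is the origin-free modulus synthesis (Patterson-type):
  # centrosymmetric and zero-mean
  gm <- delta_synthesis(sub, rep(0, 20), dims, cell)
  expect_equal(mean(gm$values), 0, tolerance = 1e-12)
  flipped <- gm$values[c(1, 12:2), c(1, 12:2), c(1, 12:2)]
  expect_equal(gm$values, flipped, tolerance = 1e-10)

  # random case against the per-voxel direct-sum oracle
  set.seed(44)
  al <- runif(20, 0, 2 * pi)
  gd <- delta_synthesis(sub, al, dims, cell)
  oracle <- oracle_direct_sum_map((sub$E - mean(sub$E)) * exp(1i * al),
                                  idx20, dims, cell)
  expect_lt(max(abs(gd$values - oracle)) / max(abs(oracle)), 1e-9)
})

test_that("eta product is the exact pointwise product", {
  g <- rnd_grid(c(6, 6, 6), seed = 45)
  mask_all1 <- real_grid(array(1, c(6, 6, 6)), g$cell, "mask")
  expect_equal(eta_product(g, mask_all1)$values, g$values)
  mask_all0 <- real_grid(array(0, c(6, 6, 6)), g$cell, "mask")
  expect_true(all(eta_product(g, mask_all0)$values == 0))
  m <- m_rho_mask(rnd_grid(c(6, 6, 6), seed = 46), 2.5)
  ep <- eta_product(g, m)
  for (lin in sample(216, 25))
    expect_identical(ep$values[lin], g$values[lin] * m$values[lin])
})

test_that("CC_M is the normalized modulus-function overlap", {
  set.seed(47)
  e <- runif(300, 0.1, 3)
  # perfect proportionality between |C| and the origin-free experimental
  # coefficients gives CC_M = 1
  expect_equal(cc_m(e, mean(e), 1.7 * (e - mean(e))), 1)
  # permutation of the centred vector destroys the overlap
  expect_lt(abs(cc_m(e, mean(e), sample(e - mean(e)))), 0.15)
  # invariant under rescaling of either vector
  c_amp <- abs(e - mean(e) + rnorm(300, 0, 0.3))
  expect_equal(cc_m(e, mean(e), c_amp), cc_m(e, mean(e), 100 * c_amp))
  expect_equal(cc_m(2 * e, mean(2 * e), c_amp), cc_m(e, mean(e), c_amp))
  expect_error(cc_m(e, mean(e), rep(0, 300)), "zero-variance")
})

test_that("R_M residual is the least-squares discrepancy", {
  cell <- unit_cell(8, 8, 8)
  a <- real_grid(array(abs(rnorm(125)), c(5, 5, 5)), cell)
  d2 <- real_grid(2 * a$values, cell)
  r <- r_m_residual(d2, a)
  expect_equal(r$k, 2)
  expect_equal(r$residual, 0)
  # orthogonal delta: k = 0 and residual = sum(delta^2)
  d_orth <- array(0, c(5, 5, 5)); d_orth[1, 1, 1] <- 1; d_orth[2, 1, 1] <- -1
  a_flat <- array(0, c(5, 5, 5)); a_flat[1, 1, 1] <- 1; a_flat[2, 1, 1] <- 1
  r2 <- r_m_residual(real_grid(d_orth, cell), real_grid(a_flat, cell))
  expect_equal(r2$k, 0)
  expect_equal(r2$residual, 2)
  # random case against an independently coded least-squares fit
  set.seed(48)
  dd <- rnd_grid(c(5, 5, 5)); aa <- real_grid(abs(rnd_grid(c(5, 5, 5))$values), cell)
  r3 <- r_m_residual(dd, aa)
  fit <- lm(as.vector(dd$values) ~ 0 + as.vector(aa$values))
  expect_equal(r3$k, unname(coef(fit)), tolerance = 1e-10)
  expect_equal(r3$residual, sum(residuals(fit)^2), tolerance = 1e-10)
  expect_error(r_m_residual(dd, real_grid(array(0, c(5, 5, 5)), cell)), "zero")
})

test_that("minimizing R_M and maximizing CC_M pick the same optimum", {
  # one-parameter phase family on a 2-atom toy structure
  cell <- unit_cell(6, 6, 6)
  st <- crystal_structure(cell, data.frame(x = c(0.15, 0.6), y = c(0.3, 0.75),
                                           z = c(0.2, 0.55), w = 6))
  ds <- make_dataset(st, 1.2)
  refl <- ds$reflections
  idx <- as.matrix(refl[, c("h", "k", "l")])
  dims <- choose_dims(cell, 1.2, 3)
  set.seed(49)
  dphi <- runif(nrow(refl), -1, 1)
  tgrid <- seq(-1, 1, by = 0.1)
  scores <- vapply(tgrid, function(t) {
    ph <- ds$truth$phases + t * dphi
    rho <- rho_synthesis(refl, ph, 0, dims, cell)
    m <- m_rho_mask(rho, 2.5)
    ar <- abs_rho(rho, m)
    C <- grid_analyze(ar, idx)
    delta <- delta_synthesis(refl, Arg(C), dims, cell)
    c(cc = cc_m(refl$E, mean(refl$E), Mod(C)),
      rm = r_m_residual(delta, ar)$residual)
  }, c(cc = 0, rm = 0))
  opt <- which.max(scores["cc", ])
  expect_equal(opt, which.min(scores["rm", ]))
  expect_lte(abs(tgrid[opt]), 0.15)   # at (or one grid step from) the truth
})
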