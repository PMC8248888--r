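test_that("random starts are reproducible and seed-sensitive", {
  idx <- hkl_shell(unit_cell(9, 9, 9), 1.0)
  s1 <- start_random(idx, 7)
  s2 <- start_random(idx, 7)
  expect_identical(s1$phases, s2$phases)
  expect_length(s1$phases, nrow(idx))
  expect_true(all(s1$phases >= 0 & s1$phases < 2 * pi))
  s3 <- start_random(idx, 8)
  expect_gt(mean(s1$phases != s3$phases), 0.99)
  # the start map synthesized from these phases is real (Friedel contract)
  cell <- unit_cell(9, 9, 9)
  g <- grid_synthesize(exp(1i * s1$phases), idx, choose_dims(cell, 1, 3), cell)
  expect_true(is.numeric(g$values))
})

test_that("shifted-modulus starts realize the translated modulus map", {
  idx <- hkl_shell(unit_cell(8, 8, 8), 1.2)
  expect_equal(start_shifted_modulus(idx, c(0, 0, 0))$phases,
               rep(0, nrow(idx)))
  expect_equal(start_shifted_modulus(matrix(c(1L, 0L, 0L), 1), c(0.5, 0, 0))$phases,
               pi)
  # for u commensurate with the grid, the delta synthesis with these phases
  # is the circularly shifted zero-phase modulus synthesis, voxel for voxel
  ds <- cached("tiny12", tiny_dataset())
  refl <- ds$reflections
  cell <- attr(refl, "cell")
  dims <- choose_dims(cell, attr(refl, "d_min"), 3)
  idxm <- as.matrix(refl[, c("h", "k", "l")])
  u <- c(5, 2, 9) / dims
  sp <- start_shifted_modulus(idxm, u)
  g_shift <- delta_synthesis(refl, sp$phases, dims, cell)
  g_zero <- delta_synthesis(refl, rep(0, nrow(refl)), dims, cell)
  roll <- function(n, s) ((seq_len(n) - 1 + s) %% n) + 1
  expect_equal(g_shift$values,
               g_zero$values[roll(dims[1], 5), roll(dims[2], 2), roll(dims[3], 9)],
               tolerance = 1e-9)
  expect_error(start_shifted_modulus(idxm, c(1.2, 0, 0)))
})

test_that("convergence detector fires on jumps and ignores slow ramps", {
  # flat trace never fires
  expect_true(is.na(detect_convergence(rep(0.5, 40))))
  # constructed jump: fires at the plateau onset
  trace <- c(rep(0.50, 10), 0.55, 0.58, 0.58, 0.58)
  expect_equal(detect_convergence(trace), 12L)
  # monotone ramp of 0.001/iter never fires (jump spread over > window)
  ramp <- 0.4 + 0.001 * (1:300)
  expect_true(is.na(detect_convergence(ramp)))
  # full-lookahead variant refuses a jump at the very end of the trace
  expect_true(is.na(detect_convergence(trace[1:12], require_lookahead = TRUE)))
})

test_that("one iteration matches a hand-stepped pipeline at every stage", {
  ds <- cached("tiny12", tiny_dataset())
  refl <- ds$reflections
  cell <- attr(refl, "cell")
  dims <- choose_dims(cell, attr(refl, "d_min"), 3)
  idx <- as.matrix(refl[, c("h", "k", "l")])
  cfg <- phasing_config(n_atoms = 12, variant = "sm_ipp", seed = 1)
  set.seed(61)
  ph <- runif(nrow(refl), 0, 2 * pi)

  step <- iterate_once(ph, refl, cfg, dims)

  # hand-stepped with the module operations plus direct-sum checks
  rho <- rho_synthesis(refl, ph, cfg$e_min, dims, cell)
  keep <- refl$E >= cfg$e_min
  oracle_rho <- oracle_dft_map(refl$E[keep] * exp(1i * ph[keep]),
                               idx[keep, ], dims, cell)
  expect_lt(max(abs(rho$values - oracle_rho)) / max(abs(oracle_rho)), 1e-9)
  m <- m_rho_mask(rho, cfg$t_rho)
  C <- grid_analyze(abs_rho(rho, m), idx)
  expect_equal(step$cc, cc_m(refl$E, mean(refl$E), Mod(C)))
  delta <- delta_synthesis(refl, Arg(C), dims, cell)
  eta <- eta_product(delta, m)
  pk <- find_peaks(eta, cfg$t_eta)
  expect_equal(step$n_eta, nrow(pk))
  eta2 <- preserve_inner_pixels(eta, pk, cfg$n_atoms)
  expect_equal(step$phases, Arg(grid_analyze(eta2, idx)))
  # updated phases satisfy the Friedel contract
  conj_q <- grid_analyze(eta2, -idx)
  expect_equal(Arg(conj_q), -step$phases, tolerance = 1e-9)

  # plain variant omits ipp entirely: phases come from unmodified eta
  cfg_sm <- phasing_config(n_atoms = 12, variant = "sm", seed = 1)
  step_sm <- iterate_once(ph, refl, cfg_sm, dims)
  rho_sm <- rho_synthesis(refl, ph, 0, dims, cell)
  m_sm <- m_rho_mask(rho_sm, cfg_sm$t_rho)
  C_sm <- grid_analyze(abs_rho(rho_sm, m_sm), idx)
  eta_sm <- eta_product(delta_synthesis(refl, Arg(C_sm), dims, cell), m_sm)
  expect_equal(step_sm$phases, Arg(grid_analyze(eta_sm, idx)))
  expect_true(is.na(step_sm$n_eta))
})

test_that("trials are deterministic and respect the iteration cap", {
  ds <- cached("tiny12", tiny_dataset())
  cfg1 <- phasing_config(n_atoms = 12, n_iter_max = 1, seed = 5)
  s <- start_random(as.matrix(ds$reflections[, c("h", "k", "l")]), 5)
  tr1 <- run_trial(ds$reflections, cfg1, s)
  expect_length(tr1$cc_trace, 1)
  expect_false(tr1$converged)
  expect_equal(tr1$n_iter, 1)

  cfg <- phasing_config(n_atoms = 12, n_iter_max = 60, seed = 5)
  tr_a <- run_trial(ds$reflections, cfg, s, truth = ds$truth)
  tr_b <- run_trial(ds$reflections, cfg, s, truth = ds$truth)
  expect_identical(tr_a$cc_trace, tr_b$cc_trace)
  expect_identical(tr_a$final_phases, tr_b$final_phases)
  expect_equal(tr_a$alignment$best_cc, tr_b$alignment$best_cc)
  expect_lte(tr_a$n_iter, 60)
})

test_that("a trial started at the true phases stays at the solution", {
  # quasi-fixed point of the ipp loop at atomic resolution: 50 equal-atom
  # weak crystal, d_min 0.9 A
  ds <- cached("wilson50", {
    st <- generate_structure(scenario_spec("weak", n_atoms = 50, seed = 6))
    make_dataset(st, 0.9)
  })
  cfg <- phasing_config(n_atoms = expected_atom_count(50), n_iter_max = 50,
                        seed = 1, min_iter = 1000)  # no early stop: all 50
  s_true <- structure(list(mode = "random", phases = ds$truth$phases,
                           seed = NULL, u = NULL), class = "start_spec")
  tr <- run_trial(ds$reflections, cfg, s_true, truth = ds$truth,
                  track_truth = TRUE)
  expect_gte(min(tr$aligned_trace), 0.9)
})

test_that("matched batches pair identical starts and summarize correctly", {
  ds <- cached("tiny12", tiny_dataset())
  cfg <- phasing_config(n_atoms = 12, n_trials = 3, n_iter_max = 25, seed = 9)
  starts <- generate_starts(ds$reflections, cfg)
  expect_length(starts, 3)
  b1 <- run_batch(ds$reflections, cfg, truth = ds$truth, starts = starts)
  b2 <- run_batch(ds$reflections,
                  phasing_config(n_atoms = 12, variant = "sm", n_trials = 3,
                                 n_iter_max = 25, seed = 9),
                  truth = ds$truth, starts = starts)
  for (k in 1:3) {
    expect_identical(b1$trials[[k]]$start$phases, b2$trials[[k]]$start$phases)
  }
  expect_equal(nrow(b1$summary), 3)
  expect_named(glance(b1),
               c("n_trials", "n_converged", "n_success", "mean_n_iter", "mean_q"))

  # shifted-modulus batches reuse the same u sequence across data sets
  cfg_u <- phasing_config(n_atoms = 12, n_trials = 3, start_mode = "shifted_modulus",
                          seed = 9)
  st1 <- generate_starts(ds$reflections, cfg_u)
  ds2 <- cached("tiny10", tiny_dataset(n_atoms = 10, seed = 8))
  st2 <- generate_starts(ds2$reflections, cfg_u)
  expect_identical(lapply(st1, `[[`, "u"), lapply(st2, `[[`, "u"))
})

test_that("mean iteration count reproduces the benchmark-table arithmetic", {
  # five converged trials at 10, 11, 12, 13, 15 iterations average to 12.2
  fake <- structure(list(summary = tibble::tibble(
    trial = 1:5, converged = TRUE, n_iter = c(10L, 11L, 12L, 13L, 15L),
    cc_final = 0.8, n_eta2 = 40L, q = 1, aligned_cc = NA_real_, success = NA),
    trials = list(), config = phasing_config(n_atoms = 10)),
    class = "phasing_batch")
  expect_equal(glance(fake)$mean_n_iter, 12.2)
  # zero converged trials: undefined mean, reported as n.c. count
  fake$summary$converged <- FALSE
  fake$summary$n_iter <- NA_integer_
  g <- glance(fake)
  expect_true(is.na(g$mean_n_iter))
  expect_equal(g$n_converged, 0)
})

test_that("trial and batch tidiers expose the traces", {
  ds <- cached("tiny12", tiny_dataset())
  cfg <- phasing_config(n_atoms = 12, n_trials = 2, n_iter_max = 15, seed = 3)
  b <- run_batch(ds$reflections, cfg, truth = ds$truth)
  td <- tidy(b$trials[[1]])
  expect_named(td, c("iteration", "cc", "n_eta"))
  expect_equal(nrow(td), length(b$trials[[1]]$cc_trace))
  expect_s3_class(autoplot(b$trials[[1]]), "ggplot")
  expect_s3_class(autoplot(b), "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_batch_summary(b, path)
  expect_equal(nrow(read.delim(path)), 2)
})
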