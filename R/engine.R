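#' Configuration of a phase-refinement run
#'
#' Collects every tunable of the dual-space loop.  Defaults follow the
#' recommended operating point: mask threshold `t_rho` by scatterer
#' class (2.5 weak / 2.6 medium / 2.8 strong), peak threshold
#' `t_eta = 3.7`, modulus cutoff `e_min = 1` for the ipp variant (the
#' plain variant always synthesizes rho from all reflections, i.e.
#' `e_min = 0`), at most 1000 iterations per trial and 5 trials.
#'
#' @param n_atoms Expected number of non-H atoms N in the cell,
#'   including any solvent (see [solvent_expansion_factor()]).
#' @param variant `"sm_ipp"` (inner-pixel preservation, the default) or
#'   `"sm"` (plain).
#' @param t_rho Sign-mask threshold factor (> 0).
#' @param t_eta Peak-search threshold factor (> 0), normally 3.5-4.0.
#' @param e_min |E| cutoff for the rho synthesis; `NULL` resolves to 1.0
#'   for `"sm_ipp"` and 0 for `"sm"`.
#' @param n_iter_max Maximum iterations per trial.
#' @param n_trials Number of refinement trials in a batch (5, 25 or 50
#'   by convention).
#' @param oversample Grid sampling factor (see [choose_dims()]).
#' @param seed Integer seed controlling all randomness of a batch.
#' @param start_mode `"random"` phases or `"shifted_modulus"` starts.
#' @param jump,window,stability Convergence detector: fire at the first
#'   iteration i >= `min_iter` with `cc[i] - cc[i - window] >= jump` and
#'   cc stable within `stability` over the following `lookahead`
#'   iterations (the documented CC_M convergence jump is 0.035-0.045 in
#'   a few cycles; `jump = 0.03` catches it with margin).
#' @param min_iter,lookahead Detector bounds, see above.
#' @param success_cc Aligned-map correlation threshold for calling a
#'   trial correct when ground truth is available.
#' @param u_seed Seed of the dedicated shift-vector generator, kept
#'   separate from per-trial phase seeds so the u sequence is the same
#'   for all data sets; `NULL` derives it from `seed`.
#' @return A `phasing_config` list.
#' @export
phasing_config <- function(n_atoms,
                           variant = c("sm_ipp", "sm"),
                           t_rho = 2.5, t_eta = 3.7, e_min = NULL,
                           n_iter_max = 1000, n_trials = 5,
                           oversample = 3, seed = 1,
                           start_mode = c("random", "shifted_modulus"),
                           jump = 0.03, window = 5, stability = 0.008,
                           min_iter = 10, lookahead = 5,
                           success_cc = 0.7, u_seed = NULL) {
  variant <- match.arg(variant)
  start_mode <- match.arg(start_mode)
  if (is.null(e_min)) e_min <- if (variant == "sm_ipp") 1.0 else 0.0
  stopifnot(n_atoms >= 1, t_rho > 0, t_eta > 0, e_min >= 0,
            n_iter_max >= 1, n_trials >= 1, window >= 2, jump > 0)
  if (is.null(u_seed)) u_seed <- (as.integer(seed) + 104729L) %% .Machine$integer.max
  structure(list(n_atoms = as.integer(n_atoms), variant = variant,
                 t_rho = t_rho, t_eta = t_eta, e_min = e_min,
                 n_iter_max = as.integer(n_iter_max),
                 n_trials = as.integer(n_trials),
                 oversample = oversample, seed = as.integer(seed),
                 start_mode = start_mode, jump = jump, window = window,
                 stability = stability, min_iter = min_iter,
                 lookahead = lookahead, success_cc = success_cc,
                 u_seed = as.integer(u_seed)),
            class = "phasing_config")
}

#' Random starting phases
#'
#' One i.i.d. uniform phase on [0, 2 pi) per Friedel-unique reflection,
#' reproducible from the seed; implicit Friedel mates are conjugated
#' inside the synthesis, so the start map is always real.
#'
#' @param indices Friedel-unique n x 3 Miller index matrix (only the row
#'   count is used).
#' @param seed Integer seed.
#' @return A `start_spec` list with `mode`, `phases`, `seed`.
#' @export
start_random <- function(indices, seed) {
  n <- if (is.null(dim(indices))) 1L else nrow(indices)
  phases <- withr_seed(seed, stats::runif(n, 0, 2 * pi))
  structure(list(mode = "random", phases = phases, seed = as.integer(seed),
                 u = NULL), class = "start_spec")
}

#' Shifted-modulus starting phases
#'
#' Phases phi_K = (-2 pi K.u) mod 2 pi, so that the difference synthesis
#' computed with them equals the zero-phase origin-free modulus
#' synthesis M translated by the random shift vector u.  Each trial's u
#' selects a different image of the structure in the Patterson-type M
#' function as its starting density estimate.
#'
#' @param indices Friedel-unique n x 3 Miller index matrix.
#' @param u Fractional shift vector, components in [0, 1).
#' @return A `start_spec` list with `mode`, `phases`, `u`.
#' @export
start_shifted_modulus <- function(indices, u) {
  if (is.null(dim(indices))) indices <- matrix(indices, ncol = 3)
  stopifnot(length(u) == 3, all(u >= 0), all(u < 1))
  phases <- as.vector((-2 * pi * (indices %*% u)) %% (2 * pi))
  structure(list(mode = "shifted_modulus", phases = phases, seed = NULL,
                 u = u), class = "start_spec")
}

# run expr with a local RNG state seeded by `seed` (forced first, so a seed
# drawn from the caller's RNG is consumed before the state is snapshot)
withr_seed <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' One dual-space iteration
#'
#' Executes, in order: rho from the experimental |E| (restricted to
#' |E| >= e_min) carried on the current phases; the sign mask m of rho
#' (stored); |rho| = m * rho; Fourier analysis of |rho| giving |C| and
#' alpha; CC_M from |C|; the origin-free difference synthesis delta on
#' the alpha phases over all reflections; eta = delta * m; for the ipp
#' variant, peak search on eta and inner-pixel preservation with the top
#' N peaks; finally the modified tangent formula -- the updated phases
#' are the angular part of eta's Fourier transform (the amplitudes of
#' that transform are discarded, and the experimental |E| are re-attached
#' at the next synthesis).
#'
#' @param phases Current phases (radians), one per reflection.
#' @param reflections Reflection tibble with attributes `cell`, `d_min`
#'   (see [make_dataset()] / [read_reflections()]).
#' @param config A [phasing_config()].
#' @param dims Grid dimensions; `NULL` chooses them from the config.
#' @return List with `phases` (updated), `cc`, `n_eta` (NA for the plain
#'   variant), and `stalled` (TRUE when eta vanished everywhere, which
#'   ends a trial as unconverged).
#' @export
iterate_once <- function(phases, reflections, config, dims = NULL) {
  cell <- attr(reflections, "cell")
  if (is.null(dims)) dims <- choose_dims(cell, attr(reflections, "d_min"), config$oversample)
  idx <- as.matrix(reflections[, c("h", "k", "l")])
  mean_E <- attr(reflections, "mean_E") %||% mean(reflections$E)

  rho  <- rho_synthesis(reflections, phases, config$e_min, dims, cell)
  mask <- m_rho_mask(rho, config$t_rho)
  arho <- abs_rho(rho, mask)
  C <- grid_analyze(arho, idx)
  cc <- cc_m(reflections$E, mean_E, Mod(C))
  delta <- delta_synthesis(reflections, Arg(C), dims, cell, mean_E = mean_E)
  eta <- eta_product(delta, mask)

  n_eta <- NA_integer_
  if (config$variant == "sm_ipp") {
    if (grid_sigma(eta)$sigma == 0)
      return(list(phases = phases, cc = cc, n_eta = 0L, stalled = TRUE))
    peaks <- find_peaks(eta, config$t_eta)
    n_eta <- nrow(peaks)
    if (n_eta == 0L)
      return(list(phases = phases, cc = cc, n_eta = 0L, stalled = TRUE))
    eta <- suppressWarnings(preserve_inner_pixels(eta, peaks, config$n_atoms))
  }
  if (max(abs(eta$values)) == 0)
    return(list(phases = phases, cc = cc, n_eta = n_eta, stalled = TRUE))
  new_phases <- Arg(grid_analyze(eta, idx))
  list(phases = new_phases, cc = cc, n_eta = n_eta, stalled = FALSE)
}

#' Detect the CC_M convergence jump in a trace
#'
#' Returns the first iteration i (1-based) with `i >= min_iter`,
#' `cc[i] - cc[i - window] >= jump`, and cc stable within `stability`
#' over the following `min(lookahead, remaining)` iterations; `NA` if
#' the trace never fires.  With `require_lookahead = TRUE` an iteration
#' only qualifies once `lookahead` later values exist (used while a
#' trial is still running).
#'
#' @param cc_trace Numeric CC_M trace.
#' @param window,jump,stability,min_iter,lookahead See [phasing_config()].
#' @param require_lookahead Require the full stability window.
#' @return Iteration index or `NA`.
#' @export
detect_convergence <- function(cc_trace, window = 5, jump = 0.03,
                               stability = 0.008, min_iter = 10,
                               lookahead = 5, require_lookahead = FALSE) {
  n <- length(cc_trace)
  for (i in seq_len(n)) {
    if (i < min_iter || i <= window) next
    la <- lookahead
    if (i + la > n) {
      if (require_lookahead) next
      la <- n - i
    }
    if (cc_trace[i] - cc_trace[i - window] >= jump) {
      if (la == 0 ||
          max(abs(cc_trace[(i + 1):(i + la)] - cc_trace[i])) <= stability)
        return(i)
    }
  }
  NA_integer_
}

#' Run one phase-refinement trial
#'
#' Iterates [iterate_once()] from the given start until the convergence
#' detector fires or `n_iter_max` is reached.  A stalled trial (empty
#' peak list or vanished eta) terminates immediately as unconverged.
#'
#' @param reflections Reflection tibble with `cell` / `d_min` attributes.
#' @param config A [phasing_config()].
#' @param start A start spec from [start_random()] /
#'   [start_shifted_modulus()].
#' @param truth Optional ground truth (list with element `phases`) for
#'   scoring; when given, the final phases are aligned and scored via
#'   [align_and_score()].
#' @param track_truth When TRUE (and truth is given), record the aligned
#'   map correlation at every iteration (costly: two extra transforms
#'   per iteration; meant for diagnostics on converged trials).
#' @return A `phasing_trial` object: list with `cc_trace`,
#'   `n_eta_trace`, `n_iter`, `converged`, `final_phases`, `q`, `start`,
#'   and when truth was given `alignment`, `success`, optionally
#'   `aligned_trace`.
#' @export
run_trial <- function(reflections, config, start, truth = NULL,
                      track_truth = FALSE) {
  stopifnot(inherits(start, "start_spec"))
  cell <- attr(reflections, "cell")
  dims <- choose_dims(cell, attr(reflections, "d_min"), config$oversample)
  idx <- as.matrix(reflections[, c("h", "k", "l")])
  phases <- start$phases
  cc <- numeric(0); neta <- integer(0); aligned <- numeric(0)
  converged <- FALSE; n_iter <- NA_integer_
  for (it in seq_len(config$n_iter_max)) {
    step <- iterate_once(phases, reflections, config, dims)
    cc[it] <- step$cc
    neta[it] <- step$n_eta
    phases <- step$phases
    if (track_truth && !is.null(truth)) {
      aligned[it] <- align_and_score(phases, truth$phases, reflections$E,
                                     idx, dims, cell)$best_cc
    }
    if (step$stalled) break
    hit <- detect_convergence(cc, config$window, config$jump, config$stability,
                              config$min_iter, config$lookahead,
                              require_lookahead = (it < config$n_iter_max))
    if (!is.na(hit)) { converged <- TRUE; n_iter <- hit; break }
  }
  if (!converged) n_iter <- length(cc)
  q <- if (length(neta) >= 2 && !is.na(neta[2]))
    q_statistic(neta[2], config$n_atoms) else NA_real_
  out <- list(cc_trace = cc, n_eta_trace = neta, n_iter = n_iter,
              converged = converged, final_phases = phases, q = q,
              start = start, config = config)
  if (!is.null(truth)) {
    out$alignment <- align_and_score(phases, truth$phases, reflections$E,
                                     idx, dims, cell)
    out$success <- classify_success(out$alignment, config$success_cc)
    if (track_truth) out$aligned_trace <- aligned
  }
  class(out) <- "phasing_trial"
  out
}

#' @export
print.phasing_trial <- function(x, ...) {
  cat(sprintf("<phasing_trial> %s, %s start: %s after %d iteration(s), final CC_M=%.3f%s\n",
              x$config$variant, x$start$mode,
              if (x$converged) "converged" else "no convergence",
              x$n_iter, x$cc_trace[length(x$cc_trace)],
              if (!is.null(x$success))
                sprintf(", aligned CC=%.3f (%s)", x$alignment$best_cc,
                        if (x$success) "correct" else "incorrect") else ""))
  invisible(x)
}

#' Generate the matched start specs of a batch
#'
#' Random-mode starts get per-trial seeds derived deterministically from
#' the batch seed; shifted-modulus starts draw their u vectors from a
#' dedicated generator (`u_seed`), so the same u sequence can be reused
#' across data sets and variants.  Reusing the returned list across
#' variants makes comparisons matched: the k-th trial of each variant
#' starts from bitwise-identical phases.
#'
#' @param reflections Reflection tibble.
#' @param config A [phasing_config()].
#' @return List of `n_trials` start specs.
#' @export
generate_starts <- function(reflections, config) {
  idx <- as.matrix(reflections[, c("h", "k", "l")])
  if (config$start_mode == "random") {
    lapply(seq_len(config$n_trials), function(k)
      start_random(idx, (config$seed + 7919L * k) %% .Machine$integer.max))
  } else {
    us <- withr_seed(config$u_seed,
                     matrix(stats::runif(3 * config$n_trials), ncol = 3))
    lapply(seq_len(config$n_trials), function(k)
      start_shifted_modulus(idx, us[k, ]))
  }
}

#' Run a batch of phase-refinement trials
#'
#' @param reflections Reflection tibble with `cell` / `d_min` attributes.
#' @param config A [phasing_config()].
#' @param truth Optional ground truth for per-trial scoring.
#' @param starts Optional list of start specs (defaults to
#'   [generate_starts()]); pass the same list to two batches for a
#'   matched-start comparison.
#' @return A `phasing_batch` object: list of `trials`, a per-trial
#'   `summary` tibble and the `config`.
#' @export
run_batch <- function(reflections, config, truth = NULL, starts = NULL) {
  if (is.null(starts)) starts <- generate_starts(reflections, config)
  stopifnot(length(starts) == config$n_trials)
  trials <- lapply(starts, function(s) run_trial(reflections, config, s, truth))
  summary <- purrr::map2_dfr(trials, seq_along(trials), function(tr, k) {
    tibble::tibble(
      trial = k, converged = tr$converged,
      n_iter = if (tr$converged) tr$n_iter else NA_integer_,
      cc_final = tr$cc_trace[length(tr$cc_trace)],
      n_eta2 = if (length(tr$n_eta_trace) >= 2) tr$n_eta_trace[2] else NA_integer_,
      q = tr$q,
      aligned_cc = if (!is.null(tr$alignment)) tr$alignment$best_cc else NA_real_,
      success = if (!is.null(tr$success)) tr$success else NA)
  })
  structure(list(trials = trials, summary = summary, config = config),
            class = "phasing_batch")
}

#' @export
print.phasing_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<phasing_batch> %s, %s starts: %d/%d converged%s\n",
              x$config$variant, x$config$start_mode,
              sum(s$converged), nrow(s),
              if (!all(is.na(s$success)))
                sprintf(", %d correct", sum(s$success, na.rm = TRUE)) else ""))
  print(s)
  invisible(x)
}

#' Matched-start comparison of the ipp and plain variants
#'
#' Runs the same trials (bitwise-identical starting phases) with and
#' without inner-pixel preservation and pairs the results, mirroring the
#' A1-vs-A2 / B1-vs-B2 protocol.  Unconverged trials are censored at
#' `n_iter_max` in the paired iteration counts.
#'
#' @param reflections Reflection tibble.
#' @param config A [phasing_config()]; its `variant` is ignored.
#' @param truth Optional ground truth.
#' @return List with both `phasing_batch`es (`ipp`, `plain`) and a
#'   `pairs` tibble of per-trial iteration counts.
#' @export
compare_variants <- function(reflections, config, truth = NULL) {
  starts <- generate_starts(reflections, config)
  cfg_ipp   <- phasing_config_update(config, variant = "sm_ipp", e_min = NULL)
  cfg_plain <- phasing_config_update(config, variant = "sm", e_min = NULL)
  b_ipp   <- run_batch(reflections, cfg_ipp, truth, starts)
  b_plain <- run_batch(reflections, cfg_plain, truth, starts)
  cens <- function(b) ifelse(b$summary$converged, b$summary$n_iter,
                             b$config$n_iter_max)
  pairs <- tibble::tibble(trial = seq_along(starts),
                          n_iter_ipp = cens(b_ipp), n_iter_plain = cens(b_plain),
                          converged_ipp = b_ipp$summary$converged,
                          converged_plain = b_plain$summary$converged)
  list(ipp = b_ipp, plain = b_plain, pairs = pairs)
}

# rebuild a config with some fields replaced (e_min = NULL re-derives it)
phasing_config_update <- function(config, ...) {
  args <- utils::modifyList(unclass(config), list(...), keep.null = FALSE)
  repl <- list(...)
  if ("e_min" %in% names(repl) && is.null(repl$e_min)) args$e_min <- NULL
  do.call(phasing_config, args[names(args) %in% names(formals(phasing_config))])
}
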