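# smipp

Ab initio phasing of atomic-resolution X-ray diffraction data in R, by a
dual-space FFT algorithm with inner-pixel-preservation (ipp) density
modification.

## The problem

A diffraction experiment measures only structure-factor *moduli* — here the
normalized moduli |E<sub>K</sub>|, rescaled so equal point atoms give
⟨|E|²⟩ = 1 — while the phases φ<sub>K</sub> needed to compute the electron
density are lost.  At atomic resolution (d<sub>min</sub> ≲ 1.2 Å) the density
is a set of resolved atomic peaks, and that real-space constraint is enough to
recover the phases by iterating between real and reciprocal space.  Everything
here works in space group P1 (the symmetry most favourable to ab initio
refinement); any origin and either enantiomorph of the solution is equally
valid, so scoring against a ground truth searches both.

## The algorithm

Each iteration performs, in order:

1. **ρ synthesis** — ρ = FT⁻¹{ |E<sub>K</sub>| e<sup>iφ<sub>K</sub></sup> }
   over the reflections with |E| ≥ |E|<sub>min</sub> (≈ 1.0 for the ipp
   variant; all reflections for the plain variant).
2. **Sign mask** — m<sub>ρ</sub> = +1 where ρ > 0, 0 on the shallow band
   −t<sub>ρ</sub>σ<sub>ρ</sub> ≤ ρ ≤ 0, −1 below it (t<sub>ρ</sub> ≈
   2.5/2.6/2.8 for weak/medium/strong scatterers).  |ρ| = m<sub>ρ</sub>·ρ.
3. **Analysis** — FT{|ρ|} gives amplitudes |C<sub>K</sub>| and phases
   α<sub>K</sub>; the modulus correlation CC<sub>M</sub> (the normalized
   overlap of {|E|−⟨|E|⟩} with {|C|}) is logged.
4. **δ<sub>M</sub> synthesis** — FT⁻¹{ (|E<sub>K</sub>|−⟨|E|⟩)
   e<sup>iα<sub>K</sub></sup> } over *all* reflections (origin-free
   coefficients).
5. **η product** — η = δ<sub>M</sub> · m<sub>ρ</sub>.
6. **ipp density modification** — find all strict 26-neighbour local maxima of
   η above t<sub>η</sub>σ<sub>η</sub> (t<sub>η</sub> ≈ 3.5–4.0); keep the
   27-voxel neighbourhoods of the N strongest peaks (N = expected non-H atom
   count, solvent included), zero the rest.
7. **Modified tangent formula** — the updated φ<sub>K</sub> are the angular
   part of FT{η}; amplitudes are discarded and the experimental |E| are
   re-attached at the next synthesis.

A refinement has converged when CC<sub>M</sub> plateaus and then jumps by a
few hundredths within a few cycles, accompanied by a sharp drop of the peak
count N<sub>η</sub>.  Trials start either from random phases or from the
randomly shifted origin-free modulus synthesis M′ (a Patterson-type map whose
phases are φ<sub>K</sub> = −2πK·u).

## Worked example

Simulate a 30-atom weak-scatterer P1 crystal (cubic cell, 20 Å³ per atom,
exact |E| data to 1.0 Å), run five random-start ipp trials, and score them
against the known structure:

```r
library(smipp)

st  <- generate_structure(scenario_spec("weak", seed = 42))
ds  <- make_dataset(st, d_min = 1.0)                 # 1258 reflections
cfg <- phasing_config(n_atoms = expected_atom_count(30),  # 37 = 30 x 1.22
                      n_trials = 5, seed = 1)
batch <- run_batch(ds$reflections, cfg, truth = ds$truth)
batch
#> <phasing_batch> sm_ipp, random starts: 5/5 converged, 5 correct
#> # A tibble: 5 x 8
#>   trial converged n_iter cc_final n_eta2     q aligned_cc success
#>   <int> <lgl>      <int>    <dbl>  <int> <dbl>      <dbl> <lgl>
#> 1     1 TRUE          11    0.606     49  1.32      0.835 TRUE
#> 2     2 TRUE          11    0.607     50  1.35      0.900 TRUE
#> 3     3 TRUE          19    0.608     56  1.51      0.787 TRUE
#> 4     4 TRUE          10    0.610     46  1.24      0.859 TRUE
#> 5     5 TRUE          10    0.606     54  1.46      0.828 TRUE
glance(batch)
#>   n_trials n_converged n_success mean_n_iter mean_q
#> 1        5           5         5        12.2   1.38
```

Every trial converges in 10–19 iterations (`n_iter`), the CC<sub>M</sub>
trace ends on its post-jump plateau (`cc_final` ≈ 0.61), the iteration-2 peak
count over N gives Q ≈ 1.2–1.5 (the recommended operating range for
t<sub>η</sub> = 3.7), and the origin/enantiomorph-aligned map correlation
with the true structure (`aligned_cc` ≈ 0.8–0.9, threshold 0.7) marks all
five as correct solutions.  `autoplot(batch)` draws the CC<sub>M</sub> traces;
`tidy(batch$trials[[1]])` exposes a single trial's per-iteration log.

The same workflow is scriptable from the shell via `inst/cli/smipp`
(`simulate`, `phase`, `score`, `bench` subcommands; see the file header).

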