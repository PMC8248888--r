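---
title: "Dual-space phasing with inner-pixel preservation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-space phasing with inner-pixel preservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smipp)
```

## The model and its assumptions

The package recovers structure-factor phases from normalized moduli $|E_K|$
alone, for crystals in P1 at atomic resolution.  The underlying variational
idea is a phasing residual

$$R_M(\Phi) \;=\; \int_V \bigl(\delta_M(\Phi) - k\,|\rho(\Phi)|\bigr)^2\,dV ,$$

where $\rho(\Phi)$ is the density synthesized from $|E_K|e^{i\varphi_K}$,
$|\rho|$ is obtained through the three-valued sign mask $m_\rho$
($|\rho| = m_\rho\,\rho$), and $\delta_M$ is the origin-free difference
synthesis with coefficients $(|E_K|-\langle|E|\rangle)e^{i\alpha_K}$ carried
on the phases $\alpha_K$ of $\mathcal{F}\{|\rho|\}$.  Because $\sum_K
(|E_K|-\langle|E|\rangle)^2$ is fixed by the data, minimizing $R_M$ is the
same as maximizing the overlap $\int \delta_M\,|\rho|$, i.e. driving
$\delta_M$ and $|\rho|$ towards proportionality.  That proportionality is a
property of *atomic-resolution* data: resolved point-like atoms make $\rho$
and its modulus share shape.  The method is therefore expected to degrade
below roughly 1.2 Å resolution, and the synthetic data used throughout reach
0.9–1.1 Å.

One iteration of the engine performs the cycle
$\varphi \to \rho \to (m_\rho, |\rho|) \to (|C|, \alpha) \to \delta_M \to
\eta = \delta_M m_\rho \to \varphi'$, with the phase update (a modified
tangent formula) taking only the angular part of $\mathcal{F}\{\eta\}$; the
amplitudes of that transform are never fed forward — the experimental $|E|$
are re-attached at the next synthesis.  The inner-pixel-preservation step
(ipp) sharpens $\eta$ between the product and the transform: every strict
26-neighbour local maximum above $t_\eta\sigma_\eta$ is located, and only the
$27$-voxel neighbourhoods (centre + 26 periodic neighbours) of the
$\min(N, N_\eta)$ strongest peaks survive.  No peak interpolation is used
anywhere; the procedure is deliberately voxel-quantized.

## CC~M~: the convergence statistic

The correlation between the experimental and calculated modulus functions is
implemented as the normalized inner product

$$\mathrm{CC}_M \;=\;
\frac{\sum_K (|E_K|-\langle|E|\rangle)\,|C_K|}
     {\sqrt{\sum_K (|E_K|-\langle|E|\rangle)^2}\,\sqrt{\sum_K |C_K|^2}} .$$

By Parseval this is (up to the out-of-band variance of $|\rho|$) the map
correlation between $\delta_M$ and $|\rho|$, which makes maximizing
CC~M~ *exactly* the complement of minimizing $R_M$.  We verified the
alternative — a Pearson correlation that also centres $|C_K|$ — and found it
inconsistent with $R_M$ on a two-atom scan: along a one-parameter phase
family through the true solution the centred statistic moves *with* the
residual instead of against it, so its maximum does not select the $R_M$
minimum.  The uncentred form does (the package tests assert this on the same
scan).  A consequence worth knowing: converged CC~M~ plateaus near 0.6 on the
packaged synthetic data; the absolute scale of the statistic depends on this
normalization choice, while its dynamics (plateau, then a jump of a few
hundredths over a few cycles at convergence) do not.

Convergence is detected from the CC~M~ trace alone: the first iteration $i
\ge 10$ with $cc_i - cc_{i-5} \ge 0.03$ that is followed by a plateau stable
within $0.008$ over the next (up to) five iterations.  The jump threshold
0.03 sits just below the typical converged jump; the stability window was
calibrated to the post-convergence wobble of the uncentred statistic
(about $\pm 0.007$ on the packaged scenarios — the earlier draft value 0.005
rejected genuine plateaus).  All three constants are `phasing_config()` keys.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `t_rho` | 2.5 / 2.6 / 2.8 | multiples of $\sigma_\rho$ | depth of the zeroed band in the sign mask, by scatterer class (weak / medium / strong) |
| `t_eta` | 3.7 | multiples of $\sigma_\eta$ | peak-acceptance threshold; 3.5–4.0 maps to $Q = N_\eta(2)/N$ of roughly 1.5–0.7, and $Q \approx 1$ is the recommended operating point |
| `e_min` | 1.0 (ipp) / 0 (plain) | $|E|$ units | reflections entering the $\rho$ synthesis; $\delta_M$ always uses all reflections |
| `n_atoms` (N) | — | atoms | peaks kept by ipp; the expected non-H count *including solvent*, estimated as $1.22\times$ the protein atom count when the water content is unknown (`solvent_expansion_factor()`) |
| `n_iter_max` | 1000 | iterations | trial budget |
| `oversample` | 3 | — | grid sampling rate: dims are the smallest 5-smooth integers $\ge$ oversample $\cdot$ edge / $d_\mathrm{min}$ |
| `jump`, `window`, `stability` | 0.03, 5, 0.008 | CC~M~ units / iterations | convergence detector (above) |
| `success_cc` | 0.7 | correlation | aligned-map threshold for calling a trial correct |

Oversampling deserves a note: 3 is not cosmetic.  At `oversample = 2` (the
Shannon floor) the 26-neighbour peak search sees aliased, blocky maxima and
the ipp variant stops converging on the packaged scenarios entirely; at 3 the
same trials converge routinely.  The floor is left available for pure
transform work.

## The synthetic-data generator

`scenario_spec()` / `generate_structure()` / `make_dataset()` emulate the
three scatterer classes on which the operating thresholds are defined: *weak*
(C/N/O only, default 30 atoms), *medium* (S sites among light atoms, default
60 atoms with ~4% S) and *strong* (Fe/Zn sites, default 60 atoms).  Atoms are
placed by rejection sampling with a periodic minimum distance (default 1.5 Å)
in a cubic cell sized to 20 Å³ per atom — the packing of real close-packed
organic and protein crystals (roughly 8–30 Å³ per non-H atom once solvent is
counted), which the constructor enforces.  This matters more than it looks:
in an artificially dilute cell (say 70 Å³ per atom) the peak-count diagnostic
$Q$ leaves its recommended range entirely ($Q \approx 5$) and random-start
convergence collapses to about half the trials, because the number of atoms
per resolution element — not the atom count — controls the relationship
between $N_\eta$ and $N$.  Moduli are computed by direct summation from
point atoms and are exact: no displacement factors, no measurement noise
(an optional Gaussian perturbation, `perturb_moduli()`, supports robustness
checks), no incompleteness, no disorder.  Passing tests on these data
demonstrate the algorithm's behaviour under its stated assumptions; they do
not show robustness to the error structure of measured intensities, to
missing outer shells, or to Wilson-scaling errors, all of which real data
add on top.

The engine-facing dataset is blinded — the reflection table carries `h, k,
l, E` only — and the true phases travel in a separate ground-truth object
consumed only by the validation module.

## Numerical choices

* **Fourier conventions.** $F_K = \sum_j w_j e^{+2\pi i K\cdot x_j}$, maps by
  $\rho(x) = V^{-1}\sum_K c_K e^{-2\pi i K\cdot x}$ over the full sphere;
  Friedel mates are stored implicitly and expanded only inside the grid
  synthesis.  $F(000)$ is always excluded, so every map is zero-mean and
  $\sigma$ is the RMS about zero (this fixes the meaning of every
  $t\cdot\sigma$ threshold).
* **Grids.** Voxel $(0,0,0)$ at fractional $(0,0,0)$, centres at $i/n$,
  periodic wrap; a synthesis refuses (naming the index) any reflection with
  $2|h|+1 > n$ on its axis.
* **Ties.** $\rho = 0$ and $\rho = -t_\rho\sigma_\rho$ belong to the mask's
  zero band; equal-valued $\eta$ peaks are ordered by lexicographic voxel
  index.  Both are measure-zero choices fixed for determinism.
* **Degenerate inputs.** A flat map is an error for the mask and the peak
  search; an empty peak list zeroes $\eta$ with a warning and the trial
  terminates immediately as unconverged (a *stall*) rather than erroring a
  batch.
* **Scoring.** Origin/enantiomorph alignment evaluates the translation
  correlation for all voxel shifts in one product transform, for the test
  phases and their conjugates; no sub-voxel refinement (adequate at
  oversample 3, where reflexivity returns 1.0 to machine precision).
* **Seeds.** A batch derives per-trial phase seeds from its `seed`, while
  shifted-modulus $u$ vectors come from a dedicated generator (`u_seed`), so
  the same $u$ sequence can be replayed across data sets and variants;
  matched comparisons (`compare_variants()`) reuse bitwise-identical start
  phases for both variants.

## Measured behaviour and limitations

The package's own acceptance runs (all problem sizes chosen to keep a full
run in minutes on one CPU) show, for the 30-atom weak scenario at 1.0 Å:
10/10 random-start ipp trials reach aligned map correlation $\ge 0.7$ within
500 iterations, converging in 10–20 iterations, while the plain variant's
matched-start trials do not fire the convergence detector within the same
budget (median censored at 500) — the ipp speedup is not subtle at this
scale.  A trial started at the true phases stays at the solution (aligned
correlation $\ge 0.9$ over 50 iterations) for the ipp variant on a 50-atom
crystal at 0.9 Å; the same quasi-fixed point is looser for the plain variant
(equilibrium near 0.75), and grazes 0.9 at 30 atoms / 1.0 Å — the fixed
point tightens with data richness, as the proportionality argument predicts.

One documented discrepancy: at these desk-scale sizes the *first-iteration*
peak count $N_\eta(1)$ does **not** reproduce the start-mode regimes reported
for large structures ($N_\eta(1) < N$ for random starts, $N_\eta(1) \gg N$
for shifted-modulus starts).  We measured the opposite ordering at every
size from 16 to 300 atoms, all three scatterer classes, and three defensible
conventions for the first iteration's $\rho$: shifted-modulus starts yield
$N_\eta(1)$ proportional to the number of *resolved* Patterson (modulus-map)
vector peaks above $3.8\sigma_\eta$, which stays below $N$ and falls further
with size as vector overlap drives the modulus map towards a Gaussian random
field, while random-start counts sit slightly above $N$.  The published
regime was observed on structures of several thousand atoms — a size this
package deliberately does not reach.  The corresponding acceptance check is
kept, and fails, as a faithful record of this limit rather than being
adjusted to pass.

Other non-goals: space-group symmetry beyond P1 (the algorithm is
mathematically extensible but not built here), Wilson scaling of measured
intensities (synthetic $|E|$ are exact by construction), structure-factor
extrapolation beyond the measured resolution, sub-voxel peak centroids, and
model building from the final map.  The mmCIF adapter is a best-effort text
parser for deposited structure-factor files (E- or F-type columns with
shell-wise normalization); binary MTZ is not read.

## A complete run

```{r example, eval = FALSE}
st  <- generate_structure(scenario_spec("weak", seed = 42))
ds  <- make_dataset(st, d_min = 1.0)
cfg <- phasing_config(n_atoms = expected_atom_count(30), n_trials = 5, seed = 1)
batch <- run_batch(ds$reflections, cfg, truth = ds$truth)
glance(batch)      # convergence, success and Q summary
autoplot(batch)    # CC_M traces, converged trials in black
autoplot(batch$trials[[1]])   # one trial's CC_M and N_eta traces
```
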