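---
title: "ICA-based real-time monitoring of fMRI networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ICA-based real-time monitoring of fMRI networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtica)
```

## The problem

Real-time fMRI feeds an estimate of a subject's ongoing brain activity back
into the experiment — for quality monitoring, brain-computer interfaces or
neurofeedback. Multivariate data-driven analysis by spatial independent
component analysis (ICA) is attractive here because it needs no explicit
hemodynamic model: the acquired data matrix $Y$ (time points $\times$
voxels) is modelled as a linear mixture

$$ Y = A X, $$

where the rows of $X$ are spatially independent source maps and the columns
of $A$ are their time courses. Estimating an unmixing matrix $W$ gives
source estimates $X = W Y$. `rtica` implements the full simulated real-time
pipeline around this model:

1. **Template ICA** on the complete series (all 220 volumes) yields the
   gold-standard network maps and courses used for evaluation.
2. A **functional localizer (FL)** — ICA on the first 60 volumes — is the
   only information available before monitoring starts. The target
   component is selected as the FL component whose map best matches a
   template (`select_target()`); templates themselves are labelled by
   correlating component time courses with the task regressors.
3. **Volume-by-volume monitoring** of the target component with one of four
   engines (below), each delivering an activation amplitude and a spatial
   map estimate at every TR.

## The four monitoring engines

**Back-projection (BP).** The FL map $x_{sel}$ is kept fixed and each new
volume $y$ is projected onto it through the pseudo-inverse,
$a = y\,x_{sel}^{\dagger}$, which for a single map is
$\langle y, x\rangle/\langle x, x\rangle$. No ICA runs during monitoring
(the package asserts this with an instrumentation counter), and several
maps can be monitored jointly by stacking them before the pseudo-inverse.
BP is exact whenever the target's spatial layout is truly stationary.

**Recursive temporally constrained (RTC).** A sliding window of the
$\Delta = 15$ most recent volumes is decomposed at every TR. The temporal
prior is the back-projected window course $a_n$ (window rows projected onto
the FL map); it seeds the first row of the whitened-space unmixing matrix,
and the whitening subspace is constructed to contain the prior's direction
(its normalized centered course plus the top $n-1$ residual principal
directions). This last point matters: on 15-sample windows a weakly
expressed component can fall below the noise floor of blind PCA, in which
case no initialization could recover it. After the symmetric fixed-point
iteration converges, the monitored component is re-identified as the one
whose map best correlates with the FL map (symmetric updates do not
preserve row order), and the amplitude is read from the last entry of its
window course with the window's DC level restored from the prior (the
decomposition is fitted on centered data, so its courses are mean-free
while the block paradigm's signal is mostly *in* the mean).

**Recursive spatially constrained (RSC).** One component is extracted from
the window by a one-unit fixed-point iteration constrained to the FL map:
the iterate starts at the projection of the reference onto the window's
whitened source space, is sign-anchored to the reference at every step, is
pulled toward the reference direction inside each update
(`constraint_strength`, default 0.9), and the returned map is finally
shrunk halfway toward the reference in map space (`reference_blend`,
default 0.5). The two-level constraint is deliberate: the subspace pull can
only reproduce the reference as well as the window's rank-5 source space
allows, while the map-space shrinkage suppresses spurious overlap with
co-localized sources that short windows cannot resolve. When the reference
is an exact source of the window both operations are no-ops at the fixed
point, so the constraint costs nothing in the ideal case. The amplitude is
the new volume projected onto the updated map, $a = y\,X_{new}^{\dagger}$.

**Recursive spatio-temporal (RSTC).** Three concatenated steps per TR:
(1) back-project the new volume onto the FL map (the localizer-space
amplitude $a_{FL}$); (2) run the temporally constrained window
decomposition and shrink the resulting component halfway toward the FL map
— the subject-space map $X_{sub}$ adapts to the new data while keeping the
localizer-defined characteristics as its target; (3) project the new volume
onto $X_{sub}$ for the subject-space amplitude. On stationary noiseless
data the subject space coincides with the localizer space and
$a_{sub} = a_{FL}$.

All window methods share a uniform warm-up: until $\Delta$ post-localizer
volumes exist, every method serves BP amplitudes. Windows are causal (the
$\Delta$ most recent volumes, both endpoints included) and advance one TR
per volume. A per-update `time_budget` can be set; an overrun records the
step as skipped, carries the previous map and falls back to BP onto it —
no step ever raises inside `run_session()`.

## Numerical core

FastICA runs in whitened space with parallel (symmetric) updates and the
`tanh` contrast by default (`pow3` and `gauss` are available). Symmetric
decorrelation $W \leftarrow (W W^\top)^{-1/2} W$ is computed in closed form
by eigen-decomposition; the classical iterative scheme
$W \leftarrow \tfrac{3}{2} W - \tfrac{1}{2} W W^\top W$ (with spectral
pre-normalization) is implemented as a cross-check and agrees to 1e-8.
Convergence is declared when $\max_i\,|1 - |\langle w_i^{new}, w_i\rangle||$
falls below the tolerance (default 1e-4, 200 iterations). Each voxel's
temporal mean and each volume's spatial mean are removed before whitening,
which makes the returned maps exactly zero-mean; unit population variance
and a non-negative-skewness sign convention are then folded into $W$ and
$A$, so `X = W %*% Yc` holds to machine precision and `A = pinv(W)`.
Inside the iteration a rank-collapsed update is handled by clamping the
decorrelation eigenvalues rather than aborting. Identification-phase fits
(`build_templates()`, `run_localizer()`) use three seeded restarts and keep
the fit with the highest total negentropy approximation — single runs of
FastICA occasionally settle in a local optimum, and the identification
phase is the foundation everything else depends on. All fits are bitwise
reproducible given data, configuration and seed; sliding-window steps
derive per-TR seeds from the session seed with a Lehmer-style stream.

Sign conventions deserve a note: maps are aligned to positive correlation
with their reference only when that correlation is meaningful (|r| > 0.2);
otherwise the non-negative-skewness convention applies. A weakly
overlapping reference would otherwise assign an essentially arbitrary —
and, for displaced activation, systematically inverted — sign to a
correctly recovered component.

## The synthetic study conditions

`simulate_subject()` builds BOLD-like data under the exact forward model
$Y = AX + E$ on a 12 × 12 × 6 grid (864 voxels), 220 volumes at TR = 1 s:

* **Paradigm**: 15 s right-hemifield stimulation, 5 s fixation, 15 s
  left-hemifield stimulation, 20 s fixation; the 55-s cycle repeats 4
  times. Task courses are the boxcars convolved with a canonical
  double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6), standardized.
* **Networks**: mirrored lateral Gaussian blobs for the right/left
  visuo-motor task networks; a *deliberately distributed* midline blob pair
  for the DMN analogue — its broad, near-Gaussian (low-kurtosis) map
  together with its slow anti-correlated course (a sinusoid at the 55-s
  cycle period, phase-picked to anti-correlate with the combined task
  regressor) makes it the hardest network for windowed ICA, reproducing
  the qualitative difficulty of tracking resting-state networks through a
  short window; and two compact nuisance blobs confined to the inferior
  slices (vascular/CSF-like), clear of the task plane. All maps are
  standardized and redrawn (nuisance only) until every pairwise |r| ≤ 0.3.
* **Noise**: voxelwise white Gaussian noise, `noise_sd` relative to the
  unit-variance signals; `noise_sd = 1` is the reference level, at which
  offline FastICA (order 5, three restarts) recovers all five maps at
  matched |r| ≥ 0.95. Optional spatial smoothing of the noise is available
  for harder regimes (off by default).
* **Drift**: an optional schedule translates one network's blob by a fixed
  step every *k* TRs, retaining the instantaneous true maps
  (`true_map_at()`). The scripted adaptivity scenario uses a 16 × 16 × 12
  grid with a 1-voxel step every 20 TRs, so a single-voxel step is small
  relative to the blob radius, as it would be at acquisition resolution;
  on the default desk grid one voxel is a third of the blob radius and the
  same schedule sweeps the blob across the whole field of view.

What the generator does *not* emulate: scanner noise spectra and
autocorrelated physiological noise, motion, spatially varying smoothness,
susceptibility dropout, and genuinely non-stationary network shapes beyond
rigid translation. Passing tests therefore demonstrate correctness of the
algorithms under the stated linear-mixing conditions, not performance on
real acquisitions.

## Evaluation protocol

`score_session()` reports the two headline metrics: the mean over monitored
TRs of the spatial correlation between the per-TR dynamic map and a
reference map, and the single Pearson correlation between the amplitude
series and the reference course restricted to the monitored TRs (a per-TR
temporal correlation is undefined). `evaluate_all()` runs the full
factorial — subjects × methods × networks × repeated runs with varying
algorithm seeds — against either the observable template references (as
with real data) or the generator's ground truth; `summarize_evaluation()`
reduces it to the three variability tiers: across repeated trials
(stochastic), across subjects, and across networks. Component matching for
recovery scoring is the permutation maximizing total matched |r|
(exhaustive to 8 components, greedy beyond). Compute times are recorded
per step and reported descriptively; they are never test assertions, being
hardware-bound.

Default problem sizes keep every analysis interactive: a full four-method
comparison on one synthetic subject takes well under a minute, and the
complete stability factorial (four methods × three networks × ten repeated
runs) a few minutes on one core.

## Design choices on genuinely open points

* **Selection metric**: template/FL matching uses Pearson correlation over
  all in-mask voxels of the signed standardized maps; a Dice overlap of
  |z|-thresholded supports (`dice_overlap()`) is provided as an alternative
  descriptive metric but does not drive selection.
* **Window placement**: windows are strictly causal; a centered window
  would require future volumes. Monitoring windows use only
  post-localizer volumes, with the uniform BP warm-up described above.
* **RTC amplitude**: read from the component's window time course (with
  the DC restoration); projection of the volume onto the updated map is
  the RSC/RSTC convention. Both are exposed through the per-step results,
  and the logged `dynamic_map` makes every amplitude replayable offline.
* **Voxel variance**: voxels are mean-centered but not variance-normalized
  before ICA (`center_voxels` is switchable); the synthetic data carry
  meaningful amplitude differences between networks that normalization
  would distort.
* **Convergence edge cases**: budget or iteration exhaustion returns the
  last iterate flagged `converged = FALSE` — never an exception — and an
  infeasible spatial constraint (reference orthogonal to the window's
  source space) is flagged the same way with a best-effort map.

## Known limitations

The temporally constrained engine's map estimate is noticeably noisier
than its amplitude estimate (the amplitude benefits from the DC
restoration; the map is a raw 15-sample ICA estimate). Under stationary
conditions back-projection dominates every dynamic method, as expected —
the dynamic engines only pay off when the spatial layout genuinely
changes. Tracking fails for any method once a drifting network no longer
overlaps the localizer map; the recursion is anchored to the localizer by
construction, so the package tracks *through* gradual drift but cannot
re-acquire a target that has moved entirely away. Finally, all guarantees
are calibrated at the reference noise level on the stated grid; harsher
regimes degrade gracefully but the numeric thresholds quoted above apply
to those conditions only.
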