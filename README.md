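# rtica

Simulated real-time monitoring of a target independent component in fMRI.

Real-time fMRI systems — quality monitoring, brain-computer interfaces,
neurofeedback — need a per-volume estimate of how strongly a brain network
of interest is active *right now*. `rtica` implements a fully data-driven,
ICA-based pipeline for that problem and the tools to evaluate it. It is
aimed at methods researchers who want a reproducible test bed for
sliding-window ICA monitoring strategies without scanner infrastructure.

## The model

Spatial ICA models the acquired data matrix (time points × voxels) as a
linear mixture

```
Y = A X,          X = W Y
```

where rows of `X` are spatially independent source maps (unit variance,
zero mean over voxels) and columns of `A` are their time courses. The
pipeline has three stages:

1. **Template ICA** over the full series — gold-standard maps/courses for
   evaluation (`build_templates()`).
2. **Functional localizer (FL)**: ICA on the first 60 volumes;
   `select_target()` picks the component whose map best matches a template.
3. **Monitoring**, one volume at a time, with four engines
   (`run_session()`):
   - **bp** — static back-projection: `a = y x_sel†` (pseudo-inverse of the
     fixed FL map); no ICA at run time; several maps monitorable jointly.
   - **rtc** — recursive temporally constrained: window FastICA (15 TRs,
     model order 5) seeded by the back-projected window course.
   - **rsc** — recursive spatially constrained: one-unit extraction
     constrained to the FL map; amplitude `a = y X_new†`.
   - **rstc** — recursive spatio-temporal: back-project (localizer space),
     temporally constrained window ICA (subject-space map), project onto
     the updated map (subject-space amplitude).

A synthetic BOLD generator (`simulate_subject()`) reproduces the study
conditions — a 55-s four-segment visuo-motor block paradigm repeated 4×
(220 volumes, TR = 1 s), two lateralized task networks, a slow
anti-correlated DMN-like network, two nuisance sources, white Gaussian
noise — and retains the ground truth, so every method is testable without
external data. Evaluation utilities compute the spatial/temporal
correlation metrics, optimal component matching, run-to-run stability, and
the full subjects × methods × networks × runs factorial.

## Worked example

```r
library(rtica)
library(dplyr)

sub <- simulate_subject(synthetic_spec(noise_sd = 1, seed = 1))
sub
#> <volume_series> synthetic-seed1: 220 volumes x 864 voxels, grid 12x12x6, TR 1 s
#>   networks: RVMT, LVMT, DMN, N1, N2; noise_sd = 1

tset <- build_templates(sub$series, ica_config(model_order = 5, seed = 7),
                        regressors = sub$truth$regressors,
                        reference_courses = cbind(DMN = sub$truth$dmn_reference))
fl <- run_localizer(sub$series, fl_length = 60, config = ica_config(5, seed = 8))
target <- select_target(fl, tset$templates$RVMT)
target
#> <target_ic> RVMT: component 1, selection score 0.987, 864 voxels

session <- run_session(sub$series,
                       monitor_config("rstc", ica = ica_config(5, seed = 42)),
                       target)
glance(session)
#> # A tibble: 1 × 5
#>   method n_trs n_skipped n_warmup mean_compute_s
#>   <chr>  <int>     <int>    <int>          <dbl>
#> 1 rstc     160         0       14         0.0287

score_session(session, tset$templates$RVMT$spatial_map,
              tset$templates$RVMT$time_course)
#> # A tibble: 1 × 4
#>   spatial_r temporal_r mean_compute_s prop_skipped
#>       <dbl>      <dbl>          <dbl>        <dbl>
#> 1     0.857      0.931         0.0287            0
```

The localizer found the right visuo-motor component (map correlation 0.987
to the gold-standard template). Monitoring the remaining 160 volumes with
the spatio-temporal engine, the estimated activation time course correlates
at 0.93 with the template course and the per-TR map estimates average 0.86
spatial correlation to the template map — at ~29 ms per update, far below
the 1-s TR. `autoplot(session, reference = ...)` overlays the estimated and
reference courses; `evaluate_all()` + `summarize_evaluation()` run the full
method × network comparison with stability summaries.

A thin command-line interface wraps the same functions:

```sh
inst/cli/rtica simulate --seed 1 --out-dir out/
inst/cli/rtica monitor --method bp --target rvmt --seed 1 --out out/bp.csv
inst/cli/rtica evaluate --subjects 3 --n-runs 10 --seed 1 --out-dir out/
```

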