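# sweepvep

Simulation and analysis of **sweep steady-state visually evoked
potentials (SSVEPs)** for dichoptic-motion experiments: the class of EEG
studies that measure displacement response functions for in-phase vs
anti-phase binocular motion, isolate motion-in-depth cues (changing
disparity vs interocular velocity differences), and quantify
*stereo-movement suppression* as a rightward shift of the response
function along the displacement axis.

The package is aimed at visual electrophysiologists who want a tested,
fully synthetic-data-driven implementation of this analysis chain — for
method development, power exploration, and teaching — and at anyone who
needs its components (harmonic coefficient estimation, reliable
components analysis, complex-domain group statistics) separately.

## What it implements

A periodic dichoptic stimulus at `f = 2` Hz steps its dot displacement
through ten log-spaced values (0.5–16 arcmin adult, 2–32 infant) within
a 10-s trial, one value per 1-s bin. Per bin, complex SSVEP coefficients
at harmonics 1F–4F are estimated, spatially filtered, vector-averaged,
and summarised by the Naka–Rushton function

    R(d) = Rmax * d^n / (d^n + d50^n) + b

with free parameters `Rmax` (saturation, µV), `d50` (displacement at
half-maximum, arcmin), exponent `n > 0`, and baseline `b`. The
anti-phase/in-phase ratio of fitted `d50` is the suppression index.

Modules, mirroring the stages of the pipeline:

| stage | key functions |
|---|---|
| synthetic data | `sweep_protocol()`, `condition_spec()`, `ground_truth_response()`, `synthesize_trial()`, `inject_artifacts()`, `generate_cohort()` |
| preprocessing | `bandpass_filter()`, `resample_to_420()`, `detect_bad_sensors()`, `interpolate_sensors()`, `rereference_common_average()`, `segment_epochs()`, `reject_epochs()`, `preprocess_trial()` |
| harmonic extraction | `rls_coefficients()` (recursive least-squares adaptive filter), `dft_coefficients()` (per-bin projection oracle), `sideband_noise()`, `extract_coefficients()` |
| reliable components | `rca_input()`, `fit_rca()` (generalized eigendecomposition of cross-trial vs pooled covariance), `project_through()`, `explained_summaries()`, `pool_participants()` |
| statistics | `vector_average()`, `displacement_average()`, `projected_amplitude()`, `paired_t_comparison()`, `condition_comparison()`, `noise_floor()` |
| response fitting | `nr_eval()`, `fit_nr()`, `suppression_index()` |
| orchestration & I/O | `run_pipeline()`, `pipeline_config()`, `analyze_cohort()`, `write_edf()`/`read_edf()`, `write_container()`/`read_container()` |

All analysis stages run on synthetic recordings with known planted
structure; no external data are required anywhere, including in the
tests.

## Worked example

Simulate a small cohort (6 participants, in-phase and anti-phase
full-cue/full-reference conditions, 4 trials each, 32 channels), run
the full chain, and read the result tables:

```r
library(sweepvep)
out <- file.path(tempdir(), "demo")
run_pipeline(list(n_participants = 6, n_trials = 4, n_channels = 32,
                  seed = 7, estimator = "rls", out_dir = out))
read.csv(file.path(out, "fits.csv"))
```

```
                                    condition rmax  d50 n_exp     b  suppression_index_vs_first
1   in_phase/corr+1/full/horizontal/one_sided 1.29 2.72  2.33 0.416                          NA
2 anti_phase/corr+1/full/horizontal/one_sided 1.45 4.88  2.93 0.188                         1.8
```

The generator plants an anti-phase `d50` shift of ×2; the fitted
suppression index of **1.8** recovers it from 48 noisy synthetic trials.
The displacement-average comparison (from `comparisons.csv`) shows the
suppression is statistically detectable even in this small demo:

```
       bin      t df       p      d
11 average  4.066  5 0.00967  1.660
```

i.e. in-phase exceeds anti-phase on the displacement average with
t(5) = 4.07, p = 0.0097, Cohen's d = 1.66. `group_vectors.csv` holds the
underlying response function — vector-averaged amplitude and SEM per
displacement bin (first condition shown):

```
   bin displacement amplitude    sem
1    1        0.500     0.318 0.2140
2    2        0.735     0.625 0.2131
...
9    9       10.886     1.826 0.1675
10  10       16.000     1.475 0.1517
```

The amplitude rises from the noise floor and saturates with increasing
displacement — the saturating displacement response function the
Naka–Rushton fit summarises. A YAML-driven command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

## Documentation

The methods vignette (`vignettes/sweep-ssvep-methods.Rmd`) documents the
generative model and its defaults, the preprocessing thresholds and
their strictness, both coefficient estimators and their equivalence
guarantee, the RCA formulation (including why second moments are used
uncentered and how the eigenproblem is regularized), the complex-domain
statistics, the fitting procedure, and known limitations.
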