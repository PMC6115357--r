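---
title: "Sweep SSVEP analysis of dichoptic motion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweep SSVEP analysis of dichoptic motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepvep)
```

## The measurement problem

When a visual stimulus modulates periodically, visual cortex produces a
steady-state visually evoked potential (SSVEP): EEG power concentrated at
exact integer multiples (harmonics) of the stimulation frequency, with a
response phase that is stable across repeated presentations of the same
stimulus. In the sweep variant of the paradigm, one stimulus parameter —
here the displacement of coherently moving random dots, in arcmin — is
stepped through a ladder of values within a single trial, one value per
1-s bin. The harmonic amplitude per bin then traces out a *displacement
response function* in a few tens of seconds of recording.

The dichoptic designs this package models present moving dot bands
independently to the two eyes. The interocular temporal phase of the
motion (0° vs 180°), the interocular correlation of the dots (+1, 0, −1),
the state of the flanking non-moving reference bands (static dots, noise
dots, blank), and the display orientation together determine which
binocular mechanisms can respond. Two regularities of such data organise
everything downstream:

* **Harmonic symmetry.** Leftward and rightward (or towards/away)
  excursions of a symmetric stimulus are interchangeable, so the response
  contains only even harmonics (2F, 4F of a 2 Hz stimulus). An
  *asymmetric* perceptual alternation — e.g. anti-phase horizontal motion
  that alternates between a segmented-in-depth and a flat percept — adds
  odd harmonics, chiefly 1F. The 1F response disappears whenever the
  asymmetry is broken: uncorrelated or anticorrelated dots, no static
  reference, or a trajectory that straddles zero disparity
  symmetrically. `expected_harmonic_signature()` encodes exactly this
  logic and the generator enforces it (odd-harmonic amplitudes are
  *exactly* zero for symmetric configurations).
* **Anti-phase suppression.** Responses to anti-phase (motion-in-depth)
  stimulation are weaker than to in-phase motion, expressed as a
  rightward shift of the displacement response function. The package
  quantifies this as the ratio of half-saturation displacements,
  `suppression_index()`.

## The generative model

`synthesize_trial()` builds a channels × time trial in which, within bin
$k$ at displacement $d_k$, channel $c$ carries

$$x_c(t) = \sum_{h=1}^{4} A_h(d_k)\, w_c(h) \cos(2\pi h f t + \varphi_h)
  + \eta_c(t),$$

where the per-harmonic amplitude follows the Naka–Rushton
(hyperbolic-ratio) function

$$A_h(d) = R_{\max}\frac{d^n}{d^n + d_{50}^n} + b,$$

$w(h)$ is a fixed unit-norm scalp topography (a Gaussian on the sphere
around a parieto-occipital centre), and $\varphi_h$ is a fixed response
phase. Phase is locked to the trial clock, so repeated trials are
coherent — the property that both reliable components analysis and
vector averaging exploit.

Key generator parameters and their defaults:

| parameter | default | meaning |
|---|---|---|
| `f_stim` | 2 Hz | monocular apparent-motion rate |
| `n_bins`, `bin_duration` | 10 × 1 s | sweep ladder; 2 stimulus cycles per bin |
| `d_min`–`d_max` | 0.5–16 arcmin (adult), 2–32 (infant) | geometric displacement grid |
| `fs` | 420 Hz | analysis sampling rate (seven samples per 60 Hz frame) |
| 2F parameters | $R_{\max}=3\,\mu V$, $d_{50}=2'$, $n=2$, $b=0$ | dominant motion response |
| 4F, 1F $R_{\max}$ | 1.5 µV | secondary responses |
| `suppression_d50_factor` | 2 | anti-phase $d_{50}$ multiplier, **even harmonics only** |
| `reference_rmax_factor` | 0.5 | $R_{\max}$ multiplier for noise/absent reference |
| `n_trials` | 15 | trials per condition per participant |
| `amp_sd`, `topo_jitter` | 0.1, 0.05 | participant-level variation |

The amplitudes are of the order of a few microvolts and the Naka–Rushton
half-saturations sit in the low-arcmin range so that the adult sweep
spans the rise and saturation of the function; the suppression and
reference modifiers express the qualitative condition effects the design
exists to detect. The anti-phase $d_{50}$ shift is applied to the even
(motion) harmonics only: the odd-harmonic component indexes the
alternation of global perceptual organisation, a different mechanism
with its own parameters, and coupling it to the motion shift would push
most of its response outside the sweep range. The infant preset instead
makes anti-phase responses *larger* than in-phase
(`infant_antiphase_rmax_factor`) and removes reference sensitivity,
matching the qualitatively different infant regime.

**Noise model.** Background EEG is modelled as `n_sources` independent
$1/f^{\alpha}$ processes ($\alpha = 1$) mixed through random smooth
topographies (spatially correlated, average per-channel RMS 8 µV) plus
independent white sensor noise (3 µV RMS). This captures the two
features that matter to the pipeline — spatial correlation, which makes
naive channel averaging suboptimal and gives RCA something to do, and a
red spectrum, which makes low-harmonic coefficients noisier than high
ones. It does **not** emulate alpha rhythms, non-stationarity,
electrode drift, or muscle artifact spectra; passing tests therefore
demonstrate correctness of the estimators and statistics under a
plausible noise field, not robustness to every pathology of real EEG.
Blinks, spikes and bad channels are injected separately and
deterministically (`inject_artifacts()`), with an exact ledger so the
rejection rules can be verified sample-by-sample.

## Preprocessing

`preprocess_trial()` fixes the stage order: band-pass filter → resample
to 420 Hz → bad-sensor detection and interpolation → common-average
re-reference → segmentation into 1-s epochs → epoch rejection.

* The 0.3–50 Hz filter is a zero-phase 4th-order Butterworth band-pass
  applied twice in cascade. Zero-phase (forward–backward) filtering is
  obligatory here because the statistics live in the complex domain: a
  causal filter would rotate coefficient phases by a
  frequency-dependent amount. Channels are demeaned before filtering so
  the slow 0.3 Hz corner does not ring on the DC offset.
* Resampling 500 → 420 Hz uses polyphase rational resampling (21/25)
  with anti-aliasing.
* All rejection thresholds are *strict* inequalities, matching their
  "more than" definitions: a sensor is excluded if >15 % of samples
  exceed the amplitude threshold (30 µV adult; 30–100 µV accepted for
  infants); a channel-epoch is rejected if >10 % of samples exceed
  30 µV or any sample exceeds 60 µV; an epoch is rejected for *all*
  channels if more than seven sensors violate the peak threshold.
  Boundary equality (exactly 15 %, exactly 10 %, exactly 7 sensors)
  does not trigger, and the tests pin these boundaries.
* Interpolation replaces a bad channel by the arithmetic mean of its six
  nearest good channels (Euclidean distance in 3-D montage coordinates,
  ties broken by channel index). The bad-sensor rule is evaluated per
  recording; other groupings can be composed from the primitives.

The montage itself is synthetic: a spherical-Fibonacci layout with the
channel count of a high-density net (128 adult / 124 infant), not the
true coordinates of any commercial product. Only distances enter the
analysis, so the layout's role is purely geometric.

## Harmonic extraction

Two estimators produce complex coefficients per harmonic × bin ×
channel, and every result must be invariant to the choice:

* `dft_coefficients()`: least-squares projection of each 1-s bin onto
  cos/sin pairs — identical to the scaled DFT bin because every target
  and sideband frequency completes an integer number of cycles per bin.
  The convention is $c = \frac{2}{N}\sum_t x(t) e^{-i2\pi ft}$, so a
  cosine of amplitude $A$ and phase $\varphi$ gives $c = Ae^{i\varphi}$.
* `rls_coefficients()`: a joint multi-frequency exponentially weighted
  recursive least-squares adaptive filter over regressors
  $\{\cos 2\pi f t, \sin 2\pi f t\}$ at all target and sideband
  frequencies simultaneously, forgetting factor
  $\lambda = 1 - 1/M$ with memory $M$ equal to the 1-s bin length,
  inverse-covariance initialisation $P_0 = 10^4 I$, read out at each
  bin's final sample. Because the regressor Gram matrix is shared, one
  $P$ recursion serves all channels. The cited adaptive-filter
  literature admits several variants; this implementation is pinned by
  an oracle-equivalence guarantee instead of bit-compatibility claims:
  on stationary input the two estimators agree to $10^{-6}\,\mu V$
  after three memory constants, and to a fraction of a percent under
  noise.

The first bin of an RLS run is flagged as burn-in (`burn_in_bin`): the
filter starts cold and its bin-1 estimate mixes transient with signal.
Group statistics nevertheless use all ten bins, matching the apparent
use of all bins in practice; the inverse-SEM weighting of the
response-function fits naturally down-weights the noisier first bin.

Noise is estimated at the two sidebands $f \pm 1$ Hz of each harmonic,
computed from the same samples with the same estimator. The scalar
per-bin noise level is the incoherent mean of the two sideband
amplitudes (`noise_floor()`); the complex sideband coefficients are also
retained and travel through the same spatial filtering and averaging as
the signal, which is what makes group-level signal/noise comparisons
fair (see below).

## Reliable components analysis

RCA finds sensor weightings $w$ maximizing trial-to-trial consistency
via the generalized eigenproblem $R_{xy} w = \rho\, R_{pool} w$, where
$R_{xy}$ averages $X_i^\top X_j$ over all ordered pairs of distinct
trials within a condition cell (rows = stacked re/im coefficient
vectors per epoch, matched by displacement bin) and $R_{pool}$ averages
$X_i^\top X_i$. With this normalisation $\rho \in [-1, 1]$ reads as a
trial-to-trial correlation; identical trials give $\rho_1 = 1$ exactly.

Choices worth making explicit:

* **No mean removal.** The across-trial mean *is* the phase-locked
  response; centering would subtract precisely the signal whose
  consistency is being maximized (a trial-identical component would
  collapse to $\rho \approx 0$). Second moments are therefore used
  uncentered.
* **Row-wise pairing.** Each (epoch, re/im) row is paired across
  whichever trials of the condition cell have that epoch valid, rather
  than requiring complete cases across all trials — one rejected epoch
  in one trial must not empty a cell.
* **Regularization.** The eigenproblem is solved in the top-`rank`
  principal subspace of $R_{pool}$ (default 60, capped at the
  numerically supported rank — common-average referencing alone costs
  one dimension). This is the standard stabilization for
  128-channel data.
* **Sign and selection.** Each weight column is scaled so its
  largest-magnitude entry is positive; amplitudes are sign-invariant.
  RC1 is the default analysis component; `component` overrides it for
  cases like the infant regime where a later component carries the
  adult-like topography.
* **Definitional summaries.** `reliability_explained` ($\rho_k$ over
  the sum of non-negative eigenvalues in the subspace) and
  `variance_explained` (variance of the rank-1 forward-model
  reconstruction over total variance) are this package's definitions —
  the quantities are conventionally reported without formulas. The
  forward-model form is used because whitened weights make the raw
  projection variance identically 1.
* **Training harmonic.** Components are fitted per harmonic, pooling
  all conditions of an experiment. Weak harmonics (1F at synthetic desk
  scale, where only a quarter of trials carry any 1F signal over
  spatially correlated noise) cannot be trained directly; the
  `rca_harmonic` argument lets the 2F-derived first component serve as
  the spatial filter for 1F data, mirroring the established practice of
  reusing first-RC weights across recordings that share stimulus
  parameters.
* **Pooling across experiments.** `pool_participants()` keeps only the
  first session of a participant who appears in several experiments.

## Group statistics in the complex domain

Because response phase is consistent across participants, coefficients
are averaged as complex numbers (*vector averaging*) and the amplitude
is taken last; incoherent noise cancels instead of rectifying into a
positive bias. Displacement averages are computed within participant
first (complex mean across the ten bins), then vector-averaged across
participants — the order matters under unbalanced validity and weights
participants equally.

Error bars and tests use *projected amplitudes*: the signed scalar
projection of each participant's coefficient onto the unit group-mean
vector, $p_i = \mathrm{Re}(x_i \bar y^* )/|\bar y|$. The group mean
includes the projected participant; that convention is forced by the
identity (held to $10^{-12}$ in the tests) that the mean of the
projections equals the group vector-average amplitude. Paired two-tailed
t tests on projected amplitudes compare conditions per bin and for the
displacement average; per-bin p values are reported uncorrected
alongside the displacement average (a Bonferroni option exists, off by
default), and Cohen's d for paired samples is the effect size.

Group-level noise floors deserve one subtlety: the per-bin incoherent
sideband average (`noise_floor()`) describes single-trial noise, which
no group vector-averaged signal should be compared against directly.
For signal-versus-noise contrasts, `analyze_cohort()` therefore also
pushes the sideband coefficients through the *identical* trial-mean /
vector-average chain as the signal (`noise_coefficients`), so the floor
enjoys the same $\sqrt{n}$ averaging gains and the comparison is
like-for-like.

## Response-function fitting

`fit_nr()` fits the four-parameter Naka–Rushton function by bounded
weighted least squares (L-BFGS-B) from a deterministic multi-start grid
($d_{50}$ at the displacement-grid quartiles × $n \in \{0.5, 1, 2,
4\}$), reporting the best converged start. Bounds:
$R_{\max} \in [0, 10\max(y)]$, $d_{50} \in [0.1 d_{\min}, 10 d_{\max}]$,
$n \in (0, 6]$, $b \in [0, \max(y)]$ — the baseline cannot be negative
because amplitudes are magnitudes. Inverse-SEM weights are used when
group SEMs are available, otherwise the fit is unweighted; noise-floor
subtraction before fitting is available but off by default, since fits
serve to summarise response functions rather than to estimate
thresholds. Flat data return a flagged degenerate solution
($R_{\max} \to 0$), which `suppression_index()` refuses to use.

## Problem sizes and what the checks do (and do not) show

The package's own acceptance checks run entirely on synthetic data at
these sizes, chosen once as the smallest configurations that exercise
the study design faithfully:

* end-to-end suppression recovery: 15 participants × 2 conditions ×
  15 trials (the design's trial count), 128 channels — the recovered
  index falls in a band around the planted ×2 shift;
* the 1F symmetry signature: 15 participants × 4 conditions ×
  15 trials at 64 channels (the contrast does not depend on channel
  count);
* statistical power and type-I calibration: 200 and 500 cohorts
  simulated at the coefficient level (`simulate_coefficient_cohort()`),
  since the t statistics operate on coefficients and the time-domain
  stages are validated separately.

These checks certify the estimators, the spatial filtering, the
complex-domain statistics and the fitting machinery against known
ground truth. They do not certify performance on real recordings —
real EEG departs from the noise model in the ways listed above, and the
planted effect sizes, while plausible, are choices. The pipeline's
outputs on real data should be read with the same care as any
exploratory SSVEP analysis.

## Known limitations

* No ICA or regression-based artifact correction; cleaning is
  threshold-based rejection and interpolation only.
* The EDF writer/reader covers the subset needed here (one data record,
  uniform rate, 16-bit). The binary `.f64` + JSON sidecar container is
  the lossless interchange format.
* Psychophysical threshold estimation (method of limits) and
  response-function extrapolation to threshold are out of scope.
* Infant analyses are expressed through configuration (124-channel
  montage, 2–32 arcmin grid, infant presets, component override), not a
  separate code path.
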