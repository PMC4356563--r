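---
title: "Methods: combined EEG/MEG deviation scanning on a digital phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined EEG/MEG deviation scanning on a digital phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, defaults and numerical decisions behind
`emegscan`. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The forward model

The head is a concentric four-shell sphere (brain, CSF, skull, scalp) with
default radii 79/82/87/92 mm and conductivities 0.33, 1.79, 0.0024 and
0.43 S/m. The skull value doubles as the ground truth for the calibration
study; 0.0024 S/m is a plausible compact-bone conductivity, deliberately low
so that EEG is strongly sensitive to it. Coordinates are head-centred RAS in
millimetres, origin at the sphere centre, left hemisphere x < 0.

**EEG.** The scalp potential of a current dipole is the exact multilayer
Legendre series. For each degree n the seven unknown shell coefficients
solve a linear system (potential and radial-current continuity at the three
interior interfaces, insulating outer boundary, unit source coefficient in
the innermost shell). Two numerical points matter:

* the raw system mixes `s^n` and `s^-(n+1)` terms whose spread reaches
  10^27 at n = 200; rows and columns are equilibrated before solving, which
  amounts to a per-shell nondimensionalization and keeps the solve
  well-conditioned at every degree;
* the series is truncated adaptively when the next term falls below 1e-10
  of the accumulated sums, with a hard cap of 200 degrees. For the deepest
  default sources the geometric ratio b/R ≈ 0.8 makes 200 degrees far more
  than needed for that tolerance.

Per degree, the radial transfer coefficient is shared by the radial and
tangential dipole terms, so a source's three gain columns come from two
accumulated electrode sums. Potentials are average-referenced; the test
suite checks the column sums and the collapse to the homogeneous-sphere
closed form (derived independently from the Legendre generating functions,
with no truncation) when all conductivities coincide.

**MEG.** The field of a dipole in a spherically symmetric conductor is the
closed-form (Sarvas) solution, evaluated along each sensor's orientation.
It is conductivity-independent and exactly silent for radial dipoles —
both properties are asserted bitwise / to machine precision in the tests.
Sensors are point magnetometers oriented radially on a helmet sphere 25 mm
outside the scalp; real axial gradiometers reject distant fields better,
a difference absorbed into the noise level rather than modelled.

## 2. The digital phantom

`make_phantom()` builds the full study geometry:

* **Source space** — a cubic grid (default 8 mm here, 10 mm in the
  acceptance runs; 2 mm is the clinical-resolution target the grid
  parameter emulates, but a desk-scale study does not need it) restricted
  to the shell band 35–76 mm, covering both deep mesial and superficial
  lateral positions. Source normals blend the radial direction with a
  seeded random tangential component (≈ 44°): purely radial normals
  would silence MEG, purely random ones would be anatomically meaningless.
* **Sensors** — Fibonacci-lattice caps: 80 EEG electrodes exactly on the
  scalp shell, 275 MEG magnetometers on the helmet sphere.
* **Irritative zone** — a deep patch (seed (−32, 8, −14) mm, amygdala /
  hippocampus analogue ≈ 56 mm under the scalp) and a lateral patch (seed
  (−64, 28, −18) mm, temporal-pole analogue ≈ 20 mm deep), 12 mm radius
  each, disjoint by construction.
* **sEEG contacts** — five straight depth electrodes (A, HA, HP, TA, E)
  carrying the 24 interictal-measuring contacts, 8 of which (A1–3, HA1–5)
  are also ictal, plus 10 inactive contacts on two distant electrodes.
  Contacts are geometric validation points only; no intracranial signal is
  synthesized, which is exactly how the validation statistics use them.

## 3. Spike simulation

Each spike draws a log-normal amplitude (median 50 nAm, σ_log = 0.4) and
stochastic origins within 6 mm of each patch seed. The waveform is a smooth
biphasic template (20 ms rise, 30 ms fall, shallow slow wave); the deep
patch fires at onset, the lateral patch follows after the 30 ms propagation
delay with twice the amplitude, so the sensor-level peak is dominated by
propagated lateral activity while the onset reflects the deep origin.
Epochs are aligned to the EEG global-field-power maximum (the operational
"EEG spike peak"): on this phantom's timeline the deep component dominates
around −33 ms and the lateral component from about −13 ms onward, with a
trough near −23 ms where the deep wave has decayed and the lateral one has
barely started.

Noise is a mixture of spatially structured brain noise — 60 random dipoles
inside the source space with AR(1)-smoothed time courses (coefficient
0.95), projected through the leadfield — and white sensor noise, mixed at a
0.3 : 0.7 variance ratio and rescaled per channel to 2.5 µV (EEG) and
350 fT (MEG). These three numbers are the phantom's operating point, chosen
once so that the gating behaviour of the study is reproduced: single spikes
mostly fail the SNR > 3 gate away from the peak, Av10 subaverages pass it
from onset onward, and the structured component is strong enough to produce
the centre-ward bias of low-SNR localizations while leaving the fused scan
its onset-phase advantage. They are free parameters of the generator, not
measured quantities.

What the generator does **not** emulate: cardiac/ocular artifacts, sensor
drift or head movement, realistic cortical geometry, ictal activity, and
any spike-morphology variability beyond amplitude scaling. Passing tests
therefore demonstrate the internal consistency of the pipeline under the
stated noise model, not clinical performance.

## 4. Detection, subaveraging, SNR

Detection is centred normalized cross-correlation of a template (the mean
of ten marked spikes on the eight EEG channels nearest the lateral patch)
with a 200 ms refractory lockout; the statistic is scale-invariant, so
variable-amplitude spikes are found alike. The default threshold of 0.45
reflects the low single-spike SNR of the phantom; on noise-free insertions
the tests use 0.9 and recover insertions exactly.

Subaverage groups are Av1 (all single spikes) and Av5 … Av50 in steps of 5,
with 200 realizations per group; within one realization spikes are drawn
without replacement, across realizations they may recur. Realization r of
group k uses sub-seed `seed + 100000·k + r`, so any single realization is
reproducible in isolation.

The SNR statistic divides the channel-mean squared amplitude at the single
sample nearest the requested instant by the channel-mean per-channel
baseline variance (−200 to −70 ms). Two readings were open and are fixed
here: the "signal power at a time point" is a single sample, not a window;
and the noise variance is pooled across the modality's channels. The gate
is strictly greater than 3.

## 5. Scanning, fusion, calibration

The deviation scan solves the local three-column least-squares problem at
every source. Implementation: per-source 3×3 normal matrices are held as
six vectors and inverted by a vectorized adjugate; a source is flagged
rank-deficient when its determinant falls below 1e-8 × (largest diagonal)³
— the cancellation floor of the determinant itself — and is then re-solved
with an eigenvalue pseudo-inverse (cutoff 1e-10 of the largest eigenvalue).
Ties in the GOF map break to the lowest source index. A zero data vector is
an error (GOF undefined), not a zero.

MEG scans are Tikhonov-regularized with λ = 1e-3 × trace of the local
normal matrix: scale-invariant, and strong enough to stop the magnetically
near-silent quasi-radial direction from fitting noise with enormous
moments, while leaving well-posed fits essentially unchanged. EEG and
fused scans are unregularized. The winning moment is always re-solved
without regularization.

EMEG fusion divides every channel's data *and* leadfield row by that
channel's baseline noise SD and stacks EEG over left-hemisphere MEG. The
weighting uses amplitude (SD), not power: the fused quantity must remain
linear in the data for least-squares scanning. Channels with zero baseline
SD are dropped with a warning. Only MEG sensors with x < 0 enter MEG and
EMEG scans (strict inequality; midline sensors are excluded).

Calibration fixes the source location by scanning the trial-averaged
somatosensory MEG topography — valid because the MEG forward model is
conductivity-independent — then rebuilds the EEG gain at that location for
each candidate skull conductivity and returns the GOF-maximizing value. A
location-fix GOF below 0.5 triggers an "unreliable" warning. The
acceptance-scale study uses the 80-electrode array: with many fewer
electrodes the GOF differences between neighbouring conductivity candidates
approach the noise floor.

## 6. Validation statistics

Centroid dipoles are the arithmetic mean of member locations plus the
renormalized mean of member orientations, sign-aligned to the first member
(a dipole and its negation are the same source). Outlier pruning is a
single pass: remove members whose centroid distance strictly exceeds
mean + 2 SD, with the *population* SD — the rule is a filter, not an
estimator — and no re-iteration (an `iterate` flag provides the variant).
The SDI is `(100/N) Σ 1/(d²+1)`; the additive 1 pins perfect
colocalization at exactly 100. It is computed on SNR-gated, pre-pruning
sets by default, with a flag for post-pruning. Coverage uses the closed
10 mm ball by default (strict open-ball variant via a flag; on continuous
coordinates the boundary has measure zero).

The table-driven reproduction path (`reproduce_s1()`) re-derives all of
these statistics from dipole and contact tables alone. The package ships
*synthetic* tables (`inst/extdata/synthetic_s1_*.csv`, generated by the
phantom pipeline and named accordingly); previously deposited clinical
tables in the same schema can be substituted, and the corresponding
acceptance check documents the expected file location.

## 7. Problem sizes and study design choices

The simulation studies are sized for a single CPU: source grid 10 mm
(≈ 1700 positions), 100–200 spikes per run, 25–60 realizations per
subaverage group, 10 independent runs for the noise-bias comparison, 80
Monte-Carlo draws for the onset-phase modality comparison, 400 trials for
calibration. The noise-bias comparison is evaluated at −3 ms (late
propagation phase): that is where this phantom's single spikes pass the SNR
gate often enough for per-run Av1 centroids to be meaningful, and the
centre-ward bias is a property of low *relative* SNR, which Av1 retains at
every instant. The onset-phase comparison draws deep-patch sources with
noise scaled as an Av10 average, i.e. at gate-level SNR.

## 8. Known limitations

* The spherical forward models replace the calibrated six-compartment
  finite-element model of realistic workflows; absolute localization
  accuracies here do not transfer to real anatomy.
* Point magnetometers instead of synthetic gradiometers; no reference-array
  noise rejection.
* The spike template search assumes one dominant spike type; multifocal
  activity would need per-focus templates.
* Spreadsheet input is supported via `readxl`; spreadsheet *output* is not
  (CSV is the canonical write format).
* Pruning is intentionally not idempotent (single pass); its behaviour on
  multimodal clusters is governed by the flag, not re-iteration.
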