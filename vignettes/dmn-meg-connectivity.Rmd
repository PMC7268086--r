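---
title: "Beamformer-based DMN connectivity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beamformer-based DMN connectivity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megdmn)
```

## The scientific problem

Resting-state magnetoencephalography (MEG) measures the magnetic field of
neuronal currents with an array of sensors outside the head. In focal
epilepsies, the functional connectivity (FC) of the default mode network
(DMN) — posterior cingulate/precuneus, angular gyri, medial prefrontal and
anterior cingulate cortices, inferior temporal gyri — is a candidate
biomarker: patients show frequency-specific elevations of DMN coupling,
strongest in the gamma band and most pronounced between the left angular
gyrus (LAG) and the left posterior cingulate cortex (LPCC).

`megdmn` implements the full analysis chain needed to ask that question of
multichannel resting-state recordings:

1. **Preprocessing** — 50-Hz band-stop filtering, segmentation into
   consecutive 500-ms epochs, robust rejection of epochs containing spikes
   or artifacts, and random selection of a fixed number (default 40) of
   clean epochs.
2. **Source reconstruction** — a two-step minimum-variance (LCMV-style)
   beamformer over a 6-mm volumetric grid in a spherical conductor model,
   with voxel-based partial sensor coverage, per-voxel orientation
   estimation, a scalar beamformer, and accumulated source imaging
   (the volumetric summation of |Q(r,t)| over time).
3. **Connectivity** — Pearson correlation of band-limited source signals at
   12 DMN seed regions (alpha 8–13 Hz, beta 14–30 Hz, gamma 31–80 Hz),
   pooled over epochs by Fisher z averaging, plus graph node degree at a
   correlation threshold (default 0.3).
4. **Group statistics** — per-pair and per-node two-sided pooled-variance
   t-tests between two cohorts, significant-pair counts per band (with a
   Benjamini–Hochberg column reported alongside the uncorrected counts),
   Spearman correlations against clinical covariates, and a clinical cohort
   summarizer.

Because no recordings ship with the package, a first-class synthetic cohort
generator produces sensor recordings with *known* ground-truth coupling, so
every stage can be verified against the generative model.

## The forward and inverse models

**Head model.** The conductor is a homogeneous sphere (default radius
0.09 m) with the sensor helmet a concentric sphere (0.12 m) carrying radial
magnetometers placed quasi-uniformly on the upper hemisphere by a
deterministic Fibonacci spiral. The magnetic field of a current dipole in a
conducting sphere has a closed form; two of its properties are load-bearing
and are tested exactly: a *radial* dipole produces no external field, and a
dipole at the center is silent. Consequently every lead field has effective
rank 2 (the tangential plane).

**Source space.** A cubic lattice at 6-mm spacing clipped to 0.9 x the head
radius (about 10,400 voxels), ordered deterministically. Seed coordinates
given in MNI millimeters are mapped into this model frame by a fixed affine
scaling of 0.8, which places all 12 packaged DMN seeds inside the mask; the
same mapping is used by the simulator and the analysis, so no per-subject
coregistration is involved.

**Beamformer.** For each voxel, channels are selected by the voxel's
lead-field row norms (all channels within 10% of the maximum norm, expanded
to at least 30 by descending norm); the covariance of the selected channels
(pooled over retained epochs after per-epoch mean removal, diagonally loaded
by 5% of the mean diagonal) defines minimum-variance unit-gain weights
`W = (L' C^-1 L)^-1 L' C^-1`. Because the sphere model is rank-2, the gain
matrix is first reduced by SVD to its effective column space; unit gain
`W L = I` holds in that basis to 1e-8 and is verified on every voxel. The
source orientation is the dominant eigenvector of the small source
covariance `W C W'`, sign-fixed so its largest-magnitude component is
positive (near-ties are broken lexicographically and flagged), and the
scalar beamformer projects the weights onto it. Accumulated source imaging
sums |Q| over the retained epochs; the signed sum, which cancels
oscillations, is available behind `signed = TRUE`.

## What the synthetic generator emulates — and what it does not

Each ROI source is a sum over the three analysis bands of band-pass-filtered
Gaussian noise. Within a band the 12 signals are mixed linearly (Cholesky
factor of a target correlation matrix), so a pair specified at coupling *c*
has population band-limited correlation exactly *c*; this generalizes
shared-component mixing `x_a = sqrt(c) z + sqrt(1-c) e_a` to arbitrary
positive-definite structures. The forward projection places one tangential
dipole per ROI — orientations are a fixed, seed-deterministic package
constant shared by all subjects, sign-canonicalized as below; the constant
was screened so that no DMN seed pair's coupling is nulled by an unlucky
orientation geometry through the inverse, since the attenuation of a
reconstructed pair correlation depends strongly on the dipole orientations —
and adds white sensor noise at `snr_db` (default 20 dB), a common
50-Hz sinusoid scaled per channel to `line_noise_amplitude` x the channel
RMS (default 0.5), and Poisson-timed 80-ms raised-cosine spike transients at
10 x the channel RMS (default 2 per minute) — large enough that the robust
rejection stage must catch them. All disturbance terms scale with the signal
so the projection stays exactly linear in the source amplitudes.

The default group presets give both cohorts a baseline inter-ROI coupling of
0.15 in every band; patients additionally carry elevated coupling on a
nested set of pairs that widens with frequency — 2 pairs in alpha, 12 in
beta, 20 in gamma — always led by LAG–LPCC and RAG–RPCC at coupling 0.65,
with the remaining elevated pairs at 0.50 (beta) and 0.60 (gamma). This
encodes the qualitative clinical pattern (group differences more widespread
at higher frequencies, the angular–posterior-cingulate pairs most affected)
while keeping every target matrix positive definite. Two aspects are
deliberate calibration choices rather than estimates of real effect sizes:
the elevated sets are *sparser* than the significant-pair counts observed in
patients, because with a dense strongly-coupled network the adaptive
beamformer partially cancels correlated sources and the group contrast
washes out at the sensor-noise levels used here (next section); and the
lead-pair couplings are strong enough that the encoded pattern remains
reliably detectable through the beamformer inverse at desk-scale cohort
sizes (15 + 15 subjects, tens of seconds of data), where group differences
attenuate roughly threefold between source and reconstruction.

The generator does **not** emulate realistic cortical geometry, BEM
conductors, gradiometer physics, 1/f background spectra, or ocular/cardiac
artifact waveforms. Clinical covariates are sampled from simple truncated
normal distributions anchored to the published cohort moments (patient age ~
Normal(21, 5) on [10, 35], epilepsy duration ~ Normal(12, 5) truncated
positive, control age ~ Normal(24, 5) on [14, 40]; male proportions 11/15
and 9/15). Passing tests on these cohorts therefore demonstrate the
correctness and calibration of the *algorithms*, not performance on real
MEG data.

## Source polarity and what "connectivity strength" means here

A beamformed source time series has an arbitrary polarity: the orientation
eigenvector is identifiable only up to sign. Two conventions keep results
reproducible. First, estimated orientations (and the simulator's generative
dipoles) are sign-fixed so the largest-magnitude component is positive.
Second, group comparisons default to connectivity **strength** |R|
(`measure = "strength"` in `compare_fc_groups()`), because the sign of a
correlation between two sign-ambiguous signals is not physically
interpretable; the raw signed correlations are always stored in the
per-subject matrices and can be compared with `measure = "signed"`.

A related, empirically verified limitation: a minimum-variance beamformer
presented with two strongly correlated sources partially cancels each using
the other. In a sparse synthetic world (12 sources plus white noise at
20 dB) this drives the *signed* reconstructed pair correlation negative
while leaving its magnitude monotone in the generative coupling (measured
strengths of about 0.15 / 0.33 / 0.51 for couplings 0.2 / 0.4 / 0.6). The
tests therefore verify (a) exact recovery of the generative coupling, within
±0.1, at the connectivity stage itself (epoching, band-pass, per-epoch
correlation, Fisher pooling of the generated source signals), and (b)
monotone, well-separated strength recovery plus localization and ROI signal
fidelity (correlation with truth at least 0.9 at 20 dB) through the full
inverse path. Real resting-state data, with its dense background activity,
sits between these regimes.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `epoch_length` | 0.5 | s | analysis unit for rejection and FC pooling |
| `n_epochs` (k) | 40 | epochs | clean epochs retained per subject |
| `z_threshold` | 6 | robust SD | separates 10x-RMS bursts from Gaussian background with negligible false-positive rate; the MAD scale is floored at machine epsilon x channel range so constant channels never flag |
| `line_freq` / `width` | 50 / 5 | Hz | band-stop edges 45–55 Hz; >= 40 dB at the line, < 1 dB at 40/60 Hz |
| bands | 8–13, 14–30, 31–80 | Hz | alpha/beta/gamma analysis bands |
| `regularization` | 0.05 | fraction | diagonal loading of the covariance; stabilizes inversion for short recordings |
| `min_fraction` / `min_count` | 0.10 / 30 | — | voxel-based partial sensor coverage rule |
| `grid_spacing` | 6 | mm | source grid resolution; localization error is bounded by it |
| `min_separation` | 10 | mm | peaks closer than this merge into one source |
| `degree_threshold` | 0.3 | — | correlation factor above which an edge counts |
| `snr_db` | 20 | dB | simulator source-to-sensor-noise ratio |

## Numerical choices

* **Zero-phase filtering** uses compiled forward-backward Butterworth
  filters (order 4) with steady-state initial conditions and odd reflection
  padding. Filtering a *finite* pure sinusoid necessarily leaves
  rectangular-window leakage outside the stop band — a time-bandwidth fact,
  not an implementation artifact — so attenuation properties are asserted on
  analysis-scale durations (tens of seconds for the notch, multi-second
  segments for the band edges); at the 500-ms epoch scale band separation is
  limited to roughly 27 dB.
* **Accumulated source imaging** is defined as the sum of |Q| per voxel: the
  printed signed sum would cancel oscillatory activity. The per-epoch slice
  index is carried as metadata only.
* **Fisher pooling** clips per-epoch correlations to 1 - 1e-15 in magnitude
  before `atanh`; epochs containing a zero-variance ROI signal are dropped
  with a warning, and an all-degenerate input is an error rather than a
  silent zero.
* **Rank deficiency.** Sphere-model lead fields are reduced to their rank-2
  tangential basis; voxels with effective rank < 2 (the center) are flagged
  and skipped. Covariances are always diagonally loaded, so duplicate
  channels do not break the inversion.
* **Degenerate group tests.** Zero pooled variance with equal means gives
  t = 0, p = 1; with unequal means the scalar test errors, while the
  group-comparison scans record the comparison as maximally significant in
  the direction of the mean difference (this happens routinely for
  saturated binary degrees).
* **Tie-breaks.** Near-equal leading eigenvalues in orientation estimation
  are resolved lexicographically and flagged; a flat accumulated image
  yields a single deterministic peak at the lowest voxel index, flagged.
* **Seeds.** Every stochastic step (source generation, projection noise,
  epoch subsampling, covariates) consumes an explicit seed derived from a
  master seed by a fixed integer mixing scheme, and all derived seeds stay
  below 2^31. Identical configuration and seed reproduce recordings,
  covariates and results bit-identically.

## Problem sizes used by the test suite

The calibration and effect-structure properties are verified on sizes
chosen to make the full suite convenient to run repeatedly on one CPU:

* Null calibration: 200 replicate cohorts of 15 + 15 subjects, 24-channel
  array, 7.5-s recordings (8 retained epochs), gamma band; the per-pair
  rejection rate at p < .05 is required to sit inside the exact binomial
  95% band for 200 trials.
* Effect structure: 20 cohorts of 15 + 15, 64-channel array, 18-s
  recordings (26 retained epochs), all three bands; significant-pair counts
  must be non-decreasing from alpha to gamma and LAG–LPCC must be flagged
  (patient-higher) in all three bands in at least 90% of cohorts.
* Localization: 50 seeded single-dipole replicates at 20 dB SNR on the full
  6-mm grid (102 channels, 4-s recordings), with dipoles placed at
  cortically plausible depths (25–76 mm radius; the deep center of a
  spherical conductor is magnetically near-silent and no anatomical source
  lives there); at least 95% must localize within one grid spacing.
* Coupling recovery: 20 subjects per coupling level with 40 epochs of
  generated source signals.

Larger cohorts, longer recordings and the 102-channel array simply scale
these numbers; nothing in the implementation depends on the reduced sizes.

## Known limitations

* The spherical conductor and radial-magnetometer idealization preserves the
  inverse-problem structure but not individual anatomy; absolute source
  amplitudes are in arbitrary units.
* Signed source-space correlations through an adaptive beamformer are
  unreliable in sparse-source regimes (see above); strength-based
  comparisons are the default for good reason.
* Seed regions 6 mm apart or less (LPCC/RPCC, LvMPFC/RvMPFC) show strong
  mutual leakage; their pairwise strengths saturate and carry little
  information, although group calibration is unaffected because leakage is
  identical in both cohorts.
* The robust-z spike rejection is a deterministic surrogate for expert
  visual screening; it is calibrated against the simulator's 10x-RMS bursts,
  not against clinical spike morphology.
* Whole-brain voxel-pair connectivity at the full grid scale is available in
  principle through `asi_map()` weights but the packaged pipeline restricts
  FC to the 12 seed regions, which is what the group statistics consume.

## A minimal run

```{r example, eval = FALSE}
cfg <- cohort_config(n_per_group = 15, duration = 30, seed = 1)
cohort <- simulate_cohort(cfg)
fit <- dmn_study(cohort, seed = 1)
print(fit)
summary(fit)
```
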