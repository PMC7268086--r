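# megdmn

Beamformer-based default-mode-network (DMN) connectivity analysis for
resting-state MEG, with a ground-truth synthetic cohort generator.

## What it is for

Resting-state MEG studies of focal epilepsy ask whether the coupling of the
DMN — posterior cingulate/precuneus, angular gyri, medial prefrontal and
anterior cingulate cortices, inferior temporal gyri — differs between
patients and controls, band by band. `megdmn` implements that analysis as a
tested R pipeline:

* **Preprocessing**: zero-phase 50-Hz band-stop filtering, segmentation into
  consecutive 500-ms epochs, robust-z rejection of spike/artifact epochs,
  seeded random selection of 40 clean epochs per subject.
* **Source reconstruction**: closed-form dipole-in-sphere lead fields on a
  6-mm volumetric grid; a two-step minimum-variance (LCMV-style) beamformer
  with voxel-based partial sensor coverage, per-voxel orientation
  estimation and a scalar beamformer; accumulated source imaging
  `Asi(r) = Σ_t |Q(r, t)|` with 10-mm peak merging.
* **Connectivity**: for 12 DMN seed regions (published MNI coordinates,
  6-mm spheres), the Pearson correlation of band-limited source signals
  `R(X_a, X_b) = C(X_a, X_b) / (S_{X_a} S_{X_b})` per 500-ms epoch, pooled
  across epochs by Fisher z averaging, in the alpha (8–13 Hz), beta
  (14–30 Hz) and gamma (31–80 Hz) bands; graph node degree
  `s_i = Σ_j w_ij` at a correlation threshold (default |R| > 0.3).
* **Group statistics**: per-pair and per-node two-sided pooled-variance
  t-tests (p < .05), per-band significant-pair counts with a
  Benjamini–Hochberg column alongside, Spearman clinical correlations, and
  a clinical cohort summarizer.
* **Synthetic cohorts**: band-limited dipole sources at the 12 DMN loci with
  exact, group- and band-specific coupling, 50-Hz line interference, sensor
  noise and spike transients — so every stage is verifiable against known
  ground truth.

## A worked example

The packaged clinical table describes the 15 operated cingulate gyrus
epilepsy patients:

```r
library(megdmn)
print(summarize_clinical(cge_clinical_table()))
#> Cohort of 15 patients
#>   age: 21.2 +/- 5.1 years (sample SD; population SD 5.0)
#>   epilepsy duration: 12.1 +/- 5.4 years
#>   sex: F=4, M=11
#>   seizure-free: 12 (80%)
#>   focal cortical dysplasia: 14 (93%)
```

A full synthetic study — 15 patients and 15 controls, 30-s recordings at
1,000 Hz on a 102-channel array, with patients carrying elevated DMN
coupling that widens and strengthens with frequency:

```r
cfg <- cohort_config(n_per_group = 15, duration = 30, seed = 1)
cohort <- simulate_cohort(cfg)
fit <- dmn_study(cohort, seed = 1)
print(fit)
#> DMN connectivity study: 15 patients vs 15 controls, bands alpha/beta/gamma
#> Significant pairs (p < 0.05, uncorrected):
#>   band n_higher n_lower n_higher_bh
#>  alpha       11       8          11
#>   beta       23      19          23
#>  gamma       30      28          30
```

`n_higher` counts ROI pairs whose connectivity strength is significantly
higher in patients: the elevation spreads from the alpha band (the two
seeded pairs plus their leakage neighbours) through beta to gamma, and the
LAG–LPCC pair is flagged in all three bands — the qualitative signature the
pipeline is built to detect. (`n_lower` pairs arise because an adaptive
beamformer partially cancels correlated sources, which depresses the
measured strength of pairs adjacent to an elevated network; the vignette
discusses this.) `summary(fit)` lists the most different pairs;
`plot(fit, band = "gamma")` draws the group-difference matrix.

## Vignette

`vignettes/dmn-meg-connectivity.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, numerical edge-case policies,
and known limitations (notably the sign-ambiguity of beamformed sources and
why group comparisons default to connectivity strength |R|).
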