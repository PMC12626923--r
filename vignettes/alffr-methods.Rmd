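---
title: "Methods: amplitude of low-frequency fluctuations, dynamic variants, and cluster inference in alffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models, parameter choices
and numerical conventions. It states no empirical result that the test suite
does not itself compute.

## 1. The measurement model

A resting-state BOLD run is a 4D lattice: `x, y, z` voxels (here isotropic,
millimetre geometry carried in an affine) by `t` volumes sampled every `TR`
seconds. The emulated acquisition is TR = 2.17 s and 186 volumes, of which
the first 10 are discarded for scanner equilibration, leaving 176.

**ALFF.** After preprocessing (Gaussian smoothing, band-pass, detrend), each
voxel series is Fourier transformed. The one-sided amplitude spectrum is
scaled so a unit sinusoid at an exact DFT bin has amplitude 1
(`(2/N)|X_k|`, with DC and the even-length Nyquist bin at `1/N`). ALFF is
the mean amplitude over the bins whose frequency lies in the closed band
[0.01, 0.08] Hz. At N = 176, TR = 2.17 s this band holds **27 bins** — a
count the package computes from N, TR and the band rather than asserting.
Two denominator conventions circulate for this statistic: mean over the
number of included bins, and division by the difference of the first and
last bin index. The package defaults to mean-over-bins (consistent with the
RESTplus lineage) and keeps the other behind `denominator = "printed"`.

**mALFF.** Dividing by the global in-mask mean gives a map whose in-mask
mean is exactly 1, invariant to global rescaling of the input series. Some
pipelines label this quantity "fALFF"; the canonical fALFF (band amplitude
over full-spectrum amplitude) is provided separately as `falff_map()` so
the two are never conflated.

**dALFF.** The series is cut into sliding windows of `L = 50` TRs stepped by
`S = 20` TRs. Window starts are `0, S, 2S, ...` while a full window fits:
`floor((N - L)/S) + 1` windows, i.e. **7** windows for N = 176. (A count of
29 sometimes quoted for this configuration is not achievable from the
formula; the package logs the computed count.) Each window is linearly
detrended by default — windows are short, so drift dominates their spectra —
then its ALFF is computed at the window's own frequency resolution
(13 in-band bins at L = 50). The dALFF statistic is the **population
variance** (divide by the window count m, not m − 1) across windows, and
maps are z-scored within the mask (population SD) per subject-session
before group statistics. Windows are rectangular; a taper is deliberately
not applied, matching the sliding-window ALFF lineage.

## 2. Preprocessing conventions

The default stage order is smooth (6 mm FWHM) → band-pass → detrend. This
follows the printed order of the pipelines this package mirrors;
conventional practice detrends before filtering, and the `order` argument
allows it. The band-pass is an ideal DFT-domain boxcar (closed interval on
bins, DC always removed) because the downstream statistic is itself
DFT-based; a zero-phase Butterworth magnitude response (order 4 per edge) is
available for robustness comparisons. Smoothing is separable Gaussian
convolution with `sigma_vox = FWHM / (voxel * 2 sqrt(2 ln 2))`, kernel
truncated at 3.5 sigma, **replicate padding** at the volume boundary. The
padding choice keeps constants exactly constant but inflates apparent
smoothness near the boundary — one reason the smoothness estimator below
reads slightly above truth.

## 3. Group statistics

Voxelwise ordinary least squares: `value ~ intercept + group + covariates`
(age in years, sex coded 0/1, education in years; all mean-centered so the
group contrast is evaluated at covariate means). Positive t means first
group > second. Covariate columns that are constant in a given sample are
dropped with a message (a 0/1 covariate is routinely constant in very small
cohorts). Voxels with zero variance across subjects are removed from the
analysis mask and counted. Paired contrasts are one-sample t statistics on
post − pre difference maps (df = n − 1); within-subject-constant covariates
cancel in differences and are not entered by default. Zero-variance non-zero
shifts would give infinite t; they are censored to a reported maximum (1e6)
and counted (`n_censored`). For random-field theory the t map is
Gaussianized voxelwise, `z = qnorm(pt(t, df))`, evaluated through log-scale
tails so large statistics do not saturate prematurely, capped at |z| = 40.

## 4. Cluster-level inference

Smoothness is estimated from the GLM residuals: each voxel's residual
vector is normalized to unit length, first spatial differences are taken
per axis inside the mask, and
`FWHM_d = voxel_d * sqrt(4 ln 2 / var(du_d))`. On a lattice the finite
difference under-measures the continuous derivative variance; at the
package's reference setting (6 mm kernel on 3 mm voxels, i.e. 2-voxel FWHM)
the analytic bias is about +9%, and with boundary padding the recovered
mean over seeds sits near 6.4 mm for a true 6.0 mm — inside the acceptance
band [5.4, 6.6] and conservative for cluster inference (fewer RESELs means
larger corrected p). No ad-hoc correction is applied.

RESEL counts R0..R3 use the standard voxel/edge/face/cube counting of the
mask. Corrected cluster p-values follow the classic recipe: expected
cluster count = expected Euler characteristic `sum R_d rho_d(u)`; expected
suprathreshold volume `S * pnorm(-u)`; extent tail
`P(N >= k) = exp(-beta k^(2/3))` with `beta = (gamma(5/2)/E[n])^(2/3)`;
`p = 1 - exp(-E[m] P(N >= k))`. Positive and negative excursions are
thresholded, labelled (26-connectivity default; 6/18 available) and
corrected separately, then merged into one table sorted by corrected p —
matching the per-comparison reporting style of the field. Peaks are the
maximum |t| voxel, ties broken by smallest linear grid index, converted to
mm through the image affine; atlas labels are looked up at the peak from
any integer-labelled volume plus a name table ("unlabeled" otherwise).

The emulated study thresholds at voxel p < 0.05. The extent approximation
is known to be liberal at thresholds that low, so the package keeps 0.05 as
the fidelity default but logs a prominent recommendation of 0.001, and all
calibration testing is done at 0.001, where the null family-wise rate over
500 simulated experiments falls inside [0.02, 0.09]. The observed rate is
a little below nominal — expected, given the upward smoothness bias and the
discreteness of 1–2 voxel clusters at that threshold.

## 5. Longitudinal delta analysis and clinical utilities

Regions of interest for the delta analysis are the exact suprathreshold
cluster masks from the paired contrast (not spheres around peaks). For each
patient, the ROI-mean change (post − pre) is correlated (Pearson) with the
change in each of six clinical indices; p-values come from the
t-transformation with n − 2 df, two-sided. The Bonferroni family defaults
to the number of contributing ROIs applied per clinical index — mirroring
the common "(k regions)" reporting convention — with the conservative
whole-table family available via `m_tests`. Utilities implement the
Child-Pugh classing (A: 5–6, B: 7–9, C: 10–15 points) and the 2-SD
psychometric impairment rule, resolved one-sided toward impairment per
instrument (Number Connection Test A slower than mean + 2SD, or Digit
Symbol Test lower than mean − 2SD), the standard direction for these tests.

## 6. What the synthetic cohort emulates — and what it does not

The generator reproduces the design the inference assumes: 32 controls (one
session), 27 patients (pre and post), TR 2.17 s, 186 volumes, an
ellipsoidal brain mask, AR(1) temporal noise (default phi = 0.3, sigma = 1)
spatially smoothed at 6 mm so the true field smoothness is known, a
constant baseline of 100 units, and band-limited sinusoids planted in box
ROIs. Longitudinal change is modelled as an amplitude change of the planted
oscillation (pre mean 1.0 → post mean 1.6, between-subject SD 0.25 by
default) — an amplitude metric should see amplitude change. Clinical scores
are drawn from the cohort's published summary statistics (normal,
physiologically truncated; skewed laboratory values lognormal), controls
carry no laboratory values, and Child-Pugh classes follow the reported
2/5/20 distribution. Where a linked delta-correlation is requested, the
clinical change is constructed as `r * z(amplitude delta) + sqrt(1-r^2) *
noise` scaled to the index's change distribution, and the post value is pre
+ change; the post-session marginal SD of that index is then emergent
rather than pinned. No effect sizes for regional differences were ever
published, so the planted amplitudes are chosen for test power, not
biological realism.

Not modelled: hemodynamic response, cardiac/respiratory physiology, head
motion, scanner drift beyond what detrending removes, and anatomical
structure. A green recovery test therefore establishes that the pipeline
recovers what it assumes — planted band-limited amplitude structure in
smooth AR(1) noise — not that it would behave identically on real data.

One emergent behaviour deserves emphasis: because mALFF divides by the
global mean, a genuine regional increase mechanically depresses every other
voxel's mALFF, and with a consistent planted change this "echo" forms a
large significant cluster of opposite sign whose delta is (negatively)
correlated with the planted change — and hence with any clinical index
linked to it. This is arithmetic, not a false positive of the inference
machinery; the recovery tests treat linked-index correlations on echo
clusters as neither hits nor false alarms, and specificity is assessed on
the five unlinked indices.

## 7. Reproducibility and scale choices

Everything derives from one integer seed: the cohort plan (demographics,
clinical draws, per-subject amplitudes, phases) is drawn first, then each
session's noise from a per-session seed, so a cohort can be generated in
full or streamed session-by-session with identical results; reruns produce
byte-identical TSVs. The default grid is desk-scale 24x24x16 at 3 mm so the
full pipeline runs in minutes; the repeated-seed acceptance loops scale down
to 16x16x12 (stated in the tests) purely for time, keeping the cohort
design (n = 27 pairs, planted r = 0.8) fixed. Full-size grids are a config
change. The end-to-end recovery configuration forms clusters at voxel
p = 0.001 — the recommended threshold — rather than the fidelity default of
0.05, since its purpose is calibrated recovery, not replication of a
reporting convention.

## 8. Known limitations

- The NIfTI-1 reader/writer is minimal by design (3D/4D, common dtypes,
  sform/qform, gzip); it is not a general neuroimaging I/O layer.
- Random-field corrections at voxel p = 0.05 inherit the approximation's
  known liberality; the package warns but does not refuse.
- The sliding-window variance is the only dynamic statistic; no state
  clustering or dynamic connectivity.
- Spatial registration, motion correction and nuisance regression are out
  of scope: inputs are assumed already on a common grid.
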