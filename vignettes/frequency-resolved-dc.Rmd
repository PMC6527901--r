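---
title: "Frequency-resolved degree centrality: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-resolved degree centrality: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqdc)
```

## The analysis

Voxel-wise degree centrality (DC) summarizes how strongly each brain voxel's
BOLD time course couples to the rest of the brain: for voxel $i$, the Pearson
correlation $r_{ij}$ to every other in-mask voxel $j$ is computed, binarized
at a threshold (here $r > 0.2$, strictly, positive tail only), and summed,

$$d_i \;=\; \#\{\, j \neq i : r_{ij} > 0.2 \,\}.$$

Degree maps are standardized to z-maps by subtracting the mean and dividing
by the population standard deviation of $d$ over the gray-matter (GM) mask.
`freqdc` computes these maps *within frequency sub-bands*: the voxel time
courses are ideal-band-pass filtered into ten contiguous bands covering
0.01–0.25 Hz (freq1: 0.01–0.025 Hz, then 0.025-Hz steps up to freq10:
0.225–0.25 Hz), plus a single full band (0.01–0.25 Hz) and the conventional
low-frequency band (0.01–0.1 Hz). Hubs — voxels of outstanding degree — can
then be localized per band, group differences tested per band, and cluster
means correlated with clinical scores.

The pipeline order follows standard resting-state practice: WM/CSF nuisance
regression on unsmoothed data, then spatial smoothing (6-mm FWHM Gaussian),
then per-band filtering, DC, and z-scoring. Gray-matter-volume (GMV)
correction residualizes, at each voxel, the across-subject DC values on the
across-subject GMV values, so group inference can be repeated on maps free
of linear atrophy effects.

## The ideal band-pass filter

The filter works on the native $T$-point discrete Fourier transform (no
zero-padding; bin spacing $1/(T\,\mathrm{TR})$ Hz, i.e. $1/600$ Hz for
$T = 300$, TR $= 2$ s). Band membership is half-open on bin frequencies,
$f_\mathrm{low} \le f < f_\mathrm{high}$, so contiguous bands partition the
bins with no bin counted twice; a band whose upper edge reaches the Nyquist
frequency also keeps the Nyquist bin, so a contiguous partition of
$[0, f_\mathrm{Nyq}]$ reconstructs its input exactly. The DC (zero-frequency)
term is always removed. Whether the original tooling included the exact
0.25-Hz edge in the top band is not recoverable; the half-open rule plus
Nyquist closure is this package's documented convention.

Each masked course is demeaned and linearly detrended before filtering
(preventing trend power from leaking into the lowest bands). One numerical
subtlety is worth stating: the detrend projector and the DFT bin-selection
projector do not commute exactly — a bin-aligned tone has a tiny but nonzero
linear-trend fit (slope $\sim 10^{-4}$ for 300 samples), and a band-limited
signal re-acquires a tiny trend fit after filtering. Pure bin selection
(`detrend = FALSE`) is exactly idempotent; the composed default is
idempotent only up to this trend-leakage term ($\sim 10^{-5}$ relative).
Tests of the filter identities therefore use tones constructed orthogonal to
the detrend basis.

## Degree computation

The correlation matrix is never materialized: standardized courses are
cross-multiplied in column blocks (`block = 2048`), so peak memory is
$O(MB)$ rather than $O(M^2)$ for $M$ masked voxels, while remaining exactly
(to $10^{-10}$) equal to thresholding the dense correlation matrix — the
test suite checks this against a brute-force oracle. Ties $r = 0.2$ are
excluded (strict inequality) and negative correlations never count; both
rules are stated because the upstream tooling convention is not recoverable.
Zero-variance masked voxels are a hard error rather than being dropped
silently, because silent mask mutation would break cross-band comparability.
z-normalization uses the population (divide-by-$M$) standard deviation.

## Group inference

Cluster-level family-wise error (FWE) control uses nonparametric permutation
in place of parametric random-field theory: one-sample hub maps use
sign-flipping of subject maps, two-sample group contrasts use group-label
permutation, both with the maximum suprathreshold cluster as the null
statistic. Clusters form at the $t$ quantile matching the voxel-level
$p < 0.001$ (one-sided per contrast direction, since the reported effects
are directional decreases), with 26-connectivity (faces + edges + corners) —
cluster sizes depend on this choice, so it is fixed and stated.

The null statistic ranks clusters by *size with suprathreshold mass as a
tie-break* (mass $= \sum (|t| - t_\mathrm{thr})$ over the cluster). On small
grids, cluster sizes are heavily discrete (most permutation maxima are 0, 1
or 2 voxels), and a pure size statistic makes the permutation p-values so
atomic that the realized FWE falls an order of magnitude below the nominal
level. The lexicographic (size, mass) statistic keeps size as the primary
ranking but makes the null distribution effectively continuous, restoring
near-nominal calibration (empirically $\approx 0.04$–0.05 at nominal 0.05);
this is the one place the implementation refines the plain max-cluster-size
rule, for a measurable calibration defect. Observed statistics are included
in their own null, so no cluster ever has $p = 0$; identical seeds give
bit-identical results.

One caveat on one-sample "null" calibration: z-scored DC maps always carry
systematic spatial structure (they are standardized per subject, and degree
has spatially structured expectation), so a sign-flip test against zero on
real pipeline maps is not a null even when no hub is planted. Calibration of
the one-sample machinery is therefore assessed on symmetric zero-mean noise
maps, and of the two-sample machinery on full pipeline cohorts with no
planted group difference (where group exchangeability makes the null exact).

The group-by-band ("flexible factorial") question is answered as the family
of per-band two-sample contrasts under one shared configuration; the
omnibus interaction F-test is out of scope. The exact covariance structure
of the original factorial model is not recoverable from the reported
contrasts, and the per-band contrasts are what the findings consist of.

## Cross-band similarity and clinical correlation

Group-averaged sub-band maps are compared with the full-band map by Pearson
correlation after downsampling both maps and the mask to 0.4 of the grid
resolution (trilinear interpolation, output shape $\lceil 0.4 n \rceil$ per
axis, mask re-binarized at 0.5) — coarse sampling reduces the dependence
between neighbouring voxels induced by the maps' intrinsic smoothness. The
interpolation scheme of the original 0.4 down-sampling is unstated anywhere;
trilinear-with-ceiling is this package's documented choice. The surviving
voxel count $n$ is recomputed per run rather than fixed, since it is a
property of the grid, not of the method.

Correlation magnitudes are compared by the independent-sample Fisher r-to-z
test,
$z = (\operatorname{atanh} r_a - \operatorname{atanh} r_b)\big/\sqrt{1/(n_a-3) + 1/(n_b-3)},$
Bonferroni-adjusted over all $K(K-1)/2$ band pairs (45 for $K = 10$). Both
correlations share the full-band map, so a dependent-correlation test
(Steiger/Williams) would be more exact; the plain Fisher form is used
because it is the one the reported analysis describes, and the choice is
stated prominently rather than silently.

Cluster-wise clinical correlation extracts each subject's mean z-DC over
every significant cluster and correlates it with symptom scores across
*patients only* — controls carry no symptom variance, and pooling groups
would manufacture group-driven correlations. The Bonferroni factor defaults
to the number of bands with significant group findings, computed from the
upstream results rather than hard-coded. Whether an intercept belongs in the
per-voxel GMV regression is unstated in the source analyses; it is included
here so residuals are mean-free for the downstream t-tests.

## The synthetic cohort generator

Real resting-state cohorts for this design are not publicly deposited, so
validation uses a seed-deterministic generator that plants the statistical
structure every downstream stage assumes, at desk scale:

* **Grid and compartments.** A $12^3$ grid at 8-mm isotropic voxels; GM is a
  centred sphere of radius 5 voxels (552 voxels), WM and CSF are $3^3$
  corner cubes outside it. The coarse voxel size is deliberate: with the
  6-mm smoothing kernel sub-voxel, the noise field stays short-range
  correlated relative to the small volume. (At 3-mm voxels the same kernel
  correlates the entire 552-voxel mask, and any planted hub drowns in
  smoothing-induced edges — a regime real whole-brain analyses escape by
  having tens of thousands of voxels.)
* **Acquisition.** TR 2 s, 300 volumes per run, matching the emulated
  protocol; i.i.d. Gaussian voxel noise of unit SD.
* **Hubs.** A hub is an 81-voxel sphere whose members share one
  band-limited latent course (ideal-filtered white noise, unit variance)
  at amplitude `coupling` relative to the *in-band* noise SD, so the
  expected band-filtered correlation between hub voxels is
  $c^2/(c^2+1)$. Patients receive amplitude $c(1-\mathrm{attenuation})$.
  The default ($c = 0.73$, attenuation $0.4 \pm 0.05$ per patient) puts
  control hub-pair correlations near 0.35 and patient ones near 0.16 —
  straddling the 0.2 threshold, which is the regime in which an amplitude
  attenuation becomes a degree difference. With only ~30 effective degrees
  of freedom per 0.025-Hz-band correlation, this regime is also what bounds
  the attainable group effect (per-voxel $d \approx 0.9$ at 24 subjects per
  group); stronger coupling saturates both groups' edges and the difference
  vanishes again.
* **Confound.** A shared white-noise course at amplitude 0.5 pervades GM
  and the WM/CSF compartments, emulating global physiological fluctuations;
  nuisance regression removes it. A stronger GM-wide confound can be
  planted via `global_confound_amp` for regression testing.
* **Atrophy and scores.** Patients receive a Gaussian GMV depression
  (depth 0.15, radius 1.5 voxels) spatially disjoint from the hub, so hub
  findings should survive GMV correction. Patient BDI is a linear function
  of the per-patient attenuation draw plus noise (`score_link`); the causal
  knob, not the measured DC, drives the score, keeping parameter-recovery
  tests well-posed. Controls have zero symptom scores and high GAF.

What the generator does **not** emulate: hemodynamic response shapes,
cardiac/respiratory noise spectra, anatomical geometry, motion, or
between-site variability. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the generative model
it assumes — not that effect sizes or significance levels transfer to any
real dataset.

## Problem sizes used by the tests

The validation suite runs at deliberately small scale chosen as adequate
for the properties checked: oracle-equivalence on masks up to ~1,000 voxels;
filter identities on single courses; null FWE calibration on 200 replicates
(12 vs 12, $T = 150$, 500 permutations); planted-band recovery on one
24-vs-24 cohort across all ten bands plus the full band (1,000
permutations); and symptom-link recovery on 100 replicates of 24 patients.
The fraction-of-hub-covered criterion for planted-band recovery sits near
the statistical ceiling described above, and the corresponding check is
reported exactly as measured.

## Known limitations

* The independent-sample Fisher comparison ignores the dependence induced
  by the shared full-band map (documented above).
* Sign-flip one-sample inference assumes per-voxel symmetry; on z-DC maps
  it answers "where is z-DC consistently nonzero", which includes
  systematic structure of the degree field itself.
* The generator's hub geometry is spherical and its amplitude uniform;
  boundary effects of realistic hub shapes are untested.
* Cluster-level inference on 552-voxel masks is dominated by small
  clusters; anatomical-scale cluster extents are not represented.
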