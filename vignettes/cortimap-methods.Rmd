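---
title: "Surface-based mapping statistics in cortimap: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based mapping statistics in cortimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortimap)
```

cortimap implements a complete surface-based analysis chain for
sensory–motor mapping fMRI: per-vertex Fourier statistics for
phase-encoded designs, cross-subject complex averaging, cluster-size
correction on triangle meshes, a block-design GLM, and overlap
quantification by vertex-wise area. This vignette documents the models,
every tunable that matters, the numerical choices made where the design
was genuinely open, and what the synthetic generator can and cannot
stand in for.

## The traveling-wave model

A phase-encoded run presents a periodic stimulus sweeping a map
dimension — polar angle of a rotating wedge, the position on a
logarithmic 150–9600 Hz frequency ramp, or a tongue-to-toe sequence of
11 body parts — with `s` cycles per run (default 8, 64 s per cycle). A
vertex tuned to coordinate `phi` (in cycle-fraction radians) responds as

$$y_t = A\cos\!\big(2\pi s t/T - \phi - \omega d\big) + \varepsilon_t,$$

where `d` is the haemodynamic delay in seconds and
`omega = 2*pi / cycle length`. The delay is not directly observable
from one run; it is a configuration parameter (default 2 s) and
`estimate_delay()` recovers it empirically as the shift maximising
stimulus-bin amplitude over the most responsive vertices.

**Run combination.** Reverse-direction runs encode `-phi`. cortimap
time-reverses them on the circular time axis (`x'(t) = x(-t)`, which
maps bin-`s` content exactly) and then applies a circular shift of
`round(2 d / TR)` samples. The factor 2 follows from the sinusoid
algebra: reversal negates the delay term along with the phase, so
restoring alignment with forward runs requires twice the one-way lag.
After combination both run types carry `phi + omega d`; decoding
subtracts the known or estimated lag via the `origin` argument of
`decode_phase()`. The only approximation is the rounding of the shift
to whole samples (at most half a sample, i.e. `pi * s / T` radians of
phase).

**The F-statistic and its degrees of freedom.** Power at the stimulus
bin is compared with the mean power over noise bins. Excluded from the
noise estimate are: the three lowest frequencies (slow drift and motion
artifact — excluding a bin is exactly equivalent to regressing out the
corresponding sine/cosine pair), the first three harmonics of `s` with
one bin on either side, and the DC and Nyquist bins. Under white noise
each retained bin contributes two degrees of freedom, so
`df = (2, 2m)` with `m` noise bins; for `T = 512`, `s = 8` this gives
`df2 = 486`. Bookkeeping conventions for the DC and Nyquist bins vary
between implementations and can move `df2` by a couple of units; at
these sizes the critical values differ only in the third decimal, and
`critical_f()` accepts any df pair so thresholds can be matched to an
external convention exactly. Zero measured noise power (a noiseless
synthetic limit) is reported as `F = Inf`, `p = 0`; the cutoff for
"zero" is `1e-12` of the signal power, which absorbs FFT rounding.

## Smoothing on the mesh

One smoothing step replaces each vertex value by the unweighted mean
over the vertex and its edge neighbours; `k` steps iterate this. The
kernel is defined by its step count, not a millimetre bandwidth: the
realised width depends on the mesh resolution, and
`smoothing_fwhm()` measures it empirically (on a cortical-resolution
mesh, ten steps correspond to roughly 3 mm FWHM). Complex maps are
smoothed component-wise. The operator is linear and, on a
regular-degree mesh, mean-preserving and variance-contracting — all
three properties are under test.

## Group statistics for complex maps

Subject maps (assumed vertex-corresponded on one shared mesh —
spherical registration is out of scope) are smoothed and averaged as
complex vectors, which handles circular wrap-around correctly: opposed
phases cancel instead of averaging to a spurious intermediate
direction. For significance, cortimap treats the per-subject
(real, imaginary) pairs as bivariate observations with isotropic noise
and uses the one-sample statistic

$$F = (n-1)\,\frac{n\,|\bar z|^2}{\sum_i |z_i - \bar z|^2}
      \sim F(2,\,2n-2)$$

under the circular-symmetric Gaussian null. The `(n-1)` constant is
what makes the null distribution exact — a Monte-Carlo check with
20,000 null vertices at `n = 15` reproduces the nominal 0.05 rate to
three decimals, and the acceptance suite re-verifies this at
0.001/0.01/0.05. A full Hotelling form with an anisotropic 2×2
covariance would be the alternative; the isotropic form was chosen to
match the `df1 = 2` convention of the single-subject statistic and
because phase-encoded noise has no preferred direction in the complex
plane by construction.

## Cluster-size correction

`estimate_cluster_threshold()` calibrates the minimum cluster area for
a familywise corrected alpha by simulation: white Gaussian vertex
noise, smoothed with the same step count as the analysed maps, is
standardised per vertex using the *exact* standard deviation of the
smoothed noise (row norms of the k-step smoothing operator, computed
sparsely), converted to one-sided p, thresholded at the vertex p, and
the maximum suprathreshold cluster area (edge connectivity, vertex-wise
areas) recorded. The area threshold is the `(1-alpha)` empirical
quantile of that max-area distribution, so "any surviving cluster on a
matching null map" has probability alpha — the self-consistency that
the acceptance suite verifies on 1000 fresh null maps.

Choices worth knowing: the null is matched to the analysed maps only
through the smoothing step count (a data-driven smoothness estimate is
not attempted); the statistic is the maximum cluster (familywise), not
a cluster count; `alpha = 1` degenerates to a zero threshold (no
exclusion) rather than an error; p maps are one-sided, with a
`two_sided` flag that halves the vertex threshold. Published area
thresholds of a few tens of mm² arise on real cortical surfaces with
their specific vertex density and smoothness; on synthetic meshes the
threshold is mesh-dependent and is always estimated, never assumed. The
same applies to the minimum areal increment (the mean vertex-wise area,
about 0.6 mm² on a typical reconstructed cortex): on an icosphere it is
whatever the tessellation gives, and it is reported, not asserted.

## The block-design GLM

Regressors are condition boxcars convolved on a 16×-oversampled grid
with a double-gamma HRF, sampled at the TR, each with its temporal
derivative; a discrete-cosine high-pass basis with
`K = floor(2 * run_length / cutoff)` columns (cutoff default 100 s)
and an intercept complete the design. The HRF is parameterised by the
mean and dispersion of each gamma lobe (peak 6 ± 3 s, undershoot
16 ± 3 s, ratio 6), all overridable via `hrf_model()`. Note that a
16 s block's convolved regressor peaks near the *end* of the block —
the boxcar integrates the kernel until its zero crossing — not one
HRF-peak-delay after onset; the design-matrix tests pin the peak to an
independent convolution oracle rather than to a rule of thumb.

Per-vertex fits are ordinary least squares; optional prewhitening is a
single Cochrane–Orcutt pass with the lag-1 autocorrelation pooled
across vertices (a deliberate simplification of full per-voxel
autocorrelation modelling: one parameter, testable closed form,
slightly conservative since OLS residuals bias the estimate low). Runs
combine by inverse-variance weighting of COPE/VARCOPE; the group model
is a one-sample t on subject COPEs (OLS "mixed effects": between-subject
variance only, VARCOPE heterogeneity ignored), which is declared rather
than hidden and is calibration-tested at 10,000 null vertices. The
p-to-Z convention is signed and one-sided-preserving, so Z = 3.09
corresponds to p < 0.001.

## Overlap quantification

The area assigned to a vertex is one third of the summed areas of its
incident triangles; regional sums therefore reproduce tessellated areas
exactly and are additive over disjoint regions. Overlap percentages
always use the activation area as denominator (a symmetric Dice
coefficient is provided as a secondary column, never the headline
number). Boundary vertices contribute their full vertex area — there is
no fractional face splitting, consistent with the vertex-area
definition. Named region partitions must be disjoint; "treat-as-map"
patches (e.g. a foveal confluence that shows no periodic signal under
central fixation yet is certainly mapped) are unioned into the map mask
before intersection and are user inputs. Empty activation masks yield
missing percentages, never zero.

## The synthetic generator: what it does and does not emulate

`make_icosphere()` + `paint_map_patch()` + `simulate_phase_runs()` /
`simulate_reading_cohort()` produce every input the analysis consumes,
with ground truth stored alongside. Emulated: periodic responses with
haemodynamic lag and phase-encoded coordinates; opposite-direction run
pairs; white noise plus optional sinusoidal drift placed exactly at the
three excluded low-frequency bins (so the exclusion rule is exercised)
and optional AR(1) autocorrelation (so prewhitening is exercised);
balanced random 16 s block orders with 1 s button-press events;
between-subject von Mises phase jitter and log-normal amplitude/effect
scaling on a shared mesh. Defaults follow the study design the package
targets: 8 cycles per run, 64 s cycles, 32 blocks of 16 s across four
conditions, 4 runs, 100 s high-pass.

Not emulated: real cortical geometry and its folding-dependent vertex
density; between-subject spatial misregistration (subjects share one
mesh, so registration error never degrades the group average);
physiological noise structure beyond AR(1) and drift; BOLD
nonlinearity and habituation. Passing recovery tests therefore show
the *estimators* are correct and calibrated, not that real-data effect
sizes or the published overlap percentages will reproduce — those
depend on data the generator cannot stand in for.

One consequence shows up directly in testing: surface smoothing
spreads true signal beyond patch boundaries, so thresholded masks
recovered from smoothed maps are dilated versions of the ground-truth
patches and their overlap percentage is biased where boundary rings are
large relative to patch size. The end-to-end recovery test therefore
runs the chain without smoothing at high SNR, where both masks are
recovered essentially exactly and the reported percentage matches the
constructed truth to well within 5 points; the bundled toy scenario
keeps smoothing on to exercise the full path and checks determinism and
internal consistency instead of truth recovery.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the
caller's RNG state; reruns are bit-identical, which the pipeline test
verifies down to output-file hashes. Scenario configs are YAML with all
units explicit; `run_scenario()` writes a provenance log (stage
parameters, seeds, MD5s). The test and acceptance simulations use
desk-scale sizes chosen to keep Monte-Carlo error well inside the
asserted tolerances: 10,000 vertices for null-calibration suites,
642–2562-vertex icospheres for cluster and end-to-end checks, 2000
estimation + 1000 fresh iterations for the familywise self-consistency
check.

## Known limitations

- Vertex correspondence across subjects is assumed, not computed; there
  is no spherical registration.
- The group complex statistic assumes isotropic complex noise; strongly
  anisotropic inter-subject variability would call for the full
  Hotelling form.
- Prewhitening is AR(1) with a pooled coefficient; long-memory noise is
  only partially absorbed (the high-pass basis takes the rest).
- Geodesic distances for patch painting use shortest edge paths, which
  overestimate true geodesics by a few percent on coarse meshes.
- The GIFTI reader/writer covers the ASCII encoding used by this
  package's own files, not the full format (no compressed binary
  encodings, no metadata blocks).
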