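---
title: "Task-based and task-free seed connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based and task-free seed connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactiv)
```

## The scientific problem

Two complementary operationalizations of functional connectivity for a
seed region are implemented end to end:

* **Task-based connectivity (MACM).** Across a database of neuroimaging
  experiments — each a reported group contrast with a subject count and a
  list of activation-peak coordinates in MNI millimetres — a seed's
  connectivity is the set of brain regions whose reported activations
  converge above chance in exactly those experiments that also activate
  the seed. The unit of observation is the experiment.
* **Task-free connectivity (resting state).** Within subjects, a seed's
  connectivity is the Pearson correlation between the seed's summary time
  course and every grey-matter voxel of denoised, band-pass-filtered BOLD
  data, Fisher-transformed and tested across subjects.

The package also implements the cross-validation layer that joins the
two — minimum-statistic conjunctions of thresholded maps and of
between-seed contrasts — and a functional-decoding layer that profiles a
region or network against a behavioural label taxonomy with exact
binomial base-rate tests.

Because the canonical inputs for these analyses (a proprietary
coordinate database; a large unpublished resting-state cohort) cannot be
shipped, the package treats synthetic data generation as a first-class,
tested module: foci databases with planted co-activation networks and
BOLD datasets with planted seed–target correlations under realistic
confounds. Every claim the test suite makes about the pipeline is a claim
about recovering that planted ground truth.

## The ALE model

Each reported focus is modelled as a 3-D Gaussian probability
distribution centred on the reported coordinate, expressing spatial
uncertainty. Discretely, the kernel mass of a voxel is the product over
axes of 1-D normal CDF differences across the voxel extents, truncated
at ±3.5σ and renormalized to unit mass (`kernel_for_experiment()`).

Within an experiment, per-focus probabilities combine by voxelwise
maximum into a modelled-activation (MA) map (`ma_map()`), so multiple
nearby peaks from one study cannot inflate the map — convergence is
counted between studies, not within. Across experiments the ALE score is
the probabilistic union

$$\mathrm{ALE}(v) \;=\; 1 - \prod_i \bigl(1 - \mathrm{MA}_i(v)\bigr),$$

computed in log space for numerical stability (`ale_from_ma()`).

**Kernel width.** The original algorithm ties kernel width to each
experiment's sample size through an empirical between-subject variance
model whose numbers are external to this package. Rather than hard-code
values from elsewhere, the default policy is a fixed 10-mm FWHM
(`fixed_fwhm()`), and `fwhm_table_policy()` accepts any user-supplied
`n_subjects → FWHM` table so the published uncertainty model can be
plugged in verbatim.

### The null of random spatial association

Significance is judged against the distribution of ALE scores obtained
when the experiments' activation locations are independent given the
brain mask. Two estimators are provided (`null_distribution()`):

* **Analytic histogram** (default): each experiment's in-mask MA values
  are binned (width 10⁻⁵ by default) and the per-experiment histograms
  are combined exactly under the union rule, giving the full null
  distribution with discretization error bounded by one bin in the CDF.
  This is deterministic and is the estimator used everywhere downstream.
* **Sampling**: one uniform in-mask voxel per experiment per draw,
  combined by the union rule. The test suite verifies the two agree to
  within 0.005 in sup-norm CDF distance at 10⁶ draws.

p-values are upper-tail probabilities, with ties counted as
greater-or-equal; sampling p-values use the `(r + 1)/(n + 1)` estimator
so p is never exactly zero, and analytic p-values floor at the smallest
representable tail mass. Z maps are the upper-tail normal quantile of p,
clipped below at −8.2 (the p = 1 boundary).

### Cluster-level family-wise-error correction

Maps are thresholded at the voxel level (p < 0.001 by default), and
cluster extents are compared against a Monte-Carlo null of the maximum
cluster size: in each simulation every experiment's foci are relocated
to uniform random in-mask voxels, the ALE and p maps are recomputed, and
the maximum suprathreshold cluster size is recorded
(`cluster_fwe_threshold()`). The extent threshold is the ceiling of the
1 − α quantile (α = 0.05 by default). The voxel-level null is
location-free by construction, so it is computed once from the observed
MA maps and reused across relocation simulations; only the spatial
configuration changes per iteration. The correction scheme used by the
original in-house implementation is not documented publicly; Monte-Carlo
cluster-size simulation is implemented here and labelled as such.

Cluster "cohesion" uses face (6-neighbour) connectivity by default —
the conservative reading — configurable to 18- or 26-connectivity in
`label_clusters()`.

## Permutation difference maps

For two seeds, the contrast of their MACM maps is assessed by a label
permutation: the two selected experiment sets are pooled and randomly
re-divided into groups of the original sizes, the voxelwise ALE
difference of the relabelled groups is recorded, and repetition (10,000
times at publication scale; 500–1,000 in the tests) yields an empirical
null of ALE-score differences (`ale_difference()`). The per-voxel
posterior probability of a true difference is the mid-p style fraction
`(#{permutation < observed} + 0.5)/(n + 1)`, thresholded at > 0.95
(A>B) and < 0.05 (B>A).

One textual ambiguity deserves note: the source procedure describes
computing observed differences on Z scores while permuting ALE-score
differences. For unit consistency both the observed and the permuted
differences are computed on ALE scores here; `observed_on = "z"`
reproduces the literal reading. Experiments selected by both seeds are
kept as distinct tokens in the pool, mirroring the pooled-relabelling
scheme.

Difference maps are then masked by the minuend's own
cluster-FWE-thresholded main effect — a difference A>B is only reported
where A's connectivity map is itself significant — and clusters below 20
cohesive voxels are removed (`apply_contrast_masking()`).

## The resting-state chain

`rsfc_subject()` runs, in fixed order: discard of initial volumes
(default 4), 5-mm FWHM spatial smoothing, nuisance regression, band-pass
filtering, seed first-eigenvariate extraction, voxelwise correlation and
Fisher Z transform.

**The nuisance model** (`build_nuisance()`) has 36 columns: the six
realignment parameters, their backward-difference derivatives (zero
first row), mean grey/white/CSF signals, the first five principal
components of the whole-brain in-mask time series, the squares of all
non-PCA columns (computed after centring, then re-centred), and an
intercept. All columns except the intercept are mean-centred. Tissue
means and PCs are computed jointly from the discard-trimmed data.

**Filtering** preserves 0.01–0.08 Hz, the band where meaningful
resting-state correlations concentrate. The filter is a zero-phase
frequency-domain (DFT) band-pass applied after linear detrending — the
construction used by standard volume-based resting-state tools. It was
chosen over a forward–backward IIR design because it is exactly
idempotent, phase-free, and meets the package's measured contract:
passband amplitude distortion at a 0.04-Hz probe below 0.1%, stopband
residual amplitude at 0.004 Hz below 5%, with TR 2.2 s and 296 retained
volumes. Filtering follows regression; the order of these two steps is
not dictated by the source procedure, and regressing first avoids
reintroducing out-of-band nuisance variance into the filtered series.

**Seed summary.** All voxel time courses inside a seed are summarized by
their first eigenvariate: the dominant temporal singular vector, scaled
to unit variance and sign-aligned to correlate non-negatively with the
seed-mean time course.

**Group model.** The published analysis used an ANOVA accounting for
non-sphericity with linear contrasts between seeds. For two seeds within
subjects this reduces to the paired contrast, which is what
`group_contrast()` implements: per-subject difference of Fisher-Z maps,
one-sample t statistic per voxel, one-sided voxel threshold (p < 0.001),
and cluster-level FWE by a sign-flipping permutation null of the maximum
cluster size. Both directions are reported; the flexible-factorial
machinery itself is out of scope.

## Conjunctions and functional decoding

For already-thresholded (binary) maps the minimum statistic reduces to
the voxelwise AND (`min_conjunction()`); the conjunction of contrasts
intersects, per direction, the MACM and resting-state surviving masks
(`conjunction_of_contrasts()`).

Functional characterization (`build_pool()` / `characterize()`) pools
the experiments activating either of two regions (or, in network mode, a
region and at least one of its partners), computes the base rate — the
prior probability that a pool membership belongs to side A — and, per
taxonomy label with at least 5 labelled experiments, compares the
conditional probability of side-A membership given the label against the
base rate with a one-sided exact binomial test, in both directions,
Bonferroni-corrected over all tested (label, direction) pairs.

Two counting conventions were left open by the source description and
resolved as follows: counting is at the experiment level (avoiding
within-study dependence among foci), and the test is one-sided
over-representation per direction with both directions tested — the
stricter multiple-testing accounting. Both choices are documented here
rather than asserted as the original authors'.

## The synthetic-data generators

### Foci databases (`simulate_foci_db()`)

A `network_spec` defines spherical regions, networks (member regions
with per-member co-report probabilities, a prevalence, a label and a
label fidelity), a uniform background focus rate and a focus jitter. The
default crossed spec plants two networks of one seed + two partner
regions each: own-seed co-report 0.9, own-partner 0.8, cross-network
0.05, prevalence 0.45 each (10% pure background), Poisson(2) background
foci, 3-mm isotropic focus jitter, 150 experiments with 10–30 subjects.
Ground truth (network and per-focus provenance) is returned alongside
the database so tests never re-derive it.

### BOLD datasets (`simulate_bold()`)

Latent unit-variance Gaussian signals are generated directly in the
0.01–0.08 Hz analysis passband, so band-pass filtering is approximately
information-preserving and filter testing is decoupled from recovery
testing. A target region's signal is
`Σ_j r_j · seed_j + √(1 − Σ r_j²) · independent`, making its expected
correlation with each seed exactly the planted value (0.5 own-network,
0.05 crossed, by default). On top of the region signals, every in-mask
voxel receives white noise (SD 0.5), a shared global fluctuation
(amplitude 1, per-voxel weight 0.8–1.2 with per-voxel vascular-lag
(quadrature) heterogeneity), per-voxel linear and quadratic drift
(amplitude 2), and a confound coupled to slow random-walk motion; the
emitted motion file carries the true motion plus realistic
realignment-estimate noise. Tissue masks are geometric shells of the
ellipsoidal brain (grey core, white shell, CSF rind).

Sixteen background networks (10-mm spheres, amplitude 1.5, placed clear
of the planted regions) provide the large-scale coherent structure that
real brains have. This matters for fidelity of the *confound model*
test: whole-brain PCs and tissue-mean regressors are data-derived, and
in a brain whose only coherent structure is the planted network they
lock onto the very signal under study — an artifact of an over-sterile
simulation, not a property of the method. With realistic background
structure the data-derived regressors are dominated by global,
drift, motion and background components, as intended.

Default dimensions mirror the study conditions at desk scale: a
24 × 28 × 24 grid at 4-mm isotropic voxels, 300 volumes at TR 2.2 s with
the first four discarded, 20 subjects.

### What passing tests do and do not show

The generators emulate network-structured co-activation, label
enrichment, and confounded BOLD with planted correlations. They do not
emulate spatially autocorrelated scanner noise, biophysical
haemodynamics (no balloon model), susceptibility artefacts, or
between-subject anatomical variability (inputs are assumed spatially
registered; registration is out of scope). Recovery of planted truth
under this model validates the statistical machinery — selection, union
scores, permutation nulls, FWE control, denoising algebra — not the
robustness of the method to every property of real data.

## Numerical choices and degenerate inputs

* Coordinates: voxel indices are 0-based; the affine maps indices to
  voxel centres in mm; mm→voxel rounding is half-away-from-zero;
  conversion happens exactly once, when foci are placed on the grid.
* Null histogram bin width 10⁻⁵ (configurable); combination aggregates
  exact bin collisions by run-length sums, so probabilities sum to 1 to
  10⁻⁹.
* Smoothing zero-pads outside the mask and re-masks, without edge
  renormalization — the standard volumetric convention, documented so
  variants can be compared.
* Correlations are clipped to ±(1 − 10⁻⁷) before `atanh`; zero-variance
  voxels yield z = 0 with a log message.
* Rank-deficient nuisance designs drop dependent columns with a message;
  empty tissue masks, empty seeds, Talairach-tagged foci files and
  sub-Nyquist-violating filter bands are errors.
* Measuring recovery "at the target": group-mean Fisher Z is evaluated
  over the planted target sphere eroded by one voxel. At 4-mm voxels a
  5-mm smoothing kernel dilutes the outermost voxel layer with
  surrounding tissue (a partial-volume effect), so the eroded core is
  the honest summary of the region's connectivity; the full-sphere mean
  runs about 0.05 lower for exactly this reason.
* All stochastic operations take an explicit `rng_seed`; pipeline
  wrappers derive child seeds deterministically so a single seed
  reproduces a whole run bit-identically.

## Problem sizes used by the tests

The test suite and the acceptance script run at desk scale, chosen as
the smallest sizes at which each statistical claim is meaningful: a 20³
grid (4-mm voxels, ellipsoidal mask of ≈3,000 voxels) for ALE
properties; 150-experiment databases; 1,000 permutations for difference
maps (10,000 reproduces publication scale); 100 Monte-Carlo simulations
for FWE extents; 200 replicates for the contrast type-I error; 12–20
subjects for the resting-state recovery. The fixture seed catalogue
(`fixture_seeds()`) ships the four published working-memory peaks as
6-mm spheres — including the dorsal right peak exactly as printed
(24, 12, 15), whose z coordinate is plausibly a typo for a posterior
superior frontal location (z ≈ 51); it is deliberately reproduced, not
corrected, and this note is the documentation of that choice.

## Known limitations

* The fixed-FWHM default kernel ignores sample-size-dependent smoothing
  unless a table is supplied.
* The analytic null treats voxels as exchangeable within the mask; mask
  edge effects (kernel truncation) are shared with the standard
  implementation but mean the null is approximate very close to the
  boundary.
* `pool_and_split()` seeding uses R's global RNG (scoped per call);
  parallel execution is not managed by the package.
* The resting-state chain assumes spatially registered inputs; no
  realignment, normalization or slice-timing correction is performed.
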