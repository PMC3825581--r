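# coactiv

Task-based and task-free seed connectivity for neuroimaging, in R.

`coactiv` implements the full inference chain that joins **meta-analytic
connectivity modelling (MACM)** over activation-focus databases with
**seed-based resting-state functional connectivity**, cross-validates the
two by **minimum-statistic conjunction**, and profiles the resulting
regions against a behavioural label taxonomy with **exact binomial
base-rate tests**. It ships first-class synthetic-data generators with
planted ground truth, so every stage is testable without access to
proprietary coordinate databases or restricted cohort data.

## What it computes

**ALE / MACM.** Each reported activation peak is a 3-D Gaussian
probability kernel; per experiment these combine by voxelwise maximum
into a modelled-activation (MA) map, and across experiments into the
activation likelihood estimate

    ALE(v) = 1 − ∏ᵢ (1 − MAᵢ(v)),

tested against the exact (histogram-combined) null of random spatial
association, with cluster-level FWE correction by Monte-Carlo
max-cluster-size simulation (voxel p < 0.001, cluster α = 0.05). MACM
selects, from a foci database, the experiments reporting at least one
focus inside a seed mask and runs ALE on them. Seed contrasts use
permutation (pool-and-relabel) nulls of ALE differences with posterior
probability > 0.95, minuend main-effect masking and a 20-voxel extent
rule.

**Resting state.** Per subject: discard → 5-mm smoothing → 36-column
nuisance regression (motion + derivatives, grey/white/CSF means, five
whole-brain PCs, squares of all non-PCA columns) → 0.01–0.08 Hz
zero-phase band-pass → seed first eigenvariate → voxelwise Pearson r →
Fisher Z. Group inference is the paired two-seed contrast with
sign-flipping cluster-level FWE.

**Decoding.** For a pool of experiments activating either of two
regions (or networks), each taxonomy label's conditional probability of
side membership is compared with the pool base rate by one-sided exact
binomial tests, Bonferroni-corrected.

## Worked example

```r
library(coactiv)

g    <- synthetic_grid(shape = c(20, 20, 20), voxel_mm = 4)
sim  <- simulate_foci_db(default_network_spec(n_experiments = 150), g, rng_seed = 11)
sim$db
#> foci_db: 150 experiments, 675 foci (MNI space)

seedA <- sphere_mask(g, c(-22, 22, 8), 9)   # frontal seed analogue A
seedB <- sphere_mask(g, c(22, 22, 8), 9)    # frontal seed analogue B

cr <- run_macm_contrast(sim$db, seedA, seedB, g,
                        spec = threshold_spec(n_cluster_sims = 100),
                        n_perm = 1000, rng_seed = 99, min_extent = 5)
cr$run_a
#> macm_run: 48 selected experiments, 3 significant clusters (extent >= 11)
cr$contrast
#> contrast_result: 1000 perms, 157 voxels A>B, 138 voxels B>A (masked)
cr$run_a$clusters[, 1:6]
#>   cluster_id size_voxels peak_value peak_x peak_y peak_z
#> 1          1          64  0.5931966    -10     -2    -22
#> 2          2          55  0.7412199    -22     22      6
#> 3          3          42  0.5493899    -22    -18     10
```

The three clusters of seed A's own MACM map sit at the planted partner
region P_A2 (−8, −2, −24), the seed itself (−22, 22, 8: selection
guarantees peak convergence at the seed), and partner P_A1
(−22, −20, 8). The masked contrast flags each seed's own partners in its
direction — the planted double dissociation. `peak_value` is the ALE
score at the cluster peak; `size_voxels` counts 4-mm voxels.

Reading real data instead: `read_sleuth()` / `read_foci_tsv()` for foci
databases (a small example lives in `inst/extdata/`), `read_nifti()` for
seed masks and volumes, `ts_dataset()` + `read_motion()` for BOLD runs,
then `rsfc_subject()` and `group_contrast()`.

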