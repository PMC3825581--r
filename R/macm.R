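# MACM orchestration: seed selection -> ALE -> thresholding, pairwise seed
# contrasts, and the reciprocal reseeding recipe.

#' Run a meta-analytic connectivity modelling analysis for one seed
#'
#' Identifies all experiments in the database reporting at least one focus
#' inside the seed, quantifies the convergence of their foci with ALE,
#' derives voxelwise p-values against the null of random spatial
#' association, applies cluster-level FWE correction (Monte-Carlo extent
#' threshold at `spec$cluster_alpha`, cluster-forming threshold
#' `spec$voxel_p`), and Z-transforms the map for display. Because
#' experiments are selected by activation in the seed, the strongest
#' convergence is expected in the seed region itself.
#'
#' @param db a [foci_db].
#' @param seed_mask a MASK [stat_volume] (bilateral seeds may be supplied
#'   as a single union mask).
#' @param grid a [brain_grid] (defaults to the seed's grid).
#' @param spec a [threshold_spec].
#' @param fwhm_policy kernel policy.
#' @param rng_seed integer seed for the cluster simulation.
#' @return A `macm_run`: list with `seed`, `selected_db`, `ale`, `p`, `z`
#'   volumes, `clusters` (FWE-surviving [label_clusters()] table),
#'   `sig_mask` (MASK of surviving clusters), `extent_threshold`, and a
#'   `provenance` config snapshot.
#' @export
run_macm <- function(db, seed_mask, grid = seed_mask$grid,
                     spec = threshold_spec(), fwhm_policy = fixed_fwhm(10),
                     rng_seed = NULL) {
  stopifnot(inherits(db, "foci_db"), inherits(seed_mask, "stat_volume"))
  if (!any(seed_mask$values > 0)) stop("seed mask is empty")
  sel <- select_by_seed(db, seed_mask)
  if (length(sel$experiments) == 0L) {
    warning("seed selects no experiments; returning empty run")
    return(structure(list(seed = seed_mask, selected_db = sel, ale = NULL,
                          p = NULL, z = NULL, clusters = NULL,
                          sig_mask = mask_volume_from_logical(grid, logical(n_mask_voxels(grid))),
                          extent_threshold = NA_integer_,
                          provenance = list(spec = spec, rng_seed = rng_seed)),
                     class = "macm_run"))
  }
  if (length(sel$experiments) < 10L)
    warning("fewer than 10 selected experiments: null distribution unstable")
  M <- ma_matrix(sel, grid, fwhm_policy)
  null <- null_distribution(M, "analytic_histogram")
  ale <- stat_volume(grid, ale_from_matrix(M), "ALE")
  p <- p_map(ale, null)
  z <- z_map(p)
  kmin <- cluster_fwe_threshold(sel, grid, fwhm_policy, spec,
                                rng_seed = rng_seed, null = null)
  supra <- mask_volume_from_logical(grid, p$values < spec$voxel_p)
  ct <- label_clusters(supra, "face", values = ale)
  ct <- ct[ct$size_voxels >= kmin, , drop = FALSE]
  ct$cluster_id <- seq_len(nrow(ct))
  sig <- logical(n_mask_voxels(grid))
  if (nrow(ct)) sig[match(unlist(ct$members), grid$mask_idx)] <- TRUE
  structure(list(seed = seed_mask, selected_db = sel, ale = ale, p = p, z = z,
                 clusters = ct, sig_mask = mask_volume_from_logical(grid, sig),
                 extent_threshold = kmin, null = null,
                 provenance = list(spec = spec, rng_seed = rng_seed,
                                   n_selected = length(sel$experiments))),
            class = "macm_run")
}

#' @export
print.macm_run <- function(x, ...) {
  cat(sprintf("macm_run: %d selected experiments, %s significant clusters (extent >= %s)\n",
              length(x$selected_db$experiments),
              if (is.null(x$clusters)) 0L else nrow(x$clusters),
              x$extent_threshold))
  invisible(x)
}

#' Contrast the MACM connectivity of two seeds
#'
#' Runs the seed-constrained selection for both seeds, computes the
#' permutation difference map of the two selected experiment sets
#' ([ale_difference()]), and applies minuend main-effect masking with the
#' cluster-FWE-thresholded map of each seed's own analysis plus the
#' minimum-extent filter ([apply_contrast_masking()]).
#'
#' @param db a [foci_db].
#' @param seedA,seedB MASK [stat_volume] seeds.
#' @param grid analysis [brain_grid].
#' @param spec a [threshold_spec] for the main effects.
#' @param fwhm_policy kernel policy.
#' @param n_perm permutations for the difference null.
#' @param rng_seed integer seed.
#' @param min_extent minimum surviving cluster extent (default 20).
#' @return A list: `contrast` (masked `contrast_result`), `run_a`,
#'   `run_b` (the per-seed `macm_run`s).
#' @export
run_macm_contrast <- function(db, seedA, seedB, grid = seedA$grid,
                              spec = threshold_spec(),
                              fwhm_policy = fixed_fwhm(10),
                              n_perm = 10000L, rng_seed = NULL,
                              min_extent = 20L) {
  rs <- derive_seeds(rng_seed, 3L)
  run_a <- run_macm(db, seedA, grid, spec, fwhm_policy, rng_seed = rs[[1]])
  run_b <- run_macm(db, seedB, grid, spec, fwhm_policy, rng_seed = rs[[2]])
  if (length(run_a$selected_db$experiments) == 0L ||
      length(run_b$selected_db$experiments) == 0L)
    stop("a seed selects no experiments; cannot contrast")
  res <- ale_difference(run_a$selected_db, run_b$selected_db, grid,
                        fwhm_policy, n_perm = n_perm, rng_seed = rs[[3]])
  res <- apply_contrast_masking(res, run_a$sig_mask, run_b$sig_mask,
                                min_extent = min_extent)
  list(contrast = res, run_a = run_a, run_b = run_b)
}

#' Reciprocal reseeding of discovered regions
#'
#' Cross-validation recipe: the regions discovered as differentially
#' connected are used as seeds themselves, their pairwise contrast is
#' computed, and the resulting difference maps are restricted to the union
#' of the original seeds (inclusive masking). Reciprocity holds when each
#' discovered region's ">" map recovers the original seed it was
#' discovered from.
#'
#' @param db a [foci_db].
#' @param discovered_masks list of two MASK volumes (the regions found
#'   differentially connected to `original_seeds[[1]]` and
#'   `original_seeds[[2]]` respectively).
#' @param original_seeds list of two MASK volumes (the original seeds,
#'   used as inclusive masks).
#' @param grid analysis grid.
#' @param spec,fwhm_policy,n_perm,rng_seed,min_extent as in
#'   [run_macm_contrast()]. `min_extent` defaults to 1 here because the
#'   inclusive masks are typically small.
#' @return A list with `contrast` (the reseeded contrast restricted to the
#'   seed union), `in_seed1_AgtB`, `in_seed1_BgtA`, `in_seed2_AgtB`,
#'   `in_seed2_BgtA` (surviving voxel counts inside each original seed per
#'   direction).
#' @export
reciprocal_reseed <- function(db, discovered_masks, original_seeds,
                              grid = original_seeds[[1]]$grid,
                              spec = threshold_spec(),
                              fwhm_policy = fixed_fwhm(10),
                              n_perm = 1000L, rng_seed = NULL,
                              min_extent = 1L) {
  stopifnot(length(discovered_masks) == 2L, length(original_seeds) == 2L)
  for (m in c(discovered_masks, original_seeds))
    if (!any(m$values > 0)) stop("empty mask supplied")
  cr <- run_macm_contrast(db, discovered_masks[[1]], discovered_masks[[2]],
                          grid, spec, fwhm_policy, n_perm, rng_seed,
                          min_extent = min_extent)
  incl <- mask_union(original_seeds[[1]], original_seeds[[2]])
  res <- cr$contrast
  res$surviving_mask_AgtB <- mask_volume_from_logical(
    grid, res$surviving_mask_AgtB$values * incl$values > 0)
  res$surviving_mask_BgtA <- mask_volume_from_logical(
    grid, res$surviving_mask_BgtA$values * incl$values > 0)
  count_in <- function(dir_mask, seed)
    sum(dir_mask$values * seed$values > 0)
  list(contrast = res,
       in_seed1_AgtB = count_in(res$surviving_mask_AgtB, original_seeds[[1]]),
       in_seed1_BgtA = count_in(res$surviving_mask_BgtA, original_seeds[[1]]),
       in_seed2_AgtB = count_in(res$surviving_mask_AgtB, original_seeds[[2]]),
       in_seed2_BgtA = count_in(res$surviving_mask_BgtA, original_seeds[[2]]),
       runs = cr[c("run_a", "run_b")])
}

#' Fixture seed spheres at the published working-memory peaks
#'
#' Four spherical seeds centred at the MNI peaks of the prior
#' working-memory meta-analysis that defined the ventral ("what") and
#' dorsal ("where") frontal regions: ventral left (-40, 12, 32), ventral
#' right (42, 6, 26), dorsal left (-20, 10, 56), dorsal right (24, 12, 15).
#' The dorsal right peak is reproduced exactly as printed even though its
#' z coordinate appears inconsistent with a posterior superior frontal
#' location (plausibly a typo for z near 51); it is deliberately not
#' corrected here.
#'
#' @param grid a [brain_grid] (default [mni_like_grid()]).
#' @param radius_mm sphere radius in millimetres (default 6; the source
#'   cluster extents are unpublished, so the radius is configurable).
#' @param bilateral if `TRUE` (default) returns two union masks
#'   (`ventral`, `dorsal`); otherwise four separate spheres.
#' @return Named list of MASK [stat_volume]s.
#' @export
fixture_seeds <- function(grid = mni_like_grid(), radius_mm = 6,
                          bilateral = TRUE) {
  peaks <- list(
    ventral_left  = c(-40, 12, 32),
    ventral_right = c(42, 6, 26),
    dorsal_left   = c(-20, 10, 56),
    dorsal_right  = c(24, 12, 15))
  spheres <- lapply(peaks, function(p) sphere_mask(grid, p, radius_mm))
  if (!bilateral) return(spheres)
  list(ventral = mask_union(spheres$ventral_left, spheres$ventral_right),
       dorsal = mask_union(spheres$dorsal_left, spheres$dorsal_right))
}

# Derive k child seeds from one integer seed, all below 2^31.
derive_seeds <- function(rng_seed, k) {
  if (is.null(rng_seed)) return(rep(list(NULL), k))
  base <- as.double(rng_seed)
  as.list((base * 7919 + 104729 * seq_len(k)) %% 2147483629)
}
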