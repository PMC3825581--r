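# Permutation-based ALE difference maps with posterior-probability
# thresholding, minuend main-effect masking and minimum-extent filtering.

#' Permutation difference map between two ALE analyses
#'
#' The observed voxelwise difference `ALE(dbA) - ALE(dbB)` is compared to
#' an empirical null of ALE-score differences: the experiments of both
#' groups are pooled and randomly re-divided into two groups of the
#' original sizes, the ALE difference of the relabelled groups is
#' recorded, and the process is repeated `n_perm` times. The per-voxel
#' posterior probability of a true difference is the mid-p style fraction
#' `(#\{permutation difference < observed\} + 0.5) / (n_perm + 1)`;
#' voxels with posterior > `prob_threshold` are flagged A>B, voxels with
#' posterior < `1 - prob_threshold` are flagged B>A.
#'
#' Both the observed and the permuted differences are computed on ALE
#' scores (one unit throughout); `observed_on = "z"` instead takes the
#' observed difference on the Z-transformed maps of each group's own
#' analytic null while still permuting ALE differences.
#'
#' @param dbA,dbB [foci_db] objects (non-empty).
#' @param grid a [brain_grid].
#' @param fwhm_policy kernel policy (see [kernel_for_experiment()]).
#' @param n_perm number of permutations (default 10000; >= 100).
#' @param rng_seed integer seed.
#' @param prob_threshold posterior threshold (default 0.95).
#' @param observed_on `"ale"` (default) or `"z"`.
#' @return A `contrast_result`: list with `diff_observed` (DIFF volume),
#'   `posterior` (R volume in \[0, 1\]), `surviving_mask_AgtB`,
#'   `surviving_mask_BgtA` (MASK volumes), `n_permutations`, `rng_seed`,
#'   `masked` (FALSE until [apply_contrast_masking()]).
#' @export
ale_difference <- function(dbA, dbB, grid, fwhm_policy = fixed_fwhm(10),
                           n_perm = 10000L, rng_seed = NULL,
                           prob_threshold = 0.95,
                           observed_on = c("ale", "z")) {
  stopifnot(inherits(dbA, "foci_db"), inherits(dbB, "foci_db"))
  observed_on <- match.arg(observed_on)
  nA <- length(dbA$experiments); nB <- length(dbB$experiments)
  if (nA == 0L || nB == 0L) stop("both databases must be non-empty")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  MA <- ma_matrix(dbA, grid, fwhm_policy)
  MB <- ma_matrix(dbB, grid, fwhm_policy)
  L <- cbind(log1p(-pmin(MA, 1 - 1e-15)), log1p(-pmin(MB, 1 - 1e-15)))
  aleA <- 1 - exp(rowSums(L[, seq_len(nA), drop = FALSE]))
  aleB <- 1 - exp(rowSums(L[, nA + seq_len(nB), drop = FALSE]))
  obs <- if (observed_on == "ale") aleA - aleB else {
    zA <- z_map(p_map(stat_volume(grid, aleA, "ALE"),
                      null_distribution(MA, "analytic_histogram")))
    zB <- z_map(p_map(stat_volume(grid, aleB, "ALE"),
                      null_distribution(MB, "analytic_histogram")))
    zA$values - zB$values
  }
  seed_rng(rng_seed)
  N <- nA + nB
  tot <- rowSums(L)
  V <- nrow(L)
  count_less <- numeric(V)
  chunk <- max(1L, min(as.integer(n_perm), as.integer(2^24 / V)))
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    I <- matrix(0, N, m)
    for (j in seq_len(m)) I[sample.int(N, nA), j] <- 1
    SA <- L %*% I
    dperm <- (1 - exp(SA)) - (1 - exp(tot - SA))
    count_less <- count_less + rowSums(dperm < obs)
    done <- done + m
  }
  posterior <- (count_less + 0.5) / (n_perm + 1)
  structure(list(
    diff_observed = stat_volume(grid, aleA - aleB, "DIFF"),
    observed = stat_volume(grid, obs, "DIFF"),
    posterior = stat_volume(grid, posterior, "R"),
    surviving_mask_AgtB = mask_volume_from_logical(grid, posterior > prob_threshold),
    surviving_mask_BgtA = mask_volume_from_logical(grid, posterior < 1 - prob_threshold),
    n_permutations = as.integer(n_perm),
    prob_threshold = prob_threshold,
    rng_seed = rng_seed, masked = FALSE
  ), class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast_result: %d perms, %d voxels A>B, %d voxels B>A%s\n",
              x$n_permutations, sum(x$surviving_mask_AgtB$values),
              sum(x$surviving_mask_BgtA$values),
              if (x$masked) " (masked)" else ""))
  invisible(x)
}

#' Minuend masking and extent filtering of a contrast
#'
#' Restricts each direction of a difference map to its minuend's own
#' significant main effect (a difference A>B is only meaningful where A's
#' thresholded connectivity map is itself significant) and removes
#' clusters smaller than `min_extent` cohesive voxels (face connectivity).
#'
#' @param res a `contrast_result` from [ale_difference()].
#' @param main_effect_A,main_effect_B cluster-FWE-thresholded main-effect
#'   MASK volumes of `dbA` and `dbB`.
#' @param min_extent minimum surviving cluster size in voxels (default 20).
#' @return The masked `contrast_result`.
#' @export
apply_contrast_masking <- function(res, main_effect_A, main_effect_B,
                                   min_extent = 20L) {
  stopifnot(inherits(res, "contrast_result"))
  grid <- res$posterior$grid
  a <- res$surviving_mask_AgtB$values * main_effect_A$values
  b <- res$surviving_mask_BgtA$values * main_effect_B$values
  res$surviving_mask_AgtB <- drop_small_clusters(
    mask_volume_from_logical(grid, a > 0), min_extent)
  res$surviving_mask_BgtA <- drop_small_clusters(
    mask_volume_from_logical(grid, b > 0), min_extent)
  res$min_extent <- as.integer(min_extent)
  res$masked <- TRUE
  res
}

#' Remove clusters below a minimum extent
#'
#' @param mask a MASK [stat_volume].
#' @param min_extent minimum cluster size (voxels, face connectivity).
#' @return The filtered MASK volume.
#' @export
drop_small_clusters <- function(mask, min_extent) {
  stopifnot(inherits(mask, "stat_volume"), mask$kind == "MASK")
  if (min_extent <= 1L || !any(mask$values > 0)) return(mask)
  ct <- label_clusters(mask, "face")
  keep_lin <- unlist(ct$members[ct$size_voxels >= min_extent])
  keep <- logical(n_mask_voxels(mask$grid))
  if (length(keep_lin)) {
    pos <- match(keep_lin, mask$grid$mask_idx)
    keep[pos] <- TRUE
  }
  mask_volume_from_logical(mask$grid, keep)
}
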