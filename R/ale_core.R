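# ALE engine: focus kernels, modelled-activation maps, union ALE scores,
# empirical null of random spatial association, p/Z maps, cluster-level FWE.

#' Fixed-FWHM kernel policy
#'
#' ALE models each reported focus as a 3-D Gaussian capturing its spatial
#' uncertainty. The width may depend on the experiment's sample size; this
#' package does not hard-code any published uncertainty table, so the
#' default policy is a fixed FWHM and [fwhm_table_policy()] lets users plug
#' in an empirical n_subjects -> FWHM mapping.
#'
#' @param fwhm_mm kernel FWHM in millimetres (default 10).
#' @return A function mapping `n_subjects` to an FWHM.
#' @export
fixed_fwhm <- function(fwhm_mm = 10) {
  force(fwhm_mm)
  stopifnot(fwhm_mm > 0)
  function(n_subjects) fwhm_mm
}

#' Sample-size dependent kernel policy from a lookup table
#'
#' @param n integer vector of subject counts.
#' @param fwhm_mm FWHM (mm) for each count; counts outside the table are
#'   mapped to the nearest tabulated count.
#' @return A policy function for [kernel_for_experiment()].
#' @export
fwhm_table_policy <- function(n, fwhm_mm) {
  stopifnot(length(n) == length(fwhm_mm), all(fwhm_mm > 0))
  ord <- order(n)
  n <- n[ord]; fwhm_mm <- fwhm_mm[ord]
  function(n_subjects) fwhm_mm[which.min(abs(n - n_subjects))]
}

#' Gaussian focus kernel for an experiment
#'
#' Discrete 3-D Gaussian: per-axis voxel masses are 1-D normal CDF
#' differences over the voxel extents (sigma = FWHM / 2.3548 / voxel size),
#' truncated at +/- 3.5 sigma and renormalized so each focus contributes
#' unit probability mass.
#'
#' @param n_subjects experiment sample size (passed to the policy).
#' @param grid a [brain_grid].
#' @param fwhm_policy function from `n_subjects` to FWHM in mm (see
#'   [fixed_fwhm()]), or a single number.
#' @return A `kernel3d` object: list with `fwhm_mm` and `support`, an
#'   odd-sized array of voxel masses summing to 1.
#' @export
kernel_for_experiment <- function(n_subjects, grid, fwhm_policy = fixed_fwhm(10)) {
  stopifnot(n_subjects >= 1)
  fwhm <- if (is.function(fwhm_policy)) fwhm_policy(n_subjects) else as.numeric(fwhm_policy)
  stopifnot(fwhm > 0)
  lines <- lapply(1:3, function(axis)
    gaussian_line_kernel(fwhm_to_sigma(fwhm) / grid$voxdim[axis]))
  support <- outer(outer(lines[[1]], lines[[2]]), lines[[3]])
  support <- support / sum(support)
  structure(list(fwhm_mm = fwhm, support = support), class = "kernel3d")
}

# Splat kernels at focus voxels into a full array, combining with max
# (default) or probabilistic union. foci_vox: n x 3 matrix of 0-based
# in-grid voxel indices.
splat_kernel <- function(foci_vox, kernel, shape, combine = c("max", "union")) {
  combine <- match.arg(combine)
  a <- array(0, shape)
  ks <- dim(kernel$support)
  r <- (ks - 1L) %/% 2L
  for (f in seq_len(nrow(foci_vox))) {
    v <- foci_vox[f, ]
    lo <- pmax(v - r, 0L)
    hi <- pmin(v + r, shape - 1L)
    if (any(lo > hi)) next
    kl <- lo - (v - r) + 1L
    kh <- hi - (v - r) + 1L
    sub <- kernel$support[kl[1]:kh[1], kl[2]:kh[2], kl[3]:kh[3], drop = FALSE]
    ai <- (lo[1]:hi[1]) + 1L; aj <- (lo[2]:hi[2]) + 1L; ak <- (lo[3]:hi[3]) + 1L
    cur <- a[ai, aj, ak, drop = FALSE]
    a[ai, aj, ak] <- if (combine == "max") pmax(cur, sub) else
      1 - (1 - cur) * (1 - sub)
  }
  a
}

# In-mask foci voxel indices for an experiment; drops out-of-mask foci.
usable_foci_vox <- function(exp, grid, warn = TRUE) {
  vox <- mm_to_voxel(exp$foci, grid)
  if (is.null(dim(vox))) vox <- matrix(vox, 1L, 3L)
  lin <- voxel_to_linear(vox, grid$shape)
  ok <- !is.na(lin) & grid$mask[ifelse(is.na(lin), 1L, lin)]
  if (warn && any(!ok))
    message(sprintf("experiment '%s': dropping %d out-of-mask focus/foci",
                    exp$id, sum(!ok)))
  vox[ok, , drop = FALSE]
}

#' Modelled-activation (MA) map of one experiment
#'
#' Each focus places its Gaussian kernel on the grid; within an experiment
#' the per-focus probabilities are combined voxelwise by maximum (the
#' revised, non-additive rule), so repeated or adjacent foci from one study
#' cannot inflate the map. `combine = "union"` gives the probabilistic
#' union variant.
#'
#' @param exp an [experiment].
#' @param grid a [brain_grid].
#' @param kernel a `kernel3d` from [kernel_for_experiment()].
#' @param combine `"max"` (default) or `"union"`.
#' @return A [stat_volume] of kind `"MA"`.
#' @export
ma_map <- function(exp, grid, kernel, combine = c("max", "union")) {
  combine <- match.arg(combine)
  vox <- usable_foci_vox(exp, grid)
  if (nrow(vox) == 0L)
    stop(sprintf("experiment '%s' has no usable (in-mask) foci", exp$id))
  a <- splat_kernel(vox, kernel, grid$shape, combine)
  stat_volume(grid, pmin(a[grid$mask_idx], 1), "MA")
}

# V x N matrix of MA values over in-mask voxels (fast path shared by ALE,
# permutation contrasts and FWE simulation). Kernels are cached per unique
# FWHM. skip_empty: drop experiments with no usable foci instead of error.
ma_matrix <- function(db, grid, fwhm_policy = fixed_fwhm(10),
                      combine = "max", warn = FALSE) {
  n <- length(db$experiments)
  V <- n_mask_voxels(grid)
  M <- matrix(0, V, n)
  cache <- list()
  for (i in seq_len(n)) {
    e <- db$experiments[[i]]
    fw <- if (is.function(fwhm_policy)) fwhm_policy(e$n_subjects) else fwhm_policy
    key <- sprintf("%.6g", fw)
    if (is.null(cache[[key]]))
      cache[[key]] <- kernel_for_experiment(e$n_subjects, grid, fixed_fwhm(fw))
    vox <- usable_foci_vox(e, grid, warn = warn)
    if (nrow(vox) == 0L)
      stop(sprintf("experiment '%s' has no usable (in-mask) foci", e$id))
    a <- splat_kernel(vox, cache[[key]], grid$shape, combine)
    M[, i] <- pmin(a[grid$mask_idx], 1)
  }
  M
}

#' Union ALE scores from MA maps
#'
#' The voxelwise ALE score is the probabilistic union of the modelled
#' activation probabilities across experiments:
#' `ALE(v) = 1 - prod_i (1 - MA_i(v))`.
#'
#' @param ma_maps list of [stat_volume] objects of kind `"MA"` sharing one
#'   grid.
#' @return A [stat_volume] of kind `"ALE"`.
#' @export
ale_from_ma <- function(ma_maps) {
  if (length(ma_maps) == 0L) stop("need at least one MA map")
  grid <- ma_maps[[1]]$grid
  for (m in ma_maps) {
    stopifnot(inherits(m, "stat_volume"))
    if (!identical(m$grid$shape, grid$shape)) stop("MA maps must share one grid")
  }
  M <- vapply(ma_maps, function(m) m$values, numeric(n_mask_voxels(grid)))
  if (is.null(dim(M))) M <- matrix(M, ncol = length(ma_maps))
  stat_volume(grid, ale_from_matrix(M), "ALE")
}

ale_from_matrix <- function(M) {
  1 - exp(rowSums(log1p(-pmin(M, 1 - 1e-15))))
}

#' Empirical null distribution of ALE under random spatial association
#'
#' The null hypothesis is that the experiments' activation locations are
#' spatially independent given the brain mask. Its ALE distribution at a
#' voxel is the union-combination of one random in-mask MA value per
#' experiment. Two estimators:
#' \describe{
#'   \item{analytic_histogram}{discretize each experiment's in-mask MA
#'     value histogram (bin width `bin_width`) and combine the histograms
#'     exactly under the union rule; deterministic, discretization error
#'     bounded by one bin in the CDF.}
#'   \item{sampling}{draw one uniform in-mask voxel per experiment per
#'     draw and combine by the union rule, `n_draws` times.}
#' }
#'
#' @param ma_maps list of MA [stat_volume]s, or a numeric matrix with one
#'   column of in-mask MA values per experiment.
#' @param method `"analytic_histogram"` (default) or `"sampling"`.
#' @param n_draws number of Monte-Carlo draws for `method = "sampling"`.
#' @param rng_seed integer seed (sampling only).
#' @param bin_width histogram bin width (analytic only; default 1e-5).
#' @return A `null_distribution` object supporting [p_from_null()] and
#'   [null_cdf()].
#' @export
null_distribution <- function(ma_maps, method = c("analytic_histogram", "sampling"),
                              n_draws = 1e5, rng_seed = NULL, bin_width = 1e-5) {
  method <- match.arg(method)
  M <- if (is.matrix(ma_maps)) ma_maps else {
    if (length(ma_maps) < 1L) stop("need at least one MA map")
    vapply(ma_maps, function(m) m$values, numeric(length(ma_maps[[1]]$values)))
  }
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L)
  if (method == "analytic_histogram") {
    probs <- combine_histograms(M, bin_width)
    tail <- rev(cumsum(rev(probs)))
    structure(list(method = "analytic_histogram", bin_width = bin_width,
                   bin_probabilities = probs, tail = tail,
                   n_experiments = ncol(M)),
              class = "null_distribution")
  } else {
    if (n_draws < 1000) warning("sampling null with fewer than 1,000 draws")
    seed_rng(rng_seed)
    V <- nrow(M)
    acc <- numeric(n_draws)
    for (i in seq_len(ncol(M))) {
      x <- M[sample.int(V, n_draws, replace = TRUE), i]
      acc <- acc + log1p(-pmin(x, 1 - 1e-15))
    }
    samples <- sort(1 - exp(acc))
    structure(list(method = "sampling", samples = samples,
                   n_draws = n_draws, n_experiments = ncol(M)),
              class = "null_distribution")
  }
}

# Exact union-combination of per-experiment binned MA histograms.
# Returns a dense probability vector over bins 0..B (bin value = index*w).
combine_histograms <- function(M, w) {
  V <- nrow(M)
  run <- 1  # point mass at ALE = 0 before any experiment
  for (i in seq_len(ncol(M))) {
    idx <- as.integer(round(M[, i] / w))
    tab <- tabulate(idx + 1L, nbins = max(idx) + 1L) / V
    nz <- which(tab > 0)
    y_idx <- nz - 1L
    y_val <- y_idx * w
    q <- tab[nz]
    run_nz <- which(run > 0)
    x_idx <- run_nz - 1L
    x_val <- x_idx * w
    p <- run[run_nz]
    max_new <- as.integer(round((max(x_val) + max(y_val) - max(x_val) * max(y_val)) / w)) + 1L
    acc <- numeric(max_new + 1L)
    for (j in seq_along(y_idx)) {
      ni <- as.integer(round((x_val + y_val[j] - x_val * y_val[j]) / w))
      pv <- p * q[j]
      # x_val ascending and the union map is monotone, so equal target bins
      # form runs: aggregate by run
      ends <- c(which(diff(ni) > 0L), length(ni))
      cs <- cumsum(pv)[ends]
      agg <- diff(c(0, cs))
      tgt <- ni[ends] + 1L
      acc[tgt] <- acc[tgt] + agg
    }
    run <- acc
  }
  run / sum(run)
}

#' Null CDF evaluated at given ALE scores
#' @param null a `null_distribution`.
#' @param x ALE scores.
#' @return `P(X <= x)` under the null.
#' @export
null_cdf <- function(null, x) {
  if (null$method == "analytic_histogram") {
    cdf <- cumsum(null$bin_probabilities)
    idx <- pmin(pmax(as.integer(round(x / null$bin_width)), -1L),
                length(cdf) - 1L)
    ifelse(idx < 0, 0, cdf[idx + 1L])
  } else {
    findInterval(x, null$samples) / null$n_draws
  }
}

#' Upper-tail null probabilities for ALE scores
#'
#' `P(X >= a)` under the null: for analytic histograms the observed value
#' is mapped to its bin (ties count as greater-or-equal); for sampling
#' nulls the `(count >= a + 1) / (n_draws + 1)` estimator is used so p is
#' never exactly zero. Values above the null support return the smallest
#' representable tail mass.
#'
#' @param x numeric ALE scores.
#' @param null a `null_distribution`.
#' @return p-values in (0, 1].
#' @export
p_from_null <- function(x, null) {
  if (null$method == "analytic_histogram") {
    tail <- null$tail
    B <- length(tail) - 1L
    idx <- as.integer(round(x / null$bin_width))
    p <- tail[pmin(pmax(idx, 0L), B) + 1L]
    floor_p <- min(tail[tail > 0])
    pmax(p, floor_p)
  } else {
    n <- null$n_draws
    cnt <- n - findInterval(x, null$samples, left.open = TRUE)
    (cnt + 1) / (n + 1)
  }
}

#' Voxelwise p-map of an ALE image
#'
#' @param ale a [stat_volume] of kind `"ALE"`.
#' @param null a `null_distribution` for the same experiment set.
#' @return A [stat_volume] of kind `"P"`: the proportion of equal or
#'   higher ALE values under the null of random spatial association.
#' @export
p_map <- function(ale, null) {
  stopifnot(inherits(ale, "stat_volume"), ale$kind == "ALE")
  stat_volume(ale$grid, p_from_null(ale$values, null), "P")
}

#' Z transform of a p-map
#'
#' `Z = qnorm(1 - p)`, computed on the upper tail for precision and
#' clipped below at -8.2 (the p = 1 boundary).
#'
#' @param p a [stat_volume] of kind `"P"`.
#' @param floor_z lower clip (default -8.2).
#' @return A [stat_volume] of kind `"Z"`.
#' @export
z_map <- function(p, floor_z = -8.2) {
  stopifnot(inherits(p, "stat_volume"), p$kind == "P")
  z <- stats::qnorm(p$values, lower.tail = FALSE)
  z <- pmax(pmin(z, -floor_z), floor_z)
  stat_volume(p$grid, z, "Z")
}

#' Thresholding specification
#'
#' Defaults follow the standard cluster-level corrected threshold of
#' p < 0.05 with a cluster-forming voxel-level threshold of p < 0.001.
#'
#' @param voxel_p cluster-forming voxel-level p threshold (default 0.001).
#' @param cluster_alpha cluster-level family-wise error rate (default 0.05).
#' @param n_cluster_sims Monte-Carlo simulations for the max-cluster-size
#'   null (default 1000).
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(voxel_p = 0.001, cluster_alpha = 0.05,
                           n_cluster_sims = 1000L) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_alpha > 0, cluster_alpha < 1)
  structure(list(voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 n_cluster_sims = as.integer(n_cluster_sims)),
            class = "threshold_spec")
}

# Max cluster size (face connectivity) of a suprathreshold logical vector
# over in-mask voxels.
max_cluster_size <- function(supra, grid) {
  on_lin <- grid$mask_idx[supra]
  if (length(on_lin) == 0L) return(0L)
  comp <- connected_components(on_lin, grid$shape, "face")
  max(tabulate(comp))
}

#' Monte-Carlo cluster-level FWE extent threshold
#'
#' Simulates the null of random spatial association at the map level: in
#' each iteration every experiment's foci are relocated to uniform random
#' in-mask voxels, the ALE map and its voxelwise p-values are recomputed,
#' the map is binarized at `spec$voxel_p`, and the maximum cluster size is
#' recorded. The returned extent threshold is the ceiling of the
#' `1 - cluster_alpha` quantile of the simulated maxima; observed clusters
#' of at least this size are FWE-significant at `cluster_alpha`.
#'
#' The voxel-level null distribution is location-free by construction and
#' is therefore computed once (from the observed MA maps or a supplied
#' `null`) and reused across iterations.
#'
#' @param db a [foci_db].
#' @param grid a [brain_grid].
#' @param fwhm_policy kernel policy (see [kernel_for_experiment()]).
#' @param spec a [threshold_spec].
#' @param rng_seed integer seed.
#' @param null optional precomputed `null_distribution`.
#' @return Integer minimum cluster size.
#' @export
cluster_fwe_threshold <- function(db, grid, fwhm_policy = fixed_fwhm(10),
                                  spec = threshold_spec(), rng_seed = NULL,
                                  null = NULL) {
  if (spec$n_cluster_sims < 100) warning("fewer than 100 cluster simulations")
  if (is.null(null)) {
    M <- ma_matrix(db, grid, fwhm_policy)
    null <- null_distribution(M, "analytic_histogram")
  }
  seed_rng(rng_seed)
  n_foci <- vapply(db$experiments, function(e) nrow(e$foci), integer(1))
  kernels <- lapply(db$experiments, function(e)
    kernel_for_experiment(e$n_subjects, grid,
                          if (is.function(fwhm_policy)) fwhm_policy else fixed_fwhm(fwhm_policy)))
  V <- n_mask_voxels(grid)
  vox_all <- mask_voxel_coords(grid)
  maxes <- integer(spec$n_cluster_sims)
  for (s in seq_len(spec$n_cluster_sims)) {
    logs <- numeric(V)
    for (i in seq_along(n_foci)) {
      pick <- sample.int(V, n_foci[i], replace = TRUE)
      a <- splat_kernel(vox_all[pick, , drop = FALSE], kernels[[i]], grid$shape)
      logs <- logs + log1p(-pmin(a[grid$mask_idx], 1 - 1e-15))
    }
    ale <- 1 - exp(logs)
    pv <- p_from_null(ale, null)
    maxes[s] <- max_cluster_size(pv < spec$voxel_p, grid)
  }
  as.integer(ceiling(stats::quantile(maxes, 1 - spec$cluster_alpha, names = FALSE)))
}

# 0-based voxel coordinates of all in-mask voxels (V x 3).
mask_voxel_coords <- function(grid) {
  lin0 <- grid$mask_idx - 1L
  i <- lin0 %% grid$shape[1]
  rest <- lin0 %/% grid$shape[1]
  cbind(i, rest %% grid$shape[2], rest %/% grid$shape[2])
}
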