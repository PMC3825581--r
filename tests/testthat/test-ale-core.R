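# ALE engine: kernels, MA maps, union scores, nulls, p/Z maps, FWE extents.

test_that("focus kernels are normalized Gaussians with CDF-difference masses", {
  g <- small_grid(voxel_mm = 2)
  k <- kernel_for_experiment(15, g, fixed_fwhm(10))
  expect_equal(sum(k$support), 1, tolerance = 1e-9)
  expect_true(all(k$support >= 0))
  expect_true(all(dim(k$support) %% 2 == 1))
  # central mass before truncation renormalization: CDF oracle
  sig <- 10 / (2 * sqrt(2 * log(2))) / 2
  ctr <- (dim(k$support) + 1) / 2
  expect_equal(k$support[ctr[1], ctr[2], ctr[3]],
               (pnorm(0.5 / sig) - pnorm(-0.5 / sig))^3, tolerance = 2e-3)
  # wider kernels spread mass: central value decreases in fwhm
  k8 <- kernel_for_experiment(15, g, fixed_fwhm(8))
  k12 <- kernel_for_experiment(15, g, fixed_fwhm(12))
  expect_gt(max(k8$support), max(k12$support))
  # subject-count table policy routes through the table
  pol <- fwhm_table_policy(c(10, 30), c(12, 8))
  expect_equal(kernel_for_experiment(9, g, pol)$fwhm_mm, 12)
  expect_equal(kernel_for_experiment(40, g, pol)$fwhm_mm, 8)
})

test_that("MA maps use the voxelwise-max rule across foci", {
  g <- small_grid()
  k <- kernel_for_experiment(12, g)
  ctr <- voxel_to_mm(round((g$shape - 1) / 2), g)
  one <- ma_map(experiment("one", 12, matrix(ctr, 1)), g, k)
  dup <- ma_map(experiment("dup", 12, rbind(ctr, ctr)), g, k)
  expect_equal(dup$values, one$values)  # idempotent under duplicated foci
  # two distant foci: map equals the elementwise max of single-focus maps
  p2 <- ctr + c(-20, 16, 0)
  two <- ma_map(experiment("two", 12, rbind(ctr, p2)), g, k)
  oracle <- pmax(one$values,
                 ma_map(experiment("b", 12, matrix(p2, 1)), g, k)$values)
  expect_equal(two$values, oracle, tolerance = 1e-12)
  # union variant upper-bounds the max rule
  twou <- ma_map(experiment("two", 12, rbind(ctr, p2)), g, k, combine = "union")
  expect_true(all(twou$values >= two$values - 1e-12))
  expect_error(ma_map(experiment("out", 12, matrix(c(500, 500, 500), 1)), g, k),
               "usable")
})

test_that("ALE is the exact probabilistic union of MA maps", {
  g <- small_grid()
  db <- random_foci_db(g, n_exp = 6L, rng_seed = 9L)
  k <- kernel_for_experiment(12, g)
  mas <- lapply(db$experiments, ma_map, grid = g, kernel = k)
  ale <- ale_from_ma(mas)
  M <- vapply(mas, function(m) m$values, numeric(length(g$mask_idx)))
  oracle <- apply(M, 1, function(row) 1 - prod(1 - row))  # brute force per voxel
  expect_lt(max(abs(ale$values - oracle)), 1e-12)
  # closed-form spot value: constant maps 0.2 and 0.3 combine to 0.44
  v2 <- length(g$mask_idx)
  spot <- ale_from_ma(list(stat_volume(g, rep(0.2, v2), "MA"),
                           stat_volume(g, rep(0.3, v2), "MA")))
  expect_equal(unique(round(spot$values, 12)), 0.44)
  expect_true(all(ale$values >= apply(M, 1, max) - 1e-12))
  expect_true(all(ale$values <= pmin(rowSums(M), 1) + 1e-12))
  # single map: identity
  expect_equal(ale_from_ma(mas[1])$values, mas[[1]]$values)
  expect_error(ale_from_ma(list()), "at least one")
  # permutation invariance and monotonicity in experiments
  expect_equal(ale_from_ma(rev(mas))$values, ale$values)
  expect_true(all(ale_from_ma(mas[1:5])$values <= ale$values + 1e-12))
})

test_that("analytic null matches exhaustive enumeration on two-valued maps", {
  g <- small_grid(shape = c(10L, 10L, 10L))
  V <- length(g$mask_idx)
  # experiment 1: MA = 0.2 on 1/4 of voxels; experiment 2: 0.3 on 1/2
  n1 <- floor(V / 4); n2 <- floor(V / 2)
  M <- cbind(c(rep(0.2, n1), rep(0, V - n1)),
             c(rep(0.3, n2), rep(0, V - n2)))
  null <- null_distribution(M, "analytic_histogram", bin_width = 1e-5)
  f1 <- n1 / V; f2 <- n2 / V
  outcomes <- c(0, 0.2, 0.3, 1 - 0.8 * 0.7)
  probs <- c((1 - f1) * (1 - f2), f1 * (1 - f2), (1 - f1) * f2, f1 * f2)
  for (i in seq_along(outcomes)) {
    idx <- round(outcomes[i] / 1e-5)
    expect_equal(null$bin_probabilities[idx + 1], probs[i], tolerance = 1e-9)
  }
  expect_equal(sum(null$bin_probabilities), 1, tolerance = 1e-9)
  # single constant map: point mass
  nc <- null_distribution(matrix(0.05, V, 1), "analytic_histogram")
  expect_equal(nc$bin_probabilities[round(0.05 / 1e-5) + 1], 1)
})

test_that("p-values count equal-or-higher null mass and never reach zero", {
  g <- small_grid(shape = c(10L, 10L, 10L))
  # sampling estimator on a fixed sample set
  null <- structure(list(method = "sampling",
                         samples = sort(c(0.1, 0.2, 0.3, 0.4)), n_draws = 4L),
                    class = "null_distribution")
  expect_equal(p_from_null(0.35, null), (1 + 1) / 5)  # one sample >= 0.35
  expect_equal(p_from_null(0, null), (4 + 1) / 5)
  expect_equal(p_from_null(0.2, null), (3 + 1) / 5)   # ties count as >=
  expect_equal(p_from_null(0.9, null), 1 / 5)         # above support: floor
  # analytic: observed above support returns smallest tail mass, not 0
  M <- matrix(c(rep(0.1, 50), rep(0, 450)), 500, 1)
  na <- null_distribution(M, "analytic_histogram")
  expect_equal(p_from_null(0.1, na), 0.1, tolerance = 1e-9)
  expect_gt(p_from_null(0.8, na), 0)
  expect_equal(p_from_null(0, na), 1)
})

test_that("analytic and sampling nulls agree on a toy database", {
  g <- ale_grid()
  db <- random_foci_db(g, n_exp = 10L, rng_seed = 4L)
  M <- coactiv:::ma_matrix(db, g)
  na <- null_distribution(M, "analytic_histogram")
  ns <- null_distribution(M, "sampling", n_draws = 2e5, rng_seed = 8)
  xs <- seq(0, max(coactiv:::ale_from_matrix(M)) * 1.2, length.out = 500)
  expect_lt(max(abs(null_cdf(na, xs) - null_cdf(ns, xs))), 0.01)
  expect_warning(null_distribution(M, "sampling", n_draws = 500), "1,000")
})

test_that("Z transform is the upper-tail normal quantile with a floor", {
  g <- small_grid(shape = c(6L, 6L, 6L))
  V <- length(g$mask_idx)
  p <- stat_volume(g, c(0.5, 0.001, 0.025, rep(1, V - 3)), "P")
  z <- z_map(p)
  expect_equal(z$values[1], 0, tolerance = 1e-12)
  expect_equal(z$values[2], qnorm(0.999), tolerance = 1e-12)
  expect_equal(z$values[3], qnorm(0.975), tolerance = 1e-12)
  expect_equal(z$values[4], -8.2)  # p = 1 clipped at the documented floor
  # monotone: smaller p, larger Z
  expect_true(all(diff(z_map(stat_volume(g, sort(runif(V, 1e-6, 1)), "P"))$values) <= 0))
})

test_that("cluster FWE extent threshold is deterministic and degenerates sanely", {
  g <- small_grid(shape = c(12L, 12L, 12L))
  db <- random_foci_db(g, n_exp = 8L, rng_seed = 2L)
  spec <- threshold_spec(n_cluster_sims = 100L)
  k1 <- cluster_fwe_threshold(db, g, spec = spec, rng_seed = 77)
  k2 <- cluster_fwe_threshold(db, g, spec = spec, rng_seed = 77)
  expect_identical(k1, k2)
  expect_gte(k1, 1L)
  # cluster_alpha near 1: any cluster passes
  lax <- threshold_spec(cluster_alpha = 0.999, n_cluster_sims = 100L)
  expect_lte(cluster_fwe_threshold(db, g, spec = lax, rng_seed = 77), 1L)
  expect_warning(
    cluster_fwe_threshold(db, g, spec = threshold_spec(n_cluster_sims = 50L),
                          rng_seed = 1),
    "100")
})
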