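# Resting-state chain: nuisance model, regression, filter, eigenvariate,
# correlation maps, group contrast.

test_that("nuisance matrix has the documented columns and centring", {
  sim <- simulate_bold(tiny_bold_spec(), rng_seed = 1)
  ds <- discard_initial(sim$subjects[[1]])
  nm <- build_nuisance(ds)
  expect_equal(ncol(nm), 36L)  # 6 motion + 6 deriv + 3 tissue + 5 PC + 15 sq + 1
  labs <- attr(nm, "column_labels")
  expect_equal(sum(grepl("^motion", labs) & !grepl("_sq", labs)), 6L)
  expect_equal(sum(grepl("_sq$", labs)), 15L)
  expect_true("intercept" %in% labs)
  # all non-intercept columns mean-centred
  expect_lt(max(abs(colMeans(nm[, -36L]))), 1e-10)
  # constant motion parameters give zero derivative columns
  ds2 <- ds; ds2$motion <- matrix(1, nrow(ds$motion), 6)
  nm2 <- build_nuisance(ds2)
  expect_equal(max(abs(nm2[, 7:12])), 0)
  expect_error(build_nuisance(sim$subjects[[1]]), "discard")
})

test_that("whole-brain PCs recover a planted rank-1 component", {
  sim <- simulate_bold(tiny_bold_spec(), rng_seed = 2)
  ds <- discard_initial(sim$subjects[[1]])
  T_ <- dim(ds$bold)[4]
  V <- length(ds$grid$mask_idx)
  set.seed(4)
  s <- sin(2 * pi * 0.03 * (1:T_) * ds$tr_s)
  w <- runif(V, 0.5, 1.5)
  X <- s %*% t(w) * 10 + matrix(rnorm(T_ * V, 0, 0.01), T_, V)
  ds$bold <- array(0, c(ds$grid$shape, T_))
  full <- matrix(0, prod(ds$grid$shape), T_)
  full[ds$grid$mask_idx, ] <- t(X)
  ds$bold[] <- full
  nm <- build_nuisance(ds)
  pc1 <- nm[, which(attr(nm, "column_labels") == "pc1")]
  expect_gt(abs(cor(pc1, s)), 0.999)  # SVD oracle: dominant direction
})

test_that("regression residuals are orthogonal to the design", {
  sim <- simulate_bold(tiny_bold_spec(), rng_seed = 3)
  ds <- discard_initial(sim$subjects[[1]])
  nm <- build_nuisance(ds)
  X <- coactiv:::bold_matrix(ds)[, 1:40]
  R <- regress_out(X, nm)
  rel <- max(abs(crossprod(nm, R))) / (max(abs(nm)) * max(abs(X)))
  expect_lt(rel, 1e-8)
  # a nuisance column regresses to ~zero
  r1 <- regress_out(nm[, 3], nm)
  expect_lt(sqrt(sum(r1^2)) / sqrt(sum(nm[, 3]^2)), 1e-8)
  # an orthogonal signal passes through unchanged
  q <- qr.Q(qr(nm))
  v <- rnorm(nrow(nm)); v <- v - q %*% crossprod(q, v)
  expect_equal(regress_out(as.numeric(v), nm), as.numeric(v), tolerance = 1e-10)
  # planted confound mixture: residual recovers the clean signal
  set.seed(9)
  signal <- coactiv:::band_limited_signal(nrow(nm), ds$tr_s, 1)[, 1]
  mixed <- signal + 0.7 * nm[, 2] / sd(nm[, 2])
  resid <- regress_out(mixed, nm)
  r_clean <- cor(regress_out(signal, nm), signal)
  expect_lt(abs(cor(resid, signal) - r_clean), 0.02)
})

test_that("band-pass filter meets its passband and stopband contract", {
  tr <- 2.2; T_ <- 296
  t <- (0:(T_ - 1)) * tr
  amp_at <- function(y, f0) {
    d <- cbind(sin(2 * pi * f0 * t), cos(2 * pi * f0 * t))
    sqrt(sum(qr.solve(d, y)^2))
  }
  pass <- sin(2 * pi * 0.04 * t + 0.7)
  stopped <- sin(2 * pi * 0.004 * t + 0.3)
  expect_gt(amp_at(bandpass(pass, tr), 0.04), 0.95)     # <= 5% distortion
  expect_lt(amp_at(bandpass(stopped, tr), 0.004), 0.10) # >= 90% attenuation
  # DC removed
  expect_lt(max(abs(bandpass(rep(3, T_), tr))), 1e-10)
  # idempotence: filtering twice changes (almost) nothing
  set.seed(5)
  x <- rnorm(T_)
  y1 <- bandpass(x, tr); y2 <- bandpass(y1, tr)
  expect_lt(max(abs(y2 - y1)) / max(abs(y1)), 0.02)
  # matrix and vector paths agree
  Xm <- cbind(x, rev(x))
  expect_equal(bandpass(Xm, tr)[, 1], y1, ignore_attr = TRUE)
  expect_error(bandpass(x, tr, f_hi = 0.3), "Nyquist")
})

test_that("seed eigenvariate matches an SVD oracle and its sign contract", {
  sim <- simulate_bold(tiny_bold_spec(), rng_seed = 4)
  ds <- discard_initial(sim$subjects[[1]])
  seed <- sim$truth$region_masks$seed_A
  T_ <- dim(ds$bold)[4]
  cols <- which(seed$values > 0)
  # rank-1 seed: eigenvariate proportional to the shared time course
  X <- coactiv:::bold_matrix(ds)
  shared <- coactiv:::band_limited_signal(T_, ds$tr_s, 1)[, 1]
  X[, cols] <- shared %*% t(runif(length(cols), 0.5, 2))
  ev <- seed_eigenvariate(X, seed)
  expect_gt(abs(cor(ev, shared)), 1 - 1e-9)
  expect_gte(cor(ev, rowMeans(X[, cols])), 0)
  expect_equal(sd(ev), 1)
  # anti-correlated halves: orientation follows the mean time course
  h <- length(cols) %/% 2
  X[, cols[1:h]] <- shared %*% t(rep(1, h))
  X[, cols[(h + 1):length(cols)]] <-
    -shared %*% t(rep(0.98, length(cols) - h))
  ev2 <- seed_eigenvariate(X, seed)
  expect_gte(sum(ev2 * rowMeans(X[, cols])), 0)
  # random low-rank data vs independent svd()
  set.seed(8)
  Y <- matrix(rnorm(T_ * 3), T_, 3) %*% matrix(rnorm(3 * length(cols)), 3)
  X[, cols] <- Y
  ev3 <- seed_eigenvariate(X, seed)
  u1 <- svd(scale(Y, scale = FALSE))$u[, 1]
  expect_gt(abs(cor(ev3, u1)), 1 - 1e-9)
  # degenerate seed errors
  X[, cols] <- 0
  expect_error(seed_eigenvariate(X, seed), "variance")
})

test_that("correlation maps apply the Fisher transform with clipping", {
  sim <- simulate_bold(tiny_bold_spec(), rng_seed = 5)
  ds <- discard_initial(sim$subjects[[1]])
  X <- coactiv:::bold_matrix(ds)
  ts <- X[, 10]
  m <- seed_corr_map(X, ts, ds$grid)
  expect_equal(m$z$values[10], atanh(1 - 1e-7), tolerance = 1e-6)
  # closed form at a constructed r = 0.5 voxel
  set.seed(6)
  a <- rnorm(nrow(X)); b <- rnorm(nrow(X))
  b <- residuals(lm(b ~ a)); a <- scale(a)[, 1]; b <- scale(b)[, 1]
  X[, 20] <- 0.5 * a + sqrt(0.75) * b
  m2 <- seed_corr_map(X, a, ds$grid)
  expect_equal(m2$z$values[20], atanh(0.5), tolerance = 1e-9)
  # zero-variance voxels map to z = 0 with a log note
  X[, 30] <- 0
  expect_message(m3 <- seed_corr_map(X, ts, ds$grid), "zero-variance")
  expect_equal(m3$z$values[30], 0)
})

test_that("group contrast recovers a planted paired effect and is antisymmetric", {
  g <- small_grid()
  V <- length(g$mask_idx)
  region <- sphere_mask(g, c(-14, -14, 5), 9)
  n <- 20L
  set.seed(12)
  mk_maps <- function(delta) {
    lapply(seq_len(n), function(s) {
      z0 <- rnorm(V, 0, 0.1)
      za <- z0 + delta * (region$values > 0) + rnorm(V, 0, 0.03)
      structure(list(subject_id = sprintf("s%02d", s), seed_id = "A",
                     z = stat_volume(g, za, "Z")), class = "subject_conn_map")
    })
  }
  base <- lapply(seq_len(n), function(s)
    structure(list(subject_id = sprintf("s%02d", s), seed_id = "B",
                   z = stat_volume(g, rnorm(V, 0, 0.1), "Z")),
              class = "subject_conn_map"))
  eff <- mk_maps(0.4)
  spec <- threshold_spec(n_cluster_sims = 200L)
  res <- group_contrast(eff, base, spec, rng_seed = 3)
  hit <- sum(res$mask_AgtB$values * region$values)
  expect_gt(hit, 0.5 * sum(region$values))
  # opposite direction carries at most FWE-level noise
  expect_lt(sum(res$mask_BgtA$values), 5)
  # swapping inputs exchanges the direction masks exactly
  res2 <- group_contrast(base, eff, spec, rng_seed = 3)
  expect_equal(res2$mask_BgtA$values, res$mask_AgtB$values)
  expect_equal(res2$mask_AgtB$values, res$mask_BgtA$values)
  # all-zero differences: empty output
  res0 <- group_contrast(base, base, spec, rng_seed = 3)
  expect_equal(sum(res0$mask_AgtB$values) + sum(res0$mask_BgtA$values), 0)
  expect_error(group_contrast(eff[1:4], base[1:4], spec), "6 subjects")
})

test_that("motion files round-trip through the text dialect", {
  m <- matrix(rnorm(60), 10, 6)
  f <- tempfile(fileext = ".txt")
  write_motion(m, f)
  back <- read_motion(f)
  expect_equal(back, m, tolerance = 1e-6)
})
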