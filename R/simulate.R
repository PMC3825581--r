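# Generators for synthetic foci databases with planted co-activation
# networks and for multi-subject BOLD data with planted seed-target
# correlations and realistic confounds.

#' Co-activation network specification for the foci simulator
#'
#' Describes a synthetic experiment-generating process: spherical regions,
#' networks of regions that co-report foci, taxonomy-label enrichment per
#' network, and a uniform background focus rate.
#'
#' @param regions named list; each element `list(centre_mm =, radius_mm =)`.
#' @param networks list; each element
#'   `list(name =, members = named numeric vector of per-region co-report
#'   probabilities q, prevalence =, label =, label_fidelity =)`.
#' @param label_universe character vector of all labels in play (networks'
#'   labels are added automatically).
#' @param background_foci_rate Poisson mean of uniform in-mask background
#'   foci per experiment.
#' @param focus_jitter_sd_mm isotropic Gaussian jitter of planted foci.
#' @param n_experiments number of experiments to generate.
#' @param subjects_range integer `c(low, high)` for uniform subject counts.
#' @return A `network_spec` object.
#' @export
network_spec <- function(regions, networks, label_universe = character(0),
                         background_foci_rate = 2, focus_jitter_sd_mm = 3,
                         n_experiments = 150L, subjects_range = c(10L, 30L)) {
  stopifnot(length(regions) >= 1L, length(networks) >= 1L)
  prev <- vapply(networks, function(nw) nw$prevalence, numeric(1))
  if (sum(prev) > 1 + 1e-9) stop("network prevalences must sum to <= 1")
  for (nw in networks) {
    stopifnot(all(names(nw$members) %in% names(regions)),
              all(nw$members >= 0 & nw$members <= 1),
              nw$label_fidelity > 0, nw$label_fidelity <= 1)
  }
  cn <- t(vapply(regions, function(r) r$centre_mm, numeric(3)))
  rr <- vapply(regions, function(r) r$radius_mm, numeric(1))
  if (length(regions) > 1L) {
    d <- as.matrix(stats::dist(cn))
    lim <- outer(rr, rr, `+`)
    diag(d) <- Inf
    if (any(d < lim)) warning("regions overlap at 2x radius")
  }
  labs <- unique(c(label_universe,
                   vapply(networks, function(nw) nw$label, character(1))))
  structure(list(regions = regions, networks = networks,
                 label_universe = labs,
                 background_foci_rate = background_foci_rate,
                 focus_jitter_sd_mm = focus_jitter_sd_mm,
                 n_experiments = as.integer(n_experiments),
                 subjects_range = as.integer(subjects_range)),
            class = "network_spec")
}

# Region layout shared by the default foci and BOLD specs: two frontal
# seed analogues, each with two planted partner regions, all inside the
# grey core of the synthetic ellipsoid brain.
default_regions <- function(radius_mm = 8) {
  mk <- function(c3) list(centre_mm = c3, radius_mm = radius_mm)
  list(seed_A = mk(c(-22, 22, 8)),
       seed_B = mk(c(22, 22, 8)),
       P_A1 = mk(c(-22, -20, 8)),
       P_A2 = mk(c(-8, -2, -24)),
       P_B1 = mk(c(22, -20, 8)),
       P_B2 = mk(c(8, -2, 26)))
}

#' Default crossed co-activation spec
#'
#' Two networks with one seed region and two partner regions each:
#' experiments of a network co-report foci in their own regions with
#' probability `q` (0.9 at the seed, 0.8 at the partners) and in the
#' other network's regions only at the cross-talk rate (0.05); 10% of
#' experiments are pure background. Network labels ("action" for network
#' A, "cognition" for B, with "perception" as a distractor) attach with
#' fidelity 0.9.
#'
#' @param n_experiments experiments to generate (default 150).
#' @param q own-partner co-report probability (default 0.8).
#' @param cross cross-network co-report probability (default 0.05).
#' @param label_fidelity probability the network's own label attaches
#'   (default 0.9).
#' @return A [network_spec].
#' @export
default_network_spec <- function(n_experiments = 150L, q = 0.8, cross = 0.05,
                                 label_fidelity = 0.9) {
  regions <- default_regions()
  mem_A <- c(seed_A = 0.9, P_A1 = q, P_A2 = q,
             seed_B = cross, P_B1 = cross, P_B2 = cross)
  mem_B <- c(seed_B = 0.9, P_B1 = q, P_B2 = q,
             seed_A = cross, P_A1 = cross, P_A2 = cross)
  network_spec(
    regions = regions,
    networks = list(
      list(name = "net_A", members = mem_A, prevalence = 0.45,
           label = "action", label_fidelity = label_fidelity),
      list(name = "net_B", members = mem_B, prevalence = 0.45,
           label = "cognition", label_fidelity = label_fidelity)),
    label_universe = c("action", "cognition", "perception"),
    n_experiments = n_experiments)
}

#' Simulate a foci database with planted co-activation networks
#'
#' Per experiment: a network is drawn by prevalence (remainder = pure
#' background); each member region contributes, with its probability q,
#' one focus at the region centre plus isotropic Gaussian jitter; a
#' Poisson number of uniform in-mask background foci is added; the
#' subject count is uniform in `subjects_range`; the network's label
#' attaches with probability `label_fidelity`, otherwise a uniformly
#' drawn other label. Experiments that end up with zero foci are redrawn
#' (bounded retries).
#'
#' @param spec a [network_spec].
#' @param grid a [brain_grid] (supplies the in-mask background support).
#' @param rng_seed integer seed.
#' @return A list: `db` ([foci_db]), `truth` (data.frame `id`, `network`,
#'   `label`), `foci_provenance` (data.frame `id`, `region`, one row per
#'   focus).
#' @export
simulate_foci_db <- function(spec, grid, rng_seed = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(grid, "brain_grid"))
  seed_rng(rng_seed)
  prev <- vapply(spec$networks, function(nw) nw$prevalence, numeric(1))
  nw_names <- vapply(spec$networks, function(nw) nw$name, character(1))
  vox_mm <- voxel_to_mm(mask_voxel_coords(grid), grid)
  exps <- vector("list", spec$n_experiments)
  truth <- vector("list", spec$n_experiments)
  prov <- vector("list", spec$n_experiments)
  for (i in seq_len(spec$n_experiments)) {
    for (attempt in 1:25) {
      u <- stats::runif(1)
      nw_i <- findInterval(u, cumsum(prev)) + 1L
      network <- if (nw_i <= length(prev) && u <= sum(prev)) nw_names[nw_i] else "background"
      foci <- NULL; regions_hit <- character(0)
      if (network != "background") {
        nw <- spec$networks[[which(nw_names == network)]]
        on <- names(nw$members)[stats::runif(length(nw$members)) < nw$members]
        for (rn in on) {
          ctr <- spec$regions[[rn]]$centre_mm
          foci <- rbind(foci, ctr + stats::rnorm(3, 0, spec$focus_jitter_sd_mm))
          regions_hit <- c(regions_hit, rn)
        }
      }
      nbg <- stats::rpois(1, spec$background_foci_rate)
      if (nbg > 0) {
        pick <- sample.int(nrow(vox_mm), nbg, replace = TRUE)
        foci <- rbind(foci, vox_mm[pick, , drop = FALSE])
        regions_hit <- c(regions_hit, rep("background", nbg))
      }
      if (!is.null(foci) && nrow(foci) > 0L) break
    }
    if (is.null(foci) || nrow(foci) == 0L)
      stop("failed to generate a non-empty experiment")
    label <- if (network == "background") {
      sample(spec$label_universe, 1)
    } else {
      nw <- spec$networks[[which(nw_names == network)]]
      if (stats::runif(1) < nw$label_fidelity) nw$label else
        sample(setdiff(spec$label_universe, nw$label), 1)
    }
    n_subj <- sample(spec$subjects_range[1]:spec$subjects_range[2], 1)
    id <- sprintf("exp%03d", i)
    exps[[i]] <- experiment(id, n_subj, foci, label)
    truth[[i]] <- data.frame(id = id, network = network, label = label)
    prov[[i]] <- data.frame(id = id, region = regions_hit)
  }
  list(db = foci_db(exps), truth = do.call(rbind, truth),
       foci_provenance = do.call(rbind, prov))
}

#' Region masks for a network spec
#'
#' @param spec a [network_spec] (or any object with a `regions` field).
#' @param grid a [brain_grid].
#' @return Named list of MASK [stat_volume]s, one per region.
#' @export
region_masks <- function(spec, grid) {
  lapply(spec$regions, function(r) sphere_mask(grid, r$centre_mm, r$radius_mm))
}

#' BOLD simulation specification
#'
#' @param n_subjects subjects to simulate (default 20).
#' @param grid a [brain_grid] (default [synthetic_grid()]: 24 x 28 x 24 at
#'   4 mm).
#' @param T_total volumes per run, including the discarded lead-in
#'   (default 300).
#' @param tr_s repetition time, seconds (default 2.2).
#' @param n_discard initial volumes to discard (default 4).
#' @param regions named region list as in [network_spec()] (default
#'   [default_regions()]).
#' @param seeds names of the seed regions (columns of `planted_r`).
#' @param planted_r targets x seeds matrix of planted correlations between
#'   each target region's latent signal and each seed's latent signal
#'   (row sums of squares < 1).
#' @param n_background_networks additional coherent background regions
#'   with independent signals (default 16), so that the whole-brain
#'   principal components and tissue-mean regressors are dominated by
#'   global and background structure rather than the planted network,
#'   as in real data where large-scale networks carry most coherent
#'   variance.
#' @param background_amp amplitude of the background network signals
#'   (default 1.5; deliberately larger than the planted unit-variance
#'   network so confound estimation locks onto it).
#' @param noise_sd white voxel noise SD relative to unit-variance signals
#'   (default 0.5).
#' @param global_amp amplitude of the brain-wide coherent fluctuation
#'   (default 1).
#' @param motion_amp amplitude of the motion-coupled confound (default 0.6).
#' @param drift_amp amplitude of per-voxel linear/quadratic drift
#'   (default 2).
#' @return A `bold_spec` object.
#' @export
bold_spec <- function(n_subjects = 20L, grid = synthetic_grid(),
                      T_total = 300L, tr_s = 2.2, n_discard = 4L,
                      regions = default_regions(),
                      seeds = c("seed_A", "seed_B"),
                      planted_r = default_planted_r(),
                      n_background_networks = 16L, background_amp = 1.5,
                      noise_sd = 0.5, global_amp = 1, motion_amp = 0.6,
                      drift_amp = 2) {
  stopifnot(T_total > 50L, all(abs(planted_r) < 1),
            all(rowSums(planted_r^2) < 1), all(seeds %in% names(regions)),
            all(rownames(planted_r) %in% names(regions)))
  structure(list(n_subjects = as.integer(n_subjects), grid = grid,
                 T_total = as.integer(T_total), tr_s = tr_s,
                 n_discard = as.integer(n_discard), regions = regions,
                 seeds = seeds, planted_r = planted_r,
                 n_background_networks = as.integer(n_background_networks),
                 background_amp = background_amp,
                 noise_sd = noise_sd, global_amp = global_amp,
                 motion_amp = motion_amp, drift_amp = drift_amp),
            class = "bold_spec")
}

#' @rdname bold_spec
#' @export
default_planted_r <- function() {
  m <- rbind(P_A1 = c(0.5, 0.05), P_A2 = c(0.5, 0.05),
             P_B1 = c(0.05, 0.5), P_B2 = c(0.05, 0.5))
  colnames(m) <- c("seed_A", "seed_B")
  m
}

# Band-limited (f_lo..f_hi Hz) unit-variance Gaussian signals, T x n.
band_limited_signal <- function(T_, tr_s, n = 1L, f_lo = 0.01, f_hi = 0.08) {
  W <- matrix(stats::rnorm(T_ * n), T_, n)
  f <- (seq_len(T_) - 1) / (T_ * tr_s)
  f <- pmin(f, 1 / tr_s - f)
  keep <- f >= f_lo & f <= f_hi
  Wf <- stats::mvfft(W)
  Wf[!keep, ] <- 0
  S <- Re(stats::mvfft(Wf, inverse = TRUE)) / T_
  sweep(S, 2, apply(S, 2, stats::sd), `/`)
}

# Tissue shells from the normalized ellipsoidal radius of the mask:
# grey core (rho <= 0.90), white shell (0.90, 0.95], csf rind (> 0.95).
tissue_masks_from_grid <- function(grid) {
  vox <- mask_voxel_coords(grid)
  mm <- voxel_to_mm(vox, grid)
  ctr <- colMeans(mm)
  semi <- apply(abs(sweep(mm, 2, ctr)), 2, max)
  rho <- sqrt(rowSums(sweep(sweep(mm, 2, ctr), 2, semi, `/`)^2))
  list(grey = stat_volume(grid, as.numeric(rho <= 0.90), "MASK"),
       white = stat_volume(grid, as.numeric(rho > 0.90 & rho <= 0.95), "MASK"),
       csf = stat_volume(grid, as.numeric(rho > 0.95), "MASK"))
}

#' Simulate multi-subject BOLD data with planted connectivity
#'
#' Latent unit-variance signals are generated directly in the analysis
#' passband (0.01-0.08 Hz). Each seed region has an independent signal;
#' each target region's signal is `sum_j r_j * seed_j + sqrt(1 - sum r_j^2)
#' * independent`, so its expected correlation with seed j is exactly
#' `planted_r[target, j]`. Voxels inside a region carry its signal; all
#' in-mask voxels additionally receive white noise, a shared global
#' fluctuation (per-voxel weight 0.8-1.2), per-voxel linear + quadratic
#' drift, and a confound coupled to the generated motion parameters (slow
#' random-walk motion, also returned as the T x 6 matrix). Background
#' network regions with independent signals provide realistic coherent
#' structure for the principal-component confound model.
#'
#' @param spec a [bold_spec].
#' @param rng_seed integer seed.
#' @return A list: `subjects` (list of [ts_dataset]), `truth` (list with
#'   `region_masks`, `planted_r`, `seeds`, `tissue_masks`, `spec`).
#' @export
simulate_bold <- function(spec, rng_seed = NULL) {
  stopifnot(inherits(spec, "bold_spec"))
  seed_rng(rng_seed)
  grid <- spec$grid
  V <- n_mask_voxels(grid)
  T_ <- spec$T_total
  masks <- region_masks(spec, grid)
  tissues <- tissue_masks_from_grid(grid)
  targets <- rownames(spec$planted_r)
  # background network centres drawn once, in the grey core but clear of
  # the planted regions (coherent structure for the PCA confounds must not
  # leak into the seed/target signals)
  vox_mm <- voxel_to_mm(mask_voxel_coords(grid), grid)
  bg_masks <- list()
  if (spec$n_background_networks > 0L) {
    bg_radius <- 10
    planted <- t(vapply(spec$regions, function(r) r$centre_mm, numeric(3)))
    planted_rad <- vapply(spec$regions, function(r) r$radius_mm, numeric(1))
    grey_mm <- vox_mm[tissues$grey$values > 0, , drop = FALSE]
    centres <- matrix(0, 0, 3)
    for (tries in seq_len(2000L)) {
      if (nrow(centres) >= spec$n_background_networks) break
      cand <- grey_mm[sample.int(nrow(grey_mm), 1L), ]
      d_plant <- sqrt(rowSums(sweep(planted, 2, cand)^2))
      ok <- all(d_plant > planted_rad + bg_radius + 2)
      if (ok && nrow(centres) > 0L) {
        d_bg <- sqrt(rowSums(sweep(centres, 2, cand)^2))
        ok <- all(d_bg > 1.5 * bg_radius)
      }
      if (ok) centres <- rbind(centres, cand)
    }
    bg_masks <- lapply(seq_len(nrow(centres)), function(i)
      sphere_mask(grid, centres[i, ], bg_radius))
  }
  tvec <- seq_len(T_) / T_
  subjects <- vector("list", spec$n_subjects)
  latents <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    n_seed <- length(spec$seeds)
    seed_sig <- band_limited_signal(T_, spec$tr_s, n_seed)
    tgt_sig <- matrix(0, T_, length(targets))
    for (j in seq_along(targets)) {
      r <- spec$planted_r[targets[j], ]
      indep <- band_limited_signal(T_, spec$tr_s, 1L)
      tgt_sig[, j] <- seed_sig %*% r + sqrt(1 - sum(r^2)) * indep
    }
    bg_sig <- if (length(bg_masks))
      band_limited_signal(T_, spec$tr_s, length(bg_masks)) else NULL
    global <- band_limited_signal(T_, spec$tr_s, 1L)
    # slow random-walk motion (3 translations mm, 3 rotations rad); the
    # BOLD confound couples to the true motion, while the emitted motion
    # file carries realignment estimates with small measurement noise, as
    # real realignment parameters do
    true_motion <- vapply(1:6, function(k)
      cumsum(stats::rnorm(T_, 0, if (k <= 3) 0.05 else 0.001)), numeric(T_))
    motion <- true_motion + vapply(1:6, function(k)
      stats::rnorm(T_, 0, if (k <= 3) 0.05 else 0.001), numeric(T_))
    mstd <- scale(true_motion)
    mconf <- mstd %*% stats::rnorm(6) / sqrt(6)
    X <- matrix(stats::rnorm(T_ * V, 0, spec$noise_sd), T_, V)
    add_signal <- function(X, mask_vol, sig) {
      cols <- which(mask_vol$values > 0)
      X[, cols] <- X[, cols] + sig
      X
    }
    for (j in seq_along(spec$seeds))
      X <- add_signal(X, masks[[spec$seeds[j]]], seed_sig[, j])
    for (j in seq_along(targets))
      X <- add_signal(X, masks[[targets[j]]], tgt_sig[, j])
    for (j in seq_along(bg_masks))
      X <- add_signal(X, bg_masks[[j]], spec$background_amp * bg_sig[, j])
    gw <- stats::runif(V, 0.8, 1.2)
    phase <- stats::rnorm(V, 0, 0.35)  # per-voxel vascular lag heterogeneity
    gquad <- band_limited_signal(T_, spec$tr_s, 1L)
    X <- X + spec$global_amp *
      (global %*% t(gw * cos(phase)) + gquad %*% t(gw * sin(phase)))
    drift <- cbind(tvec, tvec^2) %*%
      matrix(stats::rnorm(2 * V, 0, spec$drift_amp), 2, V)
    X <- X + drift
    mw <- stats::runif(V, 0.5, 1.5)
    X <- X + spec$motion_amp * (mconf %*% t(mw))
    bold <- array(0, c(grid$shape, T_))
    full <- matrix(0, prod(grid$shape), T_)
    full[grid$mask_idx, ] <- t(X)
    bold[] <- full
    subjects[[s]] <- ts_dataset(sprintf("sub%02d", s), bold, grid, spec$tr_s,
                                motion, tissues, n_discard = spec$n_discard)
    colnames(seed_sig) <- spec$seeds
    colnames(tgt_sig) <- targets
    latents[[s]] <- list(seed_sig = seed_sig, target_sig = tgt_sig,
                         global = global, motion_confound = mconf)
  }
  list(subjects = subjects,
       truth = list(region_masks = masks, planted_r = spec$planted_r,
                    seeds = spec$seeds, tissue_masks = tissues,
                    background_masks = bg_masks, latents = latents,
                    spec = spec))
}
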