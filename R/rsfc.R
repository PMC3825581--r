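# Task-independent seed connectivity: nuisance model, confound regression,
# band-pass filtering, seed eigenvariate, correlation maps, group contrast.

#' Construct a resting-state time-series dataset
#'
#' @param subject_id subject identifier.
#' @param bold 4-D numeric array (3 spatial dims x T timepoints) on `grid`.
#' @param grid a [brain_grid].
#' @param tr_s repetition time in seconds.
#' @param motion T x 6 matrix of realignment parameters (same T as bold).
#' @param tissue_masks named list of MASK [stat_volume]s: `grey`, `white`,
#'   `csf`.
#' @param n_discard initial volumes to drop before analysis (default 4).
#' @return A `ts_dataset` object.
#' @export
ts_dataset <- function(subject_id, bold, grid, tr_s, motion, tissue_masks,
                       n_discard = 4L) {
  stopifnot(inherits(grid, "brain_grid"), length(dim(bold)) == 4L,
            all(dim(bold)[1:3] == grid$shape), tr_s > 0)
  T_ <- dim(bold)[4]
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == T_, ncol(motion) == 6L)
  stopifnot(all(c("grey", "white", "csf") %in% names(tissue_masks)))
  n_discard <- as.integer(n_discard)
  if (T_ <= n_discard + 20L) stop("too few volumes after discard")
  structure(list(subject_id = as.character(subject_id), bold = bold,
                 grid = grid, tr_s = tr_s, motion = motion,
                 tissue_masks = tissue_masks, n_discard = n_discard),
            class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat(sprintf("ts_dataset '%s': %d volumes (TR %.3g s, discard %d), grid %s\n",
              x$subject_id, dim(x$bold)[4], x$tr_s, x$n_discard,
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Drop the initial volumes of a dataset
#'
#' Removes the first `n_discard` volumes from the BOLD series and the
#' matching motion-parameter rows, returning a dataset with `n_discard`
#' set to zero.
#'
#' @param ds a [ts_dataset].
#' @return The trimmed [ts_dataset].
#' @export
discard_initial <- function(ds) {
  stopifnot(inherits(ds, "ts_dataset"))
  if (ds$n_discard == 0L) return(ds)
  keep <- (ds$n_discard + 1L):dim(ds$bold)[4]
  ds$bold <- ds$bold[, , , keep, drop = FALSE]
  ds$motion <- ds$motion[keep, , drop = FALSE]
  ds$n_discard <- 0L
  ds
}

# T x V matrix of in-mask voxel time series.
bold_matrix <- function(ds, mask_idx = ds$grid$mask_idx) {
  d <- dim(ds$bold)
  m <- matrix(ds$bold, prod(d[1:3]), d[4])
  t(m[mask_idx, , drop = FALSE])
}

#' Read / write realignment-parameter text files
#'
#' Whitespace-separated T x 6 numeric table (translations then rotations),
#' the interchange dialect emitted by realignment tools.
#'
#' @param path file path.
#' @return T x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("motion file must have 6 columns")
  dimnames(m) <- NULL
  m
}

#' @rdname read_motion
#' @param motion T x 6 matrix to write.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(motion, digits = 8), path, sep = "  ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the nuisance design matrix
#'
#' Columns, in order: the six realignment parameters; their first
#' derivatives (backward differences, zero first row); mean grey-matter,
#' white-matter and CSF signal per timepoint; the first five principal
#' components of the whole-brain in-mask time series (temporal PCs of the
#' voxel-centred data); the squares of all non-PCA columns (computed after
#' centring, then re-centred); and an intercept. All columns except the
#' intercept are mean-centred. 36 columns under the defaults.
#'
#' @param ds a [ts_dataset] with initial volumes already dropped
#'   (`n_discard = 0`; see [discard_initial()]).
#' @param n_pcs number of whole-brain principal components (default 5).
#' @return A `nuisance_matrix`: the T x K matrix with a `column_labels`
#'   attribute.
#' @export
build_nuisance <- function(ds, n_pcs = 5L) {
  stopifnot(inherits(ds, "ts_dataset"))
  if (ds$n_discard != 0L)
    stop("drop initial volumes first (discard_initial)")
  X <- bold_matrix(ds)
  T_ <- nrow(X)
  centre <- function(m) sweep(m, 2, colMeans(m))
  mot <- centre(ds$motion)
  dmot <- rbind(0, diff(ds$motion))
  dmot <- centre(dmot)
  tis <- vapply(c("grey", "white", "csf"), function(tn) {
    msk <- ds$tissue_masks[[tn]]
    idx <- msk$grid$mask_idx[msk$values > 0]
    if (length(idx) == 0L) stop("empty tissue mask: ", tn)
    rowMeans(bold_matrix(ds, idx))
  }, numeric(T_))
  tis <- centre(tis)
  Xc <- centre(X)
  # temporal PCs via the T x T covariance (V >> T)
  ev <- eigen(tcrossprod(Xc), symmetric = TRUE)
  pcs <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
  pcs <- centre(pcs)
  first_order <- cbind(mot, dmot, tis)
  if (nrow(first_order) < ncol(first_order) + n_pcs + 1L)
    stop("too few timepoints for the nuisance model")
  squares <- centre(first_order^2)
  nm <- cbind(first_order, pcs, squares, 1)
  labels <- c(paste0("motion", 1:6), paste0("dmotion", 1:6),
              c("grey", "white", "csf"), paste0("pc", seq_len(n_pcs)),
              paste0(c(paste0("motion", 1:6), paste0("dmotion", 1:6),
                       c("grey", "white", "csf")), "_sq"),
              "intercept")
  structure(nm, column_labels = labels, class = c("nuisance_matrix", "matrix"))
}

#' Remove nuisance variance by least squares
#'
#' Projects the series onto the orthogonal complement of the nuisance
#' columns. Rank-deficient designs are handled by dropping dependent
#' columns (with a message).
#'
#' @param ts numeric T-vector or T x V matrix.
#' @param nm a `nuisance_matrix` (or any T x K matrix).
#' @return Residuals with the shape of `ts`.
#' @export
regress_out <- function(ts, nm) {
  v <- is.null(dim(ts))
  Y <- if (v) matrix(ts, ncol = 1L) else ts
  stopifnot(nrow(Y) == nrow(nm))
  qrX <- qr(nm)
  if (qrX$rank < ncol(nm))
    message(sprintf("nuisance matrix rank-deficient (%d/%d): dropping dependent columns",
                    qrX$rank, ncol(nm)))
  res <- qr.resid(qrX, Y)
  if (v) drop(res) else res
}

#' Band-pass filter a time series
#'
#' Zero-phase frequency-domain filter: the series is linearly detrended,
#' Fourier transformed, components outside `[f_lo, f_hi]` are zeroed, and
#' the series is transformed back. Exactly idempotent up to the detrend
#' and free of phase distortion; passband amplitudes are preserved to
#' well under 5% and out-of-band amplitudes attenuated by far more than
#' 90%.
#'
#' @param ts numeric T-vector or T x V matrix (time in rows).
#' @param tr_s sampling interval (repetition time), seconds.
#' @param f_lo,f_hi passband edges in Hz (defaults 0.01 and 0.08, the
#'   band where meaningful resting-state correlations concentrate).
#' @return Filtered series, same shape.
#' @export
bandpass <- function(ts, tr_s, f_lo = 0.01, f_hi = 0.08) {
  stopifnot(tr_s > 0, f_lo < f_hi)
  if (f_hi >= 1 / (2 * tr_s)) stop("f_hi must be below the Nyquist frequency")
  v <- is.null(dim(ts))
  Y <- if (v) matrix(ts, ncol = 1L) else ts
  n <- nrow(Y)
  tt <- seq_len(n)
  D <- cbind(1, tt - mean(tt))
  Y <- Y - D %*% qr.solve(D, Y)
  f <- (seq_len(n) - 1) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f)
  keep <- f >= f_lo & f <= f_hi
  Yf <- stats::mvfft(Y)
  Yf[!keep, ] <- 0
  out <- Re(stats::mvfft(Yf, inverse = TRUE)) / n
  if (v) drop(out) else out
}

#' First eigenvariate of a seed region
#'
#' Summarizes all voxel time courses inside a seed as the dominant
#' temporal singular vector of the T x V_seed matrix, scaled to unit
#' variance and sign-aligned to correlate non-negatively with the seed
#' mean time course.
#'
#' @param bold_mat T x V matrix of (cleaned) in-mask voxel time series,
#'   columns ordered as `grid$mask_idx`.
#' @param seed a MASK [stat_volume] on the same grid.
#' @param grid the [brain_grid] (defaults to the seed's).
#' @return Numeric T-vector.
#' @export
seed_eigenvariate <- function(bold_mat, seed, grid = seed$grid) {
  stopifnot(inherits(seed, "stat_volume"), seed$kind == "MASK")
  cols <- which(seed$values > 0)
  if (length(cols) == 0L) stop("seed mask is empty")
  S <- bold_mat[, cols, drop = FALSE]
  S <- sweep(S, 2, colMeans(S))
  if (all(abs(S) < 1e-12)) stop("seed voxels carry no variance")
  sv <- svd(S, nu = 1, nv = 0)
  ev <- sv$u[, 1]
  mts <- rowMeans(S)
  if (sum(ev * mts) < 0) ev <- -ev
  ev / stats::sd(ev)
}

#' Seed-to-voxel correlation map with Fisher Z transform
#'
#' Pearson correlation between the seed time course and every voxel in
#' the target mask (grey matter by default), Fisher-transformed
#' (`z = atanh(r)`, with r clipped to +/-(1 - 1e-7)). Zero-variance
#' voxels get z = 0.
#'
#' @param bold_mat T x V matrix of cleaned in-mask voxel time series.
#' @param seed_ts numeric T-vector (e.g. from [seed_eigenvariate()]).
#' @param grid the [brain_grid].
#' @param target_mask optional MASK [stat_volume] restricting the map
#'   (voxels outside get z = 0).
#' @param subject_id,seed_id identifiers stored with the map.
#' @return A `subject_conn_map`: list with `subject_id`, `seed_id`, and
#'   `z` (a Z [stat_volume]).
#' @export
seed_corr_map <- function(bold_mat, seed_ts, grid, target_mask = NULL,
                          subject_id = "", seed_id = "") {
  T_ <- nrow(bold_mat)
  stopifnot(length(seed_ts) == T_)
  s <- seed_ts - mean(seed_ts)
  ss <- sqrt(sum(s^2))
  Yc <- sweep(bold_mat, 2, colMeans(bold_mat))
  denom <- sqrt(colSums(Yc^2)) * ss
  r <- as.numeric(crossprod(Yc, s))
  zero_var <- denom < 1e-12
  r <- ifelse(zero_var, 0, r / pmax(denom, 1e-12))
  if (any(zero_var)) message(sprintf("%d zero-variance voxels set to z = 0",
                                     sum(zero_var)))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  if (!is.null(target_mask)) z[target_mask$values <= 0] <- 0
  structure(list(subject_id = subject_id, seed_id = seed_id,
                 z = stat_volume(grid, z, "Z")),
            class = "subject_conn_map")
}

#' Single-subject seed connectivity pipeline
#'
#' Runs the full task-independent connectivity chain for one subject:
#' discard initial volumes, optional 5-mm FWHM spatial smoothing, nuisance
#' regression ([build_nuisance()] / [regress_out()]), band-pass filtering
#' (0.01-0.08 Hz), seed first-eigenvariate extraction, and voxelwise
#' correlation with Fisher Z transform. The processing order is fixed as
#' discard, smooth, regress, filter.
#'
#' @param ds a [ts_dataset].
#' @param seeds named list of MASK [stat_volume] seeds.
#' @param smooth_fwhm spatial smoothing FWHM in mm (default 5; `NULL` or 0
#'   disables).
#' @param denoise apply the nuisance regression (default TRUE).
#' @param filter_band apply the band-pass filter (default TRUE).
#' @param f_lo,f_hi passband edges, Hz.
#' @return Named list of `subject_conn_map`s, one per seed.
#' @export
rsfc_subject <- function(ds, seeds, smooth_fwhm = 5, denoise = TRUE,
                         filter_band = TRUE, f_lo = 0.01, f_hi = 0.08) {
  stopifnot(inherits(ds, "ts_dataset"))
  ds <- discard_initial(ds)
  if (!is.null(smooth_fwhm) && smooth_fwhm > 0) {
    for (t in seq_len(dim(ds$bold)[4])) {
      vol <- ds$bold[, , , t]
      vol[!ds$grid$mask] <- 0
      ds$bold[, , , t] <- smooth_array(vol, smooth_fwhm, ds$grid$voxdim)
    }
  }
  X <- bold_matrix(ds)
  if (denoise) X <- regress_out(X, build_nuisance(ds))
  if (filter_band) X <- bandpass(X, ds$tr_s, f_lo, f_hi)
  grey <- ds$tissue_masks$grey
  lapply_named(seeds, function(seed, seed_id) {
    ev <- seed_eigenvariate(X, seed, ds$grid)
    seed_corr_map(X, ev, ds$grid, target_mask = grey,
                  subject_id = ds$subject_id, seed_id = seed_id)
  })
}

lapply_named <- function(x, f) {
  out <- lapply(seq_along(x), function(i) f(x[[i]], names(x)[i]))
  names(out) <- names(x)
  out
}

#' Group random-effects contrast of two seed connectivity map sets
#'
#' Paired within-subject contrast: per subject the difference of the two
#' seeds' Fisher Z maps is formed, a one-sample t statistic is computed
#' per voxel, the map is thresholded at the one-sided voxel-level
#' `spec$voxel_p`, and cluster-level FWE correction uses a sign-flipping
#' permutation null of the maximum cluster size (the exact paired special
#' case of a non-sphericity-corrected two-seed ANOVA). Both directions
#' are reported.
#'
#' @param maps_a,maps_b lists of `subject_conn_map`s with matching
#'   subject ids (seed A and seed B of the same subjects).
#' @param spec a [threshold_spec]; `spec$n_cluster_sims` sign-flip
#'   permutations are used.
#' @param rng_seed integer seed for the sign flips.
#' @return A list: `t` (the paired t [stat_volume] for A - B),
#'   `mask_AgtB`, `mask_BgtA` (FWE-surviving MASK volumes),
#'   `extent_threshold`, `clusters_AgtB`, `clusters_BgtA`.
#' @export
group_contrast <- function(maps_a, maps_b, spec = threshold_spec(),
                           rng_seed = NULL) {
  n <- length(maps_a)
  if (n < 6L) stop("need at least 6 subjects")
  stopifnot(length(maps_b) == n)
  ids_a <- vapply(maps_a, function(m) m$subject_id, character(1))
  ids_b <- vapply(maps_b, function(m) m$subject_id, character(1))
  if (!setequal(ids_a, ids_b)) stop("subject ids must match between seed map sets")
  maps_b <- maps_b[match(ids_a, ids_b)]
  grid <- maps_a[[1]]$z$grid
  D <- vapply(seq_len(n), function(i) maps_a[[i]]$z$values - maps_b[[i]]$z$values,
              numeric(n_mask_voxels(grid)))
  tcrit <- stats::qt(spec$voxel_p, df = n - 1, lower.tail = FALSE)
  tstat <- function(Dm) {
    mu <- rowMeans(Dm)
    sdv <- sqrt(pmax(rowSums((Dm - mu)^2) / (n - 1), 1e-24))
    mu / (sdv / sqrt(n))
  }
  t_obs <- tstat(D)
  seed_rng(rng_seed)
  maxes <- integer(spec$n_cluster_sims)
  for (s in seq_len(spec$n_cluster_sims)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    t_perm <- tstat(sweep(D, 2, flips, `*`))
    maxes[s] <- max(max_cluster_size(t_perm > tcrit, grid),
                    max_cluster_size(-t_perm > tcrit, grid))
  }
  kmin <- as.integer(ceiling(stats::quantile(maxes, 1 - spec$cluster_alpha,
                                             names = FALSE)))
  t_vol <- stat_volume(grid, t_obs, "Z")
  surviving <- function(supra) {
    ct <- label_clusters(mask_volume_from_logical(grid, supra), "face",
                         values = t_vol)
    ct <- ct[ct$size_voxels >= kmin, , drop = FALSE]
    keep <- logical(n_mask_voxels(grid))
    if (nrow(ct)) keep[match(unlist(ct$members), grid$mask_idx)] <- TRUE
    list(mask = mask_volume_from_logical(grid, keep), clusters = ct)
  }
  up <- surviving(t_obs > tcrit)
  dn <- surviving(-t_obs > tcrit)
  list(t = t_vol, mask_AgtB = up$mask, mask_BgtA = dn$mask,
       extent_threshold = kmin, clusters_AgtB = up$clusters,
       clusters_BgtA = dn$clusters)
}
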