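# Masked-grid volume data model: geometry, NIfTI I/O, smoothing, clustering.

#' Brain analysis grid
#'
#' A `brain_grid` couples a 3-D voxel lattice with a world affine (voxel
#' index -> millimetre coordinate, MNI convention) and a logical in-brain
#' mask. All statistical volumes in the package live on such a grid and
#' store one value per in-mask voxel.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to
#'   millimetres (voxel centres). Must be invertible.
#' @param mask logical array of dimension `shape` marking in-brain voxels,
#'   with at least one `TRUE` voxel.
#' @return An object of class `brain_grid` with fields `shape`, `affine`,
#'   `mask`, `mask_idx` (linear indices of in-mask voxels) and `voxdim`
#'   (voxel size per axis in mm).
#' @export
brain_grid <- function(shape, affine, mask) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  if (is.null(dim(mask))) dim(mask) <- shape
  stopifnot(is.logical(mask), all(dim(mask) == shape))
  if (!any(mask)) stop("mask must contain at least one in-brain voxel")
  voxdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxdim <= 0)) stop("degenerate voxel size")
  structure(list(
    shape = shape, affine = affine, mask = mask,
    mask_idx = which(mask), voxdim = voxdim,
    inv_affine = solve(affine)
  ), class = "brain_grid")
}

#' @export
print.brain_grid <- function(x, ...) {
  cat(sprintf("brain_grid: %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d in mask\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxdim[1], x$voxdim[2], x$voxdim[3], length(x$mask_idx)))
  invisible(x)
}

n_mask_voxels <- function(grid) length(grid$mask_idx)

#' Synthetic MNI-like grid with an ellipsoidal brain mask
#'
#' Builds an isotropic grid whose affine follows the MNI convention
#' (x increasing to the right, origin near the volume centre) and whose
#' brain mask is an axis-aligned ellipsoid filling the stated fraction of
#' each half-axis. A procedural stand-in for a template brain mask so that
#' every analysis in the package is runnable without external atlas data.
#'
#' @param shape voxels per axis (default `c(24, 28, 24)`).
#' @param voxel_mm isotropic voxel size in millimetres (default 4).
#' @param fill fraction of each half-axis covered by the ellipsoid
#'   semi-axis (default 0.9).
#' @return A [brain_grid].
#' @export
synthetic_grid <- function(shape = c(24L, 28L, 24L), voxel_mm = 4, fill = 0.9) {
  shape <- as.integer(shape)
  centre <- (shape - 1) / 2
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- -centre * voxel_mm
  semi <- fill * centre
  ii <- array(rep(0:(shape[1] - 1), times = shape[2] * shape[3]), shape)
  jj <- array(rep(rep(0:(shape[2] - 1), each = shape[1]), times = shape[3]), shape)
  kk <- array(rep(0:(shape[3] - 1), each = shape[1] * shape[2]), shape)
  mask <- ((ii - centre[1]) / semi[1])^2 + ((jj - centre[2]) / semi[2])^2 +
    ((kk - centre[3]) / semi[3])^2 <= 1
  brain_grid(shape, affine, mask)
}

#' MNI-like 2-mm default analysis grid
#'
#' Standard-resolution variant of [synthetic_grid()] sized like the usual
#' 2-mm MNI bounding box. Real template masks read with [read_nifti()] are
#' accepted everywhere a grid mask is; this procedural default merely keeps
#' the package self-contained.
#'
#' @param voxel_mm voxel size in mm (default 2).
#' @return A [brain_grid].
#' @export
mni_like_grid <- function(voxel_mm = 2) {
  shape <- ceiling(c(182, 218, 182) / voxel_mm)
  synthetic_grid(shape = shape, voxel_mm = voxel_mm, fill = 0.9)
}

#' Statistical volume on a masked grid
#'
#' @param grid a [brain_grid].
#' @param values numeric vector with one value per in-mask voxel, or a full
#'   3-D array (masked on construction).
#' @param kind one of `"MA"`, `"ALE"`, `"P"`, `"Z"`, `"DIFF"`, `"R"`,
#'   `"MASK"`. Range invariants are enforced per kind: MA/ALE in `[0, 1]`,
#'   P in `(0, 1]`, MASK in `{0, 1}`.
#' @return A `stat_volume` object.
#' @export
stat_volume <- function(grid, values, kind) {
  stopifnot(inherits(grid, "brain_grid"))
  kind <- match.arg(kind, c("MA", "ALE", "P", "Z", "DIFF", "R", "MASK"))
  if (is.array(values)) {
    stopifnot(all(dim(values) == grid$shape))
    values <- values[grid$mask_idx]
  }
  values <- as.numeric(values)
  if (length(values) != n_mask_voxels(grid))
    stop("values must have one entry per in-mask voxel")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  if (kind %in% c("MA", "ALE") && (any(values < 0) || any(values > 1)))
    stop(sprintf("%s values must lie in [0, 1]", kind))
  if (kind == "P" && (any(values <= 0) || any(values > 1)))
    stop("P values must lie in (0, 1]")
  if (kind == "MASK" && !all(values %in% c(0, 1)))
    stop("MASK values must be 0 or 1")
  structure(list(grid = grid, values = values, kind = kind),
            class = "stat_volume")
}

#' @export
print.stat_volume <- function(x, ...) {
  cat(sprintf("stat_volume[%s]: %d in-mask voxels, range [%.4g, %.4g]\n",
              x$kind, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Expand a stat_volume to a full 3-D array
#'
#' Out-of-mask voxels are filled with `fill` (default 0).
#' @param vol a [stat_volume].
#' @param fill value for out-of-mask voxels.
#' @return A 3-D array of the grid's shape.
#' @export
as_array <- function(vol, fill = 0) {
  stopifnot(inherits(vol, "stat_volume"))
  a <- array(fill, vol$grid$shape)
  a[vol$grid$mask_idx] <- vol$values
  a
}

mask_volume_from_logical <- function(grid, keep) {
  stat_volume(grid, as.numeric(keep), "MASK")
}

#' Millimetre to voxel-index conversion
#'
#' Applies the inverse affine and rounds half away from zero to the nearest
#' voxel index (0-based). No bounds check is applied: callers decide how to
#' treat out-of-grid indices.
#'
#' @param coord_mm numeric vector of length 3 or an n x 3 matrix of MNI-mm
#'   coordinates.
#' @param grid a [brain_grid].
#' @return Integer vector of length 3 (or n x 3 matrix) of 0-based voxel
#'   indices.
#' @export
mm_to_voxel <- function(coord_mm, grid) {
  stopifnot(inherits(grid, "brain_grid"))
  one_row <- is.null(dim(coord_mm))
  m <- if (one_row) matrix(coord_mm, 1L, 3L) else as.matrix(coord_mm)
  stopifnot(ncol(m) == 3L)
  v <- cbind(m, 1) %*% t(grid$inv_affine)
  idx <- round_half_away(v[, 1:3, drop = FALSE])
  storage.mode(idx) <- "integer"
  if (one_row) idx[1L, ] else idx
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Voxel-index to millimetre conversion
#'
#' @param voxel integer vector of length 3 or n x 3 matrix of 0-based voxel
#'   indices.
#' @param grid a [brain_grid].
#' @return Millimetre coordinates of the voxel centre(s).
#' @export
voxel_to_mm <- function(voxel, grid) {
  stopifnot(inherits(grid, "brain_grid"))
  one_row <- is.null(dim(voxel))
  m <- if (one_row) matrix(voxel, 1L, 3L) else as.matrix(voxel)
  mm <- cbind(m, 1) %*% t(grid$affine)
  mm <- mm[, 1:3, drop = FALSE]
  if (one_row) mm[1L, ] else mm
}

# 0-based voxel index triplets -> linear array index (1-based), NA outside.
voxel_to_linear <- function(voxel, shape) {
  m <- if (is.null(dim(voxel))) matrix(voxel, 1L, 3L) else voxel
  ok <- m[, 1] >= 0 & m[, 1] < shape[1] &
    m[, 2] >= 0 & m[, 2] < shape[2] &
    m[, 3] >= 0 & m[, 3] < shape[3]
  out <- rep(NA_integer_, nrow(m))
  out[ok] <- 1L + m[ok, 1] + shape[1] * (m[ok, 2] + shape[2] * m[ok, 3])
  out
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1-D discrete Gaussian by CDF differences over voxel extents, truncated at
# +/- trunc_sd standard deviations. sigma_vox in voxel units.
gaussian_line_kernel <- function(sigma_vox, trunc_sd = 3.5, normalize = FALSE) {
  r <- max(0L, as.integer(ceiling(sigma_vox * trunc_sd - 0.5)))
  x <- (-r):r
  w <- stats::pnorm((x + 0.5) / sigma_vox) - stats::pnorm((x - 0.5) / sigma_vox)
  if (normalize) w <- w / sum(w)
  w
}

# Convolve a 3-D array along one axis with a centred 1-D kernel,
# zero-padding outside the array.
convolve_axis <- function(a, kern, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  r <- (length(kern) - 1L) / 2L
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (o in seq_along(kern)) {
    s <- o - r - 1L  # shift
    src <- seq_len(dp[1]) - s
    ok <- src >= 1L & src <= dp[1]
    out[ok, ] <- out[ok, ] + kern[o] * m[src[ok], ]
  }
  res <- array(out, dp)
  aperm(res, order(perm))
}

smooth_array <- function(a, fwhm_mm, voxdim, trunc_sd = 3.5) {
  for (axis in 1:3) {
    sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxdim[axis]
    kern <- gaussian_line_kernel(sigma_vox, trunc_sd, normalize = TRUE)
    if (length(kern) > 1L) a <- convolve_axis(a, kern, axis)
  }
  a
}

#' Gaussian smoothing of a volume
#'
#' Separable convolution with a discrete Gaussian whose per-axis sigma is
#' `fwhm / (2 sqrt(2 ln 2)) / voxel_size`. Values outside the mask are
#' treated as zero during convolution and the result is re-masked; no edge
#' renormalization is applied, matching standard volumetric smoothing.
#'
#' @param vol a [stat_volume].
#' @param fwhm_mm full width at half maximum of the kernel, millimetres.
#' @return A smoothed [stat_volume] of the same kind (MASK inputs are
#'   returned as kind `"R"` since smoothing breaks the 0/1 invariant).
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "stat_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("fwhm_mm must be a positive number")
  a <- smooth_array(as_array(vol, fill = 0), fwhm_mm, vol$grid$voxdim)
  kind <- if (vol$kind == "MASK") "R" else vol$kind
  vals <- a[vol$grid$mask_idx]
  if (kind %in% c("MA", "ALE")) vals <- pmin(pmax(vals, 0), 1)
  stat_volume(vol$grid, vals, kind)
}

# Precompute in-mask neighbour pairs for a connectivity scheme. Returns a
# 2-column matrix of linear array indices.
neighbour_offsets <- function(connectivity) {
  base <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (connectivity == "face") return(base)
  edge <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1))
  if (connectivity == "face+edge") return(rbind(base, edge))
  corner <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  rbind(base, edge, corner)
}

#' Label connected components of a binary volume
#'
#' Connected components of the suprathreshold voxels under the chosen
#' adjacency, reported in deterministic order: descending size, ties broken
#' by the lexicographically smallest member voxel index.
#'
#' @param binary a [stat_volume] of kind `"MASK"`.
#' @param connectivity `"face"` (6 neighbours, default), `"face+edge"`
#'   (18), or `"face+edge+corner"` (26).
#' @param values optional [stat_volume] supplying the statistic used for
#'   `peak_value`/`peak_mm` (defaults to the binary volume itself).
#' @return A `data.frame` (class `cluster_table`) with columns
#'   `cluster_id`, `size_voxels`, `peak_value`, `peak_x`, `peak_y`,
#'   `peak_z`, and a list column `members` of linear array indices.
#' @export
label_clusters <- function(binary, connectivity = c("face", "face+edge", "face+edge+corner"),
                           values = NULL) {
  stopifnot(inherits(binary, "stat_volume"))
  if (binary$kind != "MASK") stop("label_clusters expects a MASK volume")
  connectivity <- match.arg(connectivity)
  grid <- binary$grid
  on_lin <- grid$mask_idx[binary$values > 0]
  val_vec <- if (is.null(values)) NULL else {
    stopifnot(identical(values$grid$shape, grid$shape))
    values
  }
  comp <- connected_components(on_lin, grid$shape, connectivity)
  build_cluster_table(comp, on_lin, grid, val_vec)
}

# Union-find connected components over a set of active linear indices.
# Returns a component id per active voxel (ids arbitrary before ordering).
connected_components <- function(on_lin, shape, connectivity) {
  n <- length(on_lin)
  if (n == 0L) return(integer(0))
  offs <- neighbour_offsets(connectivity)
  pos <- integer(prod(shape))  # linear index -> rank in on_lin
  pos[on_lin] <- seq_len(n)
  # voxel coordinates (0-based) of active voxels
  lin0 <- on_lin - 1L
  i <- lin0 %% shape[1]
  rest <- lin0 %/% shape[1]
  j <- rest %% shape[2]
  k <- rest %/% shape[2]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (o in seq_len(nrow(offs))) {
    ni <- i + offs[o, 1]; nj <- j + offs[o, 2]; nk <- k + offs[o, 3]
    ok <- ni >= 0 & ni < shape[1] & nj >= 0 & nj < shape[2] & nk >= 0 & nk < shape[3]
    nl <- 1L + ni[ok] + shape[1] * (nj[ok] + shape[2] * nk[ok])
    p2 <- pos[nl]
    hit <- p2 > 0L
    a <- which(ok)[hit]; b <- p2[hit]
    for (e in seq_along(a)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

build_cluster_table <- function(comp, on_lin, grid, values_vol) {
  if (length(comp) == 0L) {
    out <- data.frame(cluster_id = integer(0), size_voxels = integer(0),
                      peak_value = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0))
    out$members <- list()
    class(out) <- c("cluster_table", "data.frame")
    return(out)
  }
  vals <- if (is.null(values_vol)) rep(1, length(on_lin)) else {
    full <- as_array(values_vol, fill = -Inf)
    full[on_lin]
  }
  groups <- split(seq_along(comp), comp)
  sizes <- lengths(groups)
  first_lin <- vapply(groups, function(g) min(on_lin[g]), numeric(1))
  ord <- order(-sizes, first_lin)
  groups <- groups[ord]
  rows <- lapply(seq_along(groups), function(ci) {
    g <- groups[[ci]]
    pv <- vals[g]
    pk <- g[which.max(pv)]
    lin0 <- on_lin[pk] - 1L
    vox <- c(lin0 %% grid$shape[1],
             (lin0 %/% grid$shape[1]) %% grid$shape[2],
             lin0 %/% (grid$shape[1] * grid$shape[2]))
    mm <- voxel_to_mm(vox, grid)
    data.frame(cluster_id = ci, size_voxels = length(g),
               peak_value = max(pv), peak_x = mm[1], peak_y = mm[2], peak_z = mm[3])
  })
  out <- do.call(rbind, rows)
  out$members <- unname(lapply(groups, function(g) sort(unname(on_lin[g]))))
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Read a NIfTI volume onto a grid
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param kind volume kind (see [stat_volume()]); `"MASK"` volumes are
#'   binarized at > 0.5 after checking the stored values are 0/1.
#' @param reference optional [brain_grid]; if supplied, the image's shape
#'   and affine must match (affine to 1e-4 mm) and the reference mask is
#'   used. Otherwise a grid is built from the image (mask = non-zero voxels
#'   for MASK kind, all voxels otherwise).
#' @return A [stat_volume].
#' @export
read_nifti <- function(path, kind = "R", reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L) stop("expected a 3-D image: ", path)
  affine <- RNifti::xform(img)[1:4, 1:4]  # 0-based voxel -> world matrix
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "brain_grid"))
    if (!all(dim(a) == reference$shape))
      stop("image shape does not match reference grid")
    if (max(abs(affine - reference$affine)) > 1e-4)
      stop("image affine does not match reference grid")
    grid <- reference
  } else {
    mask <- if (kind == "MASK") a != 0 else array(TRUE, dim(a))
    if (!any(mask)) mask <- array(TRUE, dim(a))
    grid <- brain_grid(dim(a), affine, mask)
  }
  vals <- a[grid$mask_idx]
  if (kind == "MASK") {
    if (!all(a %in% c(0, 1))) stop("mask image contains values other than 0/1")
    vals <- as.numeric(vals > 0.5)
  }
  stat_volume(grid, vals, kind)
}

#' Write a volume as NIfTI
#'
#' Masks are written as uint8, everything else as float32. Out-of-mask
#' voxels are written as zero.
#'
#' @param vol a [stat_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "stat_volume"))
  a <- as_array(vol, fill = 0)
  if (vol$kind == "MASK") storage.mode(a) <- "integer"
  aff <- vol$grid$affine
  sh <- vol$grid$shape
  hdr <- RNifti::niftiHeader(list(
    dim = c(3, sh, 1, 1, 1, 1),
    pixdim = c(1, vol$grid$voxdim, 1, 1, 1, 1),
    srow_x = aff[1, ], srow_y = aff[2, ], srow_z = aff[3, ],
    sform_code = 4L, qform_code = 0L,
    datatype = if (vol$kind == "MASK") 2L else 16L))
  img <- RNifti::asNifti(a, reference = hdr,
                         datatype = if (vol$kind == "MASK") "uint8" else "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Spherical region mask
#'
#' @param grid a [brain_grid].
#' @param centre_mm sphere centre in millimetres.
#' @param radius_mm sphere radius in millimetres.
#' @param intersect_mask restrict to in-brain voxels (default TRUE; the
#'   volume is defined on the grid mask regardless).
#' @return A [stat_volume] of kind `"MASK"`.
#' @export
sphere_mask <- function(grid, centre_mm, radius_mm, intersect_mask = TRUE) {
  stopifnot(inherits(grid, "brain_grid"))
  lin0 <- grid$mask_idx - 1L
  i <- lin0 %% grid$shape[1]
  rest <- lin0 %/% grid$shape[1]
  vox <- cbind(i, rest %% grid$shape[2], rest %/% grid$shape[2])
  mm <- voxel_to_mm(vox, grid)
  d2 <- (mm[, 1] - centre_mm[1])^2 + (mm[, 2] - centre_mm[2])^2 +
    (mm[, 3] - centre_mm[3])^2
  stat_volume(grid, as.numeric(d2 <= radius_mm^2), "MASK")
}

#' Union of mask volumes
#'
#' @param ... [stat_volume] objects of kind `"MASK"` on one grid.
#' @return A [stat_volume] of kind `"MASK"`.
#' @export
mask_union <- function(...) {
  vols <- list(...)
  stopifnot(length(vols) >= 1L)
  v <- vols[[1L]]$values
  for (m in vols[-1L]) v <- pmax(v, m$values)
  stat_volume(vols[[1L]]$grid, v, "MASK")
}
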