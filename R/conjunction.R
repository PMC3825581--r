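# Minimum-statistic conjunctions across modalities and binomial baserate
# functional characterization against a label taxonomy.

#' Minimum-statistic conjunction of thresholded maps
#'
#' For binarized (already thresholded) maps the minimum statistic reduces
#' to the voxelwise logical AND: a voxel survives the conjunction when it
#' is significant in every input map.
#'
#' @param maps list of MASK [stat_volume]s on one grid.
#' @return A MASK [stat_volume].
#' @export
min_conjunction <- function(maps) {
  stopifnot(length(maps) >= 1L)
  grid <- maps[[1]]$grid
  v <- rep(1, n_mask_voxels(grid))
  for (m in maps) {
    stopifnot(inherits(m, "stat_volume"))
    if (m$kind != "MASK") stop("min_conjunction expects MASK volumes")
    if (!identical(m$grid$shape, grid$shape) ||
        max(abs(m$grid$affine - grid$affine)) > 1e-6)
      stop("maps must share one grid")
    v <- pmin(v, m$values)
  }
  stat_volume(grid, v, "MASK")
}

#' Conjunction across modalities of the contrasts between seeds
#'
#' Intersects, per direction, the surviving mask of a task-based (MACM)
#' seed contrast with the corresponding surviving mask of the
#' resting-state group contrast, yielding regions differentially
#' connected to the same seed in both an externally driven task state and
#' the task-free resting state.
#'
#' @param macm_contrast a masked `contrast_result` (see
#'   [run_macm_contrast()]).
#' @param rsfc_masks list with MASK volumes `mask_AgtB` and `mask_BgtA`
#'   (see [group_contrast()]).
#' @return List of MASK volumes `AgtB` and `BgtA`.
#' @export
conjunction_of_contrasts <- function(macm_contrast, rsfc_masks) {
  stopifnot(inherits(macm_contrast, "contrast_result"))
  list(
    AgtB = min_conjunction(list(macm_contrast$surviving_mask_AgtB,
                                rsfc_masks$mask_AgtB)),
    BgtA = min_conjunction(list(macm_contrast$surviving_mask_BgtA,
                                rsfc_masks$mask_BgtA)))
}

#' Build the experiment pool for functional characterization
#'
#' Region mode (`network_mode = FALSE`): the pool contains every
#' experiment reporting at least one focus in region A or region B, with
#' per-experiment membership (both allowed). Network mode: an experiment
#' belongs to the A side if it activates A and simultaneously at least one
#' of A's partner regions (and likewise for B).
#'
#' @param db a [foci_db].
#' @param regionA,regionB MASK [stat_volume]s.
#' @param network_mode logical (default FALSE).
#' @param partnersA,partnersB lists of MASK volumes (network mode only).
#' @return A list: `pool` ([foci_db]), `membership` (data.frame with
#'   columns `id`, `in_A`, `in_B`).
#' @export
build_pool <- function(db, regionA, regionB, network_mode = FALSE,
                       partnersA = NULL, partnersB = NULL) {
  stopifnot(inherits(db, "foci_db"))
  if (!any(regionA$values > 0) || !any(regionB$values > 0))
    stop("regions must be non-empty")
  hitsA <- experiments_hitting(db, regionA)
  hitsB <- experiments_hitting(db, regionB)
  if (network_mode) {
    stopifnot(length(partnersA) >= 1L, length(partnersB) >= 1L)
    pA <- Reduce(`|`, lapply(partnersA, function(m) experiments_hitting(db, m)))
    pB <- Reduce(`|`, lapply(partnersB, function(m) experiments_hitting(db, m)))
    in_A <- hitsA & pA
    in_B <- hitsB & pB
  } else {
    in_A <- hitsA
    in_B <- hitsB
  }
  keep <- in_A | in_B
  if (!any(keep)) stop("empty pool: no experiment activates the regions")
  list(pool = foci_db(db$experiments[keep]),
       membership = data.frame(id = db_ids(db)[keep],
                               in_A = in_A[keep], in_B = in_B[keep]))
}

experiments_hitting <- function(db, mask) {
  grid <- mask$grid
  inm <- array(FALSE, grid$shape)
  inm[grid$mask_idx[mask$values > 0]] <- TRUE
  vapply(db$experiments, function(e) {
    vox <- mm_to_voxel(e$foci, grid)
    lin <- voxel_to_linear(vox, grid$shape)
    any(!is.na(lin) & inm[ifelse(is.na(lin), 1L, lin)])
  }, logical(1))
}

#' Binomial baserate functional characterization
#'
#' The baserate of side A is the a priori probability that a randomly
#' drawn pool membership belongs to A rather than B. For each taxonomy
#' label with at least `min_n` labelled pool experiments, the conditional
#' probability of membership in A given the label is compared to the
#' baserate with a one-sided exact binomial test (over-representation);
#' both directions are tested and Bonferroni-corrected over all tested
#' (label, direction) pairs. Counting is at the experiment level.
#'
#' @param pool a [foci_db] (from [build_pool()]).
#' @param membership data.frame with `id`, `in_A`, `in_B` (from
#'   [build_pool()]).
#' @param labels optional data.frame `id`, `label` overriding the
#'   experiments' own label sets (one row per id-label pair).
#' @param min_n minimum labelled experiments per label (default 5).
#' @param alpha significance level after Bonferroni (default 0.05).
#' @return A `data.frame` with one row per tested (label, direction):
#'   `label`, `direction`, `n_label`, `k`, `cond_prob`, `baserate`,
#'   `p_raw`, `p_bonferroni`, `significant`.
#' @export
characterize <- function(pool, membership, labels = NULL, min_n = 5L,
                         alpha = 0.05) {
  stopifnot(inherits(pool, "foci_db"))
  ids <- db_ids(pool)
  stopifnot(setequal(ids, membership$id))
  membership <- membership[match(ids, membership$id), ]
  if (is.null(labels)) {
    labels <- do.call(rbind, lapply(pool$experiments, function(e)
      if (length(e$labels)) data.frame(id = e$id, label = e$labels) else NULL))
  }
  if (is.null(labels) || nrow(labels) == 0L) stop("no labels to characterize")
  labels <- labels[labels$id %in% ids, ]
  nA <- sum(membership$in_A)
  nB <- sum(membership$in_B)
  baserate_A <- nA / (nA + nB)
  if (baserate_A <= 0 || baserate_A >= 1)
    stop("degenerate baserate: all pool memberships on one side")
  lab_levels <- sort(unique(labels$label))
  rows <- list()
  for (L in lab_levels) {
    with_L <- unique(labels$id[labels$label == L])
    n_L <- length(with_L)
    if (n_L < min_n) next
    mrows <- membership[membership$id %in% with_L, ]
    for (dir in c("A", "B")) {
      k <- if (dir == "A") sum(mrows$in_A) else sum(mrows$in_B)
      base <- if (dir == "A") baserate_A else 1 - baserate_A
      p_raw <- stats::pbinom(k - 1, n_L, base, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        label = L, direction = dir, n_label = n_L, k = k,
        cond_prob = k / n_L, baserate = base, p_raw = p_raw)
    }
  }
  if (length(rows) == 0L) stop("no label reaches min_n")
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  class(out) <- c("characterization_result", "data.frame")
  out
}

#' Read an experiment-label table
#'
#' TSV with columns `experiment_id` (or `id`) and `label`, one row per
#' pair.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `label`.
#' @export
read_label_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("experiment_id" %in% names(d)) names(d)[names(d) == "experiment_id"] <- "id"
  if (!all(c("id", "label") %in% names(d)))
    stop("label table needs columns id (or experiment_id) and label")
  d[, c("id", "label")]
}
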