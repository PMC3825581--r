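# Shared fixtures: small grids and databases built in code at test time.

small_grid <- function(shape = c(16L, 16L, 16L), voxel_mm = 4) {
  synthetic_grid(shape = shape, voxel_mm = voxel_mm)
}

# grid used by the ALE acceptance checks (~20^3 box, ellipsoidal mask)
ale_grid <- function() synthetic_grid(shape = c(20L, 20L, 20L), voxel_mm = 4)

# a tiny database of experiments with uniform random in-mask foci
random_foci_db <- function(grid, n_exp = 10L, foci_range = c(3L, 8L),
                           rng_seed = 1L) {
  set.seed(rng_seed)
  vox_mm <- voxel_to_mm(coactiv:::mask_voxel_coords(grid), grid)
  exps <- lapply(seq_len(n_exp), function(i) {
    nf <- sample(foci_range[1]:foci_range[2], 1)
    experiment(sprintf("rand%03d", i), sample(8:25, 1),
               vox_mm[sample.int(nrow(vox_mm), nf, replace = TRUE), , drop = FALSE])
  })
  foci_db(exps)
}

# independent flood-fill oracle for connected components (breadth-first)
flood_fill_components <- function(mask_arr, connectivity = "face") {
  offs <- coactiv:::neighbour_offsets(connectivity)
  offs <- rbind(offs, -offs)
  sh <- dim(mask_arr)
  lab <- array(0L, sh)
  cur <- 0L
  idx_all <- which(mask_arr)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      lin <- queue[1]; queue <- queue[-1]
      lin0 <- lin - 1L
      v <- c(lin0 %% sh[1], (lin0 %/% sh[1]) %% sh[2], lin0 %/% (sh[1] * sh[2]))
      for (o in seq_len(nrow(offs))) {
        nv <- v + offs[o, ]
        if (any(nv < 0) || any(nv >= sh)) next
        nl <- 1L + nv[1] + sh[1] * (nv[2] + sh[2] * nv[3])
        if (mask_arr[nl] && lab[nl] == 0L) {
          lab[nl] <- cur
          queue <- c(queue, nl)
        }
      }
    }
  }
  lab
}

# tiny BOLD spec for fast rsfc unit tests (not the acceptance conditions)
tiny_bold_spec <- function(n_subjects = 1L, T_total = 120L) {
  bold_spec(n_subjects = n_subjects,
            grid = synthetic_grid(c(16L, 18L, 16L), voxel_mm = 5),
            T_total = T_total, n_discard = 4L,
            regions = local({
              mk <- function(c3) list(centre_mm = c3, radius_mm = 8)
              list(seed_A = mk(c(-14, 14, 5)), seed_B = mk(c(14, 14, 5)),
                   P_A1 = mk(c(-14, -14, 5)), P_B1 = mk(c(14, -14, 5)))
            }),
            planted_r = local({
              m <- rbind(P_A1 = c(0.5, 0.05), P_B1 = c(0.05, 0.5))
              colnames(m) <- c("seed_A", "seed_B"); m
            }),
            n_background_networks = 6L)
}

# intersection of two MASK volumes
mask_intersect <- function(a, b)
  stat_volume(a$grid, as.numeric(a$values * b$values > 0), "MASK")
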