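# Minimum-statistic conjunction and binomial functional decoding.

test_that("min_conjunction is the exact voxelwise AND with algebraic laws", {
  g <- small_grid(shape = c(10L, 10L, 10L))
  V <- length(g$mask_idx)
  set.seed(14)
  mk <- function() stat_volume(g, as.numeric(runif(V) < 0.4), "MASK")
  for (i in 1:20) {
    a <- mk(); b <- mk(); c3 <- mk()
    conj <- min_conjunction(list(a, b, c3))
    expect_equal(conj$values, pmin(a$values, pmin(b$values, c3$values)))
    # commutative, never larger than any input, idempotent
    expect_equal(min_conjunction(list(c3, a, b))$values, conj$values)
    expect_true(all(conj$values <= a$values))
    expect_equal(min_conjunction(list(a, a))$values, a$values)
  }
  ones <- stat_volume(g, rep(1, V), "MASK")
  m <- mk()
  expect_equal(min_conjunction(list(m, ones))$values, m$values)
  disj1 <- stat_volume(g, as.numeric(seq_len(V) <= 10), "MASK")
  disj2 <- stat_volume(g, as.numeric(seq_len(V) > V - 10), "MASK")
  expect_equal(sum(min_conjunction(list(disj1, disj2))$values), 0)
  g2 <- small_grid(shape = c(8L, 8L, 8L))
  expect_error(min_conjunction(list(m, stat_volume(g2, numeric(length(g2$mask_idx)), "MASK"))),
               "grid")
})

test_that("conjunction of contrasts keeps dual-modality effects only", {
  g <- small_grid(shape = c(10L, 10L, 10L))
  V <- length(g$mask_idx)
  both <- sphere_mask(g, c(-10, 10, 0), 7)$values
  macm_only <- sphere_mask(g, c(10, -10, 0), 7)$values
  macm_res <- structure(list(
    surviving_mask_AgtB = stat_volume(g, pmax(both, macm_only), "MASK"),
    surviving_mask_BgtA = stat_volume(g, numeric(V), "MASK"),
    masked = TRUE), class = "contrast_result")
  rs_masks <- list(mask_AgtB = stat_volume(g, both, "MASK"),
                   mask_BgtA = stat_volume(g, numeric(V), "MASK"))
  cj <- conjunction_of_contrasts(macm_res, rs_masks)
  expect_equal(cj$AgtB$values, both)      # region planted in both survives
  expect_equal(sum(cj$AgtB$values * macm_only), 0)  # single-modality region dropped
  expect_equal(sum(cj$BgtA$values), 0)
})

test_that("pool construction enumerates region and network memberships", {
  g <- ale_grid()
  spec <- default_network_spec(n_experiments = 120L)
  sim <- simulate_foci_db(spec, g, rng_seed = 31)
  masks <- region_masks(spec, g)
  bp <- build_pool(sim$db, masks$seed_A, masks$seed_B)
  # oracle by brute-force point-in-mask per experiment
  hitsA <- coactiv:::experiments_hitting(sim$db, masks$seed_A)
  hitsB <- coactiv:::experiments_hitting(sim$db, masks$seed_B)
  expect_equal(bp$membership$id, db_ids(sim$db)[hitsA | hitsB])
  expect_equal(bp$membership$in_A, hitsA[hitsA | hitsB])
  # network mode requires the seed AND a partner
  bpn <- build_pool(sim$db, masks$seed_A, masks$seed_B, network_mode = TRUE,
                    partnersA = masks[c("P_A1", "P_A2")],
                    partnersB = masks[c("P_B1", "P_B2")])
  pa <- coactiv:::experiments_hitting(sim$db, masks$P_A1) |
    coactiv:::experiments_hitting(sim$db, masks$P_A2)
  pb <- coactiv:::experiments_hitting(sim$db, masks$P_B1) |
    coactiv:::experiments_hitting(sim$db, masks$P_B2)
  in_A_oracle <- hitsA & pa
  in_B_oracle <- hitsB & pb
  keep <- in_A_oracle | in_B_oracle
  expect_equal(bpn$membership$id, db_ids(sim$db)[keep])
  expect_equal(bpn$membership$in_A, in_A_oracle[keep])
  expect_equal(bpn$membership$in_B, in_B_oracle[keep])
  # an experiment activating the seed but no partner is excluded from side A
  only_seed <- experiment("lonely", 10, matrix(c(-22, 22, 8), 1))
  db2 <- foci_db(c(sim$db$experiments, list(only_seed)))
  bp2 <- build_pool(db2, masks$seed_A, masks$seed_B, network_mode = TRUE,
                    partnersA = masks[c("P_A1", "P_A2")],
                    partnersB = masks[c("P_B1", "P_B2")])
  if ("lonely" %in% bp2$membership$id)
    expect_false(bp2$membership$in_A[bp2$membership$id == "lonely"])
})

test_that("characterize matches the exact binomial oracle to 1e-12", {
  g <- ale_grid()
  sim <- simulate_foci_db(default_network_spec(n_experiments = 150L), g,
                          rng_seed = 37)
  masks <- region_masks(default_network_spec(), g)
  bp <- build_pool(sim$db, masks$seed_A, masks$seed_B)
  res <- characterize(bp$pool, bp$membership)
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
  nA <- sum(bp$membership$in_A); nB <- sum(bp$membership$in_B)
  for (i in seq_len(nrow(res))) {
    base <- if (res$direction[i] == "A") nA / (nA + nB) else nB / (nA + nB)
    oracle <- sum(dbinom(res$k[i]:res$n_label[i], res$n_label[i], base))
    expect_equal(res$p_raw[i], oracle, tolerance = 1e-12)
    expect_equal(res$baserate[i], base, tolerance = 1e-12)
    expect_equal(res$p_bonferroni[i], min(1, res$p_raw[i] * nrow(res)),
                 tolerance = 1e-12)
  }
  # binom.test as an independent cross-check on one row
  r1 <- res[1, ]
  bt <- binom.test(r1$k, r1$n_label, r1$baserate, alternative = "greater")
  expect_equal(r1$p_raw, bt$p.value, tolerance = 1e-12)
})

test_that("planted label enrichment is flagged and a null profile is not", {
  g <- ale_grid()
  spec <- default_network_spec(n_experiments = 200L)
  sim <- simulate_foci_db(spec, g, rng_seed = 41)
  masks <- region_masks(spec, g)
  bp <- build_pool(sim$db, masks$seed_A, masks$seed_B)
  res <- characterize(bp$pool, bp$membership)
  act_A <- res[res$label == "action" & res$direction == "A", ]
  expect_true(act_A$significant)            # planted: action -> network A side
  cog_B <- res[res$label == "cognition" & res$direction == "B", ]
  expect_true(cog_B$significant)
  expect_false(any(res$significant[res$label == "perception"]))
  # every-label-at-baserate null: no significance
  mem <- bp$membership
  k <- nrow(mem)
  nA <- sum(mem$in_A)
  lab_null <- data.frame(id = rep(mem$id, each = 1), label = "flat")
  res0 <- characterize(bp$pool, mem, labels = lab_null)
  expect_false(any(res0$significant))
})

test_that("label shuffling yields calibrated raw p-values", {
  g <- ale_grid()
  spec <- default_network_spec(n_experiments = 200L)
  sim <- simulate_foci_db(spec, g, rng_seed = 43)
  masks <- region_masks(spec, g)
  bp <- build_pool(sim$db, masks$seed_A, masks$seed_B)
  set.seed(50)
  hits <- 0L; total <- 0L
  for (r in 1:30) {
    ids <- bp$membership$id
    lab <- do.call(rbind, lapply(bp$pool$experiments, function(e)
      data.frame(id = e$id, label = e$labels[1])))
    lab$label <- sample(lab$label)  # break the label-network link
    res <- characterize(bp$pool, bp$membership, labels = lab)
    hits <- hits + sum(res$p_raw < 0.05)
    total <- total + nrow(res)
  }
  rate <- hits / total
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

test_that("degenerate pools are rejected", {
  g <- ale_grid()
  sim <- simulate_foci_db(default_network_spec(n_experiments = 60L), g,
                          rng_seed = 47)
  masks <- region_masks(default_network_spec(), g)
  far <- sphere_mask(g, c(26, 2, -20), 4)
  expect_error(build_pool(sim$db, stat_volume(g, numeric(length(g$mask_idx)), "MASK"),
                          masks$seed_B), "non-empty")
  bp <- build_pool(sim$db, masks$seed_A, masks$seed_B)
  memA <- bp$membership; memA$in_B <- FALSE
  memA$in_A <- TRUE
  expect_error(characterize(bp$pool, memA), "degenerate")
})
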