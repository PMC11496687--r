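test_that("OLS beta estimation recovers noise-free generating patterns", {
  set.seed(6)
  sch <- build_schedules(two_designs(), n_anticipation_runs = 1,
                         n_localizer_runs = 1, seed = 21)
  # localizer: 16 conditions, 12 voxels
  true_loc <- matrix(rnorm(16 * 12), 16,
                     dimnames = list(sort(unique(
                       sch$cue_env[sch$task == "localizer"])), NULL))
  ts <- simulate_bold(true_loc, sch, "localizer", tr = 1)
  est <- estimate_betas(ts, sch, "localizer", tr = 1)
  expect_equal(est[rownames(true_loc), ], true_loc, tolerance = 1e-6,
               ignore_attr = TRUE)
  # anticipation cue phase: exactly 32 trial-type regressors
  labs <- with(sch[sch$task == "anticipation", ],
               unique(paste(map, path, cue_env, sep = "_")))
  expect_identical(length(labs), 32L)
  true_ant <- matrix(rnorm(32 * 9), 32, dimnames = list(labs, NULL))
  tsa <- simulate_bold(true_ant, sch, "anticipation", phase = "cue")
  esta <- estimate_betas(tsa, sch, "anticipation", phase = "cue")
  expect_identical(nrow(esta), 32L)
  expect_equal(esta[rownames(true_ant), ], true_ant, tolerance = 1e-6,
               ignore_attr = TRUE)
  # un-convolved boxcars recover too
  tsb <- simulate_bold(true_loc, sch, "localizer", hrf = FALSE)
  estb <- estimate_betas(tsb, sch, "localizer", hrf = FALSE)
  expect_equal(estb[rownames(true_loc), ], true_loc, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("beta estimates are invariant to event-row order", {
  set.seed(7)
  sch <- build_schedules(two_designs(), n_anticipation_runs = 1,
                         n_localizer_runs = 1, seed = 22)
  true_loc <- matrix(rnorm(16 * 5), 16,
                     dimnames = list(sort(unique(
                       sch$cue_env[sch$task == "localizer"])), NULL))
  ts <- simulate_bold(true_loc, sch, "localizer")
  est1 <- estimate_betas(ts, sch, "localizer")
  est2 <- estimate_betas(ts, sch[sample(nrow(sch)), ], "localizer")
  expect_equal(est1, est2[rownames(est1), ], tolerance = 1e-10)
})

test_that("rank-deficient designs raise an estimation error", {
  sch <- build_schedules(two_designs(), n_anticipation_runs = 1,
                         n_localizer_runs = 1, seed = 23)
  ts <- matrix(rnorm(3 * 400), 3, 400)
  nuis <- matrix(1, 400, 1)   # duplicates the intercept
  expect_error(estimate_betas(ts, sch, "localizer", nuisance = nuis),
               "rank-deficient")
})

test_that("reliability matches the definition and flags degenerate voxels", {
  # identical nonzero-variance vectors across participants: r = 1
  v16 <- rnorm(16)
  vals <- array(rep(v16, each = 5), dim = c(5, 16, 3))
  bp <- bp_from_array(vals, sprintf("E%d", 1:16), c(3, 1, 1))
  rel <- environment_reliability(bp)
  expect_equal(rel$r, rep(1, 3))
  # one negated participant contributes a fold of exactly -1
  vals2 <- vals
  vals2[1, , 1] <- -v16
  rel2 <- environment_reliability(bp_from_array(vals2, sprintf("E%d", 1:16),
                                                c(3, 1, 1)))
  expect_equal(rel2$r[1], (-1 + 4 * cor(v16, (3 * v16 - v16) / 4)) / 5)
  # zero-variance voxel flagged undefined, not zeroed
  vals3 <- vals
  vals3[, , 2] <- 1
  rel3 <- environment_reliability(bp_from_array(vals3, sprintf("E%d", 1:16),
                                                c(3, 1, 1)))
  expect_true(is.na(rel3$r[2]))
  expect_false(rel3$defined[2])
  expect_error(environment_reliability(bp_from_array(
    vals[1:2, , , drop = FALSE], sprintf("E%d", 1:16), c(3, 1, 1))),
    ">= 3 participants")
})

test_that("reliability equals the brute-force oracle and Pearson invariances", {
  set.seed(8)
  vals <- array(rnorm(6 * 16 * 20), dim = c(6, 16, 20))
  bp <- bp_from_array(vals, sprintf("E%d", 1:16), c(20, 1, 1))
  expect_equal(environment_reliability(bp)$r, brute_reliability(vals),
               tolerance = 1e-10)
  # invariant to adding a participant-common constant and positive rescale
  vals2 <- (vals + 3) * 1.7
  bp2 <- bp_from_array(vals2, sprintf("E%d", 1:16), c(20, 1, 1))
  expect_equal(environment_reliability(bp2)$r, environment_reliability(bp)$r,
               tolerance = 1e-10)
})

test_that("null reliability over independent voxels averages near zero", {
  set.seed(9)
  vals <- array(rnorm(32 * 16 * 1500), dim = c(32, 16, 1500))
  bp <- bp_from_array(vals, sprintf("E%d", 1:16), c(1500, 1, 1))
  expect_lt(abs(mean(environment_reliability(bp)$r)), 0.05)
})

test_that("cluster filtering enforces size under face connectivity", {
  dims <- c(10, 10, 5)
  mk <- function(vox_coords) {
    r <- rep(0, prod(dims))
    idx <- vox_coords[, 1] + vox_coords[, 2] * dims[1] +
      vox_coords[, 3] * dims[1] * dims[2] + 1
    r[idx] <- 0.5
    structure(list(r = r, defined = rep(TRUE, prod(dims)),
                   lattice_shape = dims,
                   voxel_coords = lattice_coords(dims)),
              class = "reliability_map")
  }
  # a face-connected blob of 9 suprathreshold voxels is removed entirely
  blob9 <- cbind(rep(1:3, 3), rep(1:3, each = 3), 1)
  expect_false(any(threshold_and_cluster(mk(blob9), 0.1, 10)))
  # a 3x3x3 cube (27 voxels) is fully retained
  cube <- as.matrix(expand.grid(4:6, 4:6, 1:3))
  m <- threshold_and_cluster(mk(cube), 0.1, 10)
  expect_identical(sum(m), 27L)
  # two diagonal-touching blobs of 6 are both removed (no corner adjacency)
  b1 <- as.matrix(expand.grid(0:1, 0:2, 0))
  b2 <- as.matrix(expand.grid(2:3, 3:5, 1))
  expect_false(any(threshold_and_cluster(mk(rbind(b1, b2)), 0.1, 10)))
  # matches the union-find oracle on random masks, and is monotone
  set.seed(10)
  for (i in 1:5) {
    r <- rep(NA_real_, prod(dims))
    supra <- runif(prod(dims)) < 0.25
    rm <- mk(lattice_coords(dims)[supra, , drop = FALSE])
    got <- threshold_and_cluster(rm, 0.1, 6)
    expect_identical(got, brute_cluster_filter(rm$r >= 0.1, dims, 6))
    expect_true(all(threshold_and_cluster(rm, 0.1, 12) <= got))
    expect_true(all(threshold_and_cluster(rm, 0.6, 6) <= got))
  }
})

test_that("conjunction ROIs intersect masks and flag empties", {
  m1 <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  m2 <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  roi <- conjunction_roi(m1, m2, "test")
  expect_identical(roi$voxels, which(m1 & m2))
  # anatomical subset of reliable mask: ROI = anatomical mask
  sub <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_identical(conjunction_roi(m1, sub)$voxels, which(sub))
  expect_warning(roi_e <- conjunction_roi(m1, !m1), "empty")
  expect_true(roi_e$empty)
  expect_error(conjunction_roi(m1, m2[1:3]), "lattice")
  set.seed(11)
  for (i in 1:5) {
    a <- runif(50) < 0.4; b <- runif(50) < 0.4
    r <- suppressWarnings(conjunction_roi(a, b))
    expect_identical(length(r$voxels), sum(a & b))
  }
})

test_that("voxel selection recovers the synthetic signal region", {
  cfg <- ground_truth_config(seed = 41)
  ds <- simulate_dataset(cfg)
  rel <- environment_reliability(ds$localizer_betas)
  mask <- threshold_and_cluster(rel, 0.1, 10)
  sig <- cfg$signal_region
  expect_gte(mean(mask[sig]), 0.9)          # >= 90% of signal voxels kept
  expect_lte(mean(mask[!sig]), 0.05)        # <= 5% of pure-noise voxels
})
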