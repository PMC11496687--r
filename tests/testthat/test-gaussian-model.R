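test_that("the asymmetric Gaussian curve has the defining properties", {
  expect_equal(asym_gaussian(0, 0.2, -0.05, 2, 1), 0.2)     # peak = A
  expect_equal(asym_gaussian(c(-50, 50), 0.2, -0.05, 2, 1),
               c(-0.05, -0.05), tolerance = 1e-10)           # asymptote
  s <- 1:4
  expect_equal(asym_gaussian(-s, 0.3, 0, 1.5, 1.5),
               asym_gaussian(s, 0.3, 0, 1.5, 1.5))           # symmetry
  expect_error(asym_gaussian(0, 1, 0, -1, 1), "widths")
})

test_that("fit_profile recovers noiseless parameters and handles edge cases", {
  y <- asym_gaussian(-4:4, 0.1, 0, 2, 1)
  f <- fit_profile(y, lambda = 0)
  expect_equal(f$amplitude, 0.1, tolerance = 1e-3)
  expect_equal(f$asymptote, 0, tolerance = 1e-3)
  expect_equal(f$sigma_b, 2, tolerance = 1e-3)
  expect_equal(f$sigma_f, 1, tolerance = 1e-3)
  expect_true(f$converged)
  expect_lt(f$sse, 1e-10)
  # flat profile: A = c = level; widths at the documented small default
  ff <- fit_profile(rep(0.07, 9), lambda = 0)
  expect_equal(ff$amplitude, 0.07, tolerance = 1e-6)
  expect_equal(ff$asymptote, 0.07, tolerance = 1e-6)
  expect_equal(ff$sigma_b + ff$sigma_f, 0.1, tolerance = 1e-6)
  # heavy regularization shrinks amplitude and asymptote to zero
  fl <- fit_profile(y, lambda = 1e7)
  expect_lt(abs(fl$amplitude), 1e-4)
  expect_lt(abs(fl$asymptote), 1e-4)
  # widths honor the bound
  fw <- fit_profile(rep(c(0.1, 0.11), length.out = 9), sigma_max = 10)
  expect_lte(fw$sigma_b, 10)
  expect_lte(fw$sigma_f, 10)
  expect_error(fit_profile(1:5), "9 positions")
  # exclude-cue fit ignores the step-0 value entirely
  y2 <- y
  y2[5] <- 99
  f_in <- fit_profile(y, include_cue = FALSE)
  f_ex <- fit_profile(y2, include_cue = FALSE)
  expect_equal(f_in$sse, f_ex$sse, tolerance = 1e-9)
  expect_identical(f_in$n_points, 8L)
})

test_that("penalized objective matches a brute-force 4-parameter optimizer", {
  set.seed(18)
  for (i in 1:5) {
    y <- rnorm(9, sd = 0.05)
    y[1] <- y[9]
    f <- fit_profile(y, lambda = 0.01)
    # oracle: direct 4-parameter Nelder-Mead from many random starts
    obj <- function(p) {
      if (p[3] <= 0.05 || p[3] > 10 || p[4] <= 0.05 || p[4] > 10)
        return(1e9)
      sum((y - asym_gaussian(-4:4, p[1], p[2], p[3], p[4]))^2) +
        0.01 * (p[1]^2 + p[2]^2)
    }
    best <- Inf
    for (s in 1:40) {
      p0 <- c(rnorm(2, 0, 0.1), runif(2, 0.1, 8))
      o <- optim(p0, obj, control = list(maxit = 2000, reltol = 1e-12))
      best <- min(best, o$value)
    }
    expect_lte(f$objective, best + 1e-6)
  }
})

test_that("leave-one-out error matches a hand-rolled fold computation", {
  set.seed(19)
  Y <- noisy_profiles(3, 0.1, -0.01, 1.5, 1)
  got <- loo_group_error(Y, include_cue = TRUE)
  # fold oracle: explicit loop using the single-profile fitter (grid mode)
  errs <- vapply(1:3, function(i) {
    train <- colMeans(Y[-i, , drop = FALSE])
    f <- fit_profile(train, refine = FALSE)
    sum((Y[i, ] - predict(f))^2)
  }, numeric(1))
  expect_equal(got, mean(errs), tolerance = 1e-10)
  expect_equal(loo_group_error(Y, per_fold = TRUE), errs,
               tolerance = 1e-10)
  # identical noiseless Gaussian profiles generalize perfectly
  Y0 <- t(replicate(4, asym_gaussian(-4:4, 0.1, 0, 2, 1)))
  expect_lt(loo_group_error(Y0, lambda = 0, refine = TRUE), 1e-6)
  expect_error(loo_group_error(Y[1:2, ]), ">= 3")
})

test_that("adding a common constant shifts asymptotes, not fold ranking", {
  set.seed(20)
  Y <- noisy_profiles(6, 0.08, -0.01, 1, 1, sd = 0.02)
  e1 <- loo_group_error(Y, lambda = 0, per_fold = TRUE)
  e2 <- loo_group_error(Y + 0.5, lambda = 0, per_fold = TRUE)
  expect_equal(e1, e2, tolerance = 1e-9)
  expect_identical(order(e1), order(e2))
  f1 <- fit_profile(colMeans(Y), lambda = 0)
  f2 <- fit_profile(colMeans(Y) + 0.5, lambda = 0)
  expect_equal(f2$asymptote - f1$asymptote, 0.5, tolerance = 1e-3)
})

test_that("permutation test separates structure from shuffled nulls", {
  set.seed(21)
  # strong noiseless structure: p at the attainable minimum
  Y <- t(replicate(8, asym_gaussian(-4:4, 0.2, -0.02, 1.2, 0.8)))
  Y <- Y + matrix(rnorm(length(Y), sd = 1e-4), nrow(Y))
  pt <- permutation_test(Y, TRUE, n_perm = 200, seed = 1)
  expect_equal(pt$p, 1 / 201)
  expect_gt(pt$r2, 0.9)
  expect_length(pt$null_errors, 200)
  # reproducible given the seed
  pt2 <- permutation_test(Y, TRUE, n_perm = 200, seed = 1)
  expect_identical(pt$null_errors, pt2$null_errors)
  expect_warning(permutation_test(Y, TRUE, n_perm = 50, seed = 1),
                 "resolution")
})

test_that("profile shuffling preserves value multisets and the antipode", {
  set.seed(22)
  Y <- noise_profiles(5)
  S <- shuffle_profiles(Y, TRUE)
  expect_identical(S[, 1], S[, 9])
  for (p in 1:5)
    expect_equal(sort(S[p, 2:9]), sort(Y[p, 2:9]))
  S2 <- shuffle_profiles(Y, FALSE)
  expect_identical(S2[, 1], S2[, 9])
  expect_identical(S2[, 5], Y[, 5])   # cue value untouched when excluded
  for (p in 1:5)
    expect_equal(sort(S2[p, c(2:4, 6:9)]), sort(Y[p, c(2:4, 6:9)]))
})

test_that("cued-vs-uncued comparison behaves under exchange and separation", {
  set.seed(23)
  Y <- noisy_profiles(8, 0.1, -0.01, 1.2, 0.9, sd = 0.01)
  # identical sets: zero observed difference, p near the middle
  r <- cued_vs_uncued_test(Y, Y, n_perm = 100, seed = 2)
  expect_equal(r$observed_diff, 0)
  expect_gt(r$p, 0.2)
  expect_lt(r$p, 0.8)
  # swapping labels flips the sign of the observed statistic
  Yu <- noise_profiles(8, sd = 0.03)
  r1 <- cued_vs_uncued_test(Y, Yu, n_perm = 50, seed = 3)
  r2 <- cued_vs_uncued_test(Yu, Y, n_perm = 50, seed = 3)
  expect_equal(r1$observed_diff, -r2$observed_diff, tolerance = 1e-12)
  expect_error(cued_vs_uncued_test(Y, Yu[1:5, ]), "mismatch")
})

test_that("parameter statistics match closed-form textbook formulas", {
  fits <- data.frame(amplitude = c(0.12, 0.10, 0.08, 0.11),
                     asymptote = c(-0.02, -0.01, -0.03, -0.02),
                     sigma_b = c(1.2, 1.5, 0.9, 1.1),
                     sigma_f = c(1.0, 1.3, 1.1, 0.8),
                     sse = 0, converged = TRUE)
  base <- c(0.01, 0.00, 0.02, 0.01)
  st <- parameter_stats(fits, base)
  d <- fits$amplitude - base
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(st$amplitude$t, t_oracle, tolerance = 1e-12)
  expect_equal(st$amplitude$mean_diff, mean(d))
  d2 <- fits$asymptote - base
  expect_equal(st$asymptote$t, mean(d2) / (sd(d2) / sqrt(4)),
               tolerance = 1e-12)
  # signed-rank oracle via stats::wilcox.test on the differences
  w_oracle <- suppressWarnings(wilcox.test(fits$sigma_b - fits$sigma_f))
  expect_equal(st$widths$V, unname(w_oracle$statistic))
  # degenerate cases reported as such
  fits_eq <- fits
  fits_eq$amplitude <- base
  st_eq <- parameter_stats(fits_eq, base)
  expect_identical(st_eq$amplitude$t, 0)
  fits_w <- fits
  fits_w$sigma_f <- fits_w$sigma_b
  expect_true(parameter_stats(fits_w, base)$widths$degenerate)
  fits_nc <- fits
  fits_nc$converged[2] <- FALSE
  expect_error(parameter_stats(fits_nc, base), "unconverged")
})
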