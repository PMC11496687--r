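#' Asymmetric Gaussian similarity curve
#'
#' The model for a cue-centered similarity profile: a Gaussian bump of height
#' `A` at step 0 decaying to an asymptote `c`, with separate backward
#' (`sigma_b`, steps < 0) and forward (`sigma_f`, steps >= 0) widths:
#' \deqn{y(s) = c + (A - c)\,e^{-s^2 / (2\sigma_{dir}^2)}}
#' The curve is continuous at 0 with y(0) = A. Amplitude indexes evidence for
#' the on-screen cue environment; the widths measure how far graded evidence
#' extends into past/future sequence positions; an asymptote below the
#' different-map baseline indicates relative suppression of far environments.
#'
#' @param s Step offsets (numeric vector; negative = past).
#' @param A Amplitude (curve value at step 0), in similarity units.
#' @param c Asymptote, in similarity units.
#' @param sigma_b,sigma_f Backward/forward widths in steps (> 0).
#' @return Curve values at `s`.
#' @export
asym_gaussian <- function(s, A, c, sigma_b, sigma_f) {
  if (sigma_b <= 0 || sigma_f <= 0) stopf("widths must be > 0")
  sig <- ifelse(s < 0, sigma_b, sigma_f)
  c + (A - c) * exp(-s^2 / (2 * sig^2))
}

# Canonical profile positions.
profile_positions <- function() c(-4L, -3L, -2L, -1L, 0L, 1L, 2L, 3L, 4L)

# Which of the 9 positions enter the fit.
used_positions <- function(include_cue) {
  if (include_cue) 1:9 else c(1:4, 6:9)
}

# Unique value slots of a profile: positions -3..+3 (indices 2..8) plus the
# shared antipode (index 9; index 1 duplicates it). Without the cue the
# position-0 slot is dropped.
unique_slots <- function(include_cue) {
  if (include_cue) c(2:8, 9L) else c(2:4, 6:8, 9L)
}

# Rebuild full 9-position profiles from slot matrices (antipode re-duplicated).
profiles_from_slots <- function(U, include_cue, cue_values = NULL) {
  n <- nrow(U)
  Y <- matrix(NA_real_, n, 9)
  if (include_cue) {
    Y[, 2:8] <- U[, 1:7]
    Y[, 9] <- U[, 8]; Y[, 1] <- U[, 8]
  } else {
    Y[, c(2:4, 6:8)] <- U[, 1:6]
    Y[, 9] <- U[, 7]; Y[, 1] <- U[, 7]
    Y[, 5] <- if (is.null(cue_values)) NA_real_ else cue_values
  }
  Y
}

# Shuffle, independently per row, the assignment of unique profile values to
# unique slots; returns full 9-position profiles.
shuffle_profiles <- function(Y, include_cue) {
  sl <- unique_slots(include_cue)
  U <- Y[, sl, drop = FALSE]
  k <- ncol(U)
  Up <- t(apply(U, 1, sample, size = k))
  profiles_from_slots(Up, include_cue, cue_values = Y[, 5])
}

# --- ridge-profiled width search --------------------------------------------
#
# For fixed widths the curve is linear in (A, c): y = A*g + c*(1 - g) with
# g_s = exp(-s^2 / (2 sigma_dir^2)). The penalized objective
#   ||y - X beta||^2 + lambda ||beta||^2,  X = [g, 1 - g]
# has the closed-form ridge solution beta = H y, H = (X'X + lambda I)^-1 X'.
# The objective as a function of the data is the quadratic form y' Q y with
# Q = (I - XH)'(I - XH) + lambda H'H, so a width grid can be scored for many
# profiles at once by matrix products. Widths are then optimized on a
# log-spaced grid, optionally refined by bounded quasi-Newton.

.grid_cache <- new.env(parent = emptyenv())

gauss_design <- function(sigma_b, sigma_f, positions) {
  sig <- ifelse(positions < 0, sigma_b, sigma_f)
  g <- exp(-positions^2 / (2 * sig^2))
  cbind(g, 1 - g)
}

ridge_pieces <- function(X, lambda) {
  H <- solve(crossprod(X) + diag(lambda, 2), t(X))
  P <- X %*% H
  R <- diag(nrow(X)) - P
  list(H = H, X = X,
       Q = crossprod(R) + lambda * crossprod(H))
}

sigma_grid <- function(sigma_min, sigma_max, n_sigma) {
  sg <- exp(seq(log(sigma_min), log(sigma_max), length.out = n_sigma))
  sg[1] <- sigma_min
  sg[n_sigma] <- sigma_max
  sg
}

grid_structures <- function(include_cue, lambda, sigma_min, sigma_max,
                            n_sigma) {
  key <- paste(include_cue, lambda, sigma_min, sigma_max, n_sigma, sep = "|")
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  pos <- profile_positions()[used_positions(include_cue)]
  sg <- sigma_grid(sigma_min, sigma_max, n_sigma)
  combos <- expand.grid(sigma_b = sg, sigma_f = sg)
  pieces <- lapply(seq_len(nrow(combos)), function(i) {
    ridge_pieces(gauss_design(combos$sigma_b[i], combos$sigma_f[i], pos),
                 lambda)
  })
  out <- list(pos = pos, combos = combos, pieces = pieces,
              sigma_sum = combos$sigma_b + combos$sigma_f)
  .grid_cache[[key]] <- out
  out
}

# Batched grid fit. Y: m x 9 profile matrix. Returns per-row best-combo
# parameters, penalized objective, unpenalized sse and fitted curves over the
# used positions.
grid_fit <- function(Y, include_cue = TRUE, lambda = 0.01,
                     sigma_min = 0.05, sigma_max = 10, n_sigma = 15,
                     fitted = FALSE) {
  gs <- grid_structures(include_cue, lambda, sigma_min, sigma_max, n_sigma)
  Yu <- Y[, used_positions(include_cue), drop = FALSE]
  m <- nrow(Yu)
  best_obj <- rep(Inf, m); best_idx <- rep(1L, m)
  for (i in seq_along(gs$pieces)) {
    obj <- rowSums((Yu %*% gs$pieces[[i]]$Q) * Yu)
    # tie-break toward the smaller total width
    upd <- obj < best_obj - 1e-12 |
      (abs(obj - best_obj) <= 1e-12 &
         gs$sigma_sum[i] < gs$sigma_sum[best_idx])
    if (any(upd)) { best_obj[upd] <- obj[upd]; best_idx[upd] <- i }
  }
  A <- numeric(m); cc <- numeric(m); sse <- numeric(m)
  Fit <- if (fitted) matrix(NA_real_, m, length(gs$pos)) else NULL
  for (i in unique(best_idx)) {
    rows <- which(best_idx == i)
    B <- Yu[rows, , drop = FALSE] %*% t(gs$pieces[[i]]$H)   # m_i x 2
    Yhat <- B %*% t(gs$pieces[[i]]$X)
    A[rows] <- B[, 1]; cc[rows] <- B[, 2]
    sse[rows] <- rowSums((Yu[rows, , drop = FALSE] - Yhat)^2)
    if (fitted) Fit[rows, ] <- Yhat
  }
  list(amplitude = A, asymptote = cc,
       sigma_b = gs$combos$sigma_b[best_idx],
       sigma_f = gs$combos$sigma_f[best_idx],
       objective = best_obj, sse = sse, combo = best_idx, fitted = Fit)
}

ridge_objective <- function(y, positions, sigma_b, sigma_f, lambda) {
  X <- gauss_design(sigma_b, sigma_f, positions)
  beta <- solve(crossprod(X) + diag(lambda, 2), crossprod(X, y))
  res <- y - X %*% beta
  list(obj = sum(res^2) + lambda * sum(beta^2), sse = sum(res^2),
       A = beta[1], c = beta[2])
}

#' Fit the asymmetric Gaussian to a similarity profile
#'
#' Minimizes the L2-regularized squared error
#' \deqn{\sum_s (v_s - y(s))^2 + \lambda (A^2 + c^2)}
#' over the profile's 9 positions (8 when the cue position is excluded), with
#' widths constrained to `(sigma_min, sigma_max]`. For fixed widths the model
#' is linear in (A, c), which are therefore profiled out in closed form
#' (ridge solution); the two widths are optimized on a deterministic
#' log-spaced grid and then refined with bounded quasi-Newton (`refine =
#' TRUE`). Ties are broken toward the smaller total width, which also fixes
#' the reported widths for degenerate flat profiles.
#'
#' @param values Numeric profile of length 9 at step positions -4..+4
#'   (positions -4 and +4 duplicate the shared antipode value).
#' @param include_cue Include the step-0 (cue) value in the fit?
#' @param lambda L2 strength on amplitude and asymptote (default 0.01).
#' @param sigma_max,sigma_min Width bounds in steps (default 10 and 0.05;
#'   the lower bound is a numerical guard).
#' @param refine Refine grid widths with `optim(method = "L-BFGS-B")`?
#' @param n_sigma Grid resolution per width dimension.
#' @return A `gaussian_fit` list: `amplitude`, `asymptote`, `sigma_b`,
#'   `sigma_f`, `sse` (unpenalized), `objective` (penalized), `converged`,
#'   `n_points`, `include_cue`, `lambda`.
#' @export
fit_profile <- function(values, include_cue = TRUE, lambda = 0.01,
                        sigma_max = 10, sigma_min = 0.05, refine = TRUE,
                        n_sigma = 15) {
  values <- as.numeric(values)
  if (length(values) != 9) stopf("a profile has 9 positions (-4..+4)")
  npt <- if (include_cue) 9L else 8L
  if (sum(is.finite(values[used_positions(include_cue)])) < npt)
    stopf("profile contains non-finite values")
  g <- grid_fit(matrix(values, 1), include_cue, lambda, sigma_min,
                sigma_max, n_sigma)
  best <- list(sigma_b = g$sigma_b[1], sigma_f = g$sigma_f[1],
               obj = g$objective[1], A = g$amplitude[1],
               c = g$asymptote[1], sse = g$sse[1])
  converged <- TRUE
  if (refine) {
    pos <- profile_positions()[used_positions(include_cue)]
    y <- values[used_positions(include_cue)]
    fn <- function(p) ridge_objective(y, pos, exp(p[1]), exp(p[2]),
                                      lambda)$obj
    op <- tryCatch(
      optim(log(c(best$sigma_b, best$sigma_f)), fn, method = "L-BFGS-B",
            lower = log(sigma_min), upper = log(sigma_max)),
      error = function(e) NULL)
    if (is.null(op)) {
      converged <- FALSE
    } else if (op$value <= best$obj + 1e-12) {
      sb <- min(max(exp(op$par[1]), sigma_min), sigma_max)
      sf <- min(max(exp(op$par[2]), sigma_min), sigma_max)
      r <- ridge_objective(y, pos, sb, sf, lambda)
      best <- list(sigma_b = sb, sigma_f = sf, obj = r$obj, A = r$A,
                   c = r$c, sse = r$sse)
      converged <- op$convergence == 0
    }
  }
  structure(list(amplitude = best$A, asymptote = best$c,
                 sigma_b = best$sigma_b, sigma_f = best$sigma_f,
                 sse = best$sse, objective = best$obj,
                 converged = converged, n_points = npt,
                 include_cue = include_cue, lambda = lambda),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "Asymmetric Gaussian fit (%d points%s): A = %.4f, c = %.4f, sigma_b = %.3f, sigma_f = %.3f, SSE = %.3g\n",
    x$n_points, if (x$include_cue) "" else ", cue excluded",
    x$amplitude, x$asymptote, x$sigma_b, x$sigma_f, x$sse))
  invisible(x)
}

#' @export
predict.gaussian_fit <- function(object, s = profile_positions(), ...) {
  asym_gaussian(s, object$amplitude, object$asymptote, object$sigma_b,
                object$sigma_f)
}

profiles_matrix <- function(profiles) {
  if (inherits(profiles, "similarity_profiles")) profiles$values
  else as.matrix(profiles)
}

#' Leave-one-participant-out group fit error
#'
#' For each held-out participant, fits the asymmetric Gaussian to the
#' positionwise mean profile of the remaining participants and measures the
#' sum of squared errors of that curve on the held-out participant's profile;
#' returns the mean over folds. This generalization error is the statistic
#' the permutation tests compare against shuffled-order nulls.
#'
#' Fold fits use the deterministic width-grid optimizer (see
#' \code{\link{fit_profile}}); set `refine = TRUE` to refine each fold.
#'
#' @param profiles An n x 9 profile matrix (rows = participants) or a
#'   `similarity_profiles` object.
#' @param include_cue Include the step-0 value?
#' @param lambda,sigma_min,sigma_max,n_sigma As in \code{\link{fit_profile}}.
#' @param refine Refine each fold fit?
#' @param per_fold Return the per-fold errors instead of their mean?
#' @return Mean held-out SSE (or per-fold vector).
#' @export
loo_group_error <- function(profiles, include_cue = TRUE, lambda = 0.01,
                            sigma_min = 0.05, sigma_max = 10, n_sigma = 15,
                            refine = FALSE, per_fold = FALSE) {
  Y <- profiles_matrix(profiles)
  n <- nrow(Y)
  if (n < 3) stopf("need >= 3 participants for leave-one-out error")
  tot <- colSums(Y)
  FM <- (matrix(tot, n, 9, byrow = TRUE) - Y) / (n - 1)
  up <- used_positions(include_cue)
  if (refine) {
    errs <- vapply(seq_len(n), function(i) {
      f <- fit_profile(FM[i, ], include_cue, lambda, sigma_max, sigma_min,
                       refine = TRUE, n_sigma = n_sigma)
      if (!f$converged) stopf("fold %d failed to converge", i)
      sum((Y[i, up] - predict(f)[up])^2)
    }, numeric(1))
  } else {
    g <- grid_fit(FM, include_cue, lambda, sigma_min, sigma_max, n_sigma,
                  fitted = TRUE)
    errs <- rowSums((Y[, up, drop = FALSE] - g$fitted)^2)
  }
  if (per_fold) errs else mean(errs)
}

# loo errors for a stack of (n_perm x n) fold-mean rows; internal fast path.
loo_errors_stacked <- function(Y, include_cue, lambda, sigma_min, sigma_max,
                               n_sigma, n_perm, shuffle) {
  n <- nrow(Y); up <- used_positions(include_cue)
  errs <- numeric(n_perm)
  chunk <- max(1L, floor(250000 / n))
  b <- 1L
  while (b <= n_perm) {
    nb <- min(chunk, n_perm - b + 1L)
    FM <- matrix(NA_real_, nb * n, 9)
    HO <- matrix(NA_real_, nb * n, 9)
    for (j in seq_len(nb)) {
      Yb <- if (shuffle) shuffle_profiles(Y, include_cue) else Y
      tot <- colSums(Yb)
      idx <- ((j - 1L) * n + 1L):(j * n)
      FM[idx, ] <- (matrix(tot, n, 9, byrow = TRUE) - Yb) / (n - 1)
      HO[idx, ] <- Yb
    }
    g <- grid_fit(FM, include_cue, lambda, sigma_min, sigma_max, n_sigma,
                  fitted = TRUE)
    se <- rowSums((HO[, up, drop = FALSE] - g$fitted)^2)
    errs[b:(b + nb - 1L)] <-
      colMeans(matrix(se, nrow = n))
    b <- b + nb
  }
  errs
}

#' Permutation test of the group Gaussian fit
#'
#' Compares the observed leave-one-out group error
#' (\code{\link{loo_group_error}}) against a null distribution in which each
#' participant's unique profile values are independently reassigned to unique
#' positions (8 slots when the cue is included, 7 when excluded; the shared
#' antipode value is re-duplicated after shuffling). The p-value is the
#' add-one-smoothed fraction of shuffles whose error is at most the observed
#' error, and the goodness score is
#' \deqn{R^2 = 1 - \mathrm{err}_{obs} / \overline{\mathrm{err}}_{null}.}
#' Observed and null errors use the identical deterministic grid fitter, so
#' the comparison is exchangeable under the null.
#'
#' @inheritParams loo_group_error
#' @param n_perm Number of shuffles (default 10000).
#' @param seed Integer seed for the shuffles.
#' @return A `permutation_result` list: `observed_error`, `null_errors`,
#'   `p`, `r2`, `n_perm`, `include_cue`, `seed`.
#' @export
permutation_test <- function(profiles, include_cue = TRUE, n_perm = 10000,
                             seed = NULL, lambda = 0.01, sigma_min = 0.05,
                             sigma_max = 10, n_sigma = 15) {
  Y <- profiles_matrix(profiles)
  if (nrow(Y) < 3) stopf("need >= 3 participants")
  if (n_perm < 100) warnf("n_perm = %d gives coarse p-value resolution",
                          n_perm)
  obs <- loo_group_error(Y, include_cue, lambda, sigma_min, sigma_max,
                         n_sigma)
  null <- with_seed(seed,
    loo_errors_stacked(Y, include_cue, lambda, sigma_min, sigma_max,
                       n_sigma, n_perm, shuffle = TRUE))
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  structure(list(observed_error = obs, null_errors = null, p = p,
                 r2 = 1 - obs / mean(null), n_perm = n_perm,
                 include_cue = include_cue, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s cue, %d shuffles): observed LOO error = %.4g, p = %.4g, R2 = %.3f\n",
    if (x$include_cue) "including" else "excluding", x$n_perm,
    x$observed_error, x$p, x$r2))
  invisible(x)
}

#' Cued- vs uncued-path fit comparison
#'
#' Tests whether the asymmetric Gaussian fits the profiles arranged along the
#' cued path better than the same similarity values arranged along the uncued
#' path, excluding the cue position from both (the cue environment is shared
#' between the two orderings). The observed statistic is
#' `loo(uncued) - loo(cued)`; the null difference recomputes both errors
#' after independently shuffling each participant's profile values; p is the
#' add-one fraction of null differences at least as large as the observed.
#'
#' @param profiles_cued,profiles_uncued Matched n x 9 profile matrices or
#'   `similarity_profiles` objects (same participant order).
#' @inheritParams permutation_test
#' @return A list with `observed_diff`, `null_diffs`, `p`, `n_perm`, `seed`.
#' @export
cued_vs_uncued_test <- function(profiles_cued, profiles_uncued,
                                n_perm = 10000, seed = NULL, lambda = 0.01,
                                sigma_min = 0.05, sigma_max = 10,
                                n_sigma = 15) {
  Yc <- profiles_matrix(profiles_cued)
  Yu <- profiles_matrix(profiles_uncued)
  if (!all(dim(Yc) == dim(Yu))) stopf("cued/uncued participant mismatch")
  loo <- function(Y) loo_group_error(Y, include_cue = FALSE, lambda,
                                     sigma_min, sigma_max, n_sigma)
  obs <- loo(Yu) - loo(Yc)
  null <- with_seed(seed, {
    ec <- loo_errors_stacked(Yc, FALSE, lambda, sigma_min, sigma_max,
                             n_sigma, n_perm, shuffle = TRUE)
    eu <- loo_errors_stacked(Yu, FALSE, lambda, sigma_min, sigma_max,
                             n_sigma, n_perm, shuffle = TRUE)
    eu - ec
  })
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  list(observed_diff = obs, null_diffs = null, p = p, n_perm = n_perm,
       seed = seed)
}

#' Per-participant fits of a profile set
#'
#' Convenience wrapper: fits \code{\link{fit_profile}} (with refinement) to
#' each participant's profile and returns a tidy data frame.
#'
#' @inheritParams loo_group_error
#' @return Data frame with one row per participant: `participant`,
#'   `amplitude`, `asymptote`, `sigma_b`, `sigma_f`, `sse`, `converged`,
#'   plus `baseline` when `profiles` is a `similarity_profiles` object.
#' @export
fit_participants <- function(profiles, include_cue = TRUE, lambda = 0.01,
                             sigma_max = 10, sigma_min = 0.05) {
  Y <- profiles_matrix(profiles)
  fits <- lapply(seq_len(nrow(Y)), function(i)
    fit_profile(Y[i, ], include_cue, lambda, sigma_max, sigma_min))
  out <- data.frame(
    participant = seq_len(nrow(Y)),
    amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
    asymptote = vapply(fits, `[[`, numeric(1), "asymptote"),
    sigma_b = vapply(fits, `[[`, numeric(1), "sigma_b"),
    sigma_f = vapply(fits, `[[`, numeric(1), "sigma_f"),
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  if (inherits(profiles, "similarity_profiles")) {
    out$baseline <- profiles$baseline
    if (!is.null(profiles$participants)) out$participant <-
      profiles$participants
  }
  out
}

#' Group tests of Gaussian parameters against the different-map baseline
#'
#' One-sample t-tests of per-participant amplitude minus baseline and
#' asymptote minus baseline, and a two-sided Wilcoxon signed-rank comparison
#' of backward vs forward widths.
#'
#' @param fits Data frame from \code{\link{fit_participants}} (needs columns
#'   `amplitude`, `asymptote`, `sigma_b`, `sigma_f`, `converged`).
#' @param baselines Per-participant different-map baselines (ignored if
#'   `fits` carries a `baseline` column and `baselines` is missing).
#' @return A `parameter_stats` list with elements `amplitude` and
#'   `asymptote` (each `t`, `p`, `mean_diff`, `df`), `widths` (`V`, `p`,
#'   `degenerate`), `n`, and the per-participant `fits`.
#' @export
parameter_stats <- function(fits, baselines = NULL) {
  if (is.null(baselines)) baselines <- fits$baseline
  if (is.null(baselines)) stopf("per-participant baselines are required")
  if (!all(fits$converged)) stopf("unconverged fits present")
  n <- nrow(fits)
  if (n < 3) stopf("need >= 3 participants")
  one_sample <- function(d) {
    if (sd(d) == 0) {
      # all differences identical: t is 0 when the common difference is 0,
      # otherwise undefined; report degenerately
      return(list(t = if (all(d == 0)) 0 else NA_real_, p = NA_real_,
                  mean_diff = mean(d), df = n - 1, degenerate = TRUE))
    }
    tt <- t.test(d)
    list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
         df = unname(tt$parameter), degenerate = FALSE)
  }
  wd <- fits$sigma_b - fits$sigma_f
  widths <- if (all(wd == 0)) {
    list(V = NA_real_, p = NA_real_, degenerate = TRUE)
  } else {
    wt <- suppressWarnings(wilcox.test(fits$sigma_b, fits$sigma_f,
                                       paired = TRUE))
    list(V = unname(wt$statistic), p = wt$p.value, degenerate = FALSE)
  }
  structure(list(amplitude = one_sample(fits$amplitude - baselines),
                 asymptote = one_sample(fits$asymptote - baselines),
                 widths = widths, n = n, fits = fits),
            class = "parameter_stats")
}

#' @export
print.parameter_stats <- function(x, ...) {
  cat(sprintf("Parameter tests over %d participants\n", x$n))
  cat(sprintf("  amplitude vs baseline: mean diff = %.4f, t(%d) = %.3f, p = %.3g\n",
              x$amplitude$mean_diff, x$amplitude$df, x$amplitude$t,
              x$amplitude$p))
  cat(sprintf("  asymptote vs baseline: mean diff = %.4f, t(%d) = %.3f, p = %.3g\n",
              x$asymptote$mean_diff, x$asymptote$df, x$asymptote$t,
              x$asymptote$p))
  if (isTRUE(x$widths$degenerate))
    cat("  widths: degenerate (all backward = forward)\n")
  else
    cat(sprintf("  widths backward vs forward: V = %.1f, p = %.3g\n",
                x$widths$V, x$widths$p))
  invisible(x)
}
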