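cube_starts <- function(extent, side, step) {
  seq(0L, max(0L, extent - 1L), by = step)
}

#' Searchlight asymmetric-Gaussian mapping
#'
#' Moves a cube of `side` voxels through the lattice with the given `step`
#' (placement starts at the lattice origin; partial cubes at boundaries are
#' allowed), keeps cubes containing at least `min_vox` reliable voxels, and
#' within each qualifying cube repeats the full profile-and-fit analysis per
#' participant: leave-one-participant-out templates from the cube's reliable
#' voxels, cue-centered profiles averaged over all trial types, and the
#' asymmetric-Gaussian fit (deterministic width-grid optimizer). With
#' `n_perm_voxel > 0` a per-cube goodness score is added:
#' \deqn{g = 1 - SSE_{correct} / \overline{SSE}_{perm}}
#' from that many per-participant profile shuffles. Cube results are
#' assigned to every voxel of the cube and averaged over all cubes covering
#' a voxel; voxels in no qualifying cube stay missing (NA).
#'
#' @param anticipation_betas,localizer_betas `beta_patterns` on one lattice.
#' @param designs List of two `map_design`s.
#' @param reliable_mask Logical vector of environment-reliable voxels.
#' @param side Cube side length in voxels (default 7).
#' @param step Cube step in voxels (default 2).
#' @param min_vox Minimum reliable voxels per cube (default 64).
#' @param n_perm_voxel Per-cube permutations for the goodness score
#'   (default 100; 0 skips goodness).
#' @param ordering Profile ordering passed to \code{\link{compute_profiles}}.
#' @param seed Seed for the per-cube shuffles.
#' @param lambda,sigma_min,sigma_max,n_sigma Fit settings.
#' @return A `searchlight_maps` list: `amplitude`, `asymptote`, `sigma_b`,
#'   `sigma_f`, `width` (mean of the two), `goodness` (participant x voxel
#'   matrices, NA where missing), `overlap` (cubes covering each voxel),
#'   `n_cubes`, `lattice_shape`, `voxel_coords`, `params`.
#' @export
searchlight_fit <- function(anticipation_betas, localizer_betas, designs,
                            reliable_mask, side = 7, step = 2,
                            min_vox = 64, n_perm_voxel = 100,
                            ordering = "cued", seed = NULL, lambda = 0.01,
                            sigma_min = 0.05, sigma_max = 10, n_sigma = 15) {
  dims <- anticipation_betas$lattice_shape
  co <- anticipation_betas$voxel_coords
  P <- dim(anticipation_betas$values)[1]
  starts <- expand.grid(x = cube_starts(dims[1], side, step),
                        y = cube_starts(dims[2], side, step),
                        z = cube_starts(dims[3], side, step))
  cubes <- list()
  for (i in seq_len(nrow(starts))) {
    inside <- co[, 1] >= starts$x[i] & co[, 1] < starts$x[i] + side &
      co[, 2] >= starts$y[i] & co[, 2] < starts$y[i] + side &
      co[, 3] >= starts$z[i] & co[, 3] < starts$z[i] + side
    vox <- which(inside & reliable_mask)
    if (length(vox) >= min_vox)
      cubes[[length(cubes) + 1]] <-
        list(vox = vox, all = which(inside))
  }
  maps <- c("amplitude", "asymptote", "sigma_b", "sigma_f", "goodness")
  acc <- lapply(maps, function(m) matrix(0, P, prod(dims)))
  names(acc) <- maps
  overlap <- numeric(prod(dims))
  if (length(cubes) == 0) {
    warnf("no cube contains >= %d reliable voxels", min_vox)
  } else {
    seeds <- child_seeds(seed, length(cubes))
    for (ci in seq_along(cubes)) {
      cb <- cubes[[ci]]
      prof <- compute_profiles(anticipation_betas, localizer_betas, designs,
                               cb$vox, ordering = ordering)
      g <- grid_fit(prof$values, TRUE, lambda, sigma_min, sigma_max,
                    n_sigma)
      res <- list(amplitude = g$amplitude, asymptote = g$asymptote,
                  sigma_b = g$sigma_b, sigma_f = g$sigma_f,
                  goodness = rep(NA_real_, P))
      if (n_perm_voxel > 0) {
        perm_sse <- with_seed(seeds[[ci]], {
          ps <- matrix(NA_real_, P, n_perm_voxel)
          PY <- matrix(NA_real_, P * n_perm_voxel, 9)
          for (b in seq_len(n_perm_voxel))
            PY[((b - 1) * P + 1):(b * P), ] <-
              shuffle_profiles(prof$values, TRUE)
          gp <- grid_fit(PY, TRUE, lambda, sigma_min, sigma_max, n_sigma)
          matrix(gp$sse, nrow = P)
        })
        res$goodness <- 1 - g$sse / rowMeans(perm_sse)
      }
      overlap[cb$all] <- overlap[cb$all] + 1
      for (m in maps)
        acc[[m]][, cb$all] <- acc[[m]][, cb$all] + res[[m]]
    }
  }
  covered <- overlap > 0
  for (m in maps) {
    acc[[m]][, covered] <- sweep(acc[[m]][, covered, drop = FALSE], 2,
                                 overlap[covered], "/")
    acc[[m]][, !covered] <- NA_real_
  }
  if (n_perm_voxel == 0) acc$goodness[] <- NA_real_
  structure(list(amplitude = acc$amplitude, asymptote = acc$asymptote,
                 sigma_b = acc$sigma_b, sigma_f = acc$sigma_f,
                 width = (acc$sigma_b + acc$sigma_f) / 2,
                 goodness = acc$goodness, overlap = overlap,
                 n_cubes = length(cubes), lattice_shape = dims,
                 voxel_coords = co,
                 params = list(side = side, step = step, min_vox = min_vox,
                               n_perm_voxel = n_perm_voxel,
                               ordering = ordering, seed = seed)),
            class = "searchlight_maps")
}

#' @export
print.searchlight_maps <- function(x, ...) {
  cat(sprintf(
    "Searchlight maps: %d qualifying cubes (side %d, step %d, min %d voxels), %d/%d voxels covered\n",
    x$n_cubes, x$params$side, x$params$step, x$params$min_vox,
    sum(x$overlap > 0), length(x$overlap)))
  invisible(x)
}

#' Group-level voxelwise test with sign-flip max-statistic FWE correction
#'
#' One-sample t statistic per voxel on participant goodness scores (against
#' 0), with familywise-error-corrected p-values from the distribution of the
#' maximum voxelwise t over random participant sign flips (exhaustive
#' enumeration when 2^n does not exceed the requested count). A
#' nonparametric alternative to cluster-enhanced permutation inference,
#' strictly valid under sign symmetry.
#'
#' @param goodness Participant x voxel matrix (NA columns are skipped).
#' @param n_signflips Number of random sign flips (default 2000).
#' @param seed Seed.
#' @param alpha Significance level for the binary map.
#' @return List: `t` (voxelwise t, NA where missing), `p_corrected`,
#'   `p_uncorrected`, `significant` (logical at `alpha`), `n_flips`,
#'   `exhaustive`.
#' @export
group_voxelwise_test <- function(goodness, n_signflips = 2000, seed = NULL,
                                 alpha = 0.05) {
  P <- nrow(goodness)
  if (P < 3) stopf("need >= 3 participants")
  ok <- colSums(is.na(goodness)) == 0 &
    apply(goodness, 2, function(x) sd(x) > 0)
  G <- goodness[, ok, drop = FALSE]
  tvox <- function(M) {
    mn <- colMeans(M)
    se <- apply(M, 2, sd) / sqrt(P)
    mn / se
  }
  t_obs <- tvox(G)
  exhaustive <- 2^P <= n_signflips
  flips <- if (exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), P)))
    n_signflips <- nrow(S)
    S
  } else {
    with_seed(seed,
      matrix(sample(c(-1, 1), n_signflips * P, replace = TRUE),
             n_signflips, P))
  }
  max_null <- numeric(n_signflips)
  exc <- numeric(ncol(G))             # per-voxel exceedance count
  for (b in seq_len(n_signflips)) {
    tb <- tvox(G * flips[b, ])
    max_null[b] <- max(tb)
    exc <- exc + (tb >= t_obs)
  }
  p_corr <- vapply(t_obs, function(t0)
    (1 + sum(max_null >= t0)) / (n_signflips + 1), numeric(1))
  p_unc <- (1 + exc) / (n_signflips + 1)
  full <- function(v) {
    out <- rep(NA_real_, length(ok)); out[ok] <- v; out
  }
  list(t = full(t_obs), p_corrected = full(p_corr),
       p_uncorrected = full(p_unc),
       significant = !is.na(full(p_corr)) & full(p_corr) < alpha,
       n_flips = n_signflips, exhaustive = exhaustive)
}

participant_spearman <- function(target, yco, amplitude = NULL) {
  ok <- !is.na(target)
  if (sum(ok) < 3 || length(unique(yco[ok])) < 3) return(NA_real_)
  if (sd(target[ok]) == 0) return(NA_real_)
  if (is.null(amplitude))
    return(cor(target[ok], yco[ok], method = "spearman"))
  ra <- rank(amplitude[ok])
  rt <- rank(target[ok]); ry <- rank(yco[ok])
  e1 <- lm.fit(cbind(1, ra), rt)$residuals
  e2 <- lm.fit(cbind(1, ra), ry)$residuals
  # target fully explained by the controlled amplitude: partial correlation 0
  if (sd(e1) < 1e-12) return(0)
  if (sd(e2) < 1e-12) return(NA_real_)
  cor(e1, e2)
}

#' Within-region gradient of a searchlight map along the anterior axis
#'
#' Per participant, the Spearman rank correlation between a voxelwise target
#' map (by default the mean of forward and backward widths) and the voxel
#' y-coordinate over ROI voxels, then a group-level one-sample t-test of the
#' participant correlations against 0. With `control = "amplitude"`, a
#' partial variant: Pearson correlation of the rank-transformed target and
#' y-coordinate after linear residualization on the rank-transformed
#' amplitude. Participants with an undefined correlation (constant target or
#' too few distinct y values) are excluded with a logged count.
#'
#' @param maps A `searchlight_maps` object.
#' @param roi ROI (voxel indices, logical mask, or `conjunction_roi`).
#' @param target Map to correlate: `"width"`, `"sigma_b"`, `"sigma_f"`,
#'   `"amplitude"`, `"asymptote"`, or `"goodness"`.
#' @param control `"none"` or `"amplitude"`.
#' @return A `gradient_result` list: `rho` (per participant), `t`, `p`,
#'   `df`, `mean_rho`, `n_excluded`, `variant`.
#' @export
gradient_correlation <- function(maps, roi, target = "width",
                                 control = c("none", "amplitude")) {
  control <- match.arg(control)
  vox <- roi_indices(roi)
  if (length(vox) < 3) stopf("ROI must contain >= 3 voxels")
  M <- maps[[target]][, vox, drop = FALSE]
  amp <- if (control == "amplitude")
    maps$amplitude[, vox, drop = FALSE] else NULL
  yco <- maps$voxel_coords[vox, "y"]
  if (length(unique(yco)) < 3)
    stopf("ROI spans < 3 distinct y values")
  rho <- vapply(seq_len(nrow(M)), function(p)
    participant_spearman(M[p, ], yco,
                         if (is.null(amp)) NULL else amp[p, ]),
    numeric(1))
  gradient_group(rho, variant = paste0(
    target, "-vs-y", if (control == "amplitude") "-partial-amplitude" else ""))
}

gradient_group <- function(rho, variant) {
  n_excl <- sum(is.na(rho))
  if (n_excl > 0)
    message(sprintf("gradient: %d participant(s) excluded (undefined rho)",
                    n_excl))
  r <- rho[!is.na(rho)]
  if (length(r) < 3) stopf("fewer than 3 participants with defined rho")
  tt <- if (sd(r) == 0) list(statistic = NA_real_, p.value = NA_real_,
                             parameter = length(r) - 1)
        else t.test(r)
  structure(list(rho = rho, mean_rho = mean(r),
                 t = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter), n_excluded = n_excl,
                 variant = variant),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("Gradient (%s): mean rho = %.3f, t(%d) = %.3f, p = %.3g (%d excluded)\n",
              x$variant, x$mean_rho, x$df, x$t, x$p, x$n_excluded))
  invisible(x)
}

#' Across-region width hierarchy
#'
#' Per participant, averages the width map within each region, ranks the
#' regions by their supplied hierarchy order, and computes the Spearman
#' correlation between mean width and hierarchy rank; the participant
#' correlations are tested against 0 with a one-sample t-test. Regions with
#' no non-missing voxels are dropped with a warning; participants whose
#' region means are all tied are excluded.
#'
#' @param maps A `searchlight_maps` object.
#' @param region_masks Named list of ROIs ordered along the hierarchy
#'   (e.g. V1 < V2 < V3 < V4 < PPA).
#' @param target Map to average per region (default `"width"`).
#' @return A `gradient_result` (variant "across-region").
#' @export
across_region_hierarchy <- function(maps, region_masks, target = "width") {
  M <- maps[[target]]
  means <- lapply(region_masks, function(r) {
    vox <- roi_indices(r)
    m <- M[, vox, drop = FALSE]
    if (all(is.na(m))) return(NULL)
    rowMeans(m, na.rm = TRUE)
  })
  dropped <- names(region_masks)[vapply(means, is.null, logical(1))]
  if (length(dropped) > 0)
    warnf("dropping empty region(s): %s", paste(dropped, collapse = ", "))
  means <- means[!vapply(means, is.null, logical(1))]
  if (length(means) < 3) stopf("need >= 3 regions with data")
  RM <- do.call(cbind, means)              # participant x region
  ranks <- seq_len(ncol(RM))
  rho <- apply(RM, 1, function(w) {
    if (anyNA(w) || sd(w) == 0) NA_real_
    else cor(w, ranks, method = "spearman")
  })
  gradient_group(rho, variant = "across-region")
}
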