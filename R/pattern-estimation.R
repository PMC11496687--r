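#' Beta-pattern container
#'
#' The common currency of the pipeline: condition beta estimates for every
#' participant on a 3-D voxel lattice, stored as a participant x condition x
#' voxel array with voxels in canonical order (see
#' \code{\link{lattice_coords}}).
#'
#' @param values Numeric array (participant x condition x voxel).
#' @param conditions Unique condition labels (length = dim 2).
#' @param lattice_shape 3-D lattice dimensions (prod = dim 3).
#' @param task Task tag (e.g. "localizer", "anticipation").
#' @param space Space tag recorded for provenance.
#' @return A `beta_patterns` object.
#' @export
beta_patterns <- function(values, conditions, lattice_shape,
                          task = "unknown", space = "lattice") {
  stopifnot(length(dim(values)) == 3,
            dim(values)[2] == length(conditions),
            dim(values)[3] == prod(lattice_shape))
  if (anyDuplicated(conditions)) stopf("condition labels must be unique")
  if (!all(is.finite(values))) stopf("beta values must be finite")
  dimnames(values)[[2]] <- conditions
  structure(list(values = values, conditions = conditions,
                 lattice_shape = lattice_shape,
                 voxel_coords = lattice_coords(lattice_shape),
                 task = task, space = space),
            class = "beta_patterns")
}

#' @export
print.beta_patterns <- function(x, ...) {
  cat(sprintf("Beta patterns (%s): %d participants x %d conditions x %d voxels (%s lattice)\n",
              x$task, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              paste(x$lattice_shape, collapse = "x")))
  invisible(x)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Standard two-gamma impulse response (peak ~5 s, undershoot ~15 s,
#' undershoot ratio 1/6), sampled at `dt`-second resolution.
#'
#' @param t Time points in seconds.
#' @return HRF values at `t` (peak normalized to 1).
#' @export
canonical_hrf <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

# Build the task design matrix for one phase of one task from a schedule.
# Localizer conditions span cue+blank+panorama; anticipation conditions are
# one boxcar per trial type for the requested phase.
build_design_matrix <- function(events, n_scans, tr, task, phase = "cue",
                                hrf = TRUE) {
  ev <- events[events$task == task, , drop = FALSE]
  if (nrow(ev) == 0) stopf("no %s events in schedule", task)
  if (task == "localizer") {
    conds <- sort(unique(ev$cue_env))
    on <- ev$onset
    dur <- ev$duration + ev$blank_dur + ev$probe_dur
    lab <- ev$cue_env
  } else {
    conds <- unique(paste(ev$map, ev$path, ev$cue_env, sep = "_"))
    lab <- paste(ev$map, ev$path, ev$cue_env, sep = "_")
    on <- switch(phase,
                 cue = ev$onset,
                 blank = ev$onset + ev$duration,
                 probe = ev$onset + ev$duration + ev$blank_dur,
                 stopf("unknown phase '%s'", phase))
    dur <- switch(phase, cue = ev$duration, blank = ev$blank_dur,
                  probe = ev$probe_dur)
  }
  dt <- 0.1
  nt <- ceiling(n_scans * tr / dt)
  X <- matrix(0, n_scans, length(conds), dimnames = list(NULL, conds))
  hk <- if (hrf) canonical_hrf(seq(0, 32, by = dt)) else 1
  for (j in seq_along(conds)) {
    s <- numeric(nt)
    rows <- which(lab == conds[j])
    for (i in rows) {
      a <- floor(on[i] / dt) + 1L
      b <- min(nt, floor((on[i] + dur[i]) / dt))
      if (b >= a) s[a:b] <- 1
    }
    if (hrf) {
      s <- convolve(s, rev(hk), type = "open")[seq_len(nt)]
    }
    X[, j] <- s[pmin(nt, floor((seq_len(n_scans) - 1) * tr / dt) + 1L)]
  }
  X
}

#' Estimate condition beta patterns by ordinary least squares
#'
#' Fits a GLM per voxel: localizer designs have one column per environment
#' (boxcar spanning cue, blank and panorama periods); anticipation designs
#' have one column per trial type (cue environment x path) for the requested
#' phase. Boxcars are convolved with the canonical double-gamma response by
#' default (`hrf = FALSE` keeps pure boxcars). An optional nuisance matrix is
#' appended but its betas are discarded.
#'
#' @param timeseries Numeric matrix, voxel x time (scans).
#' @param events Schedule data frame from \code{\link{build_schedules}}.
#' @param task `"localizer"` or `"anticipation"`.
#' @param phase Anticipation phase to return: `"cue"`, `"blank"`, `"probe"`.
#' @param tr Repetition time in seconds.
#' @param hrf Convolve with the canonical HRF?
#' @param nuisance Optional scans x k nuisance matrix.
#' @return Condition x voxel matrix of beta estimates (condition labels as
#'   rownames).
#' @export
estimate_betas <- function(timeseries, events, task = "localizer",
                           phase = "cue", tr = 1, hrf = TRUE,
                           nuisance = NULL) {
  X <- build_design_matrix(events, ncol(timeseries), tr, task, phase, hrf)
  Xf <- cbind(X, intercept = 1, nuisance)
  q <- qr(Xf)
  if (q$rank < ncol(Xf)) {
    bad <- colnames(Xf)[q$pivot[(q$rank + 1):ncol(Xf)]]
    stopf("rank-deficient design; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  B <- qr.coef(q, t(timeseries))
  B[seq_len(ncol(X)), , drop = FALSE]
}

#' Simulate BOLD time series from known condition patterns
#'
#' Composes `t(X %*% patterns)` for the given schedule and adds white noise;
#' a minimal forward model used to exercise the GLM stage.
#'
#' @param patterns Condition x voxel matrix of true betas (rownames must
#'   match the design's condition labels).
#' @param events Schedule data frame.
#' @inheritParams estimate_betas
#' @param n_scans Number of scans.
#' @param noise_sd Gaussian noise SD.
#' @return Voxel x time matrix.
#' @export
simulate_bold <- function(patterns, events, task = "localizer",
                          phase = "cue", tr = 1, n_scans = NULL,
                          hrf = TRUE, noise_sd = 0) {
  ev <- events[events$task == task, , drop = FALSE]
  n_scans <- n_scans %||%
    ceiling((max(ev$onset + ev$duration + ev$blank_dur + ev$probe_dur +
                   ev$iti_s) + 20) / tr)
  X <- build_design_matrix(events, n_scans, tr, task, phase, hrf)
  stopifnot(setequal(rownames(patterns), colnames(X)))
  ts <- t(X %*% patterns[colnames(X), , drop = FALSE])
  ts + matrix(rnorm(length(ts), sd = noise_sd), nrow(ts))
}

#' Across-participant environment reliability
#'
#' For every voxel, correlates each held-out participant's 16-element
#' environment beta vector with the average vector of the remaining
#' participants, and averages the Pearson r over held-out choices. Voxels
#' where any fold has zero variance are flagged undefined (NA), not zeroed.
#'
#' @param localizer_betas A `beta_patterns` object (>= 3 participants).
#' @return A `reliability_map` list: `r` (per-voxel score, NA where
#'   undefined), `defined`, `lattice_shape`, `voxel_coords`, `n_participants`.
#' @export
environment_reliability <- function(localizer_betas) {
  v <- localizer_betas$values
  P <- dim(v)[1]; E <- dim(v)[2]; V <- dim(v)[3]
  if (P < 3) stopf("need >= 3 participants")
  tot <- colSums(v)                       # E x V
  rsum <- matrix(0, 1, V)
  undef <- rep(FALSE, V)
  r_acc <- rep(0, V)
  for (p in seq_len(P)) {
    own <- v[p, , ]                       # E x V
    others <- (tot - own) / (P - 1)
    num <- colSums(scale(own, scale = FALSE) *
                     scale(others, scale = FALSE))
    den <- sqrt(colSums(scale(own, scale = FALSE)^2) *
                  colSums(scale(others, scale = FALSE)^2))
    bad <- den == 0
    undef <- undef | bad
    r <- num / den
    r[bad] <- 0
    r_acc <- r_acc + r
  }
  r <- r_acc / P
  r[undef] <- NA_real_
  structure(list(r = r, defined = !undef,
                 lattice_shape = localizer_betas$lattice_shape,
                 voxel_coords = localizer_betas$voxel_coords,
                 n_participants = P),
            class = "reliability_map")
}

#' @export
print.reliability_map <- function(x, ...) {
  cat(sprintf("Reliability map: %d voxels, %d defined, mean r = %.3f\n",
              length(x$r), sum(x$defined), mean(x$r, na.rm = TRUE)))
  invisible(x)
}

# face-connected (6-neighborhood) component labels over a logical 3-D mask
label_components <- function(mask, lattice_shape) {
  arr <- array(mask, dim = lattice_shape)
  lab <- array(0L, dim = lattice_shape)
  nxt <- 0L
  dims <- lattice_shape
  idx <- which(arr)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(cur, dims)
      for (d in 1:3) for (s in c(-1L, 1L)) {
        nb <- ai
        nb[d] <- nb[d] + s
        if (nb[d] < 1L || nb[d] > dims[d]) next
        lin <- nb[1] + (nb[2] - 1L) * dims[1] +
          (nb[3] - 1L) * dims[1] * dims[2]
        if (arr[lin] && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  as.integer(lab)
}

#' Threshold and cluster-filter a reliability map
#'
#' Keeps voxels with reliability at least `r_min` that belong to a
#' face-connected (6-neighborhood) component of at least `min_cluster`
#' voxels. Undefined voxels never pass.
#'
#' @param map A `reliability_map`.
#' @param r_min Reliability threshold (default 0.1).
#' @param min_cluster Minimum component size in voxels (default 10).
#' @return Logical vector over voxels (canonical order).
#' @export
threshold_and_cluster <- function(map, r_min = 0.1, min_cluster = 10) {
  supra <- !is.na(map$r) & map$r >= r_min
  if (!any(supra)) return(supra)
  lab <- label_components(supra, map$lattice_shape)
  sizes <- tabulate(lab)
  keep <- lab > 0L & sizes[pmax(lab, 1L)] >= min_cluster
  keep & supra
}

#' Conjunction ROI: anatomical mask intersected with reliable voxels
#'
#' @param mask Logical vector of reliable-and-clustered voxels.
#' @param anatomical_mask Logical vector on the same lattice.
#' @param name ROI name.
#' @param provenance Optional list recorded alongside (e.g. r_threshold,
#'   min_cluster, atlas id).
#' @return A `conjunction_roi` list: `name`, `voxels` (integer indices),
#'   `empty`, `provenance`. An empty intersection warns and flags the ROI;
#'   downstream stages refuse flagged-empty ROIs.
#' @export
conjunction_roi <- function(mask, anatomical_mask, name = "roi",
                            provenance = list()) {
  if (length(mask) != length(anatomical_mask))
    stopf("masks live on different lattices")
  vox <- which(mask & anatomical_mask)
  if (length(vox) == 0)
    warnf("conjunction ROI '%s' is empty", name)
  structure(list(name = name, voxels = vox, empty = length(vox) == 0,
                 provenance = provenance),
            class = "conjunction_roi")
}

#' @export
print.conjunction_roi <- function(x, ...) {
  cat(sprintf("Conjunction ROI '%s': %d voxels%s\n", x$name,
              length(x$voxels), if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}
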