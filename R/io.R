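#' Write / read trial schedules as BIDS-events-style TSV
#'
#' @param schedule Data frame from \code{\link{build_schedules}}.
#' @param path TSV path.
#' @return `read_schedule` returns the schedule data frame.
#' @export
write_schedule <- function(schedule, path) {
  write.table(schedule, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize / restore a map design as JSON
#'
#' @param design A `map_design`.
#' @param path JSON path.
#' @return `read_map_design` returns the `map_design`.
#' @export
write_map_design <- function(design, path) {
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_map_design
#' @export
read_map_design <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(d[c("map_id", "environments", "green_order", "blue_order")],
            class = "map_design")
}

nifti_grid <- function(img) {
  list(dim = dim(img), xform = unname(RNifti::xform(img)))
}

#' Write beta patterns as per-participant NIfTI volumes with a JSON sidecar
#'
#' Each participant's conditions are stored as the 4th axis of a NIfTI-1
#' volume; a single sidecar records the condition order, task and lattice
#' shape so that values can be re-aligned to the package's canonical
#' condition order on read.
#'
#' @param betas A `beta_patterns` object.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return `read_beta_patterns` returns the `beta_patterns`, with conditions
#'   re-aligned to the sidecar's canonical order; mismatched grids or
#'   affines across files raise an ingestion error naming the file.
#' @export
write_beta_patterns <- function(betas, dir, prefix = betas$task) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  P <- dim(betas$values)[1]
  for (p in seq_len(P)) {
    arr <- array(aperm(betas$values[p, , , drop = FALSE], c(3, 2, 1)),
                 dim = c(betas$lattice_shape, length(betas$conditions)))
    RNifti::writeNifti(RNifti::asNifti(arr),
                       file.path(dir, sprintf("%s_sub-%02d.nii.gz",
                                              prefix, p)))
  }
  jsonlite::write_json(
    list(task = betas$task, conditions = betas$conditions,
         lattice_shape = betas$lattice_shape, space = betas$space,
         n_participants = P),
    file.path(dir, sprintf("%s_sidecar.json", prefix)), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_beta_patterns
#' @param conditions Optional target condition order: values are re-aligned
#'   from the sidecar's stored order to this canonical order on read.
#' @export
read_beta_patterns <- function(dir, prefix, conditions = NULL) {
  side <- jsonlite::read_json(file.path(dir,
                                        sprintf("%s_sidecar.json", prefix)),
                              simplifyVector = TRUE)
  P <- side$n_participants
  vals <- array(NA_real_, dim = c(P, length(side$conditions),
                                  prod(side$lattice_shape)))
  ref <- NULL
  for (p in seq_len(P)) {
    f <- file.path(dir, sprintf("%s_sub-%02d.nii.gz", prefix, p))
    img <- RNifti::readNifti(f)
    g <- nifti_grid(img)
    if (is.null(ref)) ref <- g
    else if (!identical(ref$dim, g$dim) ||
             max(abs(ref$xform - g$xform)) > 1e-6)
      stopf("grid/affine mismatch in %s", f)
    vals[p, , ] <- t(matrix(img, ncol = length(side$conditions)))
  }
  if (!is.null(conditions)) {
    if (!setequal(conditions, side$conditions))
      stopf("requested condition set differs from sidecar for '%s'", prefix)
    vals <- vals[, match(conditions, side$conditions), , drop = FALSE]
    side$conditions <- conditions
  }
  beta_patterns(vals, side$conditions, side$lattice_shape,
                task = side$task, space = side$space %||% "lattice")
}

#' Write / read a voxelwise map as NIfTI
#'
#' @param values Numeric vector over voxels (canonical order).
#' @param lattice_shape 3-D lattice dimensions.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `read_map_volume` returns the numeric vector.
#' @export
write_map_volume <- function(values, lattice_shape, path) {
  RNifti::writeNifti(RNifti::asNifti(array(values, dim = lattice_shape)),
                     path)
  invisible(path)
}

#' @rdname write_map_volume
#' @export
read_map_volume <- function(path) {
  as.vector(RNifti::readNifti(path))
}

#' Pipeline configuration
#'
#' Bundles the generator truth, analysis parameters and bookkeeping for
#' \code{\link{run_pipeline}}. Round-trips through YAML via
#' \code{\link{write_pipeline_config}}.
#'
#' @param out_dir Output directory for artifacts.
#' @param truth A \code{\link{ground_truth_config}} for simulation runs.
#' @param r_min,min_cluster Reliability threshold and cluster minimum.
#' @param lambda,sigma_max Gaussian fit settings.
#' @param n_perm Permutation count for the profile-level tests.
#' @param searchlight Run the searchlight + gradient stage?
#' @param side,step,min_vox,n_perm_voxel Searchlight geometry and per-cube
#'   permutation count.
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("seqhorizon-"),
                            truth = ground_truth_config(),
                            r_min = 0.1, min_cluster = 10, lambda = 0.01,
                            sigma_max = 10, n_perm = 1000,
                            searchlight = FALSE, side = 7, step = 2,
                            min_vox = 64, n_perm_voxel = 0, seed = 1L) {
  stopifnot(r_min >= -1, r_min <= 1, min_cluster >= 1, lambda >= 0,
            sigma_max > 0, n_perm >= 1, side >= 1, step >= 1, min_vox >= 1)
  structure(list(out_dir = out_dir, truth = truth, r_min = r_min,
                 min_cluster = min_cluster, lambda = lambda,
                 sigma_max = sigma_max, n_perm = n_perm,
                 searchlight = searchlight, side = side, step = step,
                 min_vox = min_vox, n_perm_voxel = n_perm_voxel,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$truth <- unclass(x$truth)
  x$truth$signal_region <- as.integer(x$truth$signal_region)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  tr <- x$truth
  truth <- ground_truth_config(
    n_participants = tr$n_participants,
    lattice_shape = as.integer(tr$lattice_shape),
    template_sd = tr$template_sd,
    participant_template_sd = tr$participant_template_sd,
    measurement_sd = tr$measurement_sd, profile = tr$profile,
    amplitude_sd = tr$amplitude_sd, asymptote_sd = tr$asymptote_sd,
    gradient = tr$gradient,
    signal_region = as.logical(tr$signal_region),
    orthogonalize = tr$orthogonalize, behavior = tr$behavior,
    seed = tr$seed)
  pipeline_config(out_dir = x$out_dir, truth = truth, r_min = x$r_min,
                  min_cluster = x$min_cluster, lambda = x$lambda,
                  sigma_max = x$sigma_max, n_perm = x$n_perm,
                  searchlight = x$searchlight, side = x$side,
                  step = x$step, min_vox = x$min_vox,
                  n_perm_voxel = x$n_perm_voxel, seed = x$seed)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> reliability -> voxel selection -> profiles (cued and
#' uncued) -> Gaussian fits and permutation inference -> behavior linking ->
#' (optionally) searchlight + gradient, writing artifacts and a manifest
#' (parameters plus MD5 hashes of every written file) under
#' `config$out_dir`. All stochastic stages derive their seeds from
#' `config$seed`, so rerunning with the same config reproduces every output
#' exactly. With `resume = TRUE`, stages whose artifact files already exist
#' are reloaded instead of recomputed.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param resume Reload existing artifacts?
#' @return A results list (invisible components also serialized under
#'   `out_dir`): `dataset`, `reliability`, `roi`, `profiles_cued`,
#'   `profiles_uncued`, `fits`, `stats`, `perm_include`, `perm_exclude`,
#'   `cued_vs_uncued`, `behavior`, `searchlight`, `gradient`, `manifest`.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(config$seed, 6)
  art <- function(f) file.path(config$out_dir, f)

  truth <- config$truth
  truth$seed <- config$seed
  ds <- simulate_dataset(truth)
  write_schedule(ds$schedule, art("schedule.tsv"))

  rel <- environment_reliability(ds$localizer_betas)
  mask <- threshold_and_cluster(rel, config$r_min, config$min_cluster)
  roi <- conjunction_roi(mask, rep(TRUE, length(mask)), name = "reliable",
                         provenance = list(r_threshold = config$r_min,
                                           min_cluster = config$min_cluster,
                                           anatomical = "whole-lattice"))
  if (roi$empty) stopf("stage voxel-selection failed: empty ROI")

  prof_file <- art("profiles.tsv")
  if (resume && file.exists(prof_file)) {
    tab <- read.delim(prof_file)
    restore <- function(o) {
      d <- tab[tab$ordering == o, ]
      P <- length(unique(d$participant))
      structure(list(
        values = matrix(d$value, P, 9, byrow = TRUE,
                        dimnames = list(NULL, as.character(-4:4))),
        baseline = d$baseline[d$position == 0], ordering = o,
        roi = d$roi[1], n_trial_types = 32L,
        participants = unique(d$participant)),
        class = "similarity_profiles")
    }
    prof_c <- restore("cued"); prof_u <- restore("uncued")
  } else {
    prof_c <- compute_profiles(ds$anticipation_betas, ds$localizer_betas,
                               ds$designs, roi, "cued")
    prof_u <- compute_profiles(ds$anticipation_betas, ds$localizer_betas,
                               ds$designs, roi, "uncued")
    write.table(rbind(profiles_to_table(prof_c), profiles_to_table(prof_u)),
                prof_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  fits <- fit_participants(prof_c, lambda = config$lambda,
                           sigma_max = config$sigma_max)
  write.table(fits, art("fits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stats <- parameter_stats(fits)
  perm_inc <- permutation_test(prof_c, TRUE, config$n_perm, seeds[[1]],
                               config$lambda, sigma_max = config$sigma_max)
  perm_exc <- permutation_test(prof_c, FALSE, config$n_perm, seeds[[2]],
                               config$lambda, sigma_max = config$sigma_max)
  cvu <- cued_vs_uncued_test(prof_c, prof_u, config$n_perm, seeds[[3]],
                             config$lambda, sigma_max = config$sigma_max)

  acc <- accuracy_summary(ds$behavior)
  slopes <- rt_step_slope(ds$behavior)
  bb <- brain_behavior_corr(fits$asymptote, slopes, "asymptote",
                            roi = roi$name)

  sl <- NULL; grad <- NULL
  if (config$searchlight) {
    sl <- searchlight_fit(ds$anticipation_betas, ds$localizer_betas,
                          ds$designs, mask, config$side, config$step,
                          config$min_vox, config$n_perm_voxel,
                          seed = seeds[[4]], lambda = config$lambda,
                          sigma_max = config$sigma_max)
    grad <- gradient_correlation(sl, which(mask), "width")
    write_map_volume(colMeans(sl$width), ds$lattice_shape,
                     art("width_map.nii.gz"))
  }

  results <- list(
    n_roi_voxels = length(roi$voxels),
    amplitude = list(mean = mean(fits$amplitude), t = stats$amplitude$t,
                     p = stats$amplitude$p),
    asymptote = list(mean = mean(fits$asymptote), t = stats$asymptote$t,
                     p = stats$asymptote$p),
    widths = list(sigma_b = mean(fits$sigma_b),
                  sigma_f = mean(fits$sigma_f), V = stats$widths$V,
                  p = stats$widths$p),
    baseline_mean = mean(fits$baseline),
    permutation = list(include_cue = list(p = perm_inc$p, r2 = perm_inc$r2),
                       exclude_cue = list(p = perm_exc$p, r2 = perm_exc$r2),
                       cued_vs_uncued_p = cvu$p),
    behavior = list(mean_accuracy = acc$mean_accuracy, accuracy_t = acc$t,
                    mean_rt_slope = mean(slopes$slope, na.rm = TRUE),
                    brain_behavior_rho = bb$rho, brain_behavior_p = bb$p),
    gradient = if (!is.null(grad))
      list(mean_rho = grad$mean_rho, t = grad$t, p = grad$p))
  jsonlite::write_json(results, art("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write.table(ds$behavior, art("behavior.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        art("manifest.json")))
  manifest <- list(
    package = "seqhorizon",
    version = as.character(utils::packageVersion("seqhorizon")),
    seed = config$seed,
    params = list(r_min = config$r_min, min_cluster = config$min_cluster,
                  lambda = config$lambda, sigma_max = config$sigma_max,
                  n_perm = config$n_perm, searchlight = config$searchlight),
    hashes = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(dataset = ds, reliability = rel, roi = roi,
                 profiles_cued = prof_c, profiles_uncued = prof_u,
                 fits = fits, stats = stats, perm_include = perm_inc,
                 perm_exclude = perm_exc, cued_vs_uncued = cvu,
                 behavior = list(accuracy = acc, slopes = slopes,
                                 brain_behavior = bb),
                 searchlight = sl, gradient = grad, results = results,
                 manifest = manifest))
}
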