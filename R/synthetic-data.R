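#' Ground-truth configuration for the synthetic generator
#'
#' Collects every parameter of the synthetic multivoxel + behavioral
#' generator, with defaults mirroring the study conditions the analysis is
#' designed for: 32 participants, 16 environments in two maps of 8, and a
#' cue-centered mixture profile with amplitude 0.09, asymptote -0.014 and
#' backward/forward widths 0.712 / 0.634 steps.
#'
#' @param n_participants Number of participants.
#' @param lattice_shape 3-D voxel-grid dimensions.
#' @param template_sd Per-voxel standard deviation of group environment
#'   templates (arbitrary units).
#' @param participant_template_sd SD of participant-specific template noise
#'   around the group template; controls across-participant reliability.
#' @param measurement_sd Per-voxel measurement noise SD on every beta
#'   pattern.
#' @param profile List `A`, `c`, `sigma_b`, `sigma_f`: the generating
#'   similarity-scale mixture curve (negative `c` = suppression of far
#'   environments).
#' @param amplitude_sd,asymptote_sd Between-participant SDs of the true
#'   amplitude and asymptote.
#' @param gradient `NULL`, or list `intercept`, `slope`: makes both
#'   generating widths a linear function of voxel y-coordinate,
#'   sigma(y) = intercept + slope * y (clamped to [0.1, 10]).
#' @param signal_region Logical vector over voxels (canonical order, see
#'   \code{\link{lattice_coords}}) carrying sequence structure; `NULL` uses a
#'   centered box spanning half of each dimension.
#' @param orthogonalize Orthogonalize (and mean-center) group templates
#'   across environments so profile values have a closed-form expectation?
#' @param behavior List: `rt_base` (s), `rt_slope_mean` (s/step),
#'   `rt_slope_sd`, `rt_noise_sd`, `coupling` (target correlation between a
#'   participant's true asymptote and their RT slope; negative values mean
#'   deeper suppression goes with steeper response-time costs),
#'   `accuracy_logit` (intercept at 2.5 steps, slope per step).
#' @param seed Master seed; all outputs are bit-for-bit reproducible given
#'   the config.
#' @return A validated `ground_truth_config` list.
#' @export
ground_truth_config <- function(n_participants = 32,
                                lattice_shape = c(14, 14, 6),
                                template_sd = 1,
                                participant_template_sd = 0.3,
                                measurement_sd = 1,
                                profile = list(A = 0.09, c = -0.014,
                                               sigma_b = 0.712,
                                               sigma_f = 0.634),
                                amplitude_sd = 0.029,
                                asymptote_sd = 0.009,
                                gradient = NULL,
                                signal_region = NULL,
                                orthogonalize = TRUE,
                                behavior = list(),
                                seed = 1L) {
  behavior <- modifyList(list(rt_base = 1.0, rt_slope_mean = 0.126,
                              rt_slope_sd = 0.05, rt_noise_sd = 0.2,
                              coupling = -0.362,
                              accuracy_logit = c(1.9, -0.15)),
                         behavior)
  stopifnot(length(lattice_shape) == 3, all(lattice_shape >= 1))
  if (profile$sigma_b <= 0 || profile$sigma_b > 10 ||
      profile$sigma_f <= 0 || profile$sigma_f > 10)
    stopf("generating widths must lie in (0, 10]")
  if (abs(behavior$coupling) > 1) stopf("coupling must lie in [-1, 1]")
  nvox <- prod(lattice_shape)
  if (is.null(signal_region))
    signal_region <- default_signal_region(lattice_shape)
  stopifnot(length(signal_region) == nvox)
  structure(list(n_participants = n_participants,
                 lattice_shape = lattice_shape, n_env = 16L,
                 template_sd = template_sd,
                 participant_template_sd = participant_template_sd,
                 measurement_sd = measurement_sd, profile = profile,
                 amplitude_sd = amplitude_sd, asymptote_sd = asymptote_sd,
                 gradient = gradient, signal_region = signal_region,
                 orthogonalize = orthogonalize, behavior = behavior,
                 seed = seed),
            class = "ground_truth_config")
}

#' Default signal region: a centered box spanning half of each dimension
#' @param lattice_shape 3-D lattice dimensions.
#' @return Logical vector over voxels in canonical order.
#' @export
default_signal_region <- function(lattice_shape) {
  co <- lattice_coords(lattice_shape)
  inside <- rep(TRUE, nrow(co))
  for (d in 1:3) {
    lo <- floor(lattice_shape[d] / 4)
    hi <- lo + ceiling(lattice_shape[d] / 2) - 1
    inside <- inside & co[, d] >= lo & co[, d] <= hi
  }
  inside
}

#' Cue-centered mixture weights of the generator
#'
#' The generator builds each anticipation pattern as a weighted mixture of
#' the environment templates at each signed step from the cue on the cued
#' path. Weights follow the asymmetric Gaussian: weight(0) = A, weight(s) =
#' c + (A - c) exp(-s^2 / (2 sigma_dir^2)). Because steps -4 and +4 reach
#' the same (antipodal) environment, that environment receives a single
#' shared weight, the mean of the forward and backward evaluations at |s|=4;
#' the returned vector reports it at both ends.
#'
#' @inheritParams asym_gaussian
#' @param steps Step positions (default -4..+4).
#' @return Named numeric vector of weights at `steps`.
#' @export
mixture_weights <- function(A, c, sigma_b, sigma_f, steps = -4:4) {
  w <- asym_gaussian(steps, A, c, sigma_b, sigma_f)
  anti <- mean(asym_gaussian(c(-4, 4), A, c, sigma_b, sigma_f))
  w[abs(steps) == 4] <- anti
  names(w) <- steps
  w
}

# per-environment weights (one weight per unique environment) for a cue on a
# path order; names are environment ids
env_weights <- function(order, cue, A, c, sigma_b, sigma_f) {
  n <- length(order)
  i <- match(cue, order)
  envs <- order[((i - 1L + (0:(n - 1L))) %% n) + 1L]  # offsets 0..n-1
  s <- ifelse(0:(n - 1L) <= n / 2, 0:(n - 1L), 0:(n - 1L) - n)
  w <- asym_gaussian(s, A, c, sigma_b, sigma_f)
  w[s == n / 2] <- mean(asym_gaussian(c(-n / 2, n / 2), A, c, sigma_b,
                                      sigma_f))
  setNames(w, envs)
}

#' Generate group and per-participant environment templates
#'
#' Group templates are drawn independently per voxel within the signal
#' region (zero elsewhere); with `orthogonalize = TRUE` (default) they are
#' mean-centered, orthogonalized across environments, and rescaled so each
#' template's per-voxel RMS equals `template_sd`, giving profile values a
#' closed-form expectation. Participant templates add independent Gaussian
#' noise at `participant_template_sd` on signal voxels.
#'
#' @param config A \code{\link{ground_truth_config}}.
#' @param seed Seed (defaults to a stream derived from `config$seed`).
#' @return List with `group` (n_env x n_voxel matrix, environment ids as
#'   rownames) and `participant` (n_participants x n_env x n_voxel array).
#' @export
generate_templates <- function(config, seed = NULL) {
  sig <- which(config$signal_region)
  nvox <- prod(config$lattice_shape)
  E <- config$n_env
  if (config$orthogonalize && length(sig) < E + 1)
    stopf("signal region too small to orthogonalize %d environments", E)
  with_seed(seed %||% child_seeds(config$seed, 8)[[3]], {
    Tm <- matrix(0, E, nvox)
    raw <- matrix(rnorm(E * length(sig), sd = config$template_sd),
                  E, length(sig))
    if (config$orthogonalize) {
      raw <- sweep(raw, 1, rowMeans(raw))          # zero-mean rows
      qr_ <- qr(t(raw))
      ortho <- t(qr.Q(qr_))                        # orthonormal rows
      ortho <- sweep(ortho, 1, rowMeans(ortho))    # re-center (near-zero)
      raw <- ortho * sqrt(length(sig)) * config$template_sd
    }
    Tm[, sig] <- raw
    rownames(Tm) <- env_ids()
    Pt <- array(rep(Tm, each = config$n_participants),
                dim = c(config$n_participants, E, nvox))
    if (config$participant_template_sd > 0) {
      noise <- array(rnorm(config$n_participants * E * length(sig),
                           sd = config$participant_template_sd),
                     dim = c(config$n_participants, E, length(sig)))
      Pt[, , sig] <- Pt[, , sig] + noise
    }
    list(group = Tm, participant = Pt)
  })
}

env_ids <- function() c(sprintf("A%d", 1:8), sprintf("B%d", 1:8))

# canonical 32 trial types: map, path, cue in design order
trial_types <- function(designs) {
  out <- do.call(rbind, lapply(designs, function(d)
    do.call(rbind, lapply(c("green", "blue"), function(p)
      data.frame(map = d$map_id, path = p, cue_env = d$environments,
                 stringsAsFactors = FALSE)))))
  out$label <- paste(out$map, out$path, out$cue_env, sep = "_")
  out
}

gradient_sigma <- function(config, yvals) {
  pmin(pmax(config$gradient$intercept + config$gradient$slope * yvals, 0.1),
       10)
}

#' Generate anticipation beta patterns
#'
#' For each trial type (cue environment x path), the signal-region pattern
#' is the mixture of that participant's environment templates at each step
#' from the cue along the cued path (weights from
#' \code{\link{mixture_weights}} with the participant's true amplitude and
#' asymptote), plus measurement noise; voxels outside the signal region get
#' pure noise. With a configured width gradient, weights are computed per
#' y-slab with the slab-specific sigma.
#'
#' @param templates Output of \code{\link{generate_templates}}.
#' @param designs List of two `map_design`s.
#' @param config A \code{\link{ground_truth_config}}.
#' @param participant_params Data frame with per-participant true `A` and
#'   `c` (defaults drawn from the config's between-participant SDs).
#' @param seed Seed.
#' @return List: `betas` (`beta_patterns` with n_participants x 32 x n_voxel
#'   values), `trial_types`, `participant_params`.
#' @export
generate_anticipation_betas <- function(templates, designs, config,
                                        participant_params = NULL,
                                        seed = NULL) {
  tt <- trial_types(designs)
  nvox <- prod(config$lattice_shape)
  P <- config$n_participants
  sig <- which(config$signal_region)
  coords <- lattice_coords(config$lattice_shape)
  with_seed(seed %||% child_seeds(config$seed, 8)[[4]], {
    if (is.null(participant_params))
      participant_params <- data.frame(
        A = rnorm(P, config$profile$A, config$amplitude_sd),
        c = rnorm(P, config$profile$c, config$asymptote_sd))
    vals <- array(rnorm(P * nrow(tt) * nvox, sd = config$measurement_sd),
                  dim = c(P, nrow(tt), nvox))
    yslabs <- if (is.null(config$gradient)) list(`all` = sig)
      else split(sig, coords[sig, "y"])
    for (p in seq_len(P)) {
      Tp <- templates$participant[p, , , drop = TRUE]  # E x nvox
      Ap <- participant_params$A[p]; cp <- participant_params$c[p]
      for (slab in names(yslabs)) {
        vox <- yslabs[[slab]]
        if (is.null(config$gradient)) {
          sb <- config$profile$sigma_b; sf <- config$profile$sigma_f
        } else {
          sb <- sf <- gradient_sigma(config, as.numeric(slab))
        }
        W <- matrix(0, nrow(tt), config$n_env,
                    dimnames = list(tt$label, env_ids()))
        for (k in seq_len(nrow(tt))) {
          d <- designs[[match(tt$map[k], vapply(designs, `[[`, "",
                                                "map_id"))]]
          ord <- if (tt$path[k] == "green") d$green_order else d$blue_order
          ew <- env_weights(ord, tt$cue_env[k], Ap, cp, sb, sf)
          W[k, names(ew)] <- ew
        }
        vals[p, , vox] <- vals[p, , vox] + W %*% Tp[, vox]
      }
    }
    list(betas = beta_patterns(vals, tt$label, config$lattice_shape,
                               task = "anticipation"),
         trial_types = tt, participant_params = participant_params)
  })
}

#' Generate localizer beta patterns
#'
#' Each participant's localizer beta for an environment is that
#' participant's template plus independent measurement noise at
#' `measurement_sd` (all voxels).
#'
#' @inheritParams generate_anticipation_betas
#' @return A `beta_patterns` object (n_participants x 16 x n_voxel).
#' @export
generate_localizer_betas <- function(templates, config, seed = NULL) {
  P <- config$n_participants
  nvox <- prod(config$lattice_shape)
  with_seed(seed %||% child_seeds(config$seed, 8)[[5]], {
    vals <- templates$participant +
      array(rnorm(P * config$n_env * nvox, sd = config$measurement_sd),
            dim = c(P, config$n_env, nvox))
    beta_patterns(vals, env_ids(), config$lattice_shape, task = "localizer")
  })
}

#' Generate the behavioral trial table
#'
#' Response time on each trial is `rt_base + slope_i * correct_steps` plus
#' Gaussian noise; participant slopes are drawn so that their correlation
#' with the participant's true asymptote approaches `coupling` (a Gaussian
#' coupling on standardized values). Accuracy follows a logistic model of
#' steps centered at 2.5; `accuracy_logit = c(0, 0)` yields a chance-level
#' (50%) responder.
#'
#' @param config A \code{\link{ground_truth_config}}.
#' @param schedule Schedule from \code{\link{build_schedules}} (anticipation
#'   rows are used).
#' @param asymptotes Per-participant true asymptotes (defaults to draws from
#'   the config).
#' @param seed Seed.
#' @return List: `table` (participant, run, trial_index, correct_steps,
#'   correct, rt) and `participant` (true `asymptote`, `slope` per
#'   participant).
#' @export
generate_behavior <- function(config, schedule, asymptotes = NULL,
                              seed = NULL) {
  ant <- schedule[schedule$task == "anticipation", , drop = FALSE]
  if (nrow(ant) == 0) stopf("schedule has no anticipation rows")
  P <- config$n_participants
  bh <- config$behavior
  with_seed(seed %||% child_seeds(config$seed, 8)[[6]], {
    if (is.null(asymptotes))
      asymptotes <- rnorm(P, config$profile$c, config$asymptote_sd)
    z_c <- if (sd(asymptotes) > 0) as.numeric(scale(asymptotes))
           else rep(0, P)
    kap <- bh$coupling
    z_s <- kap * z_c + sqrt(max(0, 1 - kap^2)) * rnorm(P)
    slopes <- bh$rt_slope_mean + bh$rt_slope_sd * z_s
    rows <- lapply(seq_len(P), function(p) {
      steps <- ant$correct_steps
      lg <- bh$accuracy_logit[1] + bh$accuracy_logit[2] * (steps - 2.5)
      correct <- rbinom(length(steps), 1, plogis(lg)) == 1
      rt <- bh$rt_base + slopes[p] * steps +
        rnorm(length(steps), sd = bh$rt_noise_sd)
      data.frame(participant = p, run = ant$run,
                 trial_index = ant$trial_index, correct_steps = steps,
                 correct = correct, rt = rt)
    })
    list(table = do.call(rbind, rows),
         participant = data.frame(participant = seq_len(P),
                                  asymptote = asymptotes, slope = slopes))
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs the whole generator: map designs, trial schedules, group and
#' participant templates, localizer and anticipation beta patterns, and the
#' behavioral table, all driven by a single master seed. The returned truth
#' record stores the config and every per-participant generating value, for
#' parameter-recovery studies.
#'
#' @param config A \code{\link{ground_truth_config}}.
#' @return A `synthetic_dataset` list: `designs`, `schedule`,
#'   `localizer_betas`, `anticipation_betas`, `trial_types`, `behavior`,
#'   `voxel_coords`, `lattice_shape`, `truth`.
#' @export
simulate_dataset <- function(config = ground_truth_config()) {
  seeds <- child_seeds(config$seed, 8)
  designs <- list(make_map_design("A", 8, seeds[[1]]),
                  make_map_design("B", 8, seeds[[1]] + 1L))
  schedule <- build_schedules(designs, seed = seeds[[2]])
  templates <- generate_templates(config, seeds[[3]])
  ant <- generate_anticipation_betas(templates, designs, config,
                                     seed = seeds[[4]])
  loc <- generate_localizer_betas(templates, config, seeds[[5]])
  beh <- generate_behavior(config, schedule,
                           asymptotes = ant$participant_params$c,
                           seed = seeds[[6]])
  truth <- list(config = config,
                participant = cbind(ant$participant_params,
                                    slope = beh$participant$slope),
                group_templates = templates$group)
  structure(list(designs = designs, schedule = schedule,
                 localizer_betas = loc, anticipation_betas = ant$betas,
                 trial_types = ant$trial_types, behavior = beh$table,
                 voxel_coords = lattice_coords(config$lattice_shape),
                 lattice_shape = config$lattice_shape, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d participants, %s lattice (%d voxels, %d signal), %d trial types\n",
    x$truth$config$n_participants,
    paste(x$lattice_shape, collapse = "x"), prod(x$lattice_shape),
    sum(x$truth$config$signal_region), nrow(x$trial_types)))
  invisible(x)
}
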