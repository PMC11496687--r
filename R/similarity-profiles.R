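roi_indices <- function(roi, nvox = NULL) {
  if (inherits(roi, "conjunction_roi")) {
    if (roi$empty) stopf("ROI '%s' is flagged empty", roi$name)
    roi$voxels
  } else if (is.logical(roi)) which(roi)
  else as.integer(roi)
}

roi_label <- function(roi) {
  if (inherits(roi, "conjunction_roi")) roi$name else "custom"
}

#' Leave-one-participant-out environment templates
#'
#' For each participant, the environment templates are the ROI-restricted
#' localizer betas averaged over all *other* participants, so that a
#' participant's own data never contribute to the templates their
#' anticipation patterns are compared against.
#'
#' @param localizer_betas A `beta_patterns` object (>= 3 participants).
#' @param roi A `conjunction_roi`, logical mask, or integer voxel indices.
#' @return Array participant x environment x roi-voxel: templates for each
#'   held-out participant.
#' @export
loo_environment_templates <- function(localizer_betas, roi) {
  vox <- roi_indices(roi)
  if (length(vox) == 0) stopf("ROI is empty")
  v <- localizer_betas$values[, , vox, drop = FALSE]
  P <- dim(v)[1]
  if (P < 2) stopf("need >= 2 participants")
  tot <- colSums(v)                       # E x Vr
  out <- array(NA_real_, dim = dim(v), dimnames = dimnames(v))
  for (p in seq_len(P)) out[p, , ] <- (tot - v[p, , ]) / (P - 1)
  out
}

#' Similarities of one cue-phase pattern to same-map templates
#'
#' Pearson correlation of an ROI-restricted cue-phase activity pattern with
#' each of the 8 same-map environment templates.
#'
#' @param cue_pattern Numeric vector (ROI voxels).
#' @param same_map_templates Environment x voxel matrix (8 rows, environment
#'   ids as rownames).
#' @return Named vector of 8 correlations.
#' @export
trial_similarities <- function(cue_pattern, same_map_templates) {
  if (length(cue_pattern) < 3) stopf("need >= 3 voxels")
  if (sd(cue_pattern) == 0) stopf("zero-variance cue pattern")
  vv <- apply(same_map_templates, 1, sd)
  if (any(vv == 0))
    stopf("zero-variance template(s): %s",
          paste(rownames(same_map_templates)[vv == 0], collapse = ", "))
  drop(cor(cue_pattern, t(same_map_templates)))
}

#' Arrange per-environment similarities into a cue-centered profile
#'
#' Places each environment's similarity at its signed step from the cue
#' along the given path order: the cue at position 0, successors at +1..+3,
#' predecessors at -1..-3, and the shared antipode duplicated at both -4 and
#' +4.
#'
#' @param similarities Named numeric vector (one value per environment of
#'   the map, including the cue's own template).
#' @param order Cyclic path order of the 8 environments.
#' @param cue Cue environment id.
#' @return Numeric vector of length 9, names "-4".."4".
#' @export
arrange_profile <- function(similarities, order, cue) {
  if (!all(order %in% names(similarities)))
    stopf("missing environment(s): %s",
          paste(setdiff(order, names(similarities)), collapse = ", "))
  s <- signed_step(order, cue, order)
  prof <- setNames(numeric(9), as.character(-4:4))
  prof[as.character(s)] <- similarities[order]
  prof["-4"] <- prof["4"]
  prof
}

#' Different-map baseline similarity
#'
#' Correlation of a cue-phase pattern with the voxelwise average of all
#' environment templates from the other (irrelevant) map
#' (average-then-correlate). This scalar is the reference against which
#' amplitudes and asymptotes are tested.
#'
#' @param cue_pattern Numeric vector (ROI voxels).
#' @param other_map_templates Environment x voxel matrix for the other map.
#' @return A single correlation.
#' @export
different_map_baseline <- function(cue_pattern, other_map_templates) {
  m <- colMeans(other_map_templates)
  if (length(cue_pattern) < 3) stopf("need >= 3 voxels")
  if (sd(cue_pattern) == 0 || sd(m) == 0)
    stopf("zero-variance input to baseline correlation")
  cor(cue_pattern, m)
}

#' Average trial-type profiles into a participant profile
#'
#' Positionwise mean over trial-type profiles, with the mean of the
#' per-trial-type baselines.
#'
#' @param trial_profiles Matrix (trial types x 9) or list of 9-vectors.
#' @param baselines Per-trial-type baselines.
#' @return List `values` (length 9), `baseline` (scalar).
#' @export
participant_profile <- function(trial_profiles, baselines) {
  M <- if (is.list(trial_profiles)) do.call(rbind, trial_profiles)
       else as.matrix(trial_profiles)
  list(values = colMeans(M), baseline = mean(baselines))
}

#' Cue-centered similarity profiles for all participants
#'
#' Runs the full profile stage for one ROI: leave-one-participant-out
#' environment templates, correlation of each trial type's cue-phase pattern
#' with the 8 same-map templates plus the different-map baseline, arrangement
#' along the cued (or uncued) path order with the antipode duplicated, and
#' positionwise averaging over all 32 trial types.
#'
#' @param anticipation_betas `beta_patterns` (participant x trial type x
#'   voxel; trial-type labels "map_path_cue").
#' @param localizer_betas `beta_patterns` (participant x environment x
#'   voxel).
#' @param designs List of two `map_design`s.
#' @param roi A `conjunction_roi`, logical mask, or voxel indices.
#' @param ordering `"cued"` (arrange along the cued path) or `"uncued"`
#'   (same values arranged along the other path of the same map).
#' @return A `similarity_profiles` object: `values` (participant x 9
#'   matrix), `baseline` (per participant), `ordering`, `roi`,
#'   `n_trial_types`, `participants`.
#' @export
compute_profiles <- function(anticipation_betas, localizer_betas, designs,
                             roi, ordering = c("cued", "uncued")) {
  ordering <- match.arg(ordering)
  vox <- roi_indices(roi)
  if (length(vox) < 3) stopf("ROI must contain >= 3 voxels")
  tt <- do.call(rbind, strsplit(anticipation_betas$conditions, "_"))
  tt <- data.frame(map = tt[, 1], path = tt[, 2], cue_env = tt[, 3],
                   stringsAsFactors = FALSE)
  map_ids <- vapply(designs, `[[`, "", "map_id")
  loo <- loo_environment_templates(localizer_betas, vox)
  ant <- anticipation_betas$values[, , vox, drop = FALSE]
  P <- dim(ant)[1]
  n_tt <- nrow(tt)
  env_names <- dimnames(loo)[[2]]
  values <- matrix(NA_real_, P, 9,
                   dimnames = list(NULL, as.character(-4:4)))
  baseline <- numeric(P)
  for (p in seq_len(P)) {
    Tm <- loo[p, , ]                              # E x Vr
    C <- cor_columns(t(ant[p, , ]), t(Tm))        # n_tt x E
    other_means <- vapply(seq_along(designs), function(d)
      colMeans(Tm[match(designs[[d]]$environments, env_names), ,
                  drop = FALSE]),
      numeric(length(vox)))                       # Vr x 2 (per-map mean)
    Cb <- cor_columns(t(ant[p, , ]), other_means) # n_tt x 2
    prof <- matrix(NA_real_, n_tt, 9)
    base <- numeric(n_tt)
    for (k in seq_len(n_tt)) {
      d_idx <- match(tt$map[k], map_ids)
      d <- designs[[d_idx]]
      ord <- if (ordering == "cued") {
        if (tt$path[k] == "green") d$green_order else d$blue_order
      } else {
        if (tt$path[k] == "green") d$blue_order else d$green_order
      }
      sims <- setNames(C[k, match(d$environments, env_names)],
                       d$environments)
      prof[k, ] <- arrange_profile(sims, ord, tt$cue_env[k])
      base[k] <- Cb[k, if (d_idx == 1) 2 else 1]
    }
    pp <- participant_profile(prof, base)
    values[p, ] <- pp$values
    baseline[p] <- pp$baseline
  }
  structure(list(values = values, baseline = baseline, ordering = ordering,
                 roi = roi_label(roi), n_trial_types = n_tt,
                 participants = seq_len(P)),
            class = "similarity_profiles")
}

#' @export
print.similarity_profiles <- function(x, ...) {
  cat(sprintf(
    "Similarity profiles (%s ordering, ROI '%s'): %d participants, %d trial types\n",
    x$ordering, x$roi, nrow(x$values), x$n_trial_types))
  cat("  group mean profile:",
      paste(sprintf("%.3f", colMeans(x$values)), collapse = " "), "\n")
  cat(sprintf("  mean different-map baseline: %.4f\n", mean(x$baseline)))
  invisible(x)
}

#' Tidy profile table
#'
#' @param profiles A `similarity_profiles` object.
#' @return Long data frame: participant, roi, ordering, position, value,
#'   baseline.
#' @export
profiles_to_table <- function(profiles) {
  P <- nrow(profiles$values)
  data.frame(
    participant = rep(profiles$participants, each = 9),
    roi = profiles$roi, ordering = profiles$ordering,
    position = rep(-4:4, times = P),
    value = as.vector(t(profiles$values)),
    baseline = rep(profiles$baseline, each = 9))
}
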