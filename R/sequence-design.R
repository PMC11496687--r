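#' Signed circular step between two environments on a path
#'
#' Computes the signed circular offset from `cue` to `target` under a cyclic
#' path order: forward (successor) distances are positive, backward
#' (predecessor) distances negative. In an 8-environment cycle the antipode is
#' equidistant in both directions; its offset is canonicalized to +4, and
#' profile construction duplicates that value at -4.
#'
#' @param order Character vector giving the cyclic order of environments
#'   (the successor of the last element is the first).
#' @param cue,target Environment identifiers present in `order`. `target`
#'   may be a vector.
#' @return Integer offsets in `-(n/2 - 1) ... +n/2` (for n = 8: -3..+4).
#' @examples
#' ord <- paste0("E", 1:8)
#' signed_step(ord, "E1", "E2")  # +1
#' signed_step(ord, "E1", "E5")  # +4 (shared antipode)
#' @export
signed_step <- function(order, cue, target) {
  n <- length(order)
  pc <- match(cue, order)
  pt <- match(target, order)
  if (is.na(pc)) stopf("unknown environment id: %s", cue)
  if (anyNA(pt)) stopf("unknown environment id: %s",
                       paste(target[is.na(pt)], collapse = ", "))
  d <- (pt - pc) %% n
  as.integer(ifelse(d <= n / 2, d, d - n))
}

#' Validate neighbor distinctness of two cyclic orders
#'
#' Two paths over the same environments should be as distinct as possible in
#' their local temporal context: for every environment, the two environments
#' preceding it and the two succeeding it should differ across the paths.
#' Full set-disjointness of the combined four-element neighborhoods is
#' combinatorially impossible on an 8-cycle (a blue neighborhood needs four
#' distinct environments drawn from the three that are not green neighbors,
#' and exhaustive enumeration shows the achievable minimum overlap is 2), so
#' the default `mode = "disjoint"` checks the strongest achievable reading:
#' \itemize{
#'   \item the two predecessors on one path share no environment with the
#'     two predecessors on the other, and likewise for the two successors
#'     (rules out identical orders), and
#'   \item the combined two-step neighbor sets share at most `max_shared`
#'     environments (default 2, the 8-cycle minimum; rules out reversed
#'     orders, whose neighbor sets coincide).
#' }
#' `mode = "positionwise"` is a weaker check requiring only inequality at
#' matching signed offsets (provided for comparison, not used by the
#' generator).
#'
#' @param green_order,blue_order Cyclic permutations of the same environments.
#' @param mode `"disjoint"` (default) or `"positionwise"`.
#' @param max_shared Maximum allowed overlap of the combined two-step
#'   neighbor sets in `"disjoint"` mode.
#' @return `TRUE` or `FALSE`.
#' @export
validate_distinctness <- function(green_order, blue_order,
                                  mode = c("disjoint", "positionwise"),
                                  max_shared = 2) {
  mode <- match.arg(mode)
  if (!setequal(green_order, blue_order) ||
      length(green_order) != length(blue_order))
    stopf("green and blue orders must be permutations of the same set")
  n <- length(green_order)
  nb <- function(order, env, k) {
    i <- match(env, order)
    order[((i - 1L + k) %% n) + 1L]
  }
  for (env in green_order) {
    gp <- nb(green_order, env, c(-2L, -1L))
    gs <- nb(green_order, env, c(1L, 2L))
    bp <- nb(blue_order, env, c(-2L, -1L))
    bs <- nb(blue_order, env, c(1L, 2L))
    ok <- if (mode == "disjoint") {
      !any(gp %in% bp) && !any(gs %in% bs) &&
        length(intersect(c(gp, gs), c(bp, bs))) <= max_shared
    } else {
      gpos <- c(nb(green_order, env, -2L), nb(green_order, env, -1L),
                nb(green_order, env, 1L), nb(green_order, env, 2L))
      bpos <- c(nb(blue_order, env, -2L), nb(blue_order, env, -1L),
                nb(blue_order, env, 1L), nb(blue_order, env, 2L))
      !any(gpos == bpos)
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Construct a two-path circular map design
#'
#' Builds one "map": 8 (by default) environments arranged on two cyclic
#' orders (a green and a blue path) that share all environments while keeping
#' every environment's +/-2-step neighborhoods disjoint across paths.
#'
#' `method = "search"` randomly permutes the blue order until the
#' distinctness constraint holds. `method = "fixed"` applies one fixed,
#' pre-validated position shuffle to the green order (the same relative
#' shuffle for every design), so that all participants' blue paths relate to
#' their green paths identically.
#'
#' @param map_id Single-character label prefixed to environment ids.
#' @param n_env Number of environments (>= 6).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param method `"search"` or `"fixed"`.
#' @param max_iter Search budget for `method = "search"`.
#' @return A `map_design` list: `map_id`, `environments`, `green_order`,
#'   `blue_order`.
#' @export
make_map_design <- function(map_id = "A", n_env = 8, seed = NULL,
                            method = c("search", "fixed"),
                            max_iter = 10000) {
  method <- match.arg(method)
  if (n_env < 6) stopf("n_env must be >= 6 (got %d)", n_env)
  envs <- sprintf("%s%d", map_id, seq_len(n_env))
  with_seed(seed, {
    green <- sample(envs)
    blue <- NULL
    if (method == "fixed") {
      pi_fixed <- fixed_shuffle(n_env)
      blue <- green[pi_fixed]
    } else {
      for (i in seq_len(max_iter)) {
        cand <- sample(green)
        if (validate_distinctness(green, cand)) { blue <- cand; break }
      }
      if (is.null(blue))
        stopf("no valid blue order found within %d iterations", max_iter)
    }
    structure(list(map_id = map_id, environments = envs,
                   green_order = green, blue_order = blue),
              class = "map_design")
  })
}

# One fixed position shuffle that satisfies the distinctness constraint for
# any green order of length n; found by a deterministic first-accept search
# and cached per n.
fixed_shuffle <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    idx <- seq_len(n)
    ref <- as.character(idx)
    pi_found <- with_seed(20200801L, {
      found <- NULL
      for (i in seq_len(100000)) {
        cand <- sample(idx)
        if (validate_distinctness(ref, ref[cand])) { found <- cand; break }
      }
      found
    })
    if (is.null(pi_found))
      stopf("no fixed distinct shuffle exists within budget for n = %d", n)
    cache[[key]] <- pi_found
    pi_found
  }
})

#' @export
print.map_design <- function(x, ...) {
  cat("Map design", x$map_id, "\n")
  cat("  green:", paste(x$green_order, collapse = " -> "), "\n")
  cat("  blue: ", paste(x$blue_order, collapse = " -> "), "\n")
  invisible(x)
}

#' Build anticipation and localizer trial schedules
#'
#' Generates the full trial table for both scanner tasks. Each anticipation
#' run cues every environment of both maps on both paths once (32 trials per
#' run), presented in four sequence blocks with randomized cue order within a
#' block; the correct probe is 1-4 steps ahead on the cued path (exactly 8
#' trials per step per run) and the foil is 1-4 steps beyond the correct
#' probe, capped at 5 steps from the cue. Each localizer run cues every
#' environment once (16 trials per run), without a path cue.
#'
#' Timing: anticipation cue 3 s, blank 5-9 s, probe 3 s; localizer cue 1 s,
#' blank 5 s, panorama 4 s, rating 3 s; inter-trial intervals uniform on
#' 3-8 s. All jitter is drawn on a 0.5 s grid.
#'
#' @param designs List of two `map_design`s with disjoint environment sets.
#' @param n_anticipation_runs,n_localizer_runs Run counts.
#' @param seed Integer seed for cue-order and jitter randomization.
#' @return A data frame (one row per trial) with BIDS-events-style columns:
#'   `task`, `run`, `trial_index`, `onset`, `duration`, `trial_type`, `map`,
#'   `path`, `cue_env`, `correct_probe_env`, `foil_probe_env`,
#'   `correct_steps`, `foil_steps_from_cue`, `blank_dur`, `probe_dur`,
#'   `iti_s`.
#' @export
build_schedules <- function(designs, n_anticipation_runs = 2,
                            n_localizer_runs = 4, seed = NULL) {
  stopifnot(length(designs) == 2)
  if (length(intersect(designs[[1]]$environments,
                       designs[[2]]$environments)) > 0)
    stopf("map designs must have disjoint environment sets")
  with_seed(seed, {
    ant <- do.call(rbind, lapply(seq_len(n_anticipation_runs),
                                 function(r) anticipation_run(designs, r)))
    loc <- do.call(rbind, lapply(seq_len(n_localizer_runs),
                                 function(r) localizer_run(designs, r)))
    rbind(ant, loc)
  })
}

half_grid <- function(lo, hi) sample(seq(lo, hi, by = 0.5), 1L)

anticipation_run <- function(designs, run) {
  blocks <- expand.grid(map = c(1L, 2L), path = c("green", "blue"),
                        stringsAsFactors = FALSE)
  blocks <- blocks[sample(nrow(blocks)), , drop = FALSE]
  rows <- list(); onset <- 0; k <- 0L
  for (b in seq_len(nrow(blocks))) {
    d <- designs[[blocks$map[b]]]
    path <- blocks$path[b]
    ord <- if (path == "green") d$green_order else d$blue_order
    cues <- sample(d$environments)
    steps <- sample(rep(1:4, length.out = length(cues)))
    for (j in seq_along(cues)) {
      k <- k + 1L
      cue <- cues[j]; st <- steps[j]
      i <- match(cue, ord)
      at <- function(s) ord[((i - 1L + s) %% length(ord)) + 1L]
      foil_steps <- st + sample.int(min(4L, 5L - st), 1L)
      blank <- half_grid(5, 9); iti <- half_grid(3, 8)
      rows[[k]] <- data.frame(
        task = "anticipation", run = run, trial_index = k, onset = onset,
        duration = 3, trial_type = paste(d$map_id, path, cue, sep = "_"),
        map = d$map_id, path = path, cue_env = cue,
        correct_probe_env = at(st), foil_probe_env = at(foil_steps),
        correct_steps = st, foil_steps_from_cue = foil_steps,
        blank_dur = blank, probe_dur = 3, iti_s = iti,
        stringsAsFactors = FALSE)
      onset <- onset + 3 + blank + 3 + iti
    }
  }
  do.call(rbind, rows)
}

localizer_run <- function(designs, run) {
  envs <- sample(c(designs[[1]]$environments, designs[[2]]$environments))
  onset <- 0; rows <- list()
  for (k in seq_along(envs)) {
    iti <- half_grid(3, 8)
    mp <- if (envs[k] %in% designs[[1]]$environments)
      designs[[1]]$map_id else designs[[2]]$map_id
    rows[[k]] <- data.frame(
      task = "localizer", run = run, trial_index = k, onset = onset,
      duration = 1, trial_type = paste("loc", envs[k], sep = "_"),
      map = mp, path = "none", cue_env = envs[k],
      correct_probe_env = NA_character_, foil_probe_env = NA_character_,
      correct_steps = NA_integer_, foil_steps_from_cue = NA_integer_,
      blank_dur = 5, probe_dur = 4 + 3, iti_s = iti,
      stringsAsFactors = FALSE)
    onset <- onset + 1 + 5 + 4 + 3 + iti
  }
  do.call(rbind, rows)
}
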