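#' Group accuracy summary and test against chance
#'
#' Per-participant proportion correct on the two-alternative probe, and a
#' one-sample t-test of the participant proportions against the 50% chance
#' level. Participants with zero usable trials are excluded with a warning.
#'
#' @param table Behavioral table (columns `participant`, `correct`).
#' @return List: `per_participant` (data frame), `mean_accuracy`, `t`, `p`,
#'   `df`, `n`.
#' @export
accuracy_summary <- function(table) {
  acc <- tapply(table$correct, table$participant, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  })
  if (anyNA(acc)) {
    warnf("%d participant(s) with zero trials excluded", sum(is.na(acc)))
    acc <- acc[!is.na(acc)]
  }
  if (length(acc) < 3) stopf("need >= 3 participants")
  tt <- if (sd(acc) == 0) list(statistic = NA_real_, p.value = NA_real_,
                               parameter = length(acc) - 1)
        else t.test(acc, mu = 0.5)
  list(per_participant = data.frame(participant = names(acc),
                                    accuracy = as.numeric(acc)),
       mean_accuracy = mean(acc), t = unname(tt$statistic),
       p = tt$p.value, df = unname(tt$parameter), n = length(acc))
}

#' Per-participant response-time cost per step
#'
#' Ordinary-least-squares slope of response time on the number of steps
#' between cue and correct probe, over correct trials only. Participants
#' with fewer than 2 distinct step values among correct responses are
#' flagged missing (NA).
#'
#' @param table Behavioral table (columns `participant`, `correct_steps`,
#'   `correct`, `rt`).
#' @return Data frame: `participant`, `slope` (s/step), `intercept`,
#'   `n_trials`.
#' @export
rt_step_slope <- function(table) {
  ok <- table$correct & !is.na(table$rt)
  parts <- sort(unique(table$participant))
  out <- lapply(parts, function(p) {
    d <- table[ok & table$participant == p, , drop = FALSE]
    if (nrow(d) < 2 || length(unique(d$correct_steps)) < 2)
      return(data.frame(participant = p, slope = NA_real_,
                        intercept = NA_real_, n_trials = nrow(d)))
    co <- lm.fit(cbind(1, d$correct_steps), d$rt)$coefficients
    data.frame(participant = p, slope = co[2], intercept = co[1],
               n_trials = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Brain-behavior individual-differences correlation
#'
#' Spearman rank correlation (two-sided) between a per-participant brain
#' measure from the Gaussian fits (asymptote or a width) and the
#' per-participant response-time slope, over participants with both measures
#' defined. Fewer than 5 matched pairs is refused.
#'
#' @param brain_measure Named or ordered numeric vector (one value per
#'   participant).
#' @param slopes Numeric vector or the data frame from
#'   \code{\link{rt_step_slope}}.
#' @param measure Tag recorded in the result (`"asymptote"`, `"sigma_f"`,
#'   `"sigma_b"`, ...).
#' @param roi ROI name recorded in the result.
#' @return A `brain_behavior_result` list: `rho`, `p`, `n`, `measure`,
#'   `roi`.
#' @export
brain_behavior_corr <- function(brain_measure, slopes,
                                measure = "asymptote", roi = "roi") {
  if (is.data.frame(slopes)) slopes <- slopes$slope
  if (length(brain_measure) != length(slopes))
    stopf("brain measure and slopes must be matched per participant")
  ok <- !is.na(brain_measure) & !is.na(slopes)
  if (sum(ok) < 5) stopf("need >= 5 matched participants")
  ct <- suppressWarnings(cor.test(brain_measure[ok], slopes[ok],
                                  method = "spearman"))
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                 measure = measure, roi = roi),
            class = "brain_behavior_result")
}

#' @export
print.brain_behavior_result <- function(x, ...) {
  cat(sprintf("Brain-behavior (%s, %s): rho = %.3f, p = %.3g, n = %d\n",
              x$measure, x$roi, x$rho, x$p, x$n))
  invisible(x)
}
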