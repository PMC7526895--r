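# Per-recording cardiac readouts: average heart rate, SD of heart rate, and
# the per-cycle rhythm irregularity score
#
#   S[n] = 100 * |P[n] - P[n-1]| / P[n-1]   (percent),
#
# i.e. the absolute percent change of each cycle period relative to its
# predecessor.  A 50-cycle window yields 49 scores; the per-recording score is
# their mean.

#' Per-cycle irregularity scores
#'
#' @param periods ordered cycle periods (seconds or any fixed unit), all
#'   positive, length >= 2.  The score is unit-free.
#' @return An `irregularity_profile`: list with `scores` (percent,
#'   length `length(periods) - 1`) and `window_n` (number of cycles used).
#' @export
irregularity_scores <- function(periods) {
  if (inherits(periods, "cycle_series")) periods <- periods$periods
  if (!is.numeric(periods) || length(periods) < 2L)
    data_error("need at least 2 periods to score irregularity")
  if (!all(is.finite(periods)) || any(periods <= 0))
    data_error("all periods must be finite and > 0")
  scores <- 100 * abs(diff(periods)) / periods[-length(periods)]
  structure(list(scores = scores, window_n = length(periods)),
            class = "irregularity_profile")
}

#' @export
print.irregularity_profile <- function(x, ...) {
  cat(sprintf("<irregularity_profile> %d cycles -> %d scores, mean %.2f%%\n",
              x$window_n, length(x$scores), mean(x$scores)))
  invisible(x)
}

#' Cardiac summary for one recording
#'
#' Computes the three per-recording readouts over an analysis window of
#' `window_n` cycles (study default 50): average heart rate, SD of heart
#' rate, and mean irregularity score.
#'
#' Two heart-rate definitions are offered.  `"per_cycle"` (default) takes the
#' instantaneous rate `60 / P[n]` of every cycle and reports its mean and
#' sample SD; this is the definition under which the SD readout is coherent.
#' `"count_extrapolate"` reads heart rate literally as beats counted per
#' minute, `60 * n_periods / sum(periods)`; its SD is still computed
#' per-cycle.
#'
#' @param series a [cycle_series()].
#' @param hr_mode heart-rate definition, see Details.
#' @param window_n cycles in the analysis window (default 50); `NULL` uses
#'   every available period.
#' @param strategy window placement, passed to [select_analysis_window()].
#' @return An `hr_summary`: `hr_mean` and `hr_sd` in beats/min, `is_mean` in
#'   percent, the full `profile`, and `n_cycles_used`.
#' @export
heart_rate_summary <- function(series,
                               hr_mode = c("per_cycle", "count_extrapolate"),
                               window_n = 50, strategy = "first") {
  stopifnot(inherits(series, "cycle_series"))
  hr_mode <- match.arg(hr_mode)
  if (!is.null(window_n))
    series <- select_analysis_window(series, window_n, strategy)
  periods <- series$periods
  inst_hr <- 60 / periods
  hr_mean <- switch(hr_mode,
    per_cycle = mean(inst_hr),
    count_extrapolate = 60 * length(periods) / sum(periods))
  profile <- irregularity_scores(periods)
  structure(list(subject_id = series$subject_id,
                 condition_label = series$condition_label,
                 hr_mean = hr_mean,
                 hr_sd = sd(inst_hr),
                 is_mean = mean(profile$scores),
                 profile = profile,
                 n_cycles_used = length(periods),
                 hr_mode = hr_mode),
            class = "hr_summary")
}

#' @export
print.hr_summary <- function(x, ...) {
  cat(sprintf(
    "<hr_summary> %s / %s: HR %.1f +/- %.1f beats/min, IS %.2f%% (%d cycles)\n",
    x$subject_id, x$condition_label, x$hr_mean, x$hr_sd, x$is_mean,
    x$n_cycles_used))
  invisible(x)
}

#' @export
as.data.frame.hr_summary <- function(x, ...) {
  data.frame(subject_id = x$subject_id, condition_label = x$condition_label,
             hr_mean = x$hr_mean, hr_sd = x$hr_sd, is_mean = x$is_mean,
             n_cycles = x$n_cycles_used, hr_mode = x$hr_mode,
             stringsAsFactors = FALSE)
}

format_mean_sd <- function(m, s, digits = 2) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), m, s)
}

#' Aggregate per-animal summaries into group mean +/- SD
#'
#' @param summaries list of `hr_summary` objects (or a data frame with
#'   columns `hr_mean`, `hr_sd`, `is_mean`).
#' @return Data frame with one row per readout: mean, sample SD (n-1
#'   denominator; reported as 0 with a warning for a single animal), n, and a
#'   formatted `"mean ± SD"` string in the study's reporting style.
#' @export
summarize_group <- function(summaries) {
  if (is.data.frame(summaries)) {
    tab <- summaries
  } else {
    if (!is.list(summaries) || length(summaries) == 0L)
      data_error("summaries must be a non-empty list of hr_summary objects")
    tab <- do.call(rbind, lapply(summaries, as.data.frame))
  }
  if (nrow(tab) == 0L) data_error("no summaries to aggregate")
  n <- nrow(tab)
  one <- function(readout) {
    v <- tab[[readout]]
    s <- if (n == 1L) 0 else sd(v)
    data.frame(readout = readout, mean = mean(v), sd = s, n = n,
               formatted = format_mean_sd(mean(v), s),
               stringsAsFactors = FALSE)
  }
  if (n == 1L)
    warn_ecgait("group of size 1: SD reported as 0", "single_animal_sd")
  out <- rbind(one("hr_mean"), one("hr_sd"), one("is_mean"))
  rownames(out) <- NULL
  out
}
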