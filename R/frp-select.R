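#' Epoching configuration for presaccadic analysis
#'
#' Default windows and thresholds of the saccade-locked analysis: epochs
#' span \[-200, +50) ms around saccade onset, baseline \[-200, -170) ms,
#' amplitude window \[-100, -20) ms (the final 20 ms are excluded as a
#' guard against the spike potential), +/-80 µV artefact rejection, a
#' 4-degree short/long saccade boundary and a 50-trial minimum per response
#' category. All windows are half-open in samples.
#'
#' @param epoch_ms,baseline_ms,amplitude_ms Window bounds, ms relative to
#'   saccade onset.
#' @param reject_uV Absolute amplitude rejection threshold, µV.
#' @param min_trials Minimum epochs per category for inclusion.
#' @param size_boundary_deg Short/long saccade boundary, degrees; exactly
#'   4.0 degrees classifies as long.
#' @param guard_ms Spike-potential guard before onset, ms.
#' @param fix_dur_ms Closed inclusion bounds on fixation duration.
#' @param max_saccade_ms Saccades must be strictly shorter than this.
#' @param min_onset_ms Fixations must start at least this long after
#'   stimulus onset (stimulus-onset potential protection).
#' @param blink_margin_ms Half-width of the blink exclusion interval around
#'   saccade onset.
#' @param mahalanobis_percentile Distance percentile above which fixations
#'   are removed by [mahalanobis_match()].
#' @return List of class `epoch_config`.
#' @export
epoch_config <- function(epoch_ms = c(-200, 50), baseline_ms = c(-200, -170),
                         amplitude_ms = c(-100, -20), reject_uV = 80,
                         min_trials = 50, size_boundary_deg = 4,
                         guard_ms = 20, fix_dur_ms = c(200, 2000),
                         max_saccade_ms = 80, min_onset_ms = 700,
                         blink_margin_ms = 300,
                         mahalanobis_percentile = 95) {
  stopifnot(baseline_ms[1] >= epoch_ms[1], baseline_ms[2] <= epoch_ms[2],
            amplitude_ms[1] >= epoch_ms[1], amplitude_ms[2] <= epoch_ms[2],
            amplitude_ms[2] <= -guard_ms)
  structure(list(epoch_ms = epoch_ms, baseline_ms = baseline_ms,
                 amplitude_ms = amplitude_ms, reject_uV = reject_uV,
                 min_trials = min_trials,
                 size_boundary_deg = size_boundary_deg, guard_ms = guard_ms,
                 fix_dur_ms = fix_dur_ms, max_saccade_ms = max_saccade_ms,
                 min_onset_ms = min_onset_ms,
                 blink_margin_ms = blink_margin_ms,
                 mahalanobis_percentile = mahalanobis_percentile),
            class = "epoch_config")
}

#' Select fixations valid for presaccadic EEG analysis
#'
#' Applies the five inclusion rules to every fixation that has a following
#' saccade: (i) fixation duration within \[200, 2000\] ms (closed bounds);
#' (ii) following saccade strictly shorter than 80 ms; (iii) fixation onset
#' at least 700 ms after stimulus onset; (iv) saccade onset at or before
#' the verbal response; (v) no blink overlapping \[-300, +300\] ms around
#' the saccade onset.
#'
#' @param events_by_trial List, one element per trial, of event lists
#'   (`fixations`, `saccades`, `blinks`) in trial-relative ms — either the
#'   generator's ground truth or [detect_events()] output.
#' @param trials Trial-record data.frame with `response_time_ms`,
#'   `category` and optionally `onset_ms` (session clock).
#' @param config An [epoch_config()].
#' @return Data.frame of valid fixations: `trial`, `onset`, `duration`,
#'   `saccade_onset`, `saccade_duration`, `saccade_amplitude_deg`,
#'   `size_class`, `category`, and `saccade_onset_session_ms` when trial
#'   onsets are available.
#' @export
select_valid_fixations <- function(events_by_trial, trials,
                                   config = epoch_config()) {
  stopifnot(length(events_by_trial) == nrow(trials))
  rows <- lapply(seq_along(events_by_trial), function(i) {
    ev <- events_by_trial[[i]]
    cand <- pair_fixations_saccades(ev)
    if (nrow(cand) == 0) return(NULL)
    keep <- cand$duration >= config$fix_dur_ms[1] &
      cand$duration <= config$fix_dur_ms[2] &
      cand$saccade_duration < config$max_saccade_ms &
      cand$onset >= config$min_onset_ms &
      cand$saccade_onset <= trials$response_time_ms[i]
    bl <- ev$blinks
    if (!is.null(bl) && nrow(bl) > 0) {
      near_blink <- vapply(cand$saccade_onset, function(s)
        any(bl$onset < s + config$blink_margin_ms &
              bl$onset + bl$duration > s - config$blink_margin_ms),
        logical(1))
      keep <- keep & !near_blink
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    out <- data.frame(trial = i, onset = cand$onset,
                      duration = cand$duration,
                      saccade_onset = cand$saccade_onset,
                      saccade_duration = cand$saccade_duration,
                      saccade_amplitude_deg = cand$saccade_amplitude_deg,
                      category = trials$category[i])
    if (!is.null(trials$onset_ms))
      out$saccade_onset_session_ms <- trials$onset_ms[i] + cand$saccade_onset
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(trial = integer(0), onset = numeric(0),
                      duration = numeric(0), saccade_onset = numeric(0),
                      saccade_duration = numeric(0),
                      saccade_amplitude_deg = numeric(0),
                      category = character(0), size_class = character(0)))
  out$size_class <- classify_saccade_size(out$saccade_amplitude_deg,
                                          config$size_boundary_deg)
  rownames(out) <- NULL
  out
}

#' Classify saccade size
#'
#' Saccades below the boundary are short, the rest long; an amplitude of
#' exactly 4.0 degrees classifies as long.
#'
#' @param amplitude_deg Non-negative amplitudes, degrees.
#' @param boundary_deg Class boundary; default 4.
#' @return Character vector, `"short"` or `"long"`.
#' @export
classify_saccade_size <- function(amplitude_deg, boundary_deg = 4) {
  if (any(amplitude_deg < 0)) stop("saccade amplitude must be non-negative")
  ifelse(amplitude_deg < boundary_deg, "short", "long")
}

#' Mahalanobis trial matching
#'
#' Removes outlier fixations by Mahalanobis distance of their feature
#' vectors (default: saccade amplitude and fixation duration) to the
#' pooled mean and covariance; fixations whose squared distance exceeds
#' the empirical `percentile` quantile are dropped.
#'
#' @param valid_fixations Data.frame from [select_valid_fixations()].
#' @param features Character vector of feature column names.
#' @param percentile Removal percentile (default 95).
#' @return The retained subset, with a `mahalanobis_d2` column added and an
#'   attribute `removed` holding the number dropped.
#' @export
mahalanobis_match <- function(valid_fixations,
                              features = c("saccade_amplitude_deg", "duration"),
                              percentile = 95) {
  X <- as.matrix(valid_fixations[, features, drop = FALSE])
  if (nrow(X) < ncol(X) + 1)
    stop("need at least ", ncol(X) + 1, " fixations for matching")
  S <- stats::cov(X)
  if (abs(det(S)) < 1e-12) {
    sds <- apply(X, 2, stats::sd)
    flat <- features[sds < 1e-12]
    stop("singular feature covariance",
         if (length(flat)) paste0(" (degenerate feature(s): ",
                                  paste(flat, collapse = ", "), ")")
         else paste0(" (collinear features: ",
                     paste(features, collapse = ", "), ")"))
  }
  d2 <- stats::mahalanobis(X, colMeans(X), S)
  cut <- stats::quantile(d2, percentile / 100)
  keep <- d2 <= cut
  out <- valid_fixations[keep, , drop = FALSE]
  out$mahalanobis_d2 <- d2[keep]
  attr(out, "removed") <- sum(!keep)
  out
}
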