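#' Early/late search windows
#'
#' Visual search per stimulus is split at 5 s: early search spans stimulus
#' onset to 5 s, late search spans 5 s to the response. Windows are
#' half-open `[t0, t1)` in ms; the late window is empty when the response
#' precedes the boundary.
#'
#' @param response_time_ms Trial response time, ms (> 0).
#' @param boundary_ms Split point; default 5000 ms.
#' @return A list of numeric `c(t0, t1)` windows: `early`, `late`, `total`.
#' @export
bin_early_late <- function(response_time_ms, boundary_ms = 5000) {
  stopifnot(response_time_ms > 0)
  list(early = c(0, min(boundary_ms, response_time_ms)),
       late = c(min(boundary_ms, response_time_ms), response_time_ms),
       total = c(0, response_time_ms))
}

#' Visits (dwells) on an AOI
#'
#' A visit is the period from the first fixation inside an AOI until gaze
#' leaves it: consecutive in-AOI fixations and the saccades between them
#' form one visit; the saccade that exits the AOI is not part of the visit.
#' Visit duration is the span from the first in-AOI fixation's onset to the
#' last one's end.
#'
#' @param events Event lists (as from [detect_events()]); fixations must
#'   carry an `aoi` column of AOI indices (0 = none), as produced by
#'   [assign_events_to_aois()] or the generator.
#' @param aoi_index AOI index to compute visits for.
#' @return Data.frame of visits: `onset`, `duration`, `n_fixations`.
#' @export
compute_visits <- function(events, aoi_index) {
  fx <- events$fixations
  if (is.null(fx$aoi)) stop("fixations carry no AOI assignment")
  if (nrow(fx) == 0 || !any(fx$aoi == aoi_index))
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      n_fixations = integer(0)))
  fx <- fx[order(fx$onset), , drop = FALSE]
  inside <- fx$aoi == aoi_index
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- which(r$values)
  data.frame(
    onset = fx$onset[starts[keep]],
    duration = fx$onset[ends[keep]] + fx$duration[ends[keep]] -
      fx$onset[starts[keep]],
    n_fixations = r$lengths[keep])
}

#' Attach AOI labels to detected fixations
#'
#' Assigns each fixation centroid to an AOI by membership test; adds an
#' `aoi` column (index into `aois`, 0 when outside all).
#'
#' @param events Event lists from [detect_events()].
#' @param aois List of AOI objects for the stimulus.
#' @return The event lists with annotated fixations.
#' @export
assign_events_to_aois <- function(events, aois) {
  fx <- events$fixations
  fx$aoi <- if (nrow(fx) > 0) assign_aoi_index(fx$x, fx$y, aois) else integer(0)
  events$fixations <- fx
  events
}

#' AOI gaze metrics over a time window
#'
#' Computes the five NPT eye-tracking metrics per AOI: first fixation
#' duration (FFD, ms), total fixation duration (TFD, s), visit duration
#' (VD, s), fixation count (FC) and visit count (VC). Events straddling a
#' window edge contribute only their in-window portion to the duration
#' metrics but are counted once, in the window containing their onset, so
#' early + late counts and durations both reconcile with the whole trial.
#' FFD is `NA` (not 0) for an AOI never fixated in the window.
#'
#' @param events Event lists with AOI-annotated fixations (see
#'   [assign_events_to_aois()]).
#' @param aois List of AOI objects (defines the rows of the result).
#' @param window Numeric `c(t0, t1)`, half-open, ms.
#' @return Data.frame with one row per AOI: `aoi`, `label`, `ffd_ms`,
#'   `tfd_s`, `vd_s`, `fc`, `vc`.
#' @export
compute_metrics <- function(events, aois, window) {
  stopifnot(length(window) == 2)
  t0 <- window[1]; t1 <- window[2]
  fx <- events$fixations
  if (is.null(fx$aoi)) stop("fixations carry no AOI assignment")
  overlap <- function(onset, duration)
    pmax(0, pmin(onset + duration, t1) - pmax(onset, t0))
  in_by_onset <- function(onset) onset >= t0 & onset < t1

  rows <- lapply(seq_along(aois), function(i) {
    f <- fx[fx$aoi == i, , drop = FALSE]
    vis <- compute_visits(events, i)
    f_ov <- overlap(f$onset, f$duration)
    f_first <- which(f_ov > 0)[1]
    fc <- sum(in_by_onset(f$onset))
    data.frame(
      aoi = i, label = aois[[i]]$label,
      ffd_ms = if (is.na(f_first)) NA_real_ else f_ov[f_first],
      tfd_s = sum(f_ov) / 1000,
      vd_s = sum(overlap(vis$onset, vis$duration)) / 1000,
      fc = fc,
      vc = sum(in_by_onset(vis$onset)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-trial metrics table over early/late/total windows
#'
#' Convenience wrapper binding [compute_metrics()] rows for the three
#' standard windows of one trial.
#'
#' @inheritParams compute_metrics
#' @param response_time_ms Trial response time, ms.
#' @return Data.frame with a `window` column (`early`, `late`, `total`).
#' @export
trial_metrics <- function(events, aois, response_time_ms) {
  wins <- bin_early_late(response_time_ms)
  out <- do.call(rbind, lapply(names(wins), function(w) {
    m <- compute_metrics(events, aois, wins[[w]])
    if (nrow(m) > 0) m$window <- w
    m
  }))
  rownames(out) <- NULL
  out
}
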