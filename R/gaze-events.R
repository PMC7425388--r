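#' I-VT gaze event detection
#'
#' Velocity-threshold segmentation of a raw gaze stream. The angular
#' velocity of each inter-sample interval is computed from the pixel
#' displacement via [pixels_to_degrees()]; intervals below the threshold
#' accrue to fixations, intervals above to saccades. Runs of invalid
#' samples longer than `blink_min_ms` become blink events. Candidate
#' fixations shorter than `min_fixation_ms` are discarded.
#'
#' @param stream Data.frame with columns `t_ms`, `x_px`, `y_px`, `valid`
#'   (time non-decreasing).
#' @param velocity_threshold_deg_s I-VT threshold; default 30 deg/s.
#' @param min_fixation_ms Minimum fixation duration; default 60 ms.
#' @param geometry A [screen_geometry()].
#' @param blink_min_ms Invalid-gap length that counts as a blink; default
#'   50 ms.
#' @return A list of data.frames: `fixations` (`onset`, `duration`, `x`,
#'   `y` centroid), `saccades` (`onset`, `duration`, `amplitude_deg`),
#'   `blinks` (`onset`, `duration`). All durations ms.
#' @export
detect_events <- function(stream, velocity_threshold_deg_s = 30,
                          min_fixation_ms = 60,
                          geometry = screen_geometry(),
                          blink_min_ms = 50) {
  stopifnot(velocity_threshold_deg_s > 0, min_fixation_ms > 0)
  empty <- list(
    fixations = data.frame(onset = numeric(0), duration = numeric(0),
                           x = numeric(0), y = numeric(0)),
    saccades = data.frame(onset = numeric(0), duration = numeric(0),
                          amplitude_deg = numeric(0)),
    blinks = data.frame(onset = numeric(0), duration = numeric(0)))
  n <- nrow(stream)
  if (n == 0) return(empty)
  if (is.unsorted(stream$t_ms)) stop("stream must be time-ordered")

  valid <- stream$valid & !is.na(stream$x_px) & !is.na(stream$y_px)

  # Blinks: runs of invalid samples.
  blinks <- run_events(!valid, stream$t_ms)
  blinks <- blinks[blinks$duration >= blink_min_ms, , drop = FALSE]
  if (all(!valid)) {
    out <- empty
    out$blinks <- data.frame(onset = stream$t_ms[1],
                             duration = diff(range(stream$t_ms)))
    return(out)
  }

  # Per-interval angular velocity over consecutive valid samples.
  fx <- data.frame(onset = numeric(0), duration = numeric(0),
                   x = numeric(0), y = numeric(0))
  sc <- data.frame(onset = numeric(0), duration = numeric(0),
                   amplitude_deg = numeric(0))
  # split the stream at invalid gaps; segment each valid chunk separately
  chunk_id <- cumsum(c(TRUE, diff(valid) != 0))
  for (ch in split(seq_len(n)[valid], chunk_id[valid])) {
    if (length(ch) < 2) next
    t <- stream$t_ms[ch]; x <- stream$x_px[ch]; y <- stream$y_px[ch]
    dt <- diff(t)
    disp <- sqrt(diff(x)^2 + diff(y)^2)
    vel <- pixels_to_degrees(disp, geometry) / (dt / 1000)
    is_sac <- vel > velocity_threshold_deg_s
    runs <- rle(is_sac)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    for (r in seq_along(runs$values)) {
      i0 <- starts[r]; i1 <- ends[r]      # interval indices
      t0 <- t[i0]; t1 <- t[i1 + 1L]
      if (runs$values[r]) {
        amp <- pixels_to_degrees(
          sqrt((x[i1 + 1L] - x[i0])^2 + (y[i1 + 1L] - y[i0])^2), geometry)
        sc[nrow(sc) + 1L, ] <- c(t0, t1 - t0, amp)
      } else {
        if (t1 - t0 >= min_fixation_ms) {
          idx <- i0:(i1 + 1L)
          fx[nrow(fx) + 1L, ] <- c(t0, t1 - t0, mean(x[idx]), mean(y[idx]))
        }
      }
    }
  }
  list(fixations = fx, saccades = sc, blinks = blinks)
}

# Convert a logical run mask into (onset, duration) events on a time axis.
run_events <- function(mask, t_ms) {
  if (!any(mask)) return(data.frame(onset = numeric(0), duration = numeric(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- r$values
  n <- length(t_ms)
  data.frame(
    onset = t_ms[starts[keep]],
    duration = t_ms[pmin(ends[keep] + 1L, n)] - t_ms[starts[keep]])
}

#' Pair each fixation with its following saccade
#'
#' The presaccadic analysis is locked to the saccade that terminates a
#' fixation, so each fixation needs its follower. A saccade follows a
#' fixation when its onset falls within `tol_ms` of the fixation's end.
#'
#' @param events Event lists as returned by [detect_events()] (or the
#'   generator's ground truth).
#' @param tol_ms Matching tolerance between fixation end and saccade onset.
#' @return Data.frame with one row per fixation that has a follower:
#'   fixation `onset`, `duration`, centroid `x`, `y` (if present), plus
#'   `saccade_onset`, `saccade_duration`, `saccade_amplitude_deg`.
#' @export
pair_fixations_saccades <- function(events, tol_ms = 10) {
  fx <- events$fixations; sc <- events$saccades
  if (nrow(fx) == 0 || nrow(sc) == 0)
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      saccade_onset = numeric(0), saccade_duration = numeric(0),
                      saccade_amplitude_deg = numeric(0)))
  fend <- fx$onset + fx$duration
  j <- vapply(fend, function(e) {
    k <- which(sc$onset >= e - tol_ms & sc$onset <= e + tol_ms)
    if (length(k) == 0) NA_integer_ else k[1]
  }, integer(1))
  keep <- !is.na(j)
  out <- fx[keep, , drop = FALSE]
  out$saccade_onset <- sc$onset[j[keep]]
  out$saccade_duration <- sc$duration[j[keep]]
  out$saccade_amplitude_deg <- sc$amplitude_deg[j[keep]]
  rownames(out) <- NULL
  out
}
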