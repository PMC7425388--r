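#' Simulate a gaze stream for one trial
#'
#' Produces an alternating fixation/saccade event sequence over the trial's
#' viewing time plus the 120 Hz sample stream realising it, in stimulus
#' coordinates (700x700 px, origin top-left). Fixation targets are drawn
#' from the stimulus AOI centres (with within-AOI jitter) or from random
#' non-AOI locations; fixation durations follow the group profile; saccade
#' amplitudes are a mixture of short (< 4 deg) and long (>= 4 deg) moves
#' with amplitude-dependent durations; blinks arrive as a Poisson process
#' and blank the affected samples. The true event lists are returned
#' alongside the samples so detectors can be scored against ground truth.
#'
#' @param profile A [group_profile()].
#' @param stimulus One element of a [generate_stimulus_set()].
#' @param response_time_ms Trial viewing time, ms (> 0).
#' @param seed Integer RNG seed.
#' @param geometry A [screen_geometry()] for degree/pixel conversion.
#' @param sample_rate_hz Gaze sampling rate; default 120 Hz.
#' @param jitter_px SD of fixational position jitter; 0 gives a noise-free
#'   stream whose re-segmentation is exact.
#' @param canvas_px Stimulus area side, px.
#' @return A list with `samples` (data.frame `t_ms`, `x_px`, `y_px`,
#'   `valid`) and `truth` (list of data.frames `fixations`, `saccades`,
#'   `blinks`; fixations carry `aoi` — the AOI index or 0).
#' @export
simulate_gaze <- function(profile, stimulus, response_time_ms, seed = 1L,
                          geometry = screen_geometry(),
                          sample_rate_hz = 120, jitter_px = 1.5,
                          canvas_px = 700) {
  stopifnot(response_time_ms > 0)
  local_rng(seed)
  aois <- stimulus$aois
  aoi_pts <- t(vapply(aois, aoi_centre, numeric(2)))

  draw_target <- function(from) {
    long <- runif(1) < profile$long_saccade_prob
    amp_deg <- if (long) runif(1, 4.5, 12) else runif(1, 1, 3.5)
    amp_px <- degrees_to_pixels(amp_deg, geometry)
    # try to land on an AOI roughly amp_px away, else take a random direction
    if (length(aois) > 0 && runif(1) < 0.6) {
      d <- sqrt((aoi_pts[, 1] - from[1])^2 + (aoi_pts[, 2] - from[2])^2)
      ok <- which(abs(d - amp_px) < amp_px * 0.5 & d > 1)
      if (length(ok) > 0) {
        k <- ok[sample.int(length(ok), 1)]
        jit <- runif(2, -10, 10)
        to <- pmin(pmax(aoi_pts[k, ] + jit, 15), canvas_px - 15)
        return(to)
      }
    }
    for (i in 1:20) {
      th <- runif(1, 0, 2 * pi)
      to <- from + amp_px * c(cos(th), sin(th))
      if (all(to > 15) && all(to < canvas_px - 15)) return(to)
    }
    pmin(pmax(to, 15), canvas_px - 15)
  }

  draw_fix_dur <- function() {
    max(120, rnorm(1, profile$fixation_mean_ms, profile$fixation_sd_ms))
  }

  # Build alternating events until the response time is covered.
  fx <- list(); sc <- list()
  pos <- c(canvas_px / 2, canvas_px / 2)  # post fixation-cross start
  t <- 0
  repeat {
    dur <- draw_fix_dur()
    fx[[length(fx) + 1L]] <- c(onset = t, duration = dur, x = pos[1], y = pos[2])
    t <- t + dur
    if (t >= response_time_ms) break
    to <- draw_target(pos)
    amp_px <- sqrt(sum((to - pos)^2))
    amp_deg <- pixels_to_degrees(amp_px, geometry)
    sdur <- min(75, 18 + 2.2 * amp_deg)
    sc[[length(sc) + 1L]] <- c(onset = t, duration = sdur,
                               amplitude_deg = amp_deg,
                               x0 = pos[1], y0 = pos[2], x1 = to[1], y1 = to[2])
    t <- t + sdur
    pos <- to
    if (t >= response_time_ms - 150) {
      # not enough room for a scoreable fixation: close with one that
      # reaches the response exactly
      fx[[length(fx) + 1L]] <- c(onset = t,
                                 duration = max(1, response_time_ms - t),
                                 x = pos[1], y = pos[2])
      break
    }
  }
  fixations <- as.data.frame(do.call(rbind, fx))
  # truncate the final fixation at the response; if that leaves a fragment
  # too short to segment, fold it into the previous fixation so the truth
  # stays recoverable
  last <- nrow(fixations)
  fixations$duration[last] <- min(fixations$duration[last],
                                  response_time_ms - fixations$onset[last])
  if (last > 1 && fixations$duration[last] < 100) {
    fixations <- fixations[-last, , drop = FALSE]
    sc <- sc[seq_len(length(sc) - 1L)]
    last <- nrow(fixations)
    fixations$duration[last] <- response_time_ms - fixations$onset[last]
  }
  saccades <- if (length(sc) > 0) as.data.frame(do.call(rbind, sc)) else
    data.frame(onset = numeric(0), duration = numeric(0),
               amplitude_deg = numeric(0), x0 = numeric(0), y0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0))
  fixations$aoi <- assign_aoi_index(fixations$x, fixations$y, aois)

  # Blinks: Poisson over the trial, 150-250 ms each.
  n_blink <- rpois(1, profile$blink_rate_hz * response_time_ms / 1000)
  blinks <- if (n_blink > 0) {
    onset <- sort(runif(n_blink, 0, response_time_ms - 260))
    data.frame(onset = onset, duration = runif(n_blink, 150, 250))
  } else data.frame(onset = numeric(0), duration = numeric(0))

  # Realise the sample stream.
  dt <- 1000 / sample_rate_hz
  t_ms <- seq(0, response_time_ms, by = dt)
  x <- numeric(length(t_ms)); y <- numeric(length(t_ms))
  # position as a function of time: piecewise constant at fixations,
  # raised-cosine transition during saccades
  x[] <- fixations$x[1]; y[] <- fixations$y[1]
  for (i in seq_len(nrow(fixations))) {
    in_fix <- t_ms >= fixations$onset[i] &
      t_ms < fixations$onset[i] + fixations$duration[i]
    x[in_fix] <- fixations$x[i]; y[in_fix] <- fixations$y[i]
  }
  if (nrow(saccades) > 0) for (i in seq_len(nrow(saccades))) {
    s <- saccades[i, ]
    in_sac <- t_ms >= s$onset & t_ms < s$onset + s$duration
    if (any(in_sac)) {
      ph <- (t_ms[in_sac] - s$onset) / s$duration
      w <- (1 - cos(pi * ph)) / 2
      x[in_sac] <- s$x0 + w * (s$x1 - s$x0)
      y[in_sac] <- s$y0 + w * (s$y1 - s$y0)
    }
  }
  tail_mask <- t_ms >= fixations$onset[last]
  x[tail_mask] <- fixations$x[last]; y[tail_mask] <- fixations$y[last]
  if (jitter_px > 0) {
    # jitter only within fixations so saccade velocities stay clean
    in_sac_any <- rep(FALSE, length(t_ms))
    if (nrow(saccades) > 0) for (i in seq_len(nrow(saccades))) {
      s <- saccades[i, ]
      in_sac_any <- in_sac_any | (t_ms >= s$onset & t_ms < s$onset + s$duration)
    }
    x[!in_sac_any] <- x[!in_sac_any] + rnorm(sum(!in_sac_any), 0, jitter_px)
    y[!in_sac_any] <- y[!in_sac_any] + rnorm(sum(!in_sac_any), 0, jitter_px)
  }
  valid <- rep(TRUE, length(t_ms))
  if (nrow(blinks) > 0) for (i in seq_len(nrow(blinks))) {
    b <- blinks[i, ]
    valid[t_ms >= b$onset & t_ms < b$onset + b$duration] <- FALSE
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_

  list(samples = data.frame(t_ms = t_ms, x_px = x, y_px = y, valid = valid),
       truth = list(fixations = fixations, saccades = saccades,
                    blinks = blinks))
}

# Representative centre of an AOI (ellipse centre / polygon vertex mean).
aoi_centre <- function(a) {
  if (a$shape == "ellipse") c(a$cx, a$cy) else c(mean(a$x), mean(a$y))
}
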