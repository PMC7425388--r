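# Shared fixture builders; everything is generated in code.

# A small study configuration that runs in seconds.
tiny_sim_config <- function(seed = 1L, noise_sd = 0, n_images = 6,
                            subjects = c(HC = 1)) {
  profs <- default_group_profiles()[names(subjects)]
  for (g in names(profs)) profs[[g]]$response_median_s <- 6
  sim_config(n_images = n_images, n_face_images = max(1, n_images %/% 3),
             subjects = subjects, profiles = profs,
             eeg = eeg_params(noise_sd_uV = noise_sd, spike_amp_uV = 0),
             seed = seed)
}

# Deterministic gaze profile for exactness tests: no blinks, long fixations.
clean_profile <- function(fix_mean = 450, fix_sd = 30) {
  group_profile("X", hit_rate = 1, pareidolia_rate = 0,
                fixation_mean_ms = fix_mean, fixation_sd_ms = fix_sd,
                blink_rate_hz = 0)
}

# Build a synthetic eeg_epoch directly (channels x samples at 500 Hz over
# [-200, +50) ms).
make_epoch <- function(fill = 0, channels = unlist(electrode_montage(),
                                                   use.names = FALSE),
                       category = "Face", size_class = "short") {
  n <- 125
  data <- matrix(fill, length(channels), n)
  structure(list(data = data, times_ms = (seq_len(n) - 1 - 100) * 2,
                 channels = channels, srate_hz = 500,
                 category = category, size_class = size_class,
                 baseline_corrected = FALSE),
            class = "eeg_epoch")
}

# Linear presaccadic ramp waveform on the epoch time axis: 0 at -200 ms,
# `peak` at -20 ms, held to onset, decaying over [0, 50) ms.
ramp_wave <- function(times_ms, peak) {
  w <- numeric(length(times_ms))
  rise <- times_ms >= -200 & times_ms < -20
  w[rise] <- peak * (times_ms[rise] + 200) / 180
  w[times_ms >= -20 & times_ms < 0] <- peak
  fall <- times_ms >= 0 & times_ms < 50
  w[fall] <- peak * (1 - times_ms[fall] / 50)
  w
}

# Independent point-in-polygon oracle: winding number (different algorithm
# from the package's even-odd ray casting).
winding_inside <- function(px, py, vx, vy) {
  n <- length(vx)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (vy[i] <= py) {
      if (vy[j] > py &&
          ((vx[j] - vx[i]) * (py - vy[i]) -
             (px - vx[i]) * (vy[j] - vy[i])) > 0) wn <- wn + 1
    } else {
      if (vy[j] <= py &&
          ((vx[j] - vx[i]) * (py - vy[i]) -
             (px - vx[i]) * (vy[j] - vy[i])) < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# Distance from a point to a polygon boundary (for excluding boundary-
# adjacent points from oracle comparisons).
polygon_boundary_dist <- function(px, py, vx, vy) {
  n <- length(vx)
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- vx[i]; ay <- vy[i]; bx <- vx[j]; by <- vy[j]
    t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
      ((bx - ax)^2 + (by - ay)^2)
    t <- min(max(t, 0), 1)
    d <- sqrt((px - (ax + t * (bx - ax)))^2 + (py - (ay + t * (by - ay)))^2)
    dmin <- min(dmin, d)
  }
  dmin
}
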