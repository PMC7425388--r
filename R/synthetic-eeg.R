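#' Default electrode montage
#'
#' The ten analysed channels: five frontal (F3, Fz, F4, FC1, FC2) and five
#' parietal (P3, Pz, P4, PO3, PO4).
#'
#' @return Named list with `frontal` and `parietal` label vectors.
#' @export
electrode_montage <- function() {
  list(frontal = c("F3", "Fz", "F4", "FC1", "FC2"),
       parietal = c("P3", "Pz", "P4", "PO3", "PO4"))
}

#' EEG generator parameters
#'
#' @param srate_hz Sampling rate; default 500 Hz (the analysis rate).
#' @param channels Channel labels; default the ten-channel montage.
#' @param noise_sd_uV SD of the 1/f background noise per channel, µV.
#' @param pink_exponent Spectral exponent of the background (power ~
#'   1/f^exponent); default 1.
#' @param spike_amp_uV Peak of the spike potential at saccade onset, µV.
#' @param blink_amp_uV Peak of the half-cosine blink artefact, µV
#'   (default 150, comfortably beyond the 80 µV rejection threshold).
#' @param blink_dur_ms Blink artefact duration; default 200 ms.
#' @return List of class `eeg_params`.
#' @export
eeg_params <- function(srate_hz = 500,
                       channels = unlist(electrode_montage(), use.names = FALSE),
                       noise_sd_uV = 5, pink_exponent = 1,
                       spike_amp_uV = 5, blink_amp_uV = 150,
                       blink_dur_ms = 200) {
  stopifnot(srate_hz > 0, noise_sd_uV >= 0)
  structure(list(srate_hz = srate_hz, channels = channels,
                 noise_sd_uV = noise_sd_uV, pink_exponent = pink_exponent,
                 spike_amp_uV = spike_amp_uV, blink_amp_uV = blink_amp_uV,
                 blink_dur_ms = blink_dur_ms),
            class = "eeg_params")
}

#' Simulate a saccade-locked EEG recording
#'
#' Builds `signal = 1/f background + presaccadic ramps + spike potentials +
#' blink artefacts`. Each saccade contributes a linear ramp on its target
#' channels rising from 0 at -200 ms to a peak at -20 ms before onset,
#' holding the peak until onset and decaying back to 0 over the following
#' 50 ms, plus a brief Gaussian spike at onset on all channels. Blinks add
#' a half-cosine deflection on the frontal channels.
#'
#' The `amp_uV` column parameterises the *measured* presaccadic amplitude:
#' the baseline-corrected mean over the standard analysis window
#' (\[-100, -20) ms re-baselined on \[-200, -170) ms). For the linear ramp
#' that mean is 25/36 of the -20 ms peak, so the generator scales the peak
#' to 36/25 x `amp_uV` and the pipeline recovers `amp_uV` exactly at noise
#' SD 0.
#'
#' @param saccades Data.frame with `onset_ms` (session clock), `amp_uV`
#'   (target measured amplitude) and `group` (`"frontal"`, `"parietal"`,
#'   `"both"`, or a channel label). One ramp per row.
#' @param params An [eeg_params()].
#' @param duration_ms Recording length, ms; must cover all events.
#' @param blinks Optional data.frame with `onset_ms` of blink artefacts.
#' @param seed Integer RNG seed.
#' @param start_ms Recording start on the session clock.
#' @return An [eeg_recording()].
#' @export
simulate_eeg <- function(saccades, params = eeg_params(), duration_ms,
                         blinks = NULL, seed = 1L, start_ms = 0) {
  stopifnot(inherits(params, "eeg_params"))
  local_rng(seed)
  fs <- params$srate_hz
  n <- as.integer(round(duration_ms / 1000 * fs))
  chans <- params$channels
  nc <- length(chans)
  if (nrow(saccades) > 0 &&
      (any(saccades$onset_ms < start_ms) ||
       any(saccades$onset_ms > start_ms + duration_ms)))
    stop("saccade onsets must fall inside the recording")
  montage <- electrode_montage()

  data <- matrix(0, nc, n)
  if (params$noise_sd_uV > 0)
    for (c in seq_len(nc))
      data[c, ] <- pink_noise(n, params$pink_exponent) * params$noise_sd_uV

  t_ms <- start_ms + (seq_len(n) - 1L) * 1000 / fs

  resolve_channels <- function(g) {
    idx <- switch(g,
      frontal = match(montage$frontal, chans),
      parietal = match(montage$parietal, chans),
      both = match(c(montage$frontal, montage$parietal), chans),
      match(g, chans))
    if (anyNA(idx)) stop("effect targets unknown channel label in group '",
                         g, "'")
    idx
  }

  # operate on each event's local sample window only
  local_window <- function(t_lo, t_hi) {
    lo <- max(1L, as.integer(floor((t_lo - start_ms) / 1000 * fs)) - 1L)
    hi <- min(n, as.integer(ceiling((t_hi - start_ms) / 1000 * fs)) + 2L)
    if (lo > hi) integer(0) else lo:hi
  }

  if (nrow(saccades) > 0) for (i in seq_len(nrow(saccades))) {
    t0 <- saccades$onset_ms[i]
    amp <- saccades$amp_uV[i]
    if (amp != 0) {
      peak <- amp * 36 / 25
      idx <- resolve_channels(saccades$group[i])
      w <- local_window(t0 - 200, t0 + 50)
      rel <- t_ms[w] - t0
      ramp <- numeric(length(w))
      rise <- rel >= -200 & rel < -20
      ramp[rise] <- peak * (rel[rise] + 200) / 180
      ramp[rel >= -20 & rel < 0] <- peak
      fall <- rel >= 0 & rel < 50
      ramp[fall] <- peak * (1 - rel[fall] / 50)
      data[idx, w] <- data[idx, w, drop = FALSE] +
        rep(ramp, each = length(idx))
    }
    if (params$spike_amp_uV != 0) {
      w <- local_window(t0 - 25, t0 + 25)
      rel <- t_ms[w] - t0
      spk <- params$spike_amp_uV * exp(-rel^2 / (2 * 4^2))
      data[, w] <- data[, w, drop = FALSE] + rep(spk, each = nc)
    }
  }

  if (!is.null(blinks) && nrow(blinks) > 0) {
    fidx <- match(montage$frontal, chans)
    fidx <- fidx[!is.na(fidx)]
    for (i in seq_len(nrow(blinks))) {
      t0 <- blinks$onset_ms[i]
      w <- local_window(t0, t0 + params$blink_dur_ms)
      rel <- t_ms[w] - t0
      wav <- numeric(length(w))
      inb <- rel >= 0 & rel < params$blink_dur_ms
      wav[inb] <- params$blink_amp_uV *
        (1 - cos(2 * pi * rel[inb] / params$blink_dur_ms)) / 2
      data[fidx, w] <- data[fidx, w, drop = FALSE] +
        rep(wav, each = length(fidx))
    }
  }

  eeg_recording(data, chans, fs, start_ms)
}

# 1/f^a noise via spectral shaping of white Gaussian noise, rescaled to
# unit SD. a = 0 gives white noise.
pink_noise <- function(n, exponent = 1) {
  if (n < 2) return(rnorm(n))
  w <- rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n - 1)
  f <- c(1, pmin(k, n - k))          # symmetric magnitude; DC kept at 1
  W <- W / f^(exponent / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}
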