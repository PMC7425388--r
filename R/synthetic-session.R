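#' Presaccadic effect specification
#'
#' One target measured amplitude (µV; see [simulate_eeg()] for the
#' parameterisation) per subject group x response category x electrode
#' group. The defaults mirror the qualitative pattern of the study
#' conditions: positive parietal activity for faces and pareidolias,
#' negative parietal activity for noise (strongest in controls), and a
#' frontal pareidolia effect that separates pareidolic (+1.0 µV) from
#' non-pareidolic (-0.3 µV) patients.
#'
#' @return Data.frame with columns `group`, `category`, `electrode_group`,
#'   `amp_uV`.
#' @export
default_effect_spec <- function() {
  grid <- expand.grid(group = c("HC", "PDnP", "PDP"),
                      category = c("Face", "Noise", "Pareidolia", "Missed"),
                      electrode_group = c("frontal", "parietal"),
                      stringsAsFactors = FALSE)
  grid$amp_uV <- 0
  set_amp <- function(g, cat, eg, v)
    grid$amp_uV[grid$group == g & grid$category == cat &
                  grid$electrode_group == eg] <<- v
  for (g in c("HC", "PDnP", "PDP")) set_amp(g, "Face", "parietal", 0.6)
  set_amp("HC", "Noise", "parietal", -0.93)
  set_amp("PDnP", "Noise", "parietal", -0.41)
  set_amp("PDP", "Noise", "parietal", -0.38)
  set_amp("PDnP", "Pareidolia", "frontal", -0.3)
  set_amp("PDP", "Pareidolia", "frontal", 1.0)
  set_amp("PDnP", "Pareidolia", "parietal", 0.3)
  set_amp("PDP", "Pareidolia", "parietal", 0.3)
  grid
}

#' Simulation configuration for a synthetic NPT study
#'
#' Collects every constant of the emulated experiment: 80 stimuli of which
#' 20 carry an embedded face, a 2-s inter-trial fixation cross, 120 Hz gaze
#' sampling, the group roster with response and dwell behaviour, the EEG
#' generator parameters and the presaccadic effect specification.
#'
#' @param n_images,n_face_images Stimulus counts (defaults 80 / 20).
#' @param subjects Named integer vector: subjects per group (defaults
#'   `c(HC = 12, PDnP = 11, PDP = 10)`).
#' @param profiles Named list of [group_profile()]s, one per group.
#' @param effect_spec Data.frame as [default_effect_spec()].
#' @param eeg An [eeg_params()].
#' @param geometry A [screen_geometry()].
#' @param gaze_rate_hz Gaze sampling rate (default 120).
#' @param intertrial_ms Fixation-cross interval between stimuli (2000 ms).
#' @param seed Master seed; all per-subject/per-trial seeds derive from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_images = 80, n_face_images = 20,
                       subjects = c(HC = 12, PDnP = 11, PDP = 10),
                       profiles = default_group_profiles(),
                       effect_spec = default_effect_spec(),
                       eeg = eeg_params(),
                       geometry = screen_geometry(),
                       gaze_rate_hz = 120,
                       intertrial_ms = 2000,
                       seed = 1L) {
  stopifnot(n_face_images <= n_images, n_images >= 0,
            all(names(subjects) %in% names(profiles)))
  structure(list(n_images = n_images, n_face_images = n_face_images,
                 subjects = subjects, profiles = profiles,
                 effect_spec = effect_spec, eeg = eeg,
                 geometry = geometry, gaze_rate_hz = gaze_rate_hz,
                 intertrial_ms = intertrial_ms, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one subject's full NPT session
#'
#' Chains the generators: responses for every stimulus, a gaze stream per
#' trial laid out on a session clock (2-s fixation cross between trials),
#' and one continuous EEG recording containing the configured presaccadic
#' ramps for every ground-truth saccade, spike potentials, blink artefacts
#' and 1/f background.
#'
#' @param subject_id Subject identifier string.
#' @param group Group label (must exist in the config's profiles).
#' @param stimulus_set A [generate_stimulus_set()] result.
#' @param config A [sim_config()].
#' @param seed Integer seed for this subject.
#' @return A list: `trials` (trial records with `onset_ms`), `gaze` (list
#'   per trial from [simulate_gaze()]), `eeg` (an [eeg_recording()]),
#'   `truth` (session-clock event lists and per-saccade configured
#'   amplitudes).
#' @export
simulate_session <- function(subject_id, group, stimulus_set, config,
                             seed = 1L) {
  stopifnot(inherits(config, "sim_config"), group %in% names(config$profiles))
  profile <- config$profiles[[group]]
  trials <- simulate_responses(profile, stimulus_set, seed = child_seed(seed, 1))

  onset <- config$intertrial_ms
  gaze <- vector("list", nrow(trials))
  sacc_rows <- list(); blink_rows <- list(); fix_rows <- list()
  for (i in seq_len(nrow(trials))) {
    trials$onset_ms[i] <- onset
    g <- simulate_gaze(profile, stimulus_set[[i]], trials$response_time_ms[i],
                       seed = child_seed(seed, 100 + i),
                       geometry = config$geometry,
                       sample_rate_hz = config$gaze_rate_hz)
    gaze[[i]] <- g
    tr <- g$truth
    if (nrow(tr$saccades) > 0) {
      s <- tr$saccades
      s$onset_ms <- round_to_sample(onset + s$onset, config$eeg$srate_hz)
      s$trial <- i
      s$category <- trials$category[i]
      sacc_rows[[length(sacc_rows) + 1L]] <- s
    }
    if (nrow(tr$blinks) > 0) {
      b <- tr$blinks
      b$onset_ms <- onset + b$onset
      b$trial <- i
      blink_rows[[length(blink_rows) + 1L]] <- b
    }
    f <- tr$fixations
    f$onset_ms <- onset + f$onset
    f$trial <- i
    fix_rows[[length(fix_rows) + 1L]] <- f
    onset <- onset + trials$response_time_ms[i] + config$intertrial_ms
  }
  duration_ms <- onset + 1000

  saccades <- if (length(sacc_rows)) do.call(rbind, sacc_rows) else NULL
  blinks <- if (length(blink_rows)) do.call(rbind, blink_rows) else
    data.frame(onset_ms = numeric(0))
  fixations <- do.call(rbind, fix_rows)

  # per-saccade ramps: one row per electrode group with a nonzero target
  ramps <- data.frame(onset_ms = numeric(0), amp_uV = numeric(0),
                      group = character(0))
  if (!is.null(saccades)) {
    for (eg in c("frontal", "parietal")) {
      amp <- effect_amplitude(config$effect_spec, group, saccades$category, eg)
      keep <- amp != 0
      if (any(keep))
        ramps <- rbind(ramps, data.frame(onset_ms = saccades$onset_ms[keep],
                                         amp_uV = amp[keep], group = eg))
    }
  }
  eeg <- simulate_eeg(ramps, config$eeg, duration_ms = duration_ms,
                      blinks = data.frame(onset_ms = blinks$onset_ms),
                      seed = child_seed(seed, 2))

  list(subject = subject_id, group = group, trials = trials, gaze = gaze,
       eeg = eeg,
       truth = list(saccades = saccades, blinks = blinks,
                    fixations = fixations, ramps = ramps))
}

# Look up the configured amplitude for (group, category, electrode group).
effect_amplitude <- function(spec, group, category, electrode_group) {
  key <- paste(spec$group, spec$category, spec$electrode_group)
  amp <- spec$amp_uV[match(paste(group, category, electrode_group), key)]
  amp[is.na(amp)] <- 0
  amp
}

# Align an event time to the EEG sample grid so noise-free recovery is
# exact to float tolerance.
round_to_sample <- function(t_ms, srate_hz) {
  round(t_ms * srate_hz / 1000) * 1000 / srate_hz
}

#' Simulate a whole multi-group study
#'
#' One shared stimulus set; one session per subject, with per-subject seeds
#' derived from the master seed. Subjects are labelled `HC01`, `PDnP01`, ...
#'
#' @param config A [sim_config()].
#' @return List with `stimuli` and `sessions` (list of
#'   [simulate_session()] results).
#' @export
simulate_study <- function(config = sim_config()) {
  stimuli <- generate_stimulus_set(config$n_images, config$n_face_images,
                                   seed = child_seed(config$seed, 0))
  sessions <- list()
  sidx <- 0L
  for (g in names(config$subjects)) {
    for (k in seq_len(config$subjects[[g]])) {
      sidx <- sidx + 1L
      id <- sprintf("%s%02d", g, k)
      sessions[[id]] <- simulate_session(id, g, stimuli, config,
                                         seed = child_seed(config$seed, sidx))
    }
  }
  list(stimuli = stimuli, sessions = sessions)
}

#' Write a session to the pipeline's interchange formats
#'
#' Gaze TSV per trial (`t_ms`, `x_px`, `y_px`, `valid`), trial-metadata
#' CSV, headered EEG CSV, AOI JSON for the stimulus set and a ground-truth
#' JSON sidecar.
#'
#' @param session A [simulate_session()] result.
#' @param stimulus_set The study's [generate_stimulus_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_session <- function(session, stimulus_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (i in seq_along(session$gaze)) {
    p <- file.path(dir, sprintf("gaze_%03d.tsv", i))
    utils::write.table(session$gaze[[i]]$samples, p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths[sprintf("gaze_%03d", i)] <- p
  }
  p <- file.path(dir, "trials.csv")
  utils::write.csv(session$trials, p, row.names = FALSE)
  paths["trials"] <- p
  p <- file.path(dir, "eeg.csv")
  write_eeg_csv(session$eeg, p)
  paths["eeg"] <- p
  p <- file.path(dir, "aois.json")
  write_aoi_json(stimulus_set, p)
  paths["aois"] <- p
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(subject = session$subject, group = session$group,
         saccades = session$truth$saccades, blinks = session$truth$blinks,
         ramps = session$truth$ramps),
    p, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  paths["truth"] <- p
  invisible(paths)
}
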