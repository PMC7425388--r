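#' Extract saccade-onset-locked epochs
#'
#' Cuts one epoch per valid fixation out of the continuous recording,
#' time-locked to the following saccade's onset (t = 0). Samples are taken
#' over the half-open epoch window at the recording rate — 125 samples over
#' \[-200, +50) ms at 500 Hz. Epochs exceeding the recording bounds are
#' skipped; the skipped count is attached as an attribute.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param valid_fixations Data.frame from [select_valid_fixations()] (after
#'   [mahalanobis_match()]); must carry `saccade_onset_session_ms` or, for
#'   single-trial use, `saccade_onset` interpreted on the recording clock.
#' @param config An [epoch_config()].
#' @return List of `eeg_epoch` objects (fields `data` channels x samples,
#'   `times_ms`, `channels`, `srate_hz`, `category`, `size_class`,
#'   `baseline_corrected`), with attribute `skipped`.
#' @export
extract_epochs <- function(rec, valid_fixations, config = epoch_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$srate_hz
  pre <- round(-config$epoch_ms[1] * fs / 1000)
  post <- round(config$epoch_ms[2] * fs / 1000)
  n_samp <- pre + post
  times <- (seq_len(n_samp) - 1L - pre) * 1000 / fs
  onset_col <- if (!is.null(valid_fixations$saccade_onset_session_ms))
    valid_fixations$saccade_onset_session_ms else valid_fixations$saccade_onset

  epochs <- list()
  skipped <- 0L
  for (i in seq_len(nrow(valid_fixations))) {
    i0 <- round((onset_col[i] - rec$start_ms) * fs / 1000) + 1L
    idx <- (i0 - pre):(i0 + post - 1L)
    if (idx[1] < 1L || idx[length(idx)] > ncol(rec$data)) {
      skipped <- skipped + 1L
      next
    }
    epochs[[length(epochs) + 1L]] <- structure(
      list(data = rec$data[, idx, drop = FALSE], times_ms = times,
           channels = rec$channels, srate_hz = fs,
           category = valid_fixations$category[i],
           size_class = valid_fixations$size_class[i],
           trial = valid_fixations$trial[i],
           baseline_corrected = FALSE),
      class = "eeg_epoch")
  }
  if (skipped > 0)
    message(skipped, " epoch(s) skipped: outside recording bounds")
  attr(epochs, "skipped") <- skipped
  epochs
}

#' Amplitude-based artefact rejection
#'
#' Drops every epoch containing any sample whose absolute value exceeds
#' the threshold on the analysed channels. Must run before baseline
#' correction (the threshold refers to raw conditioned amplitudes).
#'
#' @param epochs List of `eeg_epoch`s.
#' @param threshold_uV Rejection threshold; default 80 µV.
#' @param channels Channel labels to screen; default all channels present.
#' @return Surviving epochs, with attribute `rejected`.
#' @export
reject_artifacts <- function(epochs, threshold_uV = 80, channels = NULL) {
  keep <- vapply(epochs, function(ep) {
    if (ep$baseline_corrected)
      stop("artefact rejection must precede baseline correction")
    rows <- if (is.null(channels)) seq_along(ep$channels)
      else match(channels, ep$channels)
    if (anyNA(rows)) stop("unknown channel label in rejection set")
    max(abs(ep$data[rows, , drop = FALSE])) <= threshold_uV
  }, logical(1))
  out <- epochs[keep]
  attr(out, "rejected") <- sum(!keep)
  out
}

#' Baseline-correct an epoch
#'
#' Subtracts each channel's mean over the baseline window; afterwards the
#' baseline-window mean is zero per channel (to float precision).
#'
#' @param epoch An `eeg_epoch`.
#' @param window_ms Baseline window, half-open, ms; default \[-200, -170).
#' @return The corrected epoch (`baseline_corrected = TRUE`).
#' @export
baseline_correct <- function(epoch, window_ms = c(-200, -170)) {
  sel <- epoch$times_ms >= window_ms[1] & epoch$times_ms < window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  epoch$data <- epoch$data - rowMeans(epoch$data[, sel, drop = FALSE])
  epoch$baseline_corrected <- TRUE
  epoch
}

#' Mean presaccadic amplitude of an epoch
#'
#' Mean over the amplitude-window samples, averaged across an electrode
#' group's channels. The epoch must already be baseline-corrected.
#'
#' @param epoch A baseline-corrected `eeg_epoch`.
#' @param group `"frontal"`, `"parietal"`, or a character vector of labels.
#' @param window_ms Amplitude window, half-open, ms; default \[-100, -20).
#' @return Mean amplitude, µV.
#' @export
mean_amplitude <- function(epoch, group = "frontal",
                           window_ms = c(-100, -20)) {
  if (!isTRUE(epoch$baseline_corrected))
    stop("epoch must be baseline-corrected before amplitude measurement")
  labels <- if (length(group) == 1 && group %in% names(electrode_montage()))
    electrode_montage()[[group]] else group
  rows <- match(labels, epoch$channels)
  if (anyNA(rows))
    stop("electrode group channel(s) missing from epoch: ",
         paste(labels[is.na(rows)], collapse = ", "))
  sel <- epoch$times_ms >= window_ms[1] & epoch$times_ms < window_ms[2]
  mean(epoch$data[rows, sel, drop = FALSE])
}

#' Equalise trial counts across response categories
#'
#' Within a subject, categories with fewer than `min_trials` epochs are
#' excluded; the remaining categories are subsampled without replacement
#' (seeded) to the smallest remaining count, so every compared category
#' contributes the same number of trials.
#'
#' @param epochs_by_category Named list of epoch lists, one per category.
#' @param min_trials Minimum epochs for a category to enter; default 50.
#' @param seed Integer RNG seed for the subsampling.
#' @return Named list of equalised epoch lists (categories below the
#'   minimum dropped), with attribute `excluded` naming them.
#' @export
match_trial_counts <- function(epochs_by_category, min_trials = 50,
                               seed = 1L) {
  counts <- vapply(epochs_by_category, length, integer(1))
  keep <- counts >= min_trials
  excluded <- names(counts)[!keep]
  kept <- epochs_by_category[keep]
  if (length(kept) > 0) {
    local_rng(seed)
    m <- min(vapply(kept, length, integer(1)))
    kept <- lapply(kept, function(eps) {
      if (length(eps) == m) eps else eps[sort(sample.int(length(eps), m))]
    })
  }
  attr(kept, "excluded") <- excluded
  kept
}

#' Grand-average epochs
#'
#' Pointwise mean across epochs per channel. The average's measured
#' amplitude equals the mean of the per-epoch amplitudes (linearity), which
#' is asserted when the inputs are baseline-corrected.
#'
#' @param epochs Non-empty list of `eeg_epoch`s with identical layout.
#' @return An `eeg_epoch` holding the average, with field `n_epochs`.
#' @export
grand_average <- function(epochs) {
  if (length(epochs) == 0) stop("cannot average zero epochs")
  avg <- epochs[[1]]
  acc <- Reduce(`+`, lapply(epochs, `[[`, "data"))
  avg$data <- acc / length(epochs)
  avg$n_epochs <- length(epochs)
  if (isTRUE(avg$baseline_corrected)) {
    a_avg <- mean_amplitude(avg, group = avg$channels)
    a_each <- mean(vapply(epochs, mean_amplitude, numeric(1),
                          group = epochs[[1]]$channels))
    stopifnot(abs(a_avg - a_each) < 1e-9)
  }
  avg
}

#' Per-subject amplitude table
#'
#' Runs the epoch-level tail of the pipeline for one subject's epochs:
#' artefact rejection, trial-count matching across categories, baseline
#' correction, then mean presaccadic amplitude per response category x
#' saccade-size class x electrode group.
#'
#' @param epochs List of `eeg_epoch`s for one subject (pre-baseline).
#' @param config An [epoch_config()].
#' @param seed Seed for trial-count matching.
#' @param subject Optional subject id carried into the rows.
#' @param match_counts Equalise counts across categories (default TRUE).
#' @return Data.frame: `subject`, `category`, `size_class`,
#'   `electrode_group`, `amp_uV`, `n_trials`.
#' @export
amplitude_table <- function(epochs, config = epoch_config(), seed = 1L,
                            subject = NA_character_, match_counts = TRUE) {
  epochs <- reject_artifacts(epochs, config$reject_uV)
  cats <- split(epochs, vapply(epochs, `[[`, character(1), "category"))
  if (match_counts)
    cats <- match_trial_counts(cats, config$min_trials, seed)
  rows <- list()
  for (cat in names(cats)) {
    eps <- lapply(cats[[cat]], baseline_correct, window_ms = config$baseline_ms)
    sizes <- vapply(eps, `[[`, character(1), "size_class")
    for (sz in unique(sizes)) {
      sub <- eps[sizes == sz]
      for (eg in c("frontal", "parietal")) {
        amps <- vapply(sub, mean_amplitude, numeric(1), group = eg,
                       window_ms = config$amplitude_ms)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject, category = cat, size_class = sz,
          electrode_group = eg, amp_uV = mean(amps),
          n_trials = length(amps))
      }
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(subject = character(0), category = character(0),
               size_class = character(0), electrode_group = character(0),
               amp_uV = numeric(0), n_trials = integer(0))
  rownames(out) <- NULL
  out
}

#' End-to-end presaccadic analysis of one synthetic session
#'
#' Convenience driver: selects valid fixations (from the session's ground
#' truth or re-detected events), applies Mahalanobis matching per subject,
#' extracts epochs from the session EEG and builds the amplitude table.
#'
#' @param session A [simulate_session()] result.
#' @param config An [epoch_config()].
#' @param use_truth Use ground-truth events (TRUE) or re-detect from the
#'   gaze samples.
#' @param geometry Screen geometry for re-detection.
#' @param seed Seed for trial-count matching.
#' @return List: `valid` (fixations), `epochs`, `table` (amplitude rows).
#' @export
session_frp <- function(session, config = epoch_config(), use_truth = TRUE,
                        geometry = screen_geometry(), seed = 1L) {
  events <- lapply(session$gaze, function(g) {
    if (use_truth) g$truth
    else detect_events(g$samples, geometry = geometry)
  })
  valid <- select_valid_fixations(events, session$trials, config)
  if (nrow(valid) > 3)
    valid <- mahalanobis_match(valid,
                               percentile = config$mahalanobis_percentile)
  epochs <- extract_epochs(session$eeg, valid, config)
  tab <- amplitude_table(epochs, config, seed = seed,
                         subject = session$subject)
  tab$group <- session$group
  list(valid = valid, epochs = epochs, table = tab)
}
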