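#' Gaze metrics for one session
#'
#' Re-detects events from each trial's raw samples, assigns fixations to
#' the stimulus AOIs and computes the five metrics over the early, late and
#' total windows.
#'
#' @param session A [simulate_session()] result (or an equivalent loaded
#'   session with `gaze`, `trials`, `subject`).
#' @param stimuli The study's stimulus set.
#' @param geometry A [screen_geometry()].
#' @param use_truth Use ground-truth events instead of re-detection.
#' @return Data.frame: `subject`, `trial`, `category`, `window`, `aoi`,
#'   `label`, `ffd_ms`, `tfd_s`, `vd_s`, `fc`, `vc`.
#' @export
session_metrics <- function(session, stimuli, geometry = screen_geometry(),
                            use_truth = FALSE) {
  rows <- lapply(seq_along(session$gaze), function(i) {
    ev <- if (use_truth) session$gaze[[i]]$truth
      else assign_events_to_aois(
        detect_events(session$gaze[[i]]$samples, geometry = geometry),
        stimuli[[i]]$aois)
    m <- trial_metrics(ev, stimuli[[i]]$aois,
                       session$trials$response_time_ms[i])
    if (nrow(m) == 0) return(NULL)
    cbind(data.frame(subject = session$subject, trial = i,
                     category = session$trials$category[i]), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate metrics for the repeated-measures analysis
#'
#' One mean value per subject x response category x window x metric,
#' averaging across trials and AOIs (target AOIs for face/missed trials,
#' noise AOIs otherwise — the AOI type the response refers to).
#'
#' @param metrics Output of [session_metrics()] (rows for several
#'   subjects), with a `group` column attached.
#' @param variables Metric columns to keep as the within-subject factor.
#' @return Long data.frame: `subject`, `group`, `category`, `window`,
#'   `variable`, `value`.
#' @export
aggregate_metrics <- function(metrics,
                              variables = c("ffd_ms", "tfd_s", "vd_s",
                                            "fc", "vc")) {
  rel <- ifelse(metrics$category %in% c("Face", "Missed"),
                "target", "noise")
  metrics <- metrics[metrics$label == rel, , drop = FALSE]
  rows <- list()
  for (v in variables) {
    agg <- stats::aggregate(metrics[[v]],
                            by = list(subject = metrics$subject,
                                      group = metrics$group,
                                      category = metrics$category,
                                      window = metrics$window),
                            FUN = function(x) mean(x, na.rm = TRUE))
    agg$variable <- v
    names(agg)[names(agg) == "x"] <- "value"
    rows[[v]] <- agg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[!is.nan(out$value), , drop = FALSE]
}

#' Score all sessions of a study
#'
#' @param study A [simulate_study()] result.
#' @param variance_ratio_s Passed to [score_subject()].
#' @return Data.frame, one row per subject: counts, rates, d-prime, the
#'   simulated group and the dichotomised patient type.
#' @export
score_sessions <- function(study, variance_ratio_s = 1) {
  rows <- lapply(study$sessions, function(s) {
    sc <- score_subject(s$trials, variance_ratio_s)
    data.frame(subject = s$subject, group = s$group,
               n_face = sc$counts[["Face"]], n_missed = sc$counts[["Missed"]],
               n_pareidolia = sc$counts[["Pareidolia"]],
               n_noise = sc$counts[["Noise"]],
               hit_rate = sc$hit_rate, fa_rate = sc$fa_rate,
               d_prime = sc$d_prime)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate session input files
#'
#' Schema and consistency checks on a session directory written by
#' [write_session()] (or assembled externally): gaze TSVs have the four
#' columns with non-decreasing timestamps, the trial CSV has the required
#' fields, the AOI JSON parses, and the EEG recording covers every trial's
#' window.
#'
#' @param dir Session directory.
#' @return Data.frame report: `file`, `check`, `ok`, `detail`. All-ok
#'   reports have `all(report$ok)`.
#' @export
validate_inputs <- function(dir) {
  rep <- list()
  add <- function(file, check, ok, detail = "")
    rep[[length(rep) + 1L]] <<- data.frame(file = file, check = check,
                                           ok = ok, detail = detail)
  gaze_files <- sort(list.files(dir, "^gaze_.*\\.tsv$", full.names = TRUE))
  add(dir, "gaze files present", length(gaze_files) > 0,
      paste(length(gaze_files), "file(s)"))
  for (gf in gaze_files) {
    g <- tryCatch(utils::read.delim(gf), error = function(e) NULL)
    if (is.null(g)) { add(basename(gf), "parses", FALSE, "read error"); next }
    need <- c("t_ms", "x_px", "y_px", "valid")
    okc <- all(need %in% names(g))
    add(basename(gf), "columns", okc,
        if (!okc) paste("missing:", paste(setdiff(need, names(g)),
                                          collapse = ", ")) else "")
    if (okc) {
      bad <- which(diff(g$t_ms) < 0)
      add(basename(gf), "timestamps non-decreasing", length(bad) == 0,
          if (length(bad)) paste("first violation at line", bad[1] + 1)
          else "")
    }
  }
  tf <- file.path(dir, "trials.csv")
  trials <- NULL
  if (file.exists(tf)) {
    trials <- utils::read.csv(tf)
    need <- c("stimulus", "face_present", "category", "response_time_ms",
              "onset_ms")
    add("trials.csv", "columns", all(need %in% names(trials)),
        paste(setdiff(need, names(trials)), collapse = ", "))
  } else add("trials.csv", "exists", FALSE)
  af <- file.path(dir, "aois.json")
  if (file.exists(af)) {
    ok <- !inherits(tryCatch(read_aoi_json(af), error = identity), "error")
    add("aois.json", "parses", ok)
  } else add("aois.json", "exists", FALSE)
  ef <- file.path(dir, "eeg.csv")
  if (file.exists(ef)) {
    rec <- tryCatch(read_eeg_csv(ef), error = function(e) NULL)
    add("eeg.csv", "parses", !is.null(rec))
    if (!is.null(rec) && !is.null(trials) && "onset_ms" %in% names(trials)) {
      end_ms <- rec$start_ms + ncol(rec$data) / rec$srate_hz * 1000
      trial_end <- max(trials$onset_ms + trials$response_time_ms)
      add("eeg.csv", "covers trials",
          rec$start_ms <= min(trials$onset_ms) && end_ms >= trial_end,
          sprintf("recording ends %.0f ms, last trial ends %.0f ms",
                  end_ms, trial_end))
    }
  } else add("eeg.csv", "exists", FALSE)
  out <- do.call(rbind, rep)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on a simulated study
#'
#' Fixed stage order: simulate, validate, metrics, scoring, presaccadic
#' FRP, group statistics. Each stage writes its outputs under `out_dir`
#' and a manifest entry (parameters, output paths, md5 hashes, exclusion
#' counts). Reruns with the same configuration and seed are bit-identical.
#'
#' The generator emits EEG at the 500 Hz analysis rate, standing in for
#' conditioned data, so the deterministic conditioning chain
#' ([preprocess_eeg()]) is exercised on its own probes rather than rerun
#' here; set `preprocess = TRUE` when feeding raw higher-rate recordings.
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory.
#' @param epoch An [epoch_config()].
#' @param use_truth Use ground-truth gaze events for metrics/FRP instead
#'   of re-detection.
#' @param preprocess Run the EEG conditioning chain on each session.
#' @param write_sessions Also write per-session interchange files.
#' @return The manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(sim = sim_config(), out_dir,
                         epoch = epoch_config(), use_truth = FALSE,
                         preprocess = FALSE, write_sessions = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = sim$seed, stages = list())
  note <- function(stage, params, outputs, extra = list()) {
    hashes <- as.list(tools::md5sum(outputs))
    names(hashes) <- basename(outputs)
    manifest$stages[[stage]] <<- c(list(params = params,
                                        outputs = hashes), extra)
  }

  study <- simulate_study(sim)
  if (write_sessions) {
    for (id in names(study$sessions))
      write_session(study$sessions[[id]], study$stimuli,
                    file.path(out_dir, "sessions", id))
  }
  note("simulate", list(n_images = sim$n_images,
                        n_face_images = sim$n_face_images,
                        subjects = as.list(sim$subjects)), character(0),
       list(n_sessions = length(study$sessions)))

  if (preprocess)
    for (id in names(study$sessions))
      study$sessions[[id]]$eeg <- preprocess_eeg(study$sessions[[id]]$eeg)

  metrics <- do.call(rbind, lapply(study$sessions, function(s) {
    m <- session_metrics(s, study$stimuli, sim$geometry,
                         use_truth = use_truth)
    m$group <- s$group
    m
  }))
  rownames(metrics) <- NULL
  mf <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, mf, row.names = FALSE)
  note("metrics", list(use_truth = use_truth), mf,
       list(n_rows = nrow(metrics)))

  scores <- score_sessions(study)
  sf <- file.path(out_dir, "scores.csv")
  utils::write.csv(scores, sf, row.names = FALSE)
  note("scoring", list(), sf)

  frp_rows <- list(); n_excluded <- list()
  for (id in names(study$sessions)) {
    res <- session_frp(study$sessions[[id]], epoch, use_truth = use_truth,
                       geometry = sim$geometry,
                       seed = child_seed(sim$seed, 9000 + match(id, names(study$sessions))))
    frp_rows[[id]] <- res$table
    n_excluded[[id]] <- attr(res$epochs, "skipped") %||% 0L
  }
  amplitudes <- do.call(rbind, frp_rows)
  rownames(amplitudes) <- NULL
  ff <- file.path(out_dir, "amplitudes.csv")
  utils::write.csv(amplitudes, ff, row.names = FALSE)
  note("frp", list(min_trials = epoch$min_trials,
                   reject_uV = epoch$reject_uV), ff,
       list(skipped_epochs = n_excluded))

  stats_out <- pipeline_stats(metrics, scores, amplitudes)
  jf <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats_out, jf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  note("stats", list(), jf)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# Group-level statistical layer over the pipeline tables; returns plain
# lists suitable for JSON serialisation.
pipeline_stats <- function(metrics, scores, amplitudes) {
  out <- list()
  out$pareidolia_kruskal <- tryCatch({
    k <- kruskal_dunn(scores$n_pareidolia, scores$group)
    list(H = k$H, df = k$df, p = k$p)
  }, error = function(e) list(error = conditionMessage(e)))

  agg <- aggregate_metrics(metrics, variables = c("tfd_s", "vd_s"))
  out$rm_anova <- list()
  for (cat in intersect(c("Face", "Noise"), unique(agg$category))) {
    sub <- agg[agg$category == cat & agg$window == "early", , drop = FALSE]
    if (length(unique(sub$group)) >= 2 && nrow(sub) > 6) {
      res <- tryCatch(rm_anova(sub), error = function(e) NULL)
      if (!is.null(res))
        out$rm_anova[[cat]] <- res$effects
    }
  }

  out$manova <- list()
  for (cat in unique(amplitudes$category)) {
    sub <- amplitudes[amplitudes$category == cat, , drop = FALSE]
    wide <- stats::reshape(
      sub[, c("subject", "group", "category", "size_class",
              "electrode_group", "amp_uV")],
      idvar = c("subject", "group", "category", "size_class"),
      timevar = "electrode_group", direction = "wide")
    names(wide) <- sub("^amp_uV\\.", "", names(wide))
    if (nrow(wide) > 8 && all(c("frontal", "parietal") %in% names(wide))) {
      res <- tryCatch(
        suppressWarnings(manova_then_univariate(wide)),
        error = function(e) NULL)
      if (!is.null(res)) out$manova[[cat]] <- res$wilks
    }
  }
  out
}

#' Read and write the pipeline run configuration
#'
#' A single YAML file surfaces every tunable default — simulation
#' constants, group profiles, effect amplitudes, epoching windows and
#' thresholds, geometry and the master seed — so the configuration gaps
#' that were resolved by explicit convention are machine-visible. Missing
#' keys fall back to package defaults.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: a list with `sim` (a [sim_config()]) and
#'   `epoch` (an [epoch_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  s <- y$sim %||% list()
  profiles <- default_group_profiles()
  for (g in names(s$profiles %||% list())) {
    base <- profiles[[g]] %||% profiles[[1]]
    upd <- s$profiles[[g]]
    for (k in names(upd)) base[[k]] <- upd[[k]]
    base$group <- g
    profiles[[g]] <- base
  }
  subjects <- unlist(s$subjects %||% c(HC = 12, PDnP = 11, PDP = 10))
  ep <- y$eeg %||% list()
  eeg <- eeg_params(
    srate_hz = ep$srate_hz %||% 500,
    noise_sd_uV = ep$noise_sd_uV %||% 5,
    pink_exponent = ep$pink_exponent %||% 1,
    spike_amp_uV = ep$spike_amp_uV %||% 5,
    blink_amp_uV = ep$blink_amp_uV %||% 150)
  g <- y$geometry %||% list()
  geometry <- screen_geometry(
    distance_mm = g$distance_mm %||% 800,
    pitch_mm_px = g$pitch_mm_px %||% 0.2766)
  effect <- default_effect_spec()
  for (row in y$effects %||% list()) {
    hit <- effect$group == row$group & effect$category == row$category &
      effect$electrode_group == row$electrode_group
    effect$amp_uV[hit] <- row$amp_uV
  }
  e <- y$epoch %||% list()
  epoch <- epoch_config(
    reject_uV = e$reject_uV %||% 80,
    min_trials = e$min_trials %||% 50,
    size_boundary_deg = e$size_boundary_deg %||% 4,
    min_onset_ms = e$min_onset_ms %||% 700,
    blink_margin_ms = e$blink_margin_ms %||% 300,
    mahalanobis_percentile = e$mahalanobis_percentile %||% 95)
  sim <- sim_config(
    n_images = s$n_images %||% 80,
    n_face_images = s$n_face_images %||% 20,
    subjects = subjects, profiles = profiles, effect_spec = effect,
    eeg = eeg, geometry = geometry,
    gaze_rate_hz = s$gaze_rate_hz %||% 120,
    intertrial_ms = s$intertrial_ms %||% 2000,
    seed = y$seed %||% 1L)
  list(sim = sim, epoch = epoch)
}

#' @rdname read_run_config
#' @param sim A [sim_config()].
#' @param epoch An [epoch_config()].
#' @export
write_run_config <- function(sim, epoch, path) {
  y <- list(
    seed = sim$seed,
    sim = list(n_images = sim$n_images, n_face_images = sim$n_face_images,
               subjects = as.list(sim$subjects),
               gaze_rate_hz = sim$gaze_rate_hz,
               intertrial_ms = sim$intertrial_ms,
               profiles = lapply(sim$profiles, function(p)
                 p[setdiff(names(p), "group")])),
    eeg = sim$eeg[c("srate_hz", "noise_sd_uV", "pink_exponent",
                    "spike_amp_uV", "blink_amp_uV")],
    geometry = sim$geometry[c("distance_mm", "pitch_mm_px")],
    effects = unname(lapply(seq_len(nrow(sim$effect_spec)), function(i)
      as.list(sim$effect_spec[i, ]))),
    epoch = epoch[c("reject_uV", "min_trials", "size_boundary_deg",
                    "min_onset_ms", "blink_margin_ms",
                    "mahalanobis_percentile")])
  yaml::write_yaml(y, path)
  invisible(path)
}
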