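test_that("stimulus set has the right composition and disjoint in-bounds AOIs", {
  ss <- generate_stimulus_set(80, 20, seed = 7)
  expect_length(ss, 80)
  has_target <- vapply(ss, function(s)
    any(vapply(s$aois, `[[`, character(1), "label") == "target"), logical(1))
  expect_equal(sum(has_target), 20)
  n_targets <- vapply(ss, function(s)
    sum(vapply(s$aois, `[[`, character(1), "label") == "target"), integer(1))
  expect_true(all(n_targets[has_target] == 1))
  n_noise <- vapply(ss, function(s)
    sum(vapply(s$aois, `[[`, character(1), "label") == "noise"), integer(1))
  expect_true(all(n_noise >= 1))

  expect_length(generate_stimulus_set(0, 0, seed = 1), 0)
  expect_error(generate_stimulus_set(10, 11, seed = 1), "exceed")
  expect_error(generate_stimulus_set(-1, 0, seed = 1), "non-negative")

  # rasterised overlap oracle on a small set: no grid point belongs to two
  # AOIs, and every AOI stays inside the 700 px canvas
  ss10 <- generate_stimulus_set(10, 3, seed = 3)
  grid <- expand.grid(x = seq(0.5, 699.5, by = 2), y = seq(0.5, 699.5, by = 2))
  for (stim in ss10) {
    masks <- vapply(stim$aois, function(a)
      point_in_aoi(grid$x, grid$y, a), logical(nrow(grid)))
    expect_true(all(rowSums(masks) <= 1))
    for (a in stim$aois) {
      if (a$shape == "polygon") {
        expect_true(all(a$x >= 0 & a$x <= 700 & a$y >= 0 & a$y <= 700))
      } else {
        expect_true(a$cx - max(a$rx, a$ry) >= 0 &&
                      a$cx + max(a$rx, a$ry) <= 700)
      }
    }
  }
})

test_that("stimulus generation is reproducible given a seed", {
  a <- generate_stimulus_set(12, 4, seed = 42)
  b <- generate_stimulus_set(12, 4, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, generate_stimulus_set(12, 4, seed = 43)))
})

test_that("simulated responses respect category bookkeeping and rates", {
  ss <- generate_stimulus_set(80, 20, seed = 1)
  det <- group_profile("X", hit_rate = 1, pareidolia_rate = 0)
  tr <- simulate_responses(det, ss, seed = 1)
  expect_equal(sum(tr$category == "Face"), 20)
  expect_equal(sum(tr$category == "Noise"), 60)

  none <- group_profile("X", hit_rate = 0, pareidolia_rate = 0)
  tr0 <- simulate_responses(none, ss, seed = 1)
  expect_equal(sum(tr0$category == "Missed"), 20)

  # category consistent with the face-present flag, every trial classified
  expect_true(all(tr$category[tr$face_present] %in% c("Face", "Missed")))
  expect_true(all(tr$category[!tr$face_present] %in% c("Noise", "Pareidolia")))

  # binomial expectation: pareidolia rate 0.4 over 60 noise images -> 24
  p40 <- group_profile("X", hit_rate = 0.8, pareidolia_rate = 0.4)
  counts <- vapply(1:500, function(s)
    sum(simulate_responses(p40, ss, seed = s)$category == "Pareidolia"),
    numeric(1))
  se <- sqrt(60 * 0.4 * 0.6 / 500)
  expect_lt(abs(mean(counts) - 24), 4 * se)
})

test_that("gaze generator honours profile parameters and is seed-stable", {
  ss <- generate_stimulus_set(4, 2, seed = 5)
  noblink <- clean_profile()
  g <- simulate_gaze(noblink, ss[[1]], 8000, seed = 2)
  expect_equal(nrow(g$truth$blinks), 0)
  expect_true(all(g$samples$valid))

  # events are time-ordered and non-overlapping within each modality
  fx <- g$truth$fixations
  expect_true(all(diff(fx$onset) > 0))
  expect_true(all(head(fx$onset + fx$duration, -1) <= fx$onset[-1] + 1e-9))

  expect_identical(simulate_gaze(noblink, ss[[1]], 8000, seed = 2),
                   simulate_gaze(noblink, ss[[1]], 8000, seed = 2))

  # fixation-duration distribution: sample mean within +/- 4 SE
  prof <- group_profile("X", 1, 0, fixation_mean_ms = 400,
                        fixation_sd_ms = 50, blink_rate_hz = 0)
  durs <- unlist(lapply(1:10, function(s) {
    tr <- simulate_gaze(prof, ss[[1]], 60000, seed = s)$truth$fixations
    head(tr$duration, -1)  # final fixation is truncated at the response
  }))
  expect_gt(length(durs), 800)
  expect_lt(abs(mean(durs) - 400), 4 * 50 / sqrt(length(durs)))
})

test_that("re-segmentation recovers the generated events", {
  ss <- generate_stimulus_set(4, 2, seed = 5)
  # noise-free: counts match exactly
  for (s in 1:5) {
    g0 <- simulate_gaze(clean_profile(), ss[[1]], 8000, seed = s,
                        jitter_px = 0)
    ev <- detect_events(g0$samples)
    expect_equal(nrow(ev$fixations), nrow(g0$truth$fixations))
    expect_equal(nrow(ev$saccades), nrow(g0$truth$saccades))
  }
  # realistic jitter and blinks: >= 95% of true fixations recovered
  prof <- default_group_profiles()$PDP
  hits <- 0; total <- 0
  for (s in 1:10) {
    g <- simulate_gaze(prof, ss[[(s %% 4) + 1]], 9000, seed = 50 + s)
    ev <- detect_events(g$samples)
    tr <- g$truth$fixations
    hits <- hits + sum(vapply(tr$onset, function(o)
      any(abs(ev$fixations$onset - o) < 25), logical(1)))
    total <- total + nrow(tr)
  }
  expect_gte(hits / total, 0.95)
})

test_that("synthetic EEG realises the configured ramp, spike and blink", {
  par0 <- eeg_params(noise_sd_uV = 0, spike_amp_uV = 0)
  sacc <- data.frame(onset_ms = 1000, amp_uV = 1, group = "frontal")
  rec <- simulate_eeg(sacc, par0, duration_ms = 2000, seed = 1)
  i <- seq_len(ncol(rec$data))
  t_ms <- (i - 1) * 2
  # closed form: the raw (uncorrected) mean over [-100, -20) ms is
  # 139/180 of the peak; peak = 36/25 of the configured amplitude
  win <- t_ms >= 900 & t_ms < 980
  f3 <- which(rec$channels == "F3")
  expect_equal(mean(rec$data[f3, win]), (36 / 25) * 139 / 180,
               tolerance = 1e-12)
  # parietal channels untouched
  pz <- which(rec$channels == "Pz")
  expect_true(all(rec$data[pz, ] == 0))

  # all amplitudes 0, noise 0 -> flat zero
  rec0 <- simulate_eeg(data.frame(onset_ms = 1000, amp_uV = 0,
                                  group = "frontal"),
                       par0, duration_ms = 2000, seed = 1)
  expect_true(all(rec0$data == 0))

  # blink artefact exceeds the 80 uV rejection threshold on frontal sites
  recb <- simulate_eeg(sacc[0, ], par0, duration_ms = 2000,
                       blinks = data.frame(onset_ms = 500), seed = 1)
  expect_gt(max(abs(recb$data[f3, ])), 80)

  expect_error(
    simulate_eeg(data.frame(onset_ms = 1000, amp_uV = 1, group = "XX9"),
                 par0, duration_ms = 2000, seed = 1),
    "unknown channel")
})

test_that("full sessions are reproducible and keep category bookkeeping", {
  cfg <- tiny_sim_config(seed = 11)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$sessions$HC01$eeg$data, st2$sessions$HC01$eeg$data)
  expect_identical(st1$sessions$HC01$trials, st2$sessions$HC01$trials)

  tr <- st1$sessions$HC01$trials
  n_face <- cfg$n_face_images
  expect_equal(sum(tr$category %in% c("Face", "Missed")), n_face)
  expect_equal(sum(tr$category %in% c("Noise", "Pareidolia")),
               cfg$n_images - n_face)
})
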