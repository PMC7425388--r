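test_that("valid-fixation selection equals brute-force rule application", {
  # constructed set: one fixation violating each rule, plus survivors
  fx <- data.frame(
    onset = c(1000, 1500, 2500, 650, 3500, 4200, 5000),
    duration = c(400, 199, 2100, 400, 400, 300, 400),
    x = 0, y = 0)
  fx$end <- fx$onset + fx$duration
  sc <- data.frame(onset = fx$end, duration = c(40, 40, 40, 40, 85, 40, 40),
                   amplitude_deg = c(2, 3, 5, 2, 3, 6, 8))
  bl <- data.frame(onset = 4550, duration = 150)  # near saccade of fix 6
  ev <- list(fixations = fx[, 1:4], saccades = sc, blinks = bl)
  trials <- data.frame(response_time_ms = 5200, category = "Face")
  out <- select_valid_fixations(list(ev), trials, epoch_config())
  # independent predicates
  p1 <- fx$duration >= 200 & fx$duration <= 2000
  p2 <- sc$duration < 80
  p3 <- fx$onset >= 700
  p4 <- sc$onset <= 5200
  p5 <- !vapply(sc$onset, function(s)
    any(bl$onset < s + 300 & bl$onset + bl$duration > s - 300), logical(1))
  expect_equal(out$onset, fx$onset[p1 & p2 & p3 & p4 & p5])

  # boundary conventions: 199 ms out, 200 ms in (closed bounds)
  fx2 <- data.frame(onset = c(1000, 2000), duration = c(199, 200), x = 0, y = 0)
  sc2 <- data.frame(onset = fx2$onset + fx2$duration, duration = 40,
                    amplitude_deg = 3)
  ev2 <- list(fixations = fx2, saccades = sc2,
              blinks = data.frame(onset = numeric(0), duration = numeric(0)))
  out2 <- select_valid_fixations(list(ev2),
                                 data.frame(response_time_ms = 9000,
                                            category = "Noise"))
  expect_equal(out2$duration, 200)

  # everything before 700 ms -> empty
  fx3 <- data.frame(onset = c(100, 300), duration = 250, x = 0, y = 0)
  sc3 <- data.frame(onset = fx3$onset + fx3$duration, duration = 30,
                    amplitude_deg = 2)
  ev3 <- list(fixations = fx3, saccades = sc3,
              blinks = data.frame(onset = numeric(0), duration = numeric(0)))
  expect_equal(nrow(select_valid_fixations(
    list(ev3), data.frame(response_time_ms = 9000, category = "Noise"))), 0)
})

test_that("saccade size classes partition at the 4-degree boundary", {
  expect_equal(classify_saccade_size(3.9), "short")
  expect_equal(classify_saccade_size(4.0), "long")
  expect_equal(classify_saccade_size(12), "long")
  expect_error(classify_saccade_size(-0.1), "non-negative")
  amps <- runif(100, 0, 15)
  cls <- classify_saccade_size(amps)
  expect_true(all(cls %in% c("short", "long")))
})

test_that("Mahalanobis matching removes the top distance percentile", {
  set.seed(12)
  n <- 10000
  vf <- data.frame(saccade_amplitude_deg = rnorm(n, 5, 2),
                   duration = rnorm(n, 600, 150))
  out <- mahalanobis_match(vf)
  removed <- attr(out, "removed")
  expect_lt(abs(removed / n - 0.05), 2 / n + 1e-3)

  # distances equal the explicit quadratic-form loop
  X <- as.matrix(vf[1:50, ])
  S <- cov(as.matrix(vf))
  mu <- colMeans(as.matrix(vf))
  Sinv <- solve(S)
  loop <- apply(X, 1, function(r) drop(t(r - mu) %*% Sinv %*% (r - mu)))
  full <- mahalanobis(as.matrix(vf), mu, S)
  expect_equal(unname(loop), unname(full[1:50]), tolerance = 1e-9)

  # degenerate features -> informative error
  bad <- data.frame(saccade_amplitude_deg = rep(3, 10),
                    duration = rep(500, 10))
  expect_error(mahalanobis_match(bad), "saccade_amplitude_deg")
})

test_that("epoch extraction is sample-exact", {
  cfg <- epoch_config(min_trials = 1)
  par0 <- eeg_params(noise_sd_uV = 0, spike_amp_uV = 0)
  sacc <- data.frame(onset_ms = 2000, amp_uV = 0.8, group = "frontal")
  rec <- simulate_eeg(sacc, par0, duration_ms = 4000, seed = 1)
  vf <- data.frame(trial = 1L, onset = 1500, duration = 500,
                   saccade_onset = 2000, saccade_duration = 40,
                   saccade_amplitude_deg = 2, category = "Face",
                   size_class = "short", saccade_onset_session_ms = 2000)
  eps <- extract_epochs(rec, vf, cfg)
  expect_length(eps, 1)
  expect_equal(ncol(eps[[1]]$data), 125)       # [-200, +50) ms at 500 Hz
  expect_equal(range(eps[[1]]$times_ms), c(-200, 48))
  # the epoch equals the generated ramp exactly at noise 0
  f3 <- which(eps[[1]]$channels == "F3")
  expect_equal(eps[[1]]$data[f3, ],
               ramp_wave(eps[[1]]$times_ms, 0.8 * 36 / 25),
               tolerance = 1e-12)

  # saccade too close to the recording start -> skipped and logged
  vf2 <- vf; vf2$saccade_onset_session_ms <- 50
  expect_message(eps2 <- extract_epochs(rec, vf2, cfg), "skipped")
  expect_length(eps2, 0)
  expect_equal(attr(eps2, "skipped"), 1L)
})

test_that("amplitude rejection drops epochs beyond +/-80 uV", {
  ok <- make_epoch(fill = 0)
  ok$data[1, 5] <- 79.9
  bad <- make_epoch(fill = 0)
  bad$data[3, 60] <- 81
  neg <- make_epoch(fill = 0)
  neg$data[2, 10] <- -81
  out <- reject_artifacts(list(ok, bad, neg))
  expect_length(out, 1)
  expect_equal(attr(out, "rejected"), 2L)

  # blink-contaminated synthetic epochs are all rejected
  par0 <- eeg_params(noise_sd_uV = 0, spike_amp_uV = 0)
  rec <- simulate_eeg(data.frame(onset_ms = numeric(0), amp_uV = numeric(0),
                                 group = character(0)),
                      par0, duration_ms = 3000,
                      blinks = data.frame(onset_ms = 1900), seed = 1)
  vf <- data.frame(trial = 1L, onset = 1500, duration = 500,
                   saccade_onset = 2000, saccade_duration = 40,
                   saccade_amplitude_deg = 2, category = "Face",
                   size_class = "short", saccade_onset_session_ms = 2000)
  eps <- extract_epochs(rec, vf, epoch_config(min_trials = 1))
  expect_length(reject_artifacts(eps), 0)
})

test_that("baseline correction zeroes the baseline window", {
  const <- make_epoch(fill = 3.7)
  out <- baseline_correct(const)
  expect_true(all(out$data == 0))

  set.seed(4)
  noisy <- make_epoch()
  noisy$data[] <- rnorm(length(noisy$data), 2, 5)
  outn <- baseline_correct(noisy)
  sel <- outn$times_ms >= -200 & outn$times_ms < -170
  expect_lt(max(abs(rowMeans(outn$data[, sel]))), 1e-12)

  # analytic ramp: baseline mean is 14/180 of the peak
  peak <- 2.5
  ep <- make_epoch()
  ep$data[] <- rep(ramp_wave(ep$times_ms, peak), each = nrow(ep$data))
  outr <- baseline_correct(ep)
  expect_equal(outr$data[1, 1], 0 - peak * 14 / 180, tolerance = 1e-12)
})

test_that("mean amplitude matches the analytic ramp and a hand loop", {
  zero <- baseline_correct(make_epoch(fill = 0))
  expect_equal(mean_amplitude(zero, "frontal"), 0)

  peak <- 1.8
  ep <- make_epoch()
  ep$data[] <- rep(ramp_wave(ep$times_ms, peak), each = nrow(ep$data))
  epc <- baseline_correct(ep)
  # window mean 139/180 minus baseline mean 14/180 -> 125/180 of the peak
  expect_equal(mean_amplitude(epc, "frontal"), peak * 125 / 180,
               tolerance = 1e-12)

  set.seed(6)
  ep2 <- make_epoch()
  ep2$data[] <- rnorm(length(ep2$data))
  ep2c <- baseline_correct(ep2)
  rows <- match(electrode_montage()$parietal, ep2c$channels)
  sel <- which(ep2c$times_ms >= -100 & ep2c$times_ms < -20)
  acc <- 0; cnt <- 0
  for (r in rows) for (s in sel) { acc <- acc + ep2c$data[r, s]; cnt <- cnt + 1 }
  expect_equal(mean_amplitude(ep2c, "parietal"), acc / cnt, tolerance = 1e-12)

  expect_error(mean_amplitude(ep2c, c("F3", "Nope")), "missing")
  expect_error(mean_amplitude(make_epoch(), "frontal"), "baseline")
})

test_that("trial-count matching equalises categories", {
  mk <- function(n, cat) replicate(n, make_epoch(category = cat),
                                   simplify = FALSE)
  sets <- list(Face = mk(120, "Face"), Noise = mk(300, "Noise"),
               Pareidolia = mk(30, "Pareidolia"))
  out <- match_trial_counts(sets, min_trials = 50, seed = 3)
  expect_equal(sort(names(out)), c("Face", "Noise"))
  expect_equal(attr(out, "excluded"), "Pareidolia")
  expect_equal(vapply(out, length, integer(1)),
               c(Face = 120, Noise = 120))

  eq <- list(A = mk(60, "A"), B = mk(60, "B"))
  oeq <- match_trial_counts(eq, min_trials = 50, seed = 1)
  expect_equal(vapply(oeq, length, integer(1)), c(A = 60, B = 60))

  o1 <- match_trial_counts(sets, min_trials = 50, seed = 9)
  o2 <- match_trial_counts(sets, min_trials = 50, seed = 9)
  expect_identical(o1, o2)
})

test_that("grand averaging is linear in the epochs", {
  e1 <- baseline_correct(make_epoch(fill = 0))
  expect_equal(grand_average(list(e1))$data, e1$data)

  a <- make_epoch(); a$data[] <- 1
  b <- make_epoch(); b$data[] <- 3
  ga <- grand_average(list(baseline_correct(a), baseline_correct(b)))
  # both epochs are constants, so baseline correction zeroes them; use raw
  ga_raw <- grand_average(list(a, b))
  expect_true(all(ga_raw$data == 2))

  set.seed(7)
  eps <- lapply(1:5, function(i) {
    e <- make_epoch(); e$data[] <- rnorm(length(e$data)); baseline_correct(e)
  })
  ga2 <- grand_average(eps)
  per <- vapply(eps, mean_amplitude, numeric(1), group = "frontal")
  expect_equal(mean_amplitude(ga2, "frontal"), mean(per), tolerance = 1e-9)

  expect_error(grand_average(list()), "zero")
})

test_that("noise-free sessions return the configured amplitudes exactly", {
  cfg <- tiny_sim_config(seed = 21, subjects = c(PDP = 1))
  cfg$profiles$PDP$fixation_mean_ms <- 500
  cfg$profiles$PDP$fixation_sd_ms <- 40
  st <- simulate_study(cfg)
  res <- session_frp(st$sessions$PDP01, epoch_config(min_trials = 1),
                     use_truth = TRUE, seed = 1)
  spec <- default_effect_spec()
  for (i in seq_len(nrow(res$table))) {
    row <- res$table[i, ]
    want <- spec$amp_uV[spec$group == "PDP" & spec$category == row$category &
                          spec$electrode_group == row$electrode_group]
    expect_equal(row$amp_uV, want, tolerance = 1e-6)
  }
})

test_that("recovered amplitude increases with the configured ramp", {
  par0 <- eeg_params(noise_sd_uV = 0, spike_amp_uV = 0)
  cfg <- epoch_config(min_trials = 1)
  amps <- c(0.2, 0.7, 1.5, 3)
  got <- vapply(amps, function(a) {
    rec <- simulate_eeg(data.frame(onset_ms = 2000, amp_uV = a,
                                   group = "frontal"),
                        par0, duration_ms = 4000, seed = 1)
    vf <- data.frame(trial = 1L, onset = 1500, duration = 500,
                     saccade_onset = 2000, saccade_duration = 40,
                     saccade_amplitude_deg = 2, category = "Face",
                     size_class = "short", saccade_onset_session_ms = 2000)
    ep <- baseline_correct(extract_epochs(rec, vf, cfg)[[1]])
    mean_amplitude(ep, "frontal")
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_equal(got, amps, tolerance = 1e-9)
})
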