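test_that("pixel-to-degree conversion matches the closed form", {
  geo <- screen_geometry()
  expect_equal(pixels_to_degrees(0, geo), 0)
  # px * pitch = distance -> 2 atan(1/2)
  px <- geo$distance_mm / geo$pitch_mm_px
  expect_equal(pixels_to_degrees(px, geo), 2 * atan(0.5) * 180 / pi)
  # independent trigonometric recomputation at 100 px
  expect_equal(pixels_to_degrees(100, geo),
               atan(100 * 0.2766 / 2 / 800) * 2 * 180 / pi)
  # inverse round-trips
  expect_equal(degrees_to_pixels(pixels_to_degrees(123.4, geo), geo), 123.4)
})

test_that("I-VT segmentation handles canonical streams", {
  geo <- screen_geometry()
  dt <- 1000 / 120
  # stationary 1 s -> one fixation of ~1000 ms
  t <- seq(0, 1000, by = dt)
  st <- data.frame(t_ms = t, x_px = 300, y_px = 300, valid = TRUE)
  ev <- detect_events(st, geometry = geo)
  expect_equal(nrow(ev$fixations), 1)
  expect_equal(ev$fixations$duration, 1000, tolerance = 0.01)
  expect_equal(nrow(ev$saccades), 0)

  # two stationary clusters joined by a fast sweep -> 2 fixations, 1 saccade
  x <- c(rep(100, 60), seq(100, 500, length.out = 5), rep(500, 60))
  t2 <- seq_along(x) * dt
  st2 <- data.frame(t_ms = t2, x_px = x, y_px = 300, valid = TRUE)
  ev2 <- detect_events(st2, geometry = geo)
  expect_equal(nrow(ev2$fixations), 2)
  expect_equal(nrow(ev2$saccades), 1)
  expect_gt(ev2$saccades$amplitude_deg, 4)

  # all samples invalid -> one blink spanning the stream
  st3 <- data.frame(t_ms = t, x_px = NA_real_, y_px = NA_real_, valid = FALSE)
  ev3 <- detect_events(st3, geometry = geo)
  expect_equal(nrow(ev3$fixations), 0)
  expect_equal(nrow(ev3$blinks), 1)
  expect_equal(ev3$blinks$duration, 1000, tolerance = 0.01)

  # empty stream -> empty lists
  ev4 <- detect_events(st[0, ], geometry = geo)
  expect_equal(nrow(ev4$fixations), 0)
})

test_that("AOI assignment matches an independent winding-number oracle", {
  set.seed(31)
  ell <- aoi_ellipse("target", cx = 300, cy = 250, rx = 80, ry = 50,
                     rotation_deg = 30)
  poly <- aoi_polygon("noise", x = c(480, 620, 650, 560, 470),
                      y = c(420, 400, 520, 600, 530))
  # centre -> its label; far point -> none
  expect_equal(assign_aoi(300, 250, list(ell, poly))$label, "target")
  expect_true(is.na(assign_aoi(5, 5, list(ell, poly))$label))

  px <- runif(10000, 0, 700); py <- runif(10000, 0, 700)
  mine <- nptfrp:::point_in_polygon(px, py, poly$x, poly$y)
  oracle <- mapply(winding_inside, px, py,
                   MoreArgs = list(vx = poly$x, vy = poly$y))
  near <- mapply(polygon_boundary_dist, px, py,
                 MoreArgs = list(vx = poly$x, vy = poly$y)) < 1
  expect_equal(mine[!near], oracle[!near])

  # ellipse membership vs an unrotate-and-scale circle oracle
  th <- -30 * pi / 180
  u <- (px - 300) * cos(th) - (py - 250) * sin(th)
  v <- (px - 300) * sin(th) + (py - 250) * cos(th)
  circ <- sqrt((u / 80)^2 + (v / 50)^2)
  expect_equal(point_in_aoi(px, py, ell)[abs(circ - 1) > 0.02],
               (circ <= 1)[abs(circ - 1) > 0.02])
})

test_that("visits follow the dwell definition", {
  aois <- list(aoi_ellipse("target", 100, 100, 50, 50))
  # fix(in,200) - sacc(30) - fix(in,250) - sacc - fix(out): one visit, 480 ms
  ev <- list(
    fixations = data.frame(onset = c(0, 230, 520),
                           duration = c(200, 250, 300),
                           x = c(100, 110, 600), y = c(100, 95, 600),
                           aoi = c(1L, 1L, 0L)),
    saccades = data.frame(onset = c(200, 480), duration = c(30, 40),
                          amplitude_deg = c(1, 9)))
  vis <- compute_visits(ev, 1)
  expect_equal(nrow(vis), 1)
  expect_equal(vis$duration, 480)
  expect_equal(vis$n_fixations, 2)

  # single in-AOI fixation of 300 ms -> one visit, VD = 300 ms
  ev1 <- list(fixations = data.frame(onset = 0, duration = 300, x = 100,
                                     y = 100, aoi = 1L),
              saccades = data.frame(onset = numeric(0), duration = numeric(0),
                                    amplitude_deg = numeric(0)))
  expect_equal(compute_visits(ev1, 1)$duration, 300)

  # alternating in/out n times -> n visits
  n <- 7
  onsets <- seq(0, by = 400, length.out = 2 * n)
  evn <- list(fixations = data.frame(onset = onsets, duration = 300,
                                     x = 0, y = 0,
                                     aoi = rep(c(1L, 0L), n)),
              saccades = data.frame(onset = numeric(0), duration = numeric(0),
                                    amplitude_deg = numeric(0)))
  expect_equal(nrow(compute_visits(evn, 1)), n)
})

test_that("metrics reproduce the worked example and edge rules", {
  aois <- list(aoi_ellipse("target", 100, 100, 50, 50))
  ev <- list(
    fixations = data.frame(onset = c(0, 230, 520),
                           duration = c(200, 250, 300),
                           x = c(100, 110, 600), y = c(100, 95, 600),
                           aoi = c(1L, 1L, 0L)),
    saccades = data.frame(onset = c(200, 480), duration = c(30, 40),
                          amplitude_deg = c(1, 9)))
  m <- compute_metrics(ev, aois, c(0, 1000))
  expect_equal(m$tfd_s, 0.450)
  expect_equal(m$vd_s, 0.480)
  expect_equal(m$fc, 2)
  expect_equal(m$vc, 1)
  expect_equal(m$ffd_ms, 200)

  # AOI never fixated: counts 0, FFD missing
  aois2 <- c(aois, list(aoi_ellipse("noise", 600, 600, 30, 30)))
  ev$fixations$aoi <- c(1L, 1L, 0L)
  m2 <- compute_metrics(ev, aois2, c(0, 1000))
  expect_true(is.na(m2$ffd_ms[2]))
  expect_equal(m2$tfd_s[2], 0)
  expect_equal(m2$vc[2], 0)

  # boundary-straddling fixation 4800-5300: 200 ms early, 300 ms late
  evs <- list(fixations = data.frame(onset = 4800, duration = 500, x = 100,
                                     y = 100, aoi = 1L),
              saccades = data.frame(onset = numeric(0), duration = numeric(0),
                                    amplitude_deg = numeric(0)))
  early <- compute_metrics(evs, aois, c(0, 5000))
  late <- compute_metrics(evs, aois, c(5000, 9000))
  expect_equal(early$tfd_s, 0.2)
  expect_equal(late$tfd_s, 0.3)
  # counted once, in the onset window
  expect_equal(early$fc, 1)
  expect_equal(late$fc, 0)
})

test_that("early/late windows split at 5 s", {
  w <- bin_early_late(9200)
  expect_equal(w$early, c(0, 5000))
  expect_equal(w$late, c(5000, 9200))
  w2 <- bin_early_late(4000)
  expect_equal(w2$early, c(0, 4000))
  expect_equal(diff(w2$late), 0)  # empty late window
  expect_error(bin_early_late(0))
})

test_that("metric invariants and conservation hold on random sessions", {
  ss <- generate_stimulus_set(6, 2, seed = 9)
  prof <- default_group_profiles()$PDnP
  for (s in 1:6) {
    i <- (s %% 6) + 1
    g <- simulate_gaze(prof, ss[[i]], 8000 + 500 * s, seed = 200 + s)
    ev <- assign_events_to_aois(detect_events(g$samples), ss[[i]]$aois)
    tm <- trial_metrics(ev, ss[[i]]$aois, 8000 + 500 * s)
    for (a in unique(tm$aoi)) {
      rows <- tm[tm$aoi == a, ]
      tot <- rows[rows$window == "total", ]
      early <- rows[rows$window == "early", ]
      late <- rows[rows$window == "late", ]
      expect_equal(early$tfd_s + late$tfd_s, tot$tfd_s, tolerance = 1e-9)
      expect_equal(early$vd_s + late$vd_s, tot$vd_s, tolerance = 1e-9)
      expect_equal(early$fc + late$fc, tot$fc)
      expect_equal(early$vc + late$vc, tot$vc)
      # VD >= TFD, FC >= VC, VC >= 1 iff FC >= 1
      expect_true(all(rows$vd_s >= rows$tfd_s - 1e-12))
      expect_true(all(rows$fc >= rows$vc))
      expect_true(all((rows$vc >= 1) == (rows$fc >= 1)))
    }
  }
})

test_that("relabelling AOIs permutes metric rows identically", {
  ss <- generate_stimulus_set(1, 0, seed = 4)
  aois <- ss[[1]]$aois
  g <- simulate_gaze(default_group_profiles()$HC, ss[[1]], 7000, seed = 3)
  ev <- assign_events_to_aois(detect_events(g$samples), aois)
  m <- compute_metrics(ev, aois, c(0, 7000))
  perm <- rev(seq_along(aois))
  evp <- assign_events_to_aois(detect_events(g$samples), aois[perm])
  mp <- compute_metrics(evp, aois[perm], c(0, 7000))
  got <- mp[order(perm), c("ffd_ms", "tfd_s", "vd_s", "fc", "vc")]
  rownames(got) <- NULL
  expect_equal(got, m[, c("ffd_ms", "tfd_s", "vd_s", "fc", "vc")])
})
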