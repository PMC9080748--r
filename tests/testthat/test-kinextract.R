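test_that("centroid kinematics are exact for rigid motion and rest", {
  n <- 200
  t <- (seq_len(n) - 1) / 100
  disp <- array(0, dim = c(n, 10, 3))
  for (m in 1:10) {
    disp[, m, 1] <- 10 * t + m   # rigid 10 cm/s translation
    disp[, m, 2] <- m
  }
  ck <- centroid_kinematics(fake_smoothed(disp))
  expect_equal(ck$mean_speed, 10, tolerance = 1e-9)
  expect_equal(ck$peak_speed, 10, tolerance = 1e-9)
  expect_lt(ck$mean_accel, 1e-8)

  static <- fake_smoothed(array(1, dim = c(n, 10, 3)))
  cs <- centroid_kinematics(static)
  expect_equal(unlist(cs), c(mean_speed = 0, peak_speed = 0,
                             mean_accel = 0, peak_accel = 0))
  disp[5, 3, 1] <- NA
  expect_error(centroid_kinematics(fake_smoothed(disp)), "missing")
})

test_that("marker summaries report peak speed and height above baseline", {
  n <- 200
  disp <- array(0, dim = c(n, 10, 3))
  t <- (seq_len(n) - 1) / 100
  for (m in 1:10) disp[, m, 1] <- 4 * t
  ms <- marker_summaries(fake_smoothed(disp))
  expect_equal(ms$peak_speed, rep(4, 10), tolerance = 1e-9)
  expect_equal(ms$max_height, rep(0, 10))
  disp[, 4, 3] <- 2 + 1.5 * sin(2 * pi * t)  # baseline is the trial minimum
  ms <- marker_summaries(fake_smoothed(disp))
  expect_equal(ms$max_height[4], 3, tolerance = 1e-3)
})

test_that("z-score band selection finds the most typical contiguous markers", {
  set.seed(44)
  vals <- matrix(rnorm(50 * 10, mean = 100, sd = 0.1), 50, 10)
  vals[, 1:2] <- vals[, 1:2] + 30          # atypical head markers
  vals[, 8:10] <- vals[, 8:10] - 20        # atypical tail markers
  band <- zscore_select(vals, candidate_range = 1:10)
  expect_equal(band, 3:7)
  # all markers identical: zero variance, full candidate range survives
  same <- matrix(5, 8, 10)
  expect_warning(band2 <- zscore_select(same, candidate_range = 2:8), "zero")
  expect_equal(band2, 2:8)
  expect_equal(zscore_select(vals, use_paper_bands = TRUE, which = "peak_speed"), 3:7)
  expect_equal(zscore_select(vals, use_paper_bands = TRUE, which = "height"), 2:8)
})

test_that("a straight-line body yields no extremum events", {
  n <- 300
  disp <- array(0, dim = c(n, 10, 3))
  t <- (seq_len(n) - 1) / 100
  for (m in 1:10) {
    disp[, m, 1] <- m * 8
    disp[, m, 2] <- 3 * t
  }
  ev <- detect_extrema(fake_smoothed(disp))
  expect_equal(nrow(ev), 0)
})

test_that("event times match ground-truth extremum passages within 1.5 frames", {
  tr <- reference_trial()
  k <- reference_smoothed()
  ev <- detect_extrema(k)
  ev <- refine_extrema(ev, k, cycle_frequency(events = ev))
  tru <- trajectory_truth(tr)
  fr <- tr$frame_rate_hz
  offs <- vapply(seq_len(nrow(ev)), function(r) {
    cand <- vapply(-2:25, function(m) tru$passage_time(ev$kind[r], m, ev$marker[r]),
                   numeric(1))
    min(abs(cand - ev$time_s[r])) * fr
  }, numeric(1))
  expect_gt(nrow(ev), 20)
  expect_lt(max(offs), 1.5)
  # and event positions sit on the analytic extremum paths
  pos_err <- vapply(seq_len(nrow(ev)), function(r) {
    cand <- vapply(-2:25, function(m) tru$passage_time(ev$kind[r], m, ev$marker[r]),
                   numeric(1))
    m <- (-2:25)[which.min(abs(cand - ev$time_s[r]))]
    p <- tru$position(ev$kind[r], m, ev$time_s[r])
    sqrt((p[1] - ev$x[r])^2 + (p[2] - ev$y[r])^2)
  }, numeric(1))
  expect_lt(stats::median(pos_err), 0.5)
})

test_that("extremum tracks interpolate linearly between events", {
  ev <- data.frame(marker = c(5L, 6L), frame = c(1L, 101L),
                   time_s = c(0, 1), x = c(0, 2), y = c(0, 2), z = 0,
                   kind = "crest", angle_deg = 90)
  tracks <- interpolate_extrema(ev, frequency_hz = 0.6)
  expect_length(tracks, 1)
  p <- sidewindr:::track_position(tracks[[1]], 0.5)
  expect_equal(as.numeric(p), c(1, 1))
  # three collinear-in-time events: interior reproduced by its neighbours
  ev3 <- data.frame(marker = 5:7, frame = c(1L, 51L, 101L),
                    time_s = c(0, 0.5, 1), x = c(0, 1, 2), y = c(0, 1.5, 3),
                    z = 0, kind = "crest", angle_deg = 90)
  tr3 <- interpolate_extrema(ev3, frequency_hz = 0.6)
  p3 <- sidewindr:::track_position(tr3[[1]], 0.5)
  expect_equal(as.numeric(p3), c(1, 1.5))
  # single events are dropped with a warning
  ev1 <- ev[1, ]
  expect_warning(tr1 <- interpolate_extrema(ev1, frequency_hz = 0.6), "single")
  expect_length(tr1, 0)
})

test_that("interpolated crest tracks follow the analytic crest path", {
  tr <- reference_trial()
  k <- reference_smoothed()
  ev <- detect_extrema(k)
  f <- cycle_frequency(events = ev)
  ev <- refine_extrema(ev, k, f)
  tracks <- suppressWarnings(interpolate_extrema(ev, f))
  tru <- trajectory_truth(tr)
  checked <- 0
  for (trk in tracks) {
    if (nrow(trk$events) < 3) next
    mid <- mean(trk$t_range)
    p <- sidewindr:::track_position(trk, mid)
    cand <- vapply(-2:25, function(m) {
      q <- tru$position(trk$kind, m, mid)
      sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2)
    }, numeric(1))
    expect_lt(min(cand), 0.5)
    checked <- checked + 1
  }
  expect_gt(checked, 2)
})

test_that("triangle geometry gives wavelength, amplitude and signed skew", {
  # hand-built scene: body axis +x (marker 4 head-most), two crests and the
  # trough between them; tracks are stationary
  n <- 6
  disp <- array(0, dim = c(n, 10, 3))
  disp[, 4, 1] <- 10; disp[, 9, 1] <- -10  # head-wards = +x
  k <- fake_smoothed(disp, frame_rate_hz = 2)
  mktrack <- function(kind, x, y) {
    list(kind = kind,
         events = data.frame(marker = c(5L, 6L), frame = c(1L, 3L),
                             time_s = c(0, 1), x = x, y = y, z = 0,
                             kind = kind, angle_deg = 60),
         t_range = c(0, 1), t_extended = c(-1, 4))
  }
  # symmetric case: apex over the midpoint -> skew 0, amplitude = |median|
  tracks <- list(mktrack("crest", c(0, 0), c(0, 0)),
                 mktrack("trough", c(5, 5), c(-10, -10)),
                 mktrack("crest", c(10, 10), c(0, 0)))
  g <- wave_geometry(tracks, k, eval_step = 1)
  expect_equal(g$wavelength_cm, 10, tolerance = 1e-9)
  expect_equal(g$skew_deg, 0, tolerance = 1e-9)
  expect_equal(g$amplitude_cm, 10, tolerance = 1e-9)
  # |median| = 10 tilted 60 deg head-wards: amplitude = 10 cos(60) = 5
  tracks2 <- list(mktrack("crest", c(0, 0), c(0, 0)),
                  mktrack("trough", c(10 - 10 * sin(pi / 3), 10 - 10 * sin(pi / 3)),
                          c(-5, -5)),
                  mktrack("crest", c(20, 20), c(0, 0)))
  g2 <- wave_geometry(tracks2, k, eval_step = 1)
  expect_equal(g2$amplitude_cm, 5, tolerance = 1e-9)
  expect_equal(abs(g2$skew_deg), 60, tolerance = 1e-9)
  # amplitude never exceeds the median length
  expect_lte(g2$amplitude_cm, 10 + 1e-12)
})

test_that("frequency is the reciprocal of the median period and robust", {
  mkev <- function(times) {
    data.frame(marker = 5L, frame = seq_along(times), time_s = times,
               x = 0, y = 0, z = 0, kind = "crest", angle_deg = 60)
  }
  expect_equal(cycle_frequency(events = mkev(c(0, 0.5, 1, 1.5))), 2)
  # one spurious long gap does not move the median
  expect_equal(cycle_frequency(events = mkev(c(0, 0.5, 1, 6))), 2)
  empty <- data.frame(marker = integer(0), time_s = numeric(0),
                      kind = character(0))
  expect_true(is.na(cycle_frequency(events = empty)))
})

test_that("handedness resolves the skew sign", {
  expect_equal(apply_handedness_sign(10, "right"), 10)
  expect_equal(apply_handedness_sign(10, "left"), -10)
  expect_error(apply_handedness_sign(10, "unknown"), "annotated")
})

test_that("mirrored trials give identical signed skew after correction", {
  kin <- lapply(c("right", "left"), function(h) {
    w <- wave_params(0.8, 20, 14, skew_deg = 15, lift_height_cm = 1.5,
                     duty = 0.5, handedness = h)
    gt <- trial_ground_truth(w, n_frames = 1700, noise_sd_cm = 0, seed = 31)
    suppressWarnings(extract_trial_kinematics(smooth_trial(generate_trajectory(gt))))
  })
  expect_equal(kin[[1]]$skew_deg, kin[[2]]$skew_deg, tolerance = 1e-6)
  expect_equal(kin[[1]]$skew_deg, 15, tolerance = 2)
})

test_that("wave variables are invariant under planar rigid motion", {
  tr <- reference_trial()
  k1 <- reference_smoothed()
  kin1 <- suppressWarnings(extract_trial_kinematics(k1))
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr2 <- tr
  for (m in 1:10) {
    xy <- tr$positions[, m, 1:2] %*% t(R)
    tr2$positions[, m, 1] <- xy[, 1] + 40
    tr2$positions[, m, 2] <- xy[, 2] - 17
  }
  kin2 <- suppressWarnings(extract_trial_kinematics(smooth_trial(tr2)))
  expect_equal(kin2$wavelength_cm, kin1$wavelength_cm, tolerance = 1e-6)
  expect_equal(kin2$amplitude_cm, kin1$amplitude_cm, tolerance = 1e-6)
  expect_equal(abs(kin2$skew_deg), abs(kin1$skew_deg), tolerance = 1e-6)
  expect_equal(kin2$frequency_hz, kin1$frequency_hz, tolerance = 1e-9)
  expect_equal(kin2$centroid_mean_speed, kin1$centroid_mean_speed, tolerance = 1e-6)
  expect_equal(kin2$height_lifted_mean, kin1$height_lifted_mean, tolerance = 1e-9)
})

test_that("trials too short for a wave triangle yield missing fields, not numbers", {
  w <- wave_params(0.5, 20, 14, skew_deg = 10, lift_height_cm = 1)
  gt <- trial_ground_truth(w, n_frames = 680, noise_sd_cm = 0, seed = 13)
  tr <- generate_trajectory(gt, min_cycles = 1)
  # 430 retained frames = 1.72 s < one full period at 0.5 Hz
  kin <- suppressWarnings(extract_trial_kinematics(smooth_trial(tr)))
  expect_true(is.na(kin$frequency_hz))
  expect_true(is.na(kin$wavelength_cm))
  expect_true(is.na(kin$amplitude_cm))
  expect_true(is.na(kin$skew_deg))
  expect_true(is.finite(kin$centroid_mean_speed))
  expect_true(is.finite(kin$height_lifted_mean))
})
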