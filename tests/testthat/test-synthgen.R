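test_that("wave parameters are validated", {
  expect_error(wave_params(0, 20, 16), "frequency")
  expect_error(wave_params(1, 20, 16, duty = 1), "duty")
  expect_error(wave_params(1, 20, 16, skew_deg = 95), "skew")
  expect_error(wave_params(1, 10, 16, skew_deg = 40), "too large")
  expect_error(wave_params(1, 20, 16, lift_height_cm = -1), "lift")
})

test_that("template true extrema match the requested geometry exactly", {
  for (sk in c(-10, 0, 18)) {
    w <- wave_params(1, 21, 13, skew_deg = sk)
    tpl <- sidewindr:::build_wave_template(w)
    A_true <- tpl$crest_apex[2] - tpl$trough_apex[2]
    o_true <- tpl$crest_apex[1] + tpl$lambda / 2 - tpl$trough_apex[1]
    expect_equal(A_true, 13, tolerance = 1e-8)
    expect_equal(o_true, 13 * tan(sk * pi / 180), tolerance = 1e-7)
    # triangle identity: amplitude = |median| cos(skew) by construction
    med <- sqrt(A_true^2 + o_true^2)
    expect_equal(med * cos(atan2(o_true, A_true)), A_true, tolerance = 1e-8)
  }
})

test_that("zero lift produces flat z and noise-free strides are exact", {
  w0 <- wave_params(1.25, 20, 14, skew_deg = 10, lift_height_cm = 0)
  tr0 <- generate_trajectory(trial_ground_truth(w0, n_frames = 1500,
                                                noise_sd_cm = 0, seed = 3))
  expect_true(all(tr0$positions[, , 3] == 0))

  # 1.25 Hz at 250 Hz -> one period is exactly 200 frames
  w <- wave_params(1.25, 20, 14, skew_deg = 10, lift_height_cm = 2)
  gt <- trial_ground_truth(w, n_frames = 1500, noise_sd_cm = 0, seed = 3)
  tr <- generate_trajectory(gt)
  d <- tr$positions[201, , ] - tr$positions[1, , ]
  expect_lt(max(abs(d[, 1])), 1e-9)
  expect_equal(unname(d[, 2]), rep(gt$stride_cm, 10), tolerance = 1e-9)
  expect_lt(max(abs(d[, 3])), 1e-9)
  expect_equal(gt$centroid_speed_cm_s, 1.25 * gt$stride_cm)
})

test_that("a duty fraction of the markers is in static contact", {
  for (duty in c(0.35, 0.55)) {
    w <- wave_params(0.9, 20, 14, skew_deg = 8, lift_height_cm = 1, duty = duty)
    tr <- generate_trajectory(trial_ground_truth(w, n_frames = 1500,
                                                 noise_sd_cm = 0, seed = 4))
    n <- dim(tr$positions)[1]
    dx <- tr$positions[-1, , 1] - tr$positions[-n, , 1]
    dy <- tr$positions[-1, , 2] - tr$positions[-n, , 2]
    static <- mean(sqrt(dx^2 + dy^2) < 1e-9)
    expect_lt(abs(static - duty), 0.06)
  }
})

test_that("left- and right-handed trials are exact mirror images", {
  mk <- function(h) {
    w <- wave_params(1, 20, 14, skew_deg = 12, lift_height_cm = 1.5,
                     handedness = h)
    generate_trajectory(trial_ground_truth(w, n_frames = 1200,
                                           noise_sd_cm = 0, seed = 9))
  }
  right <- mk("right"); left <- mk("left")
  expect_identical(left$positions[, , 1], -right$positions[, , 1])
  expect_identical(left$positions[, , 2], right$positions[, , 2])
  expect_identical(left$positions[, , 3], right$positions[, , 3])
})

test_that("identical seeds reproduce identical trajectories", {
  w <- wave_params(1, 20, 14, skew_deg = 5, lift_height_cm = 1)
  gt <- trial_ground_truth(w, n_frames = 900, noise_sd_cm = 0.2, seed = 21)
  a <- generate_trajectory(gt)
  b <- generate_trajectory(gt)
  expect_identical(a$positions, b$positions)
})

test_that("degenerate requests raise explicit errors", {
  w <- wave_params(0.4, 20, 14)
  gt <- trial_ground_truth(w, n_frames = 400, noise_sd_cm = 0)
  expect_error(generate_trajectory(gt), "cycles")
})

test_that("morphometrics follow the configured power laws", {
  traits <- default_morpho_traits()
  traits$resid_sd[] <- 0
  cfg <- morpho_gen_config(n_individuals = 60, traits = traits, seed = 5)
  m <- generate_morphometrics(cfg)
  # b = 1, no noise: width/SVL constant
  expect_lt(diff(range(m$width50_cm / m$svl_cm)), 1e-12)
  # b = 3, no noise: log-log OLS slope exactly 3
  slope <- unname(coef(lm(log10(m$mass_g) ~ log10(m$svl_cm)))[2])
  expect_equal(slope, 3, tolerance = 1e-10)
  expect_true(all(m$ventral_count == round(m$ventral_count)))
  expect_error(morpho_gen_config(traits = transform(traits, resid_sd = -1)),
               "resid_sd")
})

test_that("RMA recovers a configured allometric exponent", {
  traits <- default_morpho_traits()
  traits$resid_sd[traits$trait == "width50_cm"] <- 0.05
  traits$b[traits$trait == "width50_cm"] <- 1.2
  cfg <- morpho_gen_config(n_individuals = 500, traits = traits, seed = 7)
  m <- generate_morphometrics(cfg)
  fit <- rma_fit(log10(m$svl_cm), log10(m$width50_cm))
  # with residual noise on the trait only, the population RMA (major-axis)
  # slope is sqrt(b^2 + (sigma_e / sigma_x)^2), not b itself
  target <- sqrt(1.2^2 + (0.05 / cfg$svl_log10_sd)^2)
  expect_gt(target, fit$ci[1])
  expect_lt(target, fit$ci[2])
  expect_equal(fit$slope, target, tolerance = 0.05)
})

test_that("fixture sets round-trip losslessly", {
  dir <- withr::local_tempdir()
  # empty trial list: morphometrics only
  mf <- write_fixture_set(list(), morpho_gen_config(n_individuals = 8, seed = 2),
                          file.path(dir, "empty"))
  expect_length(mf$trials, 0)
  expect_true(file.exists(mf$morphometrics))
  expect_null(mf$metadata)

  gts <- lapply(1:3, function(i) {
    trial_ground_truth(wave_params(1, 20, 13, skew_deg = 6, lift_height_cm = 1),
                       n_frames = 800, noise_sd_cm = 0.1,
                       trial_id = sprintf("t%02d", i),
                       individual = sprintf("ind%02d", i), seed = i)
  })
  mf <- write_fixture_set(gts, morpho_gen_config(n_individuals = 8, seed = 2), dir)
  expect_length(mf$trials, 3)
  meta <- read_trial_metadata(mf$metadata)
  expect_equal(nrow(meta), 3)
  tr <- generate_trajectory(gts[[2]])
  rt <- read_marker_tracks(mf$trials[2])
  expect_identical(rt$positions, tr$positions)
  expect_equal(rt$frame_rate_hz, 250)
  truth <- jsonlite::read_json(mf$ground_truth)
  expect_equal(truth$t02$wavelength_cm, 20)
})
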