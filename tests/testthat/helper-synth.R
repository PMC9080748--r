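# Shared synthetic fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# a mid-sized noise-free reference trial and its smoothed kinematics
reference_trial <- function() {
  if (is.null(.fixture_cache$trial)) {
    w <- wave_params(0.8, 20, 14, skew_deg = 12, lift_height_cm = 1.75,
                     duty = 0.5, handedness = "right")
    gt <- trial_ground_truth(w, n_frames = 1800, noise_sd_cm = 0, seed = 11)
    .fixture_cache$trial <- generate_trajectory(gt)
  }
  .fixture_cache$trial
}

reference_smoothed <- function() {
  if (is.null(.fixture_cache$smoothed)) {
    .fixture_cache$smoothed <- smooth_trial(reference_trial())
  }
  .fixture_cache$smoothed
}

# build a smoothed_kinematics object directly from given arrays (for
# closed-form kinematics tests that need no filtering)
fake_smoothed <- function(disp, frame_rate_hz = 100) {
  n <- dim(disp)[1]
  dt <- 1 / frame_rate_hz
  vel <- acc <- array(0, dim(disp))
  for (m in seq_len(dim(disp)[2])) for (k in 1:3) {
    vel[, m, k] <- central_difference(disp[, m, k], dt, 1L)
    acc[, m, k] <- central_difference(disp[, m, k], dt, 2L)
  }
  structure(list(displacement = disp, velocity = vel, acceleration = acc,
                 retained_range = c(first = 0, last = n - 1),
                 time_s = (seq_len(n) - 1) * dt,
                 frame_rate_hz = frame_rate_hz, metadata = list()),
            class = "smoothed_kinematics")
}

# implied covariance of the default seven-variable speed model with chosen
# coefficients; used to simulate path-analysis data with known truth
fig_truth_sigma <- function() {
  spec <- sidewinding_path_spec()
  v <- spec$variables
  p <- length(v)
  A <- matrix(0, p, p, dimnames = list(v, v))
  A["speed", "frequency"] <- 0.9
  A["speed", "wavelength"] <- 0.15
  A["speed", "amplitude"] <- -0.15
  A["speed", "skew"] <- -0.05
  A["wavelength", "width50"] <- 0.6
  Sres <- diag(c(1, 0.64, 1, 1, 1, 1, 0.15))
  dimnames(Sres) <- list(v, v)
  Sres["frequency", "skew"] <- Sres["skew", "frequency"] <- 0.5
  Sres["amplitude", "height"] <- Sres["height", "amplitude"] <- 0.2
  B <- solve(diag(p) - A)
  Sigma <- B %*% Sres %*% t(B)
  dimnames(Sigma) <- list(v, v)
  list(Sigma = Sigma, A = A, Sres = Sres, spec = spec)
}
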