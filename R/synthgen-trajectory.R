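#' Ground truth for one synthetic sidewinding trial
#'
#' Combines wave parameters with the sampling scheme (marker placement, frame
#' rate, trial length, positional noise) and derives the quantities the wave
#' geometry implies: the arc length of one body wave, the stride (displacement
#' per cycle, fixed by wavelength, amplitude, skew, duty and the corner
#' smoothing extent) and the implied mean centroid speed
#' (frequency x stride).
#'
#' Default marker placement mirrors a 10-marker dorsal scheme: head, neck,
#' six markers evenly spaced along the trunk, cloaca, and tail tip.
#'
#' @param wave A [wave_params()] object.
#' @param n_markers Number of markers (default 10).
#' @param marker_arclengths_cm Optional body arc-length coordinate of each
#'   marker measured from the snout (cm). Default: the 10-marker scheme over
#'   `svl_cm` plus tail.
#' @param svl_cm Snout-vent length. Default: 1.7 body-wave arc lengths, so the
#'   body carries roughly 1.7 wave cycles as real sidewinders do.
#' @param tail_cm Tail length (default 15% of SVL).
#' @param frame_rate_hz Sampling rate (default 250).
#' @param n_frames Number of recorded frames (default 2500).
#' @param noise_sd_cm SD of i.i.d. Gaussian positional noise added to every
#'   coordinate (default 0.1).
#' @param contact_frac Fraction of the trough-to-crest flank occupied by the
#'   straight contact segment (default 0.7); the remainder of the cycle is a
#'   single smooth swing curve carrying both wave extrema.
#' @param trial_id,individual,sex,age_class,temperature_C Trial metadata.
#' @param seed Integer seed controlling noise and starting phase.
#' @return A list of class `trial_ground_truth`.
#' @export
trial_ground_truth <- function(wave, n_markers = 10L, marker_arclengths_cm = NULL,
                               svl_cm = NULL, tail_cm = NULL,
                               frame_rate_hz = 250, n_frames = 2500L,
                               noise_sd_cm = 0.1, contact_frac = 0.7,
                               trial_id = "trial01", individual = "ind01",
                               sex = "F", age_class = "adult",
                               temperature_C = 24, seed = 1L) {
  stopifnot(inherits(wave, "wave_params"))
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0")
  if (noise_sd_cm < 0) stop("noise_sd_cm must be >= 0")
  tpl <- build_wave_template(wave, contact_frac = contact_frac)
  if (is.null(svl_cm)) svl_cm <- 1.7 * tpl$arc_per_cycle
  if (is.null(tail_cm)) tail_cm <- 0.15 * svl_cm
  if (is.null(marker_arclengths_cm)) {
    if (n_markers != 10L) {
      marker_arclengths_cm <- seq(0, svl_cm + 0.95 * tail_cm, length.out = n_markers)
    } else {
      marker_arclengths_cm <- c(0, 0.08, seq(0.20, 0.85, length.out = 6), 1) * svl_cm
      marker_arclengths_cm <- c(marker_arclengths_cm, svl_cm + 0.95 * tail_cm)
    }
  }
  if (length(marker_arclengths_cm) != n_markers) {
    stop("marker_arclengths_cm must have length n_markers")
  }

  # per-period displacement: pattern advances one wavelength along the body
  # axis while the whole shape translates back along the contact direction
  stride_wave <- c(tpl$lambda, 0) - tpl$v1 * tpl$t1
  stride_cm <- sqrt(sum(stride_wave^2))
  # rotate the wave frame so the stride vector points along +y (travel axis)
  phi <- pi / 2 - atan2(stride_wave[2], stride_wave[1])
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  axial_ground <- drop(rot %*% c(1, 0))
  # base construction is right-handed when the trunk (which extends tail-wards,
  # i.e. along -axial from the head) lies at positive x
  base_right <- axial_ground[1] < 0
  mirror <- (wave$handedness == "right") != base_right

  gt <- list(wave = wave, n_markers = as.integer(n_markers),
             marker_arclengths_cm = marker_arclengths_cm,
             svl_cm = svl_cm, tail_cm = tail_cm,
             frame_rate_hz = frame_rate_hz, n_frames = as.integer(n_frames),
             noise_sd_cm = noise_sd_cm, seed = as.integer(seed),
             stride_cm = stride_cm,
             centroid_speed_cm_s = wave$frequency_hz * stride_cm,
             template = tpl, rot = rot, mirror = mirror,
             trial_id = trial_id, individual = individual, sex = sex,
             age_class = age_class, temperature_C = temperature_C)
  class(gt) <- "trial_ground_truth"
  gt
}

#' Generate a synthetic marker trajectory set
#'
#' Produces per-frame x, y, z positions (cm) of each marker for one trial.
#' The construction is an exactly shape-invariant traveling wave: at every
#' instant the marker polyline lies on the (rotated, translated) wave
#' template, a fraction `duty` of the body is in exactly static ground
#' contact, each marker advances by one stride along +y per cycle, vertical
#' lift peaks at `lift_height_cm` during the swing phase, and i.i.d. Gaussian
#' positional noise is added last. Left-handed trials are exact mirror images
#' (x -> -x) of right-handed ones.
#'
#' @param gt A [trial_ground_truth()] object.
#' @param min_cycles Minimum number of full cycles the trial must contain
#'   (default 3); shorter recordings raise an error.
#' @return A `marker_tracks` object: `positions`
#'   (n_frames x n_markers x 3 array, cm), `time_s`, `frame_rate_hz` and
#'   `metadata`; the ground truth is attached as attribute `"ground_truth"`.
#' @export
generate_trajectory <- function(gt, min_cycles = 3) {
  stopifnot(inherits(gt, "trial_ground_truth"))
  wave <- gt$wave
  duration <- gt$n_frames / gt$frame_rate_hz
  if (duration * wave$frequency_hz < min_cycles) {
    stop("n_frames = ", gt$n_frames, " at ", gt$frame_rate_hz,
         " Hz spans only ", round(duration * wave$frequency_hz, 2),
         " cycles; at least ", min_cycles, " full cycles are required")
  }
  set.seed(gt$seed)
  phi0 <- stats::runif(1)
  tpl <- gt$template
  tt <- (seq_len(gt$n_frames) - 1) / gt$frame_rate_hz
  pos <- array(NA_real_, dim = c(gt$n_frames, gt$n_markers, 3))
  # rigid translation cancelling the contact-flank pattern velocity
  Rx <- -wave$frequency_hz * tpl$v1 * drop(gt$rot %*% tpl$t1)
  for (i in seq_len(gt$n_markers)) {
    u <- phi0 + wave$frequency_hz * tt -
      gt$marker_arclengths_cm[i] / tpl$arc_per_cycle
    wf <- template_point(tpl, u)
    xy <- wf %*% t(gt$rot)
    pos[, i, 1] <- xy[, 1] + Rx[1] * tt
    pos[, i, 2] <- xy[, 2] + Rx[2] * tt
    pos[, i, 3] <- template_z(tpl, u, wave$lift_height_cm)
  }
  if (gt$mirror) pos[, , 1] <- -pos[, , 1]
  if (gt$noise_sd_cm > 0) {
    pos <- pos + stats::rnorm(length(pos), 0, gt$noise_sd_cm)
  }
  out <- list(positions = pos, time_s = tt, frame_rate_hz = gt$frame_rate_hz,
              metadata = list(trial_id = gt$trial_id, individual = gt$individual,
                              sex = gt$sex, age_class = gt$age_class,
                              temperature_C = gt$temperature_C,
                              handedness = wave$handedness),
              phase0 = phi0)
  class(out) <- "marker_tracks"
  attr(out, "ground_truth") <- gt
  out
}

#' Analytic extremum paths of a synthetic trial
#'
#' For a generated trial, returns the exact ground-frame paths of the wave
#' crests and troughs and the exact times at which each marker passes them.
#' In the shape-invariant construction every extremum moves at constant
#' velocity (the pattern slides along the contact direction), so these paths
#' are linear in time. Useful as an oracle when validating extraction code.
#'
#' @param tracks A `marker_tracks` object from [generate_trajectory()].
#' @return A list with `position(kind, m, t)` returning the x-y position of
#'   the m-th crest/trough at times `t`, `passage_time(kind, m, marker)`, and
#'   `active_range(kind, m)` giving the time window during which the
#'   extremum lies on the marked body section.
#' @export
trajectory_truth <- function(tracks) {
  gt <- attr(tracks, "ground_truth")
  if (is.null(gt)) stop("tracks carry no ground-truth attribute")
  tpl <- gt$template
  wave <- gt$wave
  f <- wave$frequency_hz
  phi0 <- tracks$phase0
  u_apex <- c(crest = tpl$duty + (1 - tpl$duty) * tpl$tau_crest,
              trough = tpl$duty + (1 - tpl$duty) * tpl$tau_trough)
  Rx <- -f * tpl$v1 * drop(gt$rot %*% tpl$t1)
  position <- function(kind, m, t) {
    base <- drop(gt$rot %*% drop(template_point(tpl, u_apex[[kind]] + m)))
    xy <- cbind(base[1] + Rx[1] * t, base[2] + Rx[2] * t)
    if (gt$mirror) xy[, 1] <- -xy[, 1]
    xy
  }
  passage_time <- function(kind, m, marker) {
    s <- gt$marker_arclengths_cm[marker]
    (u_apex[[kind]] + m - phi0 + s / tpl$arc_per_cycle) / f
  }
  active_range <- function(kind, m) {
    smax <- max(gt$marker_arclengths_cm)
    c(from = (u_apex[[kind]] + m - phi0) / f,
      to = (u_apex[[kind]] + m - phi0 + smax / tpl$arc_per_cycle) / f)
  }
  list(u_apex = u_apex, position = position, passage_time = passage_time,
       active_range = active_range)
}
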