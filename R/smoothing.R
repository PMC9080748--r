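#' Savitzky-Golay smoothing of a 1-D series
#'
#' Applies a local-polynomial (Savitzky-Golay) filter with uniform weights one
#' or more times in sequence. Output length equals input length; edge frames
#' are handled by polynomial fits on the truncated end windows (they are
#' normally discarded later by edge trimming, see [smooth_trial()]).
#'
#' @param x Numeric vector.
#' @param order Polynomial order of the local regression (default 4).
#' @param span Window length in frames; must be odd and greater than `order`
#'   (default 143).
#' @param passes Number of sequential applications of the filter (default 1).
#' @return Numeric vector of the same length as `x`.
#' @export
sgolay_smooth <- function(x, order = 4L, span = 143L, passes = 1L) {
  stopifnot(is.numeric(x), passes >= 1L)
  if (span %% 2L != 1L) stop("`span` must be odd, got ", span)
  if (span <= order) stop("`span` (", span, ") must exceed `order` (", order, ")")
  if (length(x) < span) {
    stop("series has ", length(x), " frames but the filter span requires at least ",
         span, " frames")
  }
  for (i in seq_len(passes)) {
    x <- as.numeric(signal::sgolayfilt(x, p = order, n = span))
  }
  x
}

#' Central finite differences
#'
#' First- or second-order central differences of a uniformly sampled series.
#' Interior points use `(x[i+1] - x[i-1]) / (2 dt)` or
#' `(x[i+1] - 2 x[i] + x[i-1]) / dt^2`; endpoints use one-sided formulas of
#' the matching derivative order (exact for polynomials up to degree 2).
#'
#' @param x Numeric vector (length >= 3 for order 1, >= 4 for order 2).
#' @param dt Sampling interval in seconds (> 0).
#' @param order Derivative order, 1 (velocity) or 2 (acceleration).
#' @return Numeric vector, same length as `x`.
#' @export
central_difference <- function(x, dt, order = 1L) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("`dt` must be a positive scalar")
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2")
  n <- length(x)
  if (n < 3L + (order == 2L)) stop("series too short for central differences")
  d <- numeric(n)
  i <- 2:(n - 1)
  if (order == 1L) {
    d[i] <- (x[i + 1] - x[i - 1]) / (2 * dt)
    d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
    d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  } else {
    d[i] <- (x[i + 1] - 2 * x[i] + x[i - 1]) / dt^2
    d[1] <- (2 * x[1] - 5 * x[2] + 4 * x[3] - x[4]) / dt^2
    d[n] <- (2 * x[n] - 5 * x[n - 1] + 4 * x[n - 2] - x[n - 3]) / dt^2
  }
  d
}

#' Smoothing and trimming configuration
#'
#' Defaults follow the processing applied to 250 Hz digitized video: span-143
#' order-4 Savitzky-Golay, 3 passes on displacement and 1 pass on each
#' derivative, with 150 leading and 100 trailing frames dropped to remove
#' edge effects.
#'
#' @param order,span Savitzky-Golay polynomial order and window span.
#' @param passes_displacement,passes_derivative Number of filter passes
#'   applied to displacement and to velocity/acceleration.
#' @param trim_head,trim_tail Frames dropped at the start/end of each trial.
#' @return A list of class `smoothing_config`.
#' @export
smoothing_config <- function(order = 4L, span = 143L, passes_displacement = 3L,
                             passes_derivative = 1L, trim_head = 150L,
                             trim_tail = 100L) {
  cfg <- list(order = as.integer(order), span = as.integer(span),
              passes_displacement = as.integer(passes_displacement),
              passes_derivative = as.integer(passes_derivative),
              trim_head = as.integer(trim_head), trim_tail = as.integer(trim_tail))
  stopifnot(cfg$trim_head >= 0L, cfg$trim_tail >= 0L)
  class(cfg) <- "smoothing_config"
  cfg
}

#' Smooth a trial and compute velocity and acceleration
#'
#' Per marker and coordinate: multi-pass Savitzky-Golay smoothing of
#' displacement, first- and second-order central differences for velocity and
#' acceleration, single-pass smoothing of both derivatives, then removal of
#' the leading/trailing edge frames from all three arrays.
#'
#' @param tracks A `marker_tracks` object (see [generate_trajectory()] /
#'   [read_marker_tracks()]).
#' @param cfg A [smoothing_config()].
#' @return A `smoothed_kinematics` object: arrays `displacement`, `velocity`
#'   (cm/s) and `acceleration` (cm/s^2) of dimension
#'   retained_frames x n_markers x 3, the retained frame index range
#'   (0-based, relative to the original recording), `time_s`, `frame_rate_hz`
#'   and the trial metadata.
#' @export
smooth_trial <- function(tracks, cfg = smoothing_config()) {
  stopifnot(inherits(tracks, "marker_tracks"))
  pos <- tracks$positions
  n <- dim(pos)[1]
  trim <- cfg$trim_head + cfg$trim_tail
  if (n <= trim + cfg$span) {
    stop("trial has ", n, " frames; need more than trim_head + trim_tail + span = ",
         trim + cfg$span, " to retain a usable window")
  }
  dt <- 1 / tracks$frame_rate_hz
  disp <- vel <- acc <- array(NA_real_, dim = dim(pos))
  for (m in seq_len(dim(pos)[2])) {
    for (k in 1:3) {
      d <- sgolay_smooth(pos[, m, k], cfg$order, cfg$span, cfg$passes_displacement)
      v <- sgolay_smooth(central_difference(d, dt, 1L), cfg$order, cfg$span,
                         cfg$passes_derivative)
      a <- sgolay_smooth(central_difference(d, dt, 2L), cfg$order, cfg$span,
                         cfg$passes_derivative)
      disp[, m, k] <- d
      vel[, m, k] <- v
      acc[, m, k] <- a
    }
  }
  keep <- (cfg$trim_head + 1L):(n - cfg$trim_tail)
  out <- list(
    displacement = disp[keep, , , drop = FALSE],
    velocity = vel[keep, , , drop = FALSE],
    acceleration = acc[keep, , , drop = FALSE],
    retained_range = c(first = cfg$trim_head, last = n - cfg$trim_tail - 1L),
    time_s = tracks$time_s[keep],
    frame_rate_hz = tracks$frame_rate_hz,
    metadata = tracks$metadata
  )
  class(out) <- "smoothed_kinematics"
  out
}
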