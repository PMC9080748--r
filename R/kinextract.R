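#' Whole-animal (centroid) speed and acceleration
#'
#' The centroid of all markers approximates the center of mass. Centroid
#' displacement is the per-frame mean of the smoothed marker positions;
#' velocity comes from a first-order central difference, acceleration from a
#' second-order central difference of centroid displacement; speed and
#' acceleration magnitudes are vector norms.
#'
#' @param k A `smoothed_kinematics` object from [smooth_trial()].
#' @return A list with `mean_speed`, `peak_speed` (cm/s), `mean_accel`,
#'   `peak_accel` (cm/s^2).
#' @export
centroid_kinematics <- function(k) {
  stopifnot(inherits(k, "smoothed_kinematics"))
  if (anyNA(k$displacement)) {
    stop("centroid kinematics require all markers at all retained frames; ",
         "input contains missing values")
  }
  cen <- apply(k$displacement, c(1, 3), mean)
  dt <- 1 / k$frame_rate_hz
  vel <- apply(cen, 2, central_difference, dt = dt, order = 1L)
  acc <- apply(cen, 2, central_difference, dt = dt, order = 2L)
  speed <- sqrt(rowSums(vel^2))
  amag <- sqrt(rowSums(acc^2))
  list(mean_speed = mean(speed), peak_speed = max(speed),
       mean_accel = mean(amag), peak_accel = max(amag))
}

#' Per-marker peak speed and height lifted
#'
#' @param k A `smoothed_kinematics` object.
#' @return Data frame with one row per marker: `marker`, `peak_speed` (cm/s,
#'   max of the 3-D velocity norm) and `max_height` (cm, maximum z above the
#'   marker's own trial minimum, taken as the substrate baseline).
#' @export
marker_summaries <- function(k) {
  stopifnot(inherits(k, "smoothed_kinematics"))
  n_m <- dim(k$displacement)[2]
  if (dim(k$displacement)[1] < 1) stop("empty retained window")
  peak_speed <- vapply(seq_len(n_m), function(m) {
    max(sqrt(rowSums(k$velocity[, m, , drop = FALSE]^2)))
  }, numeric(1))
  max_height <- vapply(seq_len(n_m), function(m) {
    z <- k$displacement[, m, 3]
    max(z) - min(z)
  }, numeric(1))
  data.frame(marker = seq_len(n_m), peak_speed = peak_speed,
             max_height = max_height)
}

#' Select the marker band closest to the trial mean by z-scores
#'
#' For each trial the per-marker values are replaced by z-scores; a marker's
#' typicality is its mean |z| across trials. Returns the longest contiguous
#' marker band inside `candidate_range` whose mean of mean-|z| lies within
#' `tol_frac` of the best achievable band score (sampling noise would
#' otherwise almost always hand the win to a single marker); exact ties go to
#' the band starting closest to the head. With `use_paper_bands = TRUE` the
#' fixed bands 3-7 (peak speed) or 2-8 (height lifted) are returned instead.
#'
#' @param values Numeric matrix, trials in rows, markers in columns.
#' @param candidate_range Integer vector of marker indices to consider.
#' @param use_paper_bands If `TRUE`, bypass the search and return the fixed
#'   band given by `which`.
#' @param which `"peak_speed"` or `"height"`; used only with fixed bands.
#' @param tol_frac Bands scoring within this fraction of the across-marker
#'   |z| spread above the minimum count as equivalent (default 0.05).
#' @return Integer vector of selected marker indices.
#' @export
zscore_select <- function(values, candidate_range = seq_len(ncol(values)),
                          use_paper_bands = FALSE,
                          which = c("peak_speed", "height"),
                          tol_frac = 0.05) {
  which <- match.arg(which)
  if (use_paper_bands) return(if (which == "peak_speed") 3:7 else 2:8)
  stopifnot(is.matrix(values), ncol(values) >= 2, nrow(values) >= 1)
  degenerate <- FALSE
  z <- t(apply(values, 1, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      degenerate <<- TRUE
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }))
  if (degenerate) {
    warning("trial(s) with zero across-marker variance; z-scores set to 0")
  }
  mz <- colMeans(abs(z))
  bands <- list(); scores <- numeric(0)
  for (i in seq_along(candidate_range)) {
    for (j in i:length(candidate_range)) {
      band <- candidate_range[i:j]
      if (any(diff(band) != 1)) next
      bands[[length(bands) + 1]] <- band
      scores <- c(scores, mean(mz[band]))
    }
  }
  tol <- tol_frac * max(diff(range(mz)), 1e-12)
  ok <- which(scores <= min(scores) + tol)
  lens <- lengths(bands[ok])
  pick <- ok[lens == max(lens)]
  if (length(pick) > 1) pick <- pick[which.min(vapply(bands[pick], min, 1L))]
  bands[[pick]]
}

# local minima of a series with a prominence threshold
find_local_minima <- function(x, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    maxl <- -Inf
    j <- i - 1L
    while (j >= 1L && x[j] >= x[i]) { maxl <- max(maxl, x[j]); j <- j - 1L }
    if (j < 1L) maxl <- max(maxl, max(x[1:i]))
    maxr <- -Inf
    j <- i + 1L
    while (j <= n && x[j] >= x[i]) { maxr <- max(maxr, x[j]); j <- j + 1L }
    if (j > n) maxr <- max(maxr, max(x[i:n]))
    keep[k] <- (min(maxl, maxr) - x[i]) >= min_prom
  }
  cand[keep]
}

#' Detect wave extremum passages from three-point angles
#'
#' For each interior marker of the band, the planar angle formed with its two
#' body neighbours is computed at every frame; temporal local minima of the
#' angle series (with a prominence threshold to suppress noise) mark the
#' instants at which the marker sits at a wave extremum. The extremum kind
#' (crest vs trough) is assigned from the sign of the planar cross product of
#' the two segment vectors; which sign is called "crest" is a fixed
#' convention, so the sign of the downstream skew angle is resolved by
#' [apply_handedness_sign()].
#'
#' @param k A `smoothed_kinematics` object.
#' @param markers Marker band used for waveform extraction (default 4:9);
#'   events are produced for the band's interior markers.
#' @param min_prominence_deg Minimum prominence of an angle minimum, in
#'   degrees (default 5).
#' @return Data frame of events: `marker`, `frame` (index into the retained
#'   window), `time_s`, `x`, `y`, `z`, `kind`, `angle_deg`.
#' @export
detect_extrema <- function(k, markers = 4:9, min_prominence_deg = 5) {
  stopifnot(inherits(k, "smoothed_kinematics"))
  markers <- sort(markers)
  if (length(markers) < 3 || any(diff(markers) != 1)) {
    stop("need at least 3 consecutive markers")
  }
  interior <- markers[-c(1, length(markers))]
  prom <- min_prominence_deg * pi / 180
  ev <- list()
  for (m in interior) {
    p0 <- k$displacement[, m - 1, 1:2]
    p1 <- k$displacement[, m, 1:2]
    p2 <- k$displacement[, m + 1, 1:2]
    u <- p0 - p1
    v <- p2 - p1
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    ang <- acos(cosang)
    idx <- find_local_minima(ang, prom)
    if (!length(idx)) next
    w1 <- p1[idx, , drop = FALSE] - p0[idx, , drop = FALSE]
    w2 <- p2[idx, , drop = FALSE] - p1[idx, , drop = FALSE]
    cz <- w1[, 1] * w2[, 2] - w1[, 2] * w2[, 1]
    ev[[length(ev) + 1]] <- data.frame(
      marker = m, frame = idx, time_s = k$time_s[idx],
      x = k$displacement[idx, m, 1], y = k$displacement[idx, m, 2],
      z = k$displacement[idx, m, 3],
      kind = ifelse(cz > 0, "crest", "trough"),
      angle_deg = ang[idx] * 180 / pi)
  }
  if (!length(ev)) {
    return(data.frame(marker = integer(0), frame = integer(0),
                      time_s = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), kind = character(0),
                      angle_deg = numeric(0)))
  }
  out <- do.call(rbind, ev)
  out[order(out$time_s, out$marker), ]
}

#' Refine extremum event timing by detrended lateral excursion
#'
#' An angle minimum marks the instant the middle marker is most sharply bent
#' relative to its neighbours; on a skewed wave that instant is slightly
#' offset from the true apex passage (the body tangent there parallels the
#' tilted neighbour chord, not the wave axis), which biases the skew angle
#' away from zero. Because the body wave is shape-invariant in steady-state
#' sidewinding, a marker sits exactly on a lateral apex when its lateral
#' excursion, detrended by the whole-animal lateral drift, is locally
#' extremal. For each detected event this function relocates the event to that
#' nearby lateral extremum (crests to the local maximum, troughs to the local
#' minimum, searched within a quarter period) and updates the event position.
#'
#' @param events Event table from [detect_extrema()].
#' @param k The `smoothed_kinematics` object the events came from.
#' @param frequency_hz Cycle frequency estimate (see [cycle_frequency()]).
#' @param markers Marker band (default 4:9), used for the body-axis direction.
#' @return The event table with refined `frame`, `time_s`, `x`, `y`, `z`.
#' @export
refine_extrema <- function(events, k, frequency_hz, markers = 4:9) {
  if (!nrow(events) || is.na(frequency_hz) || frequency_hz <= 0) return(events)
  n <- dim(k$displacement)[1]
  mhead <- min(markers); mtail <- max(markers)
  # trial-mean body axis: per-frame estimates wobble within a cycle
  hx <- mean(k$displacement[, mhead, 1] - k$displacement[, mtail, 1])
  hy <- mean(k$displacement[, mhead, 2] - k$displacement[, mtail, 2])
  hn <- sqrt(hx^2 + hy^2)
  hx <- hx / hn; hy <- hy / hn
  # lateral drift rate of the whole animal (centroid), projected per frame
  cen_x <- rowMeans(k$displacement[, , 1])
  cen_y <- rowMeans(k$displacement[, , 2])
  span <- k$time_s[n] - k$time_s[1]
  vbar <- c(cen_x[n] - cen_x[1], cen_y[n] - cen_y[1]) / span
  half <- max(2L, round(0.25 / frequency_hz * k$frame_rate_hz))
  for (r in seq_len(nrow(events))) {
    m <- events$marker[r]
    i0 <- max(1L, events$frame[r] - half)
    i1 <- min(n, events$frame[r] + half)
    idx <- i0:i1
    eta <- -(k$displacement[idx, m, 1] - vbar[1] * k$time_s[idx]) * hy +
      (k$displacement[idx, m, 2] - vbar[2] * k$time_s[idx]) * hx
    # nearest lateral extremum (max or min) to the angle-minimum instant;
    # a hit on the window edge means no local extremum was found: keep as is
    jmax <- idx[which.max(eta)]; jmin <- idx[which.min(eta)]
    cand <- c(jmax, jmin)
    cand <- cand[cand != i0 & cand != i1]
    if (!length(cand)) next
    j <- cand[which.min(abs(cand - events$frame[r]))]
    events$frame[r] <- j
    events$time_s[r] <- k$time_s[j]
    events$x[r] <- k$displacement[j, m, 1]
    events$y[r] <- k$displacement[j, m, 2]
    events$z[r] <- k$displacement[j, m, 3]
  }
  events
}

#' Wave frequency from extremum passage periods
#'
#' For each marker, the periods are the time gaps between successive
#' same-kind extremum events; the trial frequency is the reciprocal of the
#' median of all pooled periods (robust to occasional spurious events).
#'
#' @param k A `smoothed_kinematics` object (used when `events` is `NULL`).
#' @param markers Marker band (default 4:9).
#' @param events Optional precomputed event table from [detect_extrema()].
#' @return Frequency in Hz, or `NA` if fewer than two same-kind events exist
#'   on every marker.
#' @export
cycle_frequency <- function(k = NULL, markers = 4:9, events = NULL) {
  if (is.null(events)) events <- detect_extrema(k, markers)
  periods <- numeric(0)
  for (m in unique(events$marker)) {
    for (kk in c("crest", "trough")) {
      tt <- sort(events$time_s[events$marker == m & events$kind == kk])
      if (length(tt) >= 2) periods <- c(periods, diff(tt))
    }
  }
  if (!length(periods)) return(NA_real_)
  1 / stats::median(periods)
}

#' Chain extremum events into continuous tracks
#'
#' Events belonging to the same physical wave extremum are chained across
#' markers: the wave travels head to tail, so an extremum passes marker m
#' before marker m+1, with a lag well under one period. Chained events are
#' linearly interpolated in time to estimate the extremum's planar position
#' at every frame it spans; outside the observed span the track's
#' least-squares line is extended by up to `extend_periods` cycles (sound
#' under the steady-state assumption, where extremum paths are linear in
#' time). Chains with a single event cannot be interpolated and are dropped
#' with a warning.
#'
#' @param events Event table from [detect_extrema()].
#' @param frequency_hz Cycle frequency (used to bound chaining lags and the
#'   extrapolation window); estimate it first with [cycle_frequency()].
#' @param extend_periods How far beyond the observed events a track may be
#'   linearly extended, in cycles (default 0.75).
#' @return List of tracks; each has `kind`, `events`, `t_range` and
#'   `t_extended`.
#' @export
interpolate_extrema <- function(events, frequency_hz, extend_periods = 0.75) {
  if (is.na(frequency_hz) || frequency_hz <= 0) return(list())
  period <- 1 / frequency_hz
  tracks <- list()
  for (kk in c("crest", "trough")) {
    sub <- events[events$kind == kk, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$marker, sub$time_s), ]
    chains <- list()  # each: list(markers, times, idx into sub)
    for (r in seq_len(nrow(sub))) {
      m <- sub$marker[r]; tmv <- sub$time_s[r]
      best <- NULL; best_gap <- Inf
      for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        lm_ <- ch$markers[length(ch$markers)]
        lt <- ch$times[length(ch$times)]
        if (lm_ >= m) next
        gap <- tmv - lt
        lim <- (m - lm_) * 0.7 * period
        if (gap > 0 && gap < lim && gap < best_gap) {
          best <- ci; best_gap <- gap
        }
      }
      if (is.null(best)) {
        chains[[length(chains) + 1]] <- list(markers = m, times = tmv, rows = r)
      } else {
        ch <- chains[[best]]
        chains[[best]] <- list(markers = c(ch$markers, m),
                               times = c(ch$times, tmv), rows = c(ch$rows, r))
      }
    }
    for (ch in chains) {
      if (length(ch$rows) < 2) {
        warning("dropping unchainable single ", kk, " event at marker ",
                sub$marker[ch$rows], call. = FALSE)
        next
      }
      ev <- sub[ch$rows, ]
      tr <- list(kind = kk, events = ev,
                 t_range = range(ev$time_s),
                 t_extended = range(ev$time_s) +
                   c(-1, 1) * extend_periods * period)
      tracks[[length(tracks) + 1]] <- tr
    }
  }
  tracks
}

# planar position of a track at times t: piecewise-linear between events,
# least-squares linear extension outside the observed span
track_position <- function(track, t) {
  ev <- track$events
  if (nrow(ev) == 2 || stats::var(ev$time_s) == 0) {
    fitx <- stats::lm.fit(cbind(1, ev$time_s), ev$x)$coefficients
    fity <- stats::lm.fit(cbind(1, ev$time_s), ev$y)$coefficients
    return(cbind(fitx[1] + fitx[2] * t, fity[1] + fity[2] * t))
  }
  x <- stats::approx(ev$time_s, ev$x, xout = t, rule = 1)$y
  y <- stats::approx(ev$time_s, ev$y, xout = t, rule = 1)$y
  out <- which(t < ev$time_s[1] | t > ev$time_s[nrow(ev)])
  if (length(out)) {
    fitx <- stats::lm.fit(cbind(1, ev$time_s), ev$x)$coefficients
    fity <- stats::lm.fit(cbind(1, ev$time_s), ev$y)$coefficients
    x[out] <- fitx[1] + fitx[2] * t[out]
    y[out] <- fity[1] + fity[2] * t[out]
  }
  cbind(x, y)
}

#' Wavelength, amplitude and skew angle from extremum tracks
#'
#' At each evaluated frame, extrema are ordered along the body axis (the
#' head-wards direction estimated from the marker polyline). Every pair of
#' successive same-kind extrema with exactly one opposite-kind extremum
#' between them forms a triangle: wavelength is the distance between the
#' same-kind pair, the median runs from the pair's midpoint to the opposite
#' extremum, the skew angle is the signed angle between the median and the
#' perpendicular of the pair line (positive = tilted head-wards under the
#' fixed crest convention; see [apply_handedness_sign()]), and the
#' peak-to-peak amplitude is the median length times the cosine of the skew.
#' Trial values are means over all triangles and evaluated frames.
#'
#' @param tracks Track list from [interpolate_extrema()].
#' @param k The `smoothed_kinematics` object (for the body-axis direction).
#' @param markers Marker band used for the body axis (default 4:9).
#' @param eval_step Evaluate every `eval_step`-th retained frame (default 5).
#' @return A list with trial means `wavelength_cm`, `amplitude_cm`,
#'   `skew_deg` (all `NA` if no complete triangle exists), `n_samples`, and
#'   the per-sample table `samples`.
#' @export
wave_geometry <- function(tracks, k, markers = 4:9, eval_step = 5L) {
  empty <- list(wavelength_cm = NA_real_, amplitude_cm = NA_real_,
                skew_deg = NA_real_, n_samples = 0L, samples = NULL)
  if (!length(tracks)) return(empty)
  times <- k$time_s[seq(1, length(k$time_s), by = eval_step)]
  frames <- seq(1, length(k$time_s), by = eval_step)
  # head-wards unit vector per evaluated frame, from the marker polyline
  mhead <- min(markers); mtail <- max(markers)
  hx <- k$displacement[frames, mhead, 1] - k$displacement[frames, mtail, 1]
  hy <- k$displacement[frames, mhead, 2] - k$displacement[frames, mtail, 2]
  hn <- sqrt(hx^2 + hy^2)
  hx <- hx / hn; hy <- hy / hn
  # precompute track positions on the evaluated grid
  act <- lapply(tracks, function(tr) {
    inside <- times >= tr$t_extended[1] & times <= tr$t_extended[2]
    pos <- matrix(NA_real_, length(times), 2)
    if (any(inside)) pos[inside, ] <- track_position(tr, times[inside])
    list(kind = tr$kind, pos = pos, inside = inside)
  })
  samples <- list()
  for (i in seq_along(times)) {
    live <- Filter(function(a) a$inside[i], act)
    if (length(live) < 3) next
    kind <- vapply(live, `[[`, character(1), "kind")
    px <- vapply(live, function(a) a$pos[i, 1], numeric(1))
    py <- vapply(live, function(a) a$pos[i, 2], numeric(1))
    proj <- px * hx[i] + py * hy[i]
    o <- order(proj)
    kind <- kind[o]; px <- px[o]; py <- py[o]
    for (j in seq_len(length(kind) - 2)) {
      if (kind[j] != kind[j + 2] || kind[j + 1] == kind[j]) next
      p1 <- c(px[j], py[j]); q <- c(px[j + 1], py[j + 1])
      p2 <- c(px[j + 2], py[j + 2])
      b <- p2 - p1                      # head-wards along the pair line
      wl <- sqrt(sum(b^2))
      bh <- b / wl
      med <- q - (p1 + p2) / 2
      np <- c(-bh[2], bh[1])            # perpendicular of the pair line
      # orient the perpendicular towards the crest side and the median
      # "upwards" (trough -> crest): labels come from the opposite extremum
      side <- sum(med * np)
      if (kind[j + 1] == "crest") {
        if (side < 0) np <- -np
        m_up <- med
      } else {
        if (side > 0) np <- -np
        m_up <- -med
      }
      skew <- atan2(sum(m_up * bh), sum(m_up * np))
      samples[[length(samples) + 1]] <- data.frame(
        time_s = times[i], wavelength_cm = wl,
        amplitude_cm = sqrt(sum(med^2)) * cos(skew),
        skew_deg = skew * 180 / pi)
    }
  }
  if (!length(samples)) return(empty)
  s <- do.call(rbind, samples)
  list(wavelength_cm = mean(s$wavelength_cm),
       amplitude_cm = mean(s$amplitude_cm),
       skew_deg = mean(s$skew_deg), n_samples = nrow(s), samples = s)
}

#' Resolve the sign of the skew angle using trial handedness
#'
#' Sidewinding is an asymmetrical gait: the extraction code cannot tell
#' left- from right-handed trials, so the raw skew angle sign is only
#' consistent within a handedness class. Right-handed trials are returned
#' unchanged; left-handed trials are negated, so that positive always means a
#' head-wards tilt.
#'
#' @param skew_deg Raw signed skew angle(s).
#' @param handedness `"left"` or `"right"` (vector recycled as needed).
#' @return Corrected skew angle(s).
#' @export
apply_handedness_sign <- function(skew_deg, handedness) {
  if (any(!handedness %in% c("left", "right"))) {
    stop("handedness must be annotated as \"left\" or \"right\" for every trial")
  }
  ifelse(handedness == "left", -skew_deg, skew_deg)
}

#' Extract the full set of per-trial kinematic variables
#'
#' Runs centroid kinematics, marker summaries over the peak-speed and height
#' bands, extremum detection, frequency estimation and wave geometry, and
#' resolves the skew sign from the annotated handedness. Wave variables that
#' cannot be computed (trial too short for a complete extremum triangle) are
#' reported as `NA`, never fabricated.
#'
#' @param k A `smoothed_kinematics` object.
#' @param speed_band Markers averaged for peak speed (default 3:7).
#' @param height_band Markers averaged for height lifted (default 2:8).
#' @param wave_band Markers used for waveform extraction (default 4:9).
#' @param min_prominence_deg Angle-minimum prominence threshold (degrees).
#' @param eval_step Frame subsampling for wave geometry (default 5).
#' @return One-row data frame with the trial's kinematic variables.
#' @export
extract_trial_kinematics <- function(k, speed_band = 3:7, height_band = 2:8,
                                     wave_band = 4:9, min_prominence_deg = 5,
                                     eval_step = 5L) {
  cen <- centroid_kinematics(k)
  ms <- marker_summaries(k)
  events <- detect_extrema(k, wave_band, min_prominence_deg)
  freq <- cycle_frequency(events = events, markers = wave_band)
  geom <- if (is.na(freq)) {
    list(wavelength_cm = NA_real_, amplitude_cm = NA_real_, skew_deg = NA_real_)
  } else {
    events <- refine_extrema(events, k, freq, wave_band)
    tracks <- interpolate_extrema(events, freq)
    wave_geometry(tracks, k, wave_band, eval_step)
  }
  hand <- k$metadata$handedness
  skew <- if (is.null(hand) || is.na(geom$skew_deg)) {
    geom$skew_deg
  } else {
    apply_handedness_sign(geom$skew_deg, hand)
  }
  data.frame(
    trial_id = if (!is.null(k$metadata$trial_id)) k$metadata$trial_id else NA,
    individual = if (!is.null(k$metadata$individual)) k$metadata$individual else NA,
    centroid_mean_speed = cen$mean_speed,
    centroid_peak_speed = cen$peak_speed,
    centroid_mean_accel = cen$mean_accel,
    centroid_peak_accel = cen$peak_accel,
    marker_peak_speed_mean = mean(ms$peak_speed[speed_band]),
    height_lifted_mean = mean(ms$max_height[height_band]),
    frequency_hz = freq,
    wavelength_cm = geom$wavelength_cm,
    amplitude_cm = geom$amplitude_cm,
    skew_deg = skew,
    handedness = if (is.null(hand)) NA_character_ else hand,
    stringsAsFactors = FALSE)
}
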