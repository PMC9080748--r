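#' Wave parameters for a synthetic sidewinding trial
#'
#' Describes the body wave of a sidewinding bout: temporal frequency, planar
#' wave geometry (crest-to-crest wavelength, peak-to-peak amplitude, signed
#' skew angle with positive = tilted head-wards), maximum vertical lift, the
#' fraction of each cycle a body section spends in static ground contact, and
#' the handedness of the gait (whether the trunk lies left or right of the
#' head).
#'
#' @param frequency_hz Cycle frequency in Hz (> 0).
#' @param wavelength_cm Distance between successive crests in cm (> 0).
#' @param amplitude_cm Peak-to-peak lateral amplitude in cm (> 0).
#' @param skew_deg Signed skew angle in degrees, in (-90, 90).
#' @param lift_height_cm Maximum vertical marker excursion in cm (>= 0).
#' @param duty Fraction of a cycle in static contact, in (0, 1).
#' @param handedness `"left"` or `"right"`.
#' @return A list of class `wave_params`.
#' @export
wave_params <- function(frequency_hz, wavelength_cm, amplitude_cm, skew_deg = 0,
                        lift_height_cm = 0, duty = 0.5, handedness = "right") {
  if (!is.numeric(frequency_hz) || frequency_hz <= 0) stop("frequency_hz must be > 0")
  if (!is.numeric(wavelength_cm) || wavelength_cm <= 0) stop("wavelength_cm must be > 0")
  if (!is.numeric(amplitude_cm) || amplitude_cm <= 0) stop("amplitude_cm must be > 0")
  if (abs(skew_deg) >= 90) stop("skew_deg must lie strictly between -90 and 90")
  if (lift_height_cm < 0) stop("lift_height_cm must be >= 0")
  if (duty <= 0 || duty >= 1) stop("duty must lie strictly between 0 and 1")
  handedness <- match.arg(handedness, c("left", "right"))
  if (abs(amplitude_cm * tan(skew_deg * pi / 180)) >= wavelength_cm / 2) {
    stop("skew angle too large: |amplitude * tan(skew)| must be < wavelength / 2")
  }
  structure(list(frequency_hz = frequency_hz, wavelength_cm = wavelength_cm,
                 amplitude_cm = amplitude_cm, skew_deg = skew_deg,
                 lift_height_cm = lift_height_cm, duty = duty,
                 handedness = handedness),
            class = "wave_params")
}

# cubic Bezier position for 2-column control matrix P (4 x 2), vectorized tau
bezier3_point <- function(P, tau) {
  b <- cbind((1 - tau)^3, 3 * tau * (1 - tau)^2, 3 * tau^2 * (1 - tau), tau^3)
  b %*% P
}

# cubic Bezier derivative d/dtau
bezier3_deriv <- function(P, tau) {
  d <- 3 * rbind(P[2, ] - P[1, ], P[3, ] - P[2, ], P[4, ] - P[3, ])
  b <- cbind((1 - tau)^2, 2 * tau * (1 - tau), tau^2)
  b %*% d
}

# roots of the lateral derivative of a cubic Bezier inside (0, 1)
bezier3_lateral_extrema <- function(P) {
  d <- 3 * c(P[2, 2] - P[1, 2], P[3, 2] - P[2, 2], P[4, 2] - P[3, 2])
  # l'(tau) = d1 (1-t)^2 + 2 d2 t(1-t) + d3 t^2
  a <- d[1] - 2 * d[2] + d[3]
  b <- 2 * (d[2] - d[1])
  cc <- d[1]
  if (abs(a) < 1e-12 * max(abs(d), 1)) {
    if (abs(b) < 1e-15) return(numeric(0))
    r <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(numeric(0))
    r <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  sort(r[r > 1e-9 & r < 1 - 1e-9])
}

# Internal: build the periodic C1 wave template in the wave frame.
#
# Frame: axial coordinate a (+a = head-wards), lateral coordinate l. One cycle
# is a straight contact flank running from near the trough corner up to near
# the crest corner (u in [0, duty], uniform speed) followed by a single cubic
# Bezier swing (u in [duty, 1]) that carries the body over the crest, down
# past the trough and back to the start of the next contact segment, with
# matching tangent direction and speed at both junctions. Both true lateral
# extrema of the wave therefore lie inside the smooth swing; the corner
# geometry (Ac, delta) is adjusted by fixed-point iteration so the true
# extrema reproduce the requested peak-to-peak amplitude and skew exactly,
# while crest spacing equals the wavelength by periodicity.
#
# `contact_frac` is the fraction of the trough-to-crest flank occupied by the
# straight contact segment.
build_wave_template <- function(wave, contact_frac = 0.7, smooth_cm = NULL) {
  lam <- wave$wavelength_cm
  A_req <- wave$amplitude_cm
  th <- wave$skew_deg * pi / 180
  d <- wave$duty
  o_req <- A_req * tan(th)
  if (!is.null(smooth_cm)) {
    # back-compatible knob: cap extent in cm on each flank end
    l1_0 <- sqrt((lam / 2 + o_req)^2 + A_req^2)
    contact_frac <- max(0.2, 1 - 2 * smooth_cm / l1_0)
  }
  if (contact_frac <= 0.05 || contact_frac >= 0.98) {
    stop("contact_frac must lie in (0.05, 0.98)")
  }

  Ac <- A_req
  delta <- lam / 2 + o_req
  geom <- NULL
  for (iter in 1:80) {
    if (delta <= 0 || delta >= lam) {
      stop("wave template degenerate: skew/amplitude/wavelength combination leaves no room for both flanks")
    }
    T0 <- c(0, -Ac / 2)
    C0 <- c(delta, Ac / 2)
    T1 <- c(lam, -Ac / 2)
    l1 <- sqrt(delta^2 + Ac^2)
    t1 <- (C0 - T0) / l1
    g <- (1 - contact_frac) / 2 * l1
    Ps <- T0 + g * t1            # contact start
    Pe <- C0 - g * t1            # contact end
    v1 <- contact_frac * l1 / d  # cm per cycle unit on the contact flank
    arm <- v1 * (1 - d) / 3      # Bezier tangent arm for speed continuity
    swing <- rbind(Pe, Pe + arm * t1,
                   Ps + c(lam, 0) - arm * t1, Ps + c(lam, 0))
    taus <- bezier3_lateral_extrema(swing)
    if (length(taus) != 2) {
      stop("wave template degenerate: the swing curve does not produce one crest and one trough (extreme skew/duty combination)")
    }
    pts <- bezier3_point(swing, taus)
    crest <- pts[which.max(pts[, 2]), ]
    trough <- pts[which.min(pts[, 2]), ]
    tau_crest <- taus[which.max(pts[, 2])]
    tau_trough <- taus[which.min(pts[, 2])]
    A_true <- crest[2] - trough[2]
    o_true <- crest[1] + lam / 2 - trough[1]
    geom <- list(Ac = Ac, delta = delta, T0 = T0, C0 = C0, T1 = T1,
                 l1 = l1, t1 = t1, g = g, Ps = Ps, Pe = Pe, v1 = v1,
                 swing = swing, tau_crest = tau_crest, tau_trough = tau_trough,
                 crest_apex = crest, trough_apex = trough,
                 A_true = A_true, o_true = o_true)
    if (abs(A_true - A_req) < 1e-10 && abs(o_true - o_req) < 1e-10) break
    Ac <- Ac + 0.9 * (A_req - A_true)
    delta <- delta + 0.9 * (o_req - o_true)
  }
  if (abs(geom$A_true - A_req) > 1e-6 || abs(geom$o_true - o_req) > 1e-6) {
    stop("wave template construction did not converge for this parameter combination")
  }

  # arclength lookup: u (cycle fraction) -> arc length s along the curve
  ugrid <- seq(0, 1, length.out = 4097L)
  spd <- template_speed(geom, d, ugrid)
  du <- diff(ugrid)
  s <- c(0, cumsum((spd[-1] + spd[-length(spd)]) / 2 * du))
  tpl <- c(geom, list(wave = wave, lambda = lam, duty = d,
                      contact_frac = contact_frac,
                      u_grid = ugrid, s_grid = s, arc_per_cycle = s[length(s)]))
  class(tpl) <- "wave_template"
  tpl
}

# |dW/du| at cycle positions u (vectorized), in cm per cycle unit.
template_speed <- function(g, d, u) {
  um <- u - floor(u)
  out <- numeric(length(u))
  in_contact <- um < d
  out[in_contact] <- g$v1
  if (any(!in_contact)) {
    tau <- (um[!in_contact] - d) / (1 - d)
    dv <- bezier3_deriv(g$swing, tau)
    out[!in_contact] <- sqrt(rowSums(dv^2)) / (1 - d)
  }
  out
}

# Planar template position W(u): n x 2 matrix (a, l), vectorized over u.
template_point <- function(tpl, u) {
  um <- u - floor(u)
  cyc <- floor(u)
  d <- tpl$duty
  out <- matrix(NA_real_, length(u), 2)
  in_contact <- um < d
  if (any(in_contact)) {
    s <- um[in_contact] / d * tpl$contact_frac * tpl$l1
    out[in_contact, ] <- cbind(tpl$Ps[1] + s * tpl$t1[1],
                               tpl$Ps[2] + s * tpl$t1[2])
  }
  if (any(!in_contact)) {
    tau <- (um[!in_contact] - d) / (1 - d)
    out[!in_contact, ] <- bezier3_point(tpl$swing, tau)
  }
  out[, 1] <- out[, 1] + cyc * tpl$lambda
  out
}

# Vertical lift profile: zero during contact, H sin^2(pi tau) over the swing.
template_z <- function(tpl, u, H) {
  um <- u - floor(u)
  d <- tpl$duty
  z <- numeric(length(u))
  sw <- um >= d
  z[sw] <- H * sin(pi * (um[sw] - d) / (1 - d))^2
  z
}

# Map body arc length (cm, from the head) to cycle units along the template.
arclength_to_u <- function(tpl, s_cm) {
  per <- tpl$arc_per_cycle
  cyc <- floor(s_cm / per)
  rem <- s_cm - cyc * per
  u_rem <- stats::approx(tpl$s_grid, tpl$u_grid, xout = rem, rule = 2)$y
  cyc + u_rem
}
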