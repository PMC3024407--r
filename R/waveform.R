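#' Myocardial motion model
#'
#' Ground-truth velocity waveform parameters for the dynamic phantom. Each
#' direction (radial, longitudinal) has one systolic and one diastolic peak
#' of opposite sign. Sign conventions: radial velocity is positive toward
#' the blood-pool centroid (systolic contraction positive); longitudinal
#' velocity is positive toward the apex.
#'
#' Waveforms are sums of two opposite-signed raised-cosine (Hann) pulses
#' plus a constant chosen so the cycle integral — the net displacement over
#' one heart cycle — is exactly zero. Pulse amplitudes are adjusted so the
#' waveform attains exactly the configured peak values at the configured
#' peak times. Peak times and the pulse width are fractions of the cycle;
#' the two pulses must not overlap (circular distance between peaks at
#' least `pulse_width`).
#'
#' Default peak magnitudes (radial +3.5/-3.0 cm/s, longitudinal
#' +8/-7 cm/s) are of the order of healthy-volunteer myocardial velocities;
#' they are configurable model inputs, not reproductions of any measured
#' subject.
#'
#' @param peak_radial_sys,peak_radial_dias Radial systolic / diastolic peak
#'   velocities (cm/s), opposite signs.
#' @param peak_long_sys,peak_long_dias Longitudinal peaks (cm/s), opposite
#'   signs.
#' @param t_sys_peak,t_dias_peak Peak times as fractions of the cycle.
#' @param pulse_width Full width of each Hann pulse, fraction of the cycle.
#' @param venc_cm_s Encoding limit; all waveform values must stay below it
#'   in magnitude.
#' @return An object of class `motion_model`.
#' @examples
#' m <- motion_model()
#' velocity_waveform(m$t_sys_peak, m, "radial")  # == peak_radial_sys
#' @export
motion_model <- function(peak_radial_sys = 3.5, peak_radial_dias = -3.0,
                         peak_long_sys = 8, peak_long_dias = -7,
                         t_sys_peak = 0.15, t_dias_peak = 0.55,
                         pulse_width = 0.25, venc_cm_s = 30) {
  m <- list(
    peak_radial_sys = peak_radial_sys, peak_radial_dias = peak_radial_dias,
    peak_long_sys = peak_long_sys, peak_long_dias = peak_long_dias,
    t_sys_peak = t_sys_peak, t_dias_peak = t_dias_peak,
    pulse_width = pulse_width, venc_cm_s = venc_cm_s
  )
  null_radial <- peak_radial_sys == 0 && peak_radial_dias == 0
  null_long <- peak_long_sys == 0 && peak_long_dias == 0
  if (!null_radial && peak_radial_sys * peak_radial_dias >= 0)
    stop("radial systolic and diastolic peaks must have opposite signs")
  if (!null_long && peak_long_sys * peak_long_dias >= 0)
    stop("longitudinal systolic and diastolic peaks must have opposite signs")
  if (pulse_width <= 0 || pulse_width >= 1)
    stop("'pulse_width' must lie in (0, 1)")
  gap <- circ_dist(t_sys_peak, t_dias_peak)
  if (gap < pulse_width)
    stop("systolic and diastolic pulses overlap: increase peak separation ",
         "or reduce 'pulse_width'")
  # the zero-integral offset slightly exceeds the configured peaks; check both
  for (dir in c("radial", "longitudinal")) {
    amp <- waveform_coeffs(m, dir)
    peak_vals <- c(amp$a_sys + amp$c0, amp$a_dias + amp$c0, amp$c0)
    if (max(abs(peak_vals)) >= venc_cm_s)
      stop("configured ", dir, " peaks reach or exceed VENC (",
           venc_cm_s, " cm/s)")
  }
  structure(m, class = "motion_model")
}

circ_dist <- function(a, b) {
  d <- abs(a - b) %% 1
  min(d, 1 - d)
}

# Solve pulse amplitudes and constant offset so that
#   w(t_sys) = peak_sys, w(t_dias) = peak_dias, integral over cycle = 0.
# Each unit Hann pulse of width w integrates to w/2, so
#   c0 = -(w/2) (P_s + P_d) / (1 - w).
waveform_coeffs <- function(m, direction) {
  ps <- switch(direction, radial = m$peak_radial_sys,
               longitudinal = m$peak_long_sys,
               stop("unknown direction: ", direction))
  pd <- switch(direction, radial = m$peak_radial_dias,
               longitudinal = m$peak_long_dias)
  w <- m$pulse_width
  c0 <- -(w / 2) * (ps + pd) / (1 - w)
  list(a_sys = ps - c0, a_dias = pd - c0, c0 = c0)
}

# Periodic unit Hann pulse centred at t0 with full width w, on t in [0, 1).
hann_pulse <- function(t_frac, t0, w) {
  d <- (t_frac - t0) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  ifelse(abs(d) < w / 2, 0.5 * (1 + cos(2 * pi * d / w)), 0)
}

#' Ground-truth velocity waveform
#'
#' Smooth periodic two-lobed velocity curve of the motion model: a systolic
#' and a diastolic raised-cosine pulse of opposite sign plus the constant
#' that zeroes the cycle integral. Continuous first derivative everywhere.
#'
#' @param t_frac Time as a fraction of the cycle, in `[0, 1)` (vectorized;
#'   values outside are wrapped periodically).
#' @param m A [motion_model()].
#' @param direction `"radial"` or `"longitudinal"`.
#' @return Velocity in cm/s, same length as `t_frac`.
#' @export
velocity_waveform <- function(t_frac, m, direction = c("radial", "longitudinal")) {
  direction <- match.arg(direction)
  amp <- waveform_coeffs(m, direction)
  t_frac <- t_frac %% 1
  amp$a_sys * hann_pulse(t_frac, m$t_sys_peak, m$pulse_width) +
    amp$a_dias * hann_pulse(t_frac, m$t_dias_peak, m$pulse_width) +
    amp$c0
}

# Cumulative displacement (cm) of the waveform over t_frac in [0, 1],
# with cycle duration `cycle_s` seconds. Dense trapezoidal integration;
# periodicity of the waveform guarantees zero net displacement.
waveform_displacement <- function(t_frac, m, direction, cycle_s,
                                  n_grid = 4096) {
  tg <- seq(0, 1, length.out = n_grid + 1)
  vg <- velocity_waveform(tg, m, direction)
  disp <- pracma::cumtrapz(tg * cycle_s, vg)[, 1]
  stats::approx(tg, disp, xout = t_frac %% 1, rule = 2)$y
}
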