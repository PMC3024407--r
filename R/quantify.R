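#' Phase-difference velocity map
#'
#' Referenced phase-contrast reconstruction: per pixel,
#' `v = Arg(enc * Conj(ref)) / pi * venc`. Pixels with zero magnitude in
#' either image carry no phase information and are returned as `NA`
#' (excluded from mask means downstream).
#'
#' @param ref,enc Complex images of equal dimension (reference and
#'   velocity-encoded segment).
#' @param venc_cm_s Encoding velocity in cm/s.
#' @return Numeric velocity image (cm/s) with `NA` at invalid pixels.
#' @export
phase_to_velocity <- function(ref, enc, venc_cm_s) {
  if (!all(dim(ref) == dim(enc))) stop("image dimensions differ")
  stopifnot(venc_cm_s > 0)
  v <- Arg(enc * Conj(ref)) / pi * venc_cm_s
  v[Mod(ref) == 0 | Mod(enc) == 0] <- NA_real_
  v
}

#' Linear background correction from static tissue
#'
#' Fits a plane `offset + slope_row * (row - 1) + slope_col * (col - 1)`
#' to the values over the static-tissue mask by least squares and
#' subtracts it from the whole image. Applied to velocity images this
#' removes the linear-in-space background phase error of the encoding.
#'
#' @param v Numeric image (e.g. a velocity map; `NA`s inside the mask are
#'   dropped from the fit).
#' @param static_mask Logical mask of static tissue with at least 3
#'   non-collinear pixels.
#' @return List with `corrected` (image) and `coeffs`
#'   (`c(offset, slope_row, slope_col)`, in the units of `v`).
#' @export
correct_background <- function(v, static_mask) {
  if (!all(dim(v) == dim(static_mask))) stop("mask dimensions differ")
  idx <- which(static_mask & !is.na(v), arr.ind = TRUE)
  if (nrow(idx) < 3) stop("static mask has fewer than 3 usable pixels")
  X <- cbind(1, idx[, 1] - 1, idx[, 2] - 1)
  if (qr(X)$rank < 3) stop("static mask pixels are collinear")
  fit <- stats::lm.fit(X, v[static_mask & !is.na(v)])
  coeffs <- unname(fit$coefficients)
  rows <- matrix(seq_len(nrow(v)) - 1, nrow(v), ncol(v))
  cols <- matrix(seq_len(ncol(v)) - 1, nrow(v), ncol(v), byrow = TRUE)
  plane <- coeffs[1] + coeffs[2] * rows + coeffs[3] * cols
  list(corrected = v - plane, coeffs = coeffs)
}

#' Velocity curve container
#'
#' @param direction `"radial"` or `"longitudinal"`.
#' @param t_ms,v_cm_s Sampled curve (acquisition time per cardiac phase,
#'   myocardial-mask mean velocity).
#' @param window_ms Duration of the acquisition window (curve period).
#' @param dense Optional tibble `t_ms`, `v_cm_s` of the spline-resampled
#'   curve.
#' @param dt_ms Dense grid step, if resampled.
#' @param peak_windows Optional list with elements `systole` and
#'   `diastole` (`c(from, to)` in ms) used as default search windows by
#'   [find_peaks()]; when absent the cycle is split in half.
#' @return An object of class `velocity_curve`.
#' @export
velocity_curve <- function(direction, t_ms, v_cm_s, window_ms,
                           dense = NULL, dt_ms = NULL,
                           peak_windows = NULL) {
  stopifnot(length(t_ms) == length(v_cm_s), window_ms > 0)
  structure(list(direction = direction,
                 samples = tibble::tibble(t_ms = t_ms, v_cm_s = v_cm_s),
                 window_ms = window_ms, dense = dense, dt_ms = dt_ms,
                 peak_windows = peak_windows),
            class = "velocity_curve")
}

#' @export
print.velocity_curve <- function(x, ...) {
  cat(sprintf("<velocity_curve> %s, %d phases over %g ms%s\n",
              x$direction, nrow(x$samples), x$window_ms,
              if (is.null(x$dense)) "" else
                sprintf(", dense dt = %g ms", x$dt_ms)))
  invisible(x)
}

#' Radial and longitudinal myocardial velocity curves
#'
#' Per cardiac phase, the radial value is the myocardial-mask mean of the
#' in-plane velocity projected onto the unit vectors pointing from each
#' pixel to the blood-pool centroid (positive = toward the centroid); the
#' longitudinal value is the mask mean of the through-plane component
#' (positive = toward the apex). Invalid (`NA`) pixels are excluded from
#' the means; their count is recorded in the `n_invalid` attribute.
#'
#' @param vfields Numeric array `rows x cols x n_phases x 3` of velocity
#'   components (x = column direction, y = row direction, z =
#'   through-plane), e.g. assembled from [phase_to_velocity()] maps.
#' @param myo_mask Logical array `rows x cols x n_phases`.
#' @param centroid `c(row, col)` of the blood-pool centre.
#' @param window_ms Acquisition window (ms); phase `i` is assigned time
#'   `(i - 1) / n_phases * window_ms`.
#' @param apex_sign `+1` if positive z velocity points toward the apex.
#' @return Named list of two [velocity_curve()] objects
#'   (`radial`, `longitudinal`).
#' @export
extract_curves <- function(vfields, myo_mask, centroid, window_ms,
                           apex_sign = 1) {
  d <- dim(vfields)
  nt <- d[3]
  stopifnot(length(dim(myo_mask)) == 3, all(dim(myo_mask) == d[1:3]))
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  dr <- rows - centroid[1]
  dc <- cols - centroid[2]
  dist <- pmax(sqrt(dr^2 + dc^2), .Machine$double.eps)
  u_row <- -dr / dist
  u_col <- -dc / dist
  v_rad <- numeric(nt); v_long <- numeric(nt); n_invalid <- 0L
  for (i in seq_len(nt)) {
    msk <- myo_mask[, , i]
    if (!any(msk)) stop("empty myocardial mask at phase ", i)
    proj <- vfields[, , i, 1] * u_col + vfields[, , i, 2] * u_row
    vz <- vfields[, , i, 3] * apex_sign
    bad <- is.na(proj[msk]) | is.na(vz[msk])
    n_invalid <- n_invalid + sum(bad)
    v_rad[i] <- mean(proj[msk], na.rm = TRUE)
    v_long[i] <- mean(vz[msk], na.rm = TRUE)
  }
  t_ms <- (seq_len(nt) - 1) / nt * window_ms
  out <- list(
    radial = velocity_curve("radial", t_ms, v_rad, window_ms),
    longitudinal = velocity_curve("longitudinal", t_ms, v_long, window_ms)
  )
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Periodic cubic-spline resampling of a velocity curve
#'
#' Interpolates the sampled curve onto a uniform grid of step `dt_ms`
#' across the acquisition window with a periodic cubic spline (the curve
#' is one heart cycle, so value and derivative are continuous across the
#' wrap). Enables comparison of acquisitions with different phase counts.
#'
#' @param curve A [velocity_curve()] with at least 4 samples.
#' @param dt_ms Dense grid step in ms (default 0.01 ms).
#' @return The curve with its `dense` field filled.
#' @export
resample_spline <- function(curve, dt_ms = 0.01) {
  stopifnot(inherits(curve, "velocity_curve"), dt_ms > 0)
  s <- curve$samples
  if (nrow(s) < 4) stop("need at least 4 phases for spline resampling")
  # close the cycle: append the first sample one period later
  fun <- stats::splinefun(c(s$t_ms, s$t_ms[1] + curve$window_ms),
                          c(s$v_cm_s, s$v_cm_s[1]), method = "periodic")
  tg <- seq(0, curve$window_ms - dt_ms / 2, by = dt_ms)
  curve$dense <- tibble::tibble(t_ms = tg, v_cm_s = fun(tg))
  curve$dt_ms <- dt_ms
  curve
}

#' Zero-integral shift of a velocity curve
#'
#' The accumulated displacement over the full heart cycle must vanish;
#' residual nonlinear background phase shows up as a nonzero cycle mean.
#' Subtracts the time-mean of the dense curve (a constant shift) so the
#' cycle integral is zero. Idempotent.
#'
#' @param curve A resampled [velocity_curve()].
#' @return The shifted curve; the applied shift is stored in the
#'   `zero_shift_cm_s` field.
#' @export
zero_shift <- function(curve) {
  stopifnot(inherits(curve, "velocity_curve"))
  if (is.null(curve$dense)) stop("resample the curve first")
  shift <- mean(curve$dense$v_cm_s)
  curve$dense$v_cm_s <- curve$dense$v_cm_s - shift
  curve$samples$v_cm_s <- curve$samples$v_cm_s - shift
  curve$zero_shift_cm_s <- (curve$zero_shift_cm_s %||% 0) + shift
  curve
}

#' Systolic / diastolic peak features of a velocity curve
#'
#' `v_p_sys` is the signed extremum of largest magnitude inside the
#' systolic window; `v_p_dias` the extremum of opposite sign and largest
#' magnitude inside the diastolic window; `delta_v = v_p_sys - v_p_dias`;
#' `t_dias` the dense-grid time of the diastolic extremum. Ties are
#' broken by the earliest time; a flat zero curve yields all-zero
#' features with `t_dias` at the window start.
#'
#' @param curve A resampled [velocity_curve()].
#' @param systole_window,diastole_window Two-element `c(from, to)` time
#'   windows in ms partitioning the cycle. Default: the curve's
#'   `peak_windows` (e.g. set from the known phase timing of a study),
#'   falling back to the first / second half of the acquisition window.
#' @return One-row tibble: `direction`, `v_p_sys`, `v_p_dias`, `delta_v`
#'   (cm/s), `t_dias_ms`.
#' @export
find_peaks <- function(curve, systole_window = NULL, diastole_window = NULL) {
  stopifnot(inherits(curve, "velocity_curve"))
  if (is.null(curve$dense)) stop("resample the curve first")
  if (is.null(systole_window))
    systole_window <- curve$peak_windows$systole %||%
      c(0, curve$window_ms / 2)
  if (is.null(diastole_window))
    diastole_window <- curve$peak_windows$diastole %||%
      c(curve$window_ms / 2, curve$window_ms)
  dn <- curve$dense
  in_sys <- dn$t_ms >= systole_window[1] & dn$t_ms < systole_window[2]
  in_dia <- dn$t_ms >= diastole_window[1] & dn$t_ms < diastole_window[2]
  if (!any(in_sys) || !any(in_dia)) stop("empty peak-search window")
  vs <- dn$v_cm_s[in_sys]
  i_sys <- which.max(abs(vs))          # earliest max by which.max tie rule
  v_p_sys <- vs[i_sys]
  vd <- dn$v_cm_s[in_dia]
  td <- dn$t_ms[in_dia]
  if (v_p_sys > 0) {
    i_dia <- which.min(vd)
  } else if (v_p_sys < 0) {
    i_dia <- which.max(vd)
  } else {
    i_dia <- 1L
  }
  v_p_dias <- vd[i_dia]
  if (v_p_sys == 0 && v_p_dias == 0) {
    return(tibble::tibble(direction = curve$direction, v_p_sys = 0,
                          v_p_dias = 0, delta_v = 0,
                          t_dias_ms = diastole_window[1]))
  }
  tibble::tibble(direction = curve$direction, v_p_sys = v_p_sys,
                 v_p_dias = v_p_dias, delta_v = v_p_sys - v_p_dias,
                 t_dias_ms = td[i_dia])
}
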