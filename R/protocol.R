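#' Acquisition protocol parameters
#'
#' Container for the constants of the segmented, navigator-gated,
#' velocity-encoded gradient-echo protocol. Defaults reproduce a 3 T
#' short-axis tissue phase mapping acquisition: TE/TR = 4.7/7.1 ms,
#' flip angle 15 deg, acquisition matrix 172 x 168, 3 k-lines per segment
#' plus one startup echo, a 12 ms black-blood saturation module, a 15.5 ms
#' respiratory navigator with 5 ms feedback, an acquisition window of 90%
#' of the RR interval, VENC = 30 cm/s and four-point velocity encoding
#' (reference + 3 directions) in consecutive heart beats.
#'
#' `kt_factor = 1` denotes the non-accelerated protocol. `training_lines`
#' is the number of central k_y lines of the low-resolution training scan;
#' `training_overhead_beats` is the fixed per-scan cost of the training
#' stage (constant in R), and `prep_beats` the preparation cost of the
#' non-accelerated scan. Both overhead constants are calibrated so the
#' timing model reproduces the protocol table of the accelerated sweep.
#'
#' @param tr_ms,te_ms Repetition / echo time in ms.
#' @param flip_deg Excitation flip angle in degrees.
#' @param n_freq,n_pe Acquisition matrix: frequency-encode samples and
#'   phase-encode lines.
#' @param klines_per_segment k-space lines acquired per cardiac phase per beat.
#' @param startup_echoes Dummy echoes per segment.
#' @param sat_module_ms Duration of the black-blood saturation module (ms).
#' @param nav_ms,nav_feedback_ms Navigator duration and feedback time (ms).
#' @param acq_window_fraction Usable fraction of the RR interval.
#' @param rr_ms RR interval in ms.
#' @param venc_cm_s Velocity encoding sensitivity (cm/s).
#' @param n_encodings Number of velocity-encoding segments (4 = reference +
#'   3 directions).
#' @param training_lines Central phase-encode lines of the training scan.
#' @param training_overhead_beats Heartbeats spent on the training stage of an
#'   accelerated scan.
#' @param prep_beats Preparation beats of the non-accelerated scan.
#' @param kt_factor k-t undersampling factor R (1 = no acceleration).
#'
#' @return An object of class `protocol_params` (a named list).
#' @examples
#' p <- protocol_params()
#' phase_interval(p)         # 40.4 ms
#' max_heart_phases(p)       # 21 at 60 bpm
#' @export
protocol_params <- function(tr_ms = 7.1, te_ms = 4.7, flip_deg = 15,
                            n_freq = 172, n_pe = 168,
                            klines_per_segment = 3, startup_echoes = 1,
                            sat_module_ms = 12, nav_ms = 15.5,
                            nav_feedback_ms = 5, acq_window_fraction = 0.9,
                            rr_ms = 1000, venc_cm_s = 30, n_encodings = 4,
                            training_lines = 11,
                            training_overhead_beats = 13, prep_beats = 1,
                            kt_factor = 1) {
  p <- list(
    tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
    n_freq = n_freq, n_pe = n_pe,
    klines_per_segment = klines_per_segment, startup_echoes = startup_echoes,
    sat_module_ms = sat_module_ms, nav_ms = nav_ms,
    nav_feedback_ms = nav_feedback_ms,
    acq_window_fraction = acq_window_fraction, rr_ms = rr_ms,
    venc_cm_s = venc_cm_s, n_encodings = n_encodings,
    training_lines = training_lines,
    training_overhead_beats = training_overhead_beats,
    prep_beats = prep_beats, kt_factor = kt_factor
  )
  validate_protocol_params(p)
  structure(p, class = "protocol_params")
}

validate_protocol_params <- function(p) {
  durations <- c("tr_ms", "te_ms", "sat_module_ms", "nav_ms",
                 "nav_feedback_ms", "rr_ms")
  for (d in durations) {
    if (!is.numeric(p[[d]]) || length(p[[d]]) != 1 || p[[d]] < 0)
      stop(sprintf("'%s' must be a single nonnegative duration", d))
  }
  counts <- c("n_freq", "n_pe", "n_encodings", "training_lines", "kt_factor")
  for (cn in counts) {
    if (!is.numeric(p[[cn]]) || length(p[[cn]]) != 1 || p[[cn]] < 1 ||
        p[[cn]] != round(p[[cn]]))
      stop(sprintf("'%s' must be a positive integer", cn))
  }
  for (cn in c("klines_per_segment", "startup_echoes",
               "training_overhead_beats", "prep_beats")) {
    if (p[[cn]] < 0 || p[[cn]] != round(p[[cn]]))
      stop(sprintf("'%s' must be a nonnegative integer", cn))
  }
  if (p$acq_window_fraction <= 0 || p$acq_window_fraction > 1)
    stop("'acq_window_fraction' must lie in (0, 1]")
  if (p$venc_cm_s <= 0) stop("'venc_cm_s' must be positive")
  invisible(p)
}

#' @export
print.protocol_params <- function(x, ...) {
  cat("<protocol_params>\n")
  cat(sprintf("  TE/TR %.1f/%.1f ms, flip %g deg, matrix %d x %d\n",
              x$te_ms, x$tr_ms, x$flip_deg, x$n_freq, x$n_pe))
  cat(sprintf("  %d k-lines/segment + %d startup, sat %g ms, nav %g + %g ms\n",
              x$klines_per_segment, x$startup_echoes, x$sat_module_ms,
              x$nav_ms, x$nav_feedback_ms))
  cat(sprintf("  VENC %g cm/s, %d encodings, RR %g ms, window %g%%, R = %d\n",
              x$venc_cm_s, x$n_encodings, x$rr_ms,
              100 * x$acq_window_fraction, x$kt_factor))
  invisible(x)
}

#' Cardiac phase interval of the segmented acquisition
#'
#' Time needed to acquire one cardiac phase within a heartbeat:
#' `(klines_per_segment + startup_echoes) * tr_ms + sat_module_ms`.
#' Independent of the k-t factor: undersampling removes whole phase-encode
#' segments from the schedule rather than shortening a phase.
#'
#' @param p A [protocol_params()] object.
#' @return Phase interval in ms.
#' @examples
#' phase_interval(protocol_params())  # (3 + 1) * 7.1 + 12 = 40.4
#' @export
phase_interval <- function(p) {
  validate_protocol_params(p)
  (p$klines_per_segment + p$startup_echoes) * p$tr_ms + p$sat_module_ms
}

#' Maximum number of cardiac phases per heartbeat
#'
#' Number of phase intervals fitting the usable acquisition window:
#' `floor((acq_window_fraction * rr_ms - nav_ms - nav_feedback_ms) /
#' phase_interval(p))`.
#'
#' @inheritParams phase_interval
#' @return Integer count of cardiac phases.
#' @examples
#' max_heart_phases(protocol_params())  # 21 at RR = 1000 ms
#' @export
max_heart_phases <- function(p) {
  pi_ms <- phase_interval(p)
  if (pi_ms <= 0) stop("phase interval must be positive")
  usable <- p$acq_window_fraction * p$rr_ms - p$nav_ms - p$nav_feedback_ms
  if (usable <= 0) stop("usable acquisition window is not positive")
  as.integer(floor(usable / pi_ms))
}

#' Acquired cardiac phases for a k-t factor
#'
#' The acquired phase count is forced to a multiple of the k-t factor so that
#' the undersampling factor is uniform over k-space:
#' `R * floor(max_phases / R)`.
#'
#' @param max_phases Maximum phase count fitting the acquisition window.
#' @param R k-t factor (1 = no acceleration).
#' @return Integer phase count, `<= max_phases` and divisible by `R`.
#' @examples
#' phases_for_factor(21, 2)  # 20
#' phases_for_factor(21, 6)  # 18
#' @export
phases_for_factor <- function(max_phases, R) {
  stopifnot(length(max_phases) == 1, length(R) == 1,
            R >= 1, R == round(R), max_phases == round(max_phases))
  if (max_phases < R) stop("max_phases must be >= R")
  as.integer(R * (max_phases %/% R))
}

#' Nominal scan duration in heartbeats
#'
#' For the non-accelerated scan all `n_pe` lines are acquired in segments of
#' `klines_per_segment` lines per beat per encoding, plus `prep_beats`
#' preparation: `n_encodings * ceiling(n_pe / klines_per_segment) + prep_beats`.
#' An accelerated scan acquires every R-th line plus a fixed training stage:
#' `n_encodings * floor(n_pe / (klines_per_segment * R)) +
#' training_overhead_beats`. Assumes 100% navigator-gating efficiency.
#'
#' @inheritParams phase_interval
#' @return Integer number of heartbeats.
#' @examples
#' nominal_scan_beats(protocol_params())                 # 225
#' nominal_scan_beats(protocol_params(kt_factor = 2))    # 125
#' @export
nominal_scan_beats <- function(p) {
  validate_protocol_params(p)
  if (p$kt_factor == 1) {
    beats <- p$n_encodings * ceiling(p$n_pe / p$klines_per_segment) +
      p$prep_beats
  } else {
    beats <- p$n_encodings *
      (p$n_pe %/% (p$klines_per_segment * p$kt_factor)) +
      p$training_overhead_beats
  }
  as.integer(beats)
}

#' Nominal scan time in seconds
#'
#' @param beats Number of heartbeats.
#' @param rr_ms RR interval in ms.
#' @return Duration in seconds.
#' @examples
#' nominal_scan_time(225, 1000)  # 225 s
#' @export
nominal_scan_time <- function(beats, rr_ms) {
  stopifnot(beats >= 0, rr_ms > 0)
  beats * rr_ms / 1000
}

#' Protocol table over a k-t factor sweep
#'
#' One row per k-t factor with the acquired phase count and nominal scan
#' time, mirroring the printed protocol summary of the accelerated study.
#'
#' @param p A [protocol_params()] object (its `kt_factor` is ignored).
#' @param R_list Integer vector of k-t factors; 1 denotes no acceleration.
#' @return A tibble with columns `R`, `phases`, `scan_beats`, `scan_time_s`.
#' @examples
#' protocol_table(protocol_params())
#' @export
protocol_table <- function(p, R_list = 1:7) {
  mp <- max_heart_phases(p)
  rows <- purrr::map(as.integer(R_list), function(R) {
    pR <- p
    pR$kt_factor <- R
    beats <- nominal_scan_beats(pR)
    tibble::tibble(
      R = R,
      phases = phases_for_factor(mp, R),
      scan_beats = beats,
      scan_time_s = nominal_scan_time(beats, p$rr_ms)
    )
  })
  dplyr::bind_rows(rows)
}

#' Read / write protocol parameters as a flat key-value config file
#'
#' YAML with one scalar per key; keys are the field names of
#' [protocol_params()].
#'
#' @param p A `protocol_params` object.
#' @param path File path.
#' @return `write_protocol_config()` returns `path` invisibly;
#'   `read_protocol_config()` returns a `protocol_params` object.
#' @export
write_protocol_config <- function(p, path) {
  validate_protocol_params(p)
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(protocol_params, vals)
}
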