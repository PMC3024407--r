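#' Experiment configuration
#'
#' Settings of the seeded in-silico study: one reproducibility arm (two
#' non-accelerated acquisitions) plus one k-t accelerated acquisition per
#' factor in `R_list`, for a cohort of synthetic subjects whose motion
#' parameters are drawn uniformly from the configured ranges.
#'
#' For an accelerated arm the phase-encode matrix is rounded to the
#' nearest multiple of R (`R * round(n_pe / R)`) so that the sheared
#' lattice has an exact alias structure on the grid — the same
#' "multiple-integer" device the protocol applies to the cardiac phase
#' count. At the default 120-line matrix only R = 7 deviates (119 lines);
#' the field of view is held fixed, so the pixel size changes by less
#' than 1%.
#'
#' @param protocol A [protocol_params()] object.
#' @param n_subjects Number of synthetic subjects.
#' @param R_list k-t factors of the accelerated arms.
#' @param matrix_size Image matrix `c(rows, cols)` of the simulation.
#' @param noise_sd Complex k-space noise level (image tissue magnitude
#'   is 1).
#' @param background_coeffs Background phase plane
#'   `c(offset, slope_row, slope_col)` in radians (per pixel for the
#'   slopes).
#' @param motion_ranges Named list of `c(min, max)` ranges for
#'   [motion_model()] parameters sampled per subject.
#' @param psi Unaliasing noise variance; `NULL` (default) estimates it
#'   from the outer k-space corners of each accelerated acquisition.
#' @param dt_ms Dense resampling step (ms).
#' @param seed Master seed; per-subject and per-arm seeds derive from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(protocol = protocol_params(),
                              n_subjects = 10,
                              R_list = 2:7,
                              matrix_size = c(120, 120),
                              noise_sd = 0.05,
                              background_coeffs = c(0.3, 0.004, -0.006),
                              motion_ranges = list(
                                peak_radial_sys = c(2.5, 4.5),
                                peak_radial_dias = c(-3.5, -2.0),
                                peak_long_sys = c(6, 10),
                                peak_long_dias = c(-8, -5),
                                t_sys_peak = c(0.12, 0.18),
                                t_dias_peak = c(0.50, 0.60),
                                pulse_width = c(0.20, 0.28)
                              ),
                              psi = NULL,
                              dt_ms = 0.01,
                              seed = 1L) {
  stopifnot(inherits(protocol, "protocol_params"), n_subjects >= 1,
            all(R_list >= 2), length(matrix_size) == 2)
  structure(list(protocol = protocol, n_subjects = as.integer(n_subjects),
                 R_list = as.integer(R_list), matrix_size = matrix_size,
                 noise_sd = noise_sd, background_coeffs = background_coeffs,
                 motion_ranges = motion_ranges, psi = psi, dt_ms = dt_ms,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

draw_motion_model <- function(ranges, venc_cm_s, seed) {
  withr_seed(seed, {
    vals <- lapply(ranges, function(r) stats::runif(1, r[1], r[2]))
  })
  do.call(motion_model, c(vals, list(venc_cm_s = venc_cm_s)))
}

# phase-encode matrix of an accelerated arm: nearest multiple of R
pe_lines_for_factor <- function(n_pe, R) {
  n <- as.integer(R * round(n_pe / R))
  max(n, R)
}

# simulate one acquisition arm and return quantified curves + features
simulate_arm <- function(m, cfg, R, n_phases, seed) {
  p <- cfg$protocol
  nx <- cfg$matrix_size[2]
  ny <- if (R == 1) cfg$matrix_size[1] else
    pe_lines_for_factor(cfg$matrix_size[1], R)
  fov_mm <- cfg$matrix_size[1] * 2  # fixed FOV; pixel size follows
  pixel_mm <- fov_mm / ny
  cycle_s <- p$acq_window_fraction * p$rr_ms / 1000
  ph <- build_phantom(m, n_phases, matrix_size = c(ny, nx),
                      pixel_mm = pixel_mm, cycle_s = cycle_s)
  enc <- encode_velocity(ph, venc_cm_s = p$venc_cm_s,
                         background_coeffs = cfg$background_coeffs)
  ksp <- to_kspace(enc, noise_sd = cfg$noise_sd, seed = seed)
  if (R == 1) {
    rec <- reconstruct_full(ksp)
  } else {
    pat <- make_kt_pattern(ny, n_phases, R)
    und <- undersample(ksp, pat)
    tr <- acquire_training(ksp, p$training_lines)
    psi <- cfg$psi %||% max(estimate_noise_psi(und), 1e-8)
    svm <- estimate_signal_variance(tr, psi = psi)
    rec <- reconstruct_ktblast(und, pat, svm)
  }
  # peak-search windows split the cycle at the midpoint between the
  # subject's systolic and diastolic peak times (the analyst's knowledge
  # of the cardiac phase timing), shared by all arms of the subject
  wms <- cycle_s * 1000
  b <- (m$t_sys_peak + m$t_dias_peak) / 2 * wms
  pw <- list(systole = c(0, b), diastole = c(b, wms))
  quantify_arm(rec, ph, p$venc_cm_s, cfg$dt_ms, peak_windows = pw)
}

#' Quantify a reconstructed acquisition
#'
#' Runs the analysis chain on reconstructed complex images: referenced
#' phase-difference velocity maps per direction, linear background
#' correction from static tissue, radial/longitudinal mask-mean curves,
#' periodic spline resampling, zero-integral shift and peak detection.
#'
#' @param rec Complex image array `rows x cols x n_phases x 4`
#'   (encodings ordered ref, x, y, z).
#' @param ph The [build_phantom()] object supplying masks and centroid
#'   (or user-supplied masks with the same fields).
#' @param venc_cm_s Encoding velocity.
#' @param dt_ms Dense resampling step.
#' @param peak_windows Optional `list(systole =, diastole =)` search
#'   windows (ms) attached to the curves for peak detection.
#' @return List with `curves` (radial/longitudinal, resampled and
#'   zero-shifted), `features` (two-row tibble from [find_peaks()]) and
#'   `background` (3 x 3 matrix of fitted plane coefficients per
#'   component, averaged over phases, velocity units).
#' @export
quantify_arm <- function(rec, ph, venc_cm_s, dt_ms = 0.01,
                         peak_windows = NULL) {
  d <- dim(rec)
  nt <- d[3]
  vf <- array(NA_real_, c(d[1], d[2], nt, 3))
  bg <- matrix(0, 3, 3,
               dimnames = list(c("x", "y", "z"),
                               c("offset", "slope_row", "slope_col")))
  for (e in 1:3) {
    for (i in seq_len(nt)) {
      v <- phase_to_velocity(rec[, , i, 1], rec[, , i, e + 1], venc_cm_s)
      cb <- correct_background(v, ph$static_mask)
      vf[, , i, e] <- cb$corrected
      bg[e, ] <- bg[e, ] + cb$coeffs / nt
    }
  }
  window_ms <- ph$cycle_s * 1000
  curves <- extract_curves(vf, ph$myo_mask, ph$centroid, window_ms)
  curves <- lapply(curves, function(cv) {
    cv$peak_windows <- peak_windows
    zero_shift(resample_spline(cv, dt_ms))
  })
  features <- dplyr::bind_rows(lapply(curves, find_peaks))
  list(curves = curves, features = features, background = bg)
}

#' Run the full in-silico acceleration study
#'
#' For every synthetic subject: two non-accelerated acquisitions (the
#' reproducibility arm) and one k-t BLAST accelerated acquisition per
#' factor in `R_list`, each independently noised, reconstructed and
#' quantified. Comparisons are oriented seq. 2 minus seq. 1 with the
#' first non-accelerated acquisition as seq. 1 throughout; nRMSD is
#' normalized by the non-accelerated velocity range per direction.
#' Fully reproducible given the configuration.
#'
#' @param cfg An [experiment_config()].
#' @param output_dir Optional directory; when given, per-subject curves,
#'   the comparison table and the cohort summary are written as CSV and
#'   a provenance log as JSON.
#' @return An object of class `tpm_experiment`: `comparisons`
#'   (per-subject tibble), `summary` ([summarize_cohort()] tables),
#'   `features` (per-subject, per-arm peak features), `protocol`
#'   (the [protocol_table()]), and `config`.
#' @export
run_experiment <- function(cfg, output_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  p <- cfg$protocol
  max_phases <- max_heart_phases(p)
  arms <- c("ref", paste0("kt", cfg$R_list))

  all_cmp <- list(); all_feat <- list(); all_curves <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sub_seed <- cfg$seed * 10000L + s * 100L
    m <- draw_motion_model(cfg$motion_ranges, p$venc_cm_s, sub_seed)
    nokt1 <- simulate_arm(m, cfg, 1, max_phases, sub_seed + 1L)
    nokt2 <- simulate_arm(m, cfg, 1, max_phases, sub_seed + 2L)
    dv_ref <- stats::setNames(nokt1$features$delta_v,
                              nokt1$features$direction)
    cmp <- list(
      dplyr::mutate(
        compare_acquisitions(nokt1$curves, nokt2$curves, dv_ref = dv_ref),
        arm = "ref", .before = 1)
    )
    feat <- list(dplyr::mutate(nokt1$features, arm = "nokt1", .before = 1),
                 dplyr::mutate(nokt2$features, arm = "nokt2", .before = 1))
    curves_s <- list(nokt1 = nokt1$curves, nokt2 = nokt2$curves)
    for (R in cfg$R_list) {
      n_ph <- phases_for_factor(max_phases, R)
      arm <- simulate_arm(m, cfg, R, n_ph, sub_seed + 2L + R)
      cmp[[length(cmp) + 1]] <- dplyr::mutate(
        compare_acquisitions(nokt1$curves, arm$curves, dv_ref = dv_ref),
        arm = paste0("kt", R), .before = 1)
      feat[[length(feat) + 1]] <-
        dplyr::mutate(arm$features, arm = paste0("kt", R), .before = 1)
      curves_s[[paste0("kt", R)]] <- arm$curves
    }
    all_cmp[[s]] <- dplyr::mutate(dplyr::bind_rows(cmp), subject = s,
                                  .before = 1)
    all_feat[[s]] <- dplyr::mutate(dplyr::bind_rows(feat), subject = s,
                                   .before = 1)
    all_curves[[s]] <- curves_s
  }
  comparisons <- dplyr::bind_rows(all_cmp)
  features <- dplyr::bind_rows(all_feat)
  summary_tbl <- summarize_cohort(comparisons)
  out <- structure(list(
    comparisons = comparisons, summary = summary_tbl, features = features,
    protocol = protocol_table(p, c(1, cfg$R_list)),
    config = cfg, curves = all_curves
  ), class = "tpm_experiment")
  if (!is.null(output_dir)) write_experiment(out, output_dir)
  out
}

#' @export
print.tpm_experiment <- function(x, ...) {
  cat(sprintf("<tpm_experiment> %d subjects, arms: %s\n",
              x$config$n_subjects,
              paste(unique(x$comparisons$arm), collapse = ", ")))
  print(x$summary, n = 20)
  invisible(x)
}

#' Write experiment outputs to disk
#'
#' CSV tables (comparisons, cohort summary, per-arm features, protocol
#' table, sampled curves) plus a JSON provenance log carrying the
#' configuration, seed and package version.
#'
#' @param exp A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "tpm_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(exp$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$summary, file.path(dir, "cohort_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$protocol, file.path(dir, "protocol_table.csv"),
                   row.names = FALSE)
  curves <- purrr::imap_dfr(exp$curves, function(arms, s) {
    purrr::imap_dfr(arms, function(cv, arm) {
      dplyr::bind_rows(
        dplyr::mutate(cv$radial$samples, direction = "radial"),
        dplyr::mutate(cv$longitudinal$samples, direction = "longitudinal")
      ) |> dplyr::mutate(subject = s, arm = arm)
    })
  })
  utils::write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE)
  cfg <- exp$config
  log <- list(
    seed = cfg$seed, n_subjects = cfg$n_subjects, R_list = cfg$R_list,
    matrix_size = cfg$matrix_size, noise_sd = cfg$noise_sd,
    dt_ms = cfg$dt_ms,
    package_version = as.character(utils::packageVersion("kttpm")),
    config_hash = rlang::hash(unclass(cfg))
  )
  jsonlite::write_json(log, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
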