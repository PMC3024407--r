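#' Peak factor between two acquisitions
#'
#' Ratio of the systolic-diastolic velocity ranges,
#' `PF(seq1, seq2) = delta_v_seq2 / delta_v_seq1`. Ideally 1; temporal
#' smoothing of an accelerated reconstruction abrades sharp peaks and
#' pushes PF below 1.
#'
#' @param dv_seq1,dv_seq2 Velocity ranges `delta_v` (cm/s) of the first
#'   (reference) and second acquisition.
#' @return The ratio; `NA` with a warning if `dv_seq1` is zero.
#' @export
peak_factor <- function(dv_seq1, dv_seq2) {
  if (any(dv_seq1 == 0)) {
    warning("peak factor undefined for zero reference velocity range")
    return(ifelse(dv_seq1 == 0, NA_real_, dv_seq2 / dv_seq1))
  }
  dv_seq2 / dv_seq1
}

#' Normalized root mean square deviation between two curves
#'
#' `sqrt(mean((u - w)^2)) / |dv_ref|`, with `dv_ref` the velocity range
#' of the non-accelerated acquisition. Symmetric in `u` and `w`.
#'
#' @param u,w Dense velocity curves on the same time grid (numeric
#'   vectors of equal length).
#' @param dv_ref Reference velocity range (cm/s), nonzero.
#' @return Nonnegative ratio.
#' @export
nrmsd <- function(u, w, dv_ref) {
  if (length(u) != length(w)) stop("curves are on different grids")
  if (dv_ref == 0) stop("reference velocity range is zero")
  sqrt(mean((u - w)^2)) / abs(dv_ref)
}

#' Correlation between two velocity curves
#'
#' Pearson product-moment correlation of the dense curves; 1 for
#' identical temporal shapes. Constant input has no defined correlation
#' and raises an error.
#'
#' @inheritParams nrmsd
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
curve_correlation <- function(u, w) {
  if (length(u) != length(w)) stop("curves are on different grids")
  if (length(u) < 2) stop("need at least 2 points")
  if (stats::sd(u) == 0 || stats::sd(w) == 0)
    stop("correlation undefined for a constant curve")
  stats::cor(u, w)
}

#' Bland-Altman agreement statistics
#'
#' Differences are oriented as second minus first sequence,
#' `d_k = seq2_k - seq1_k`. Returns their mean, sample standard
#' deviation (n - 1 denominator) and the 95% limits of agreement
#' `mean +/- 1.96 sd`.
#'
#' @param seq1,seq2 Paired measurements (equal length >= 2).
#' @return One-row tibble: `mean_diff`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n`.
#' @export
bland_altman <- function(seq1, seq2) {
  if (length(seq1) != length(seq2)) stop("unequal pair lengths")
  if (length(seq1) < 2) stop("need at least 2 pairs")
  d <- seq2 - seq1
  m <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(mean_diff = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 n = length(d))
}

#' Pooled two-sample t-test
#'
#' Unpaired, two-tailed Student's t-test assuming equal variances in both
#' groups (pooled variance, `df = n_a + n_b - 2`). Thin wrapper around
#' [stats::t.test()] returning a tidy row; p-values below 0.05 are
#' conventionally taken as significant.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
pooled_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  df <- length(group_a) + length(group_b) - 2
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    # degenerate: no within-group variance
    delta <- mean(group_a) - mean(group_b)
    return(tibble::tibble(t = ifelse(delta == 0, 0, sign(delta) * Inf),
                          df = df, p_value = ifelse(delta == 0, 1, 0),
                          mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE,
                      alternative = "two.sided")
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_a = mean(group_a),
                 mean_b = mean(group_b))
}

#' Compare two quantified acquisitions
#'
#' Computes, per direction, the peak factor, normalized RMSD, curve
#' correlation, velocity-range difference and diastolic time-to-peak
#' difference between a reference acquisition (seq. 1) and a test
#' acquisition (seq. 2). Differences are seq. 2 minus seq. 1. The nRMSD
#' is normalized by the reference velocity range per direction (pass
#' `dv_ref` to normalize by a different acquisition, e.g. the
#' non-accelerated scan when comparing two repeats).
#'
#' @param curves1,curves2 Lists with elements `radial` and
#'   `longitudinal`, each a resampled (and zero-shifted)
#'   [velocity_curve()]; `curves1` is the reference.
#' @param dv_ref Optional named vector `c(radial = , longitudinal = )`
#'   of reference velocity ranges for the nRMSD normalization; default
#'   uses the ranges of `curves1`.
#' @return Tibble with one row per direction: `direction`, `pf`,
#'   `nrmsd`, `corr`, `dv_diff`, `dt_dias_ms`, `dv_seq1`, `dv_seq2`.
#' @export
compare_acquisitions <- function(curves1, curves2, dv_ref = NULL) {
  purrr::map_dfr(c("radial", "longitudinal"), function(dir) {
    c1 <- curves1[[dir]]; c2 <- curves2[[dir]]
    stopifnot(inherits(c1, "velocity_curve"), inherits(c2, "velocity_curve"))
    if (is.null(c1$dense) || is.null(c2$dense))
      stop("curves must be resampled before comparison")
    if (nrow(c1$dense) != nrow(c2$dense))
      stop("dense grids differ between acquisitions")
    f1 <- find_peaks(c1); f2 <- find_peaks(c2)
    dvr <- if (is.null(dv_ref)) f1$delta_v else unname(dv_ref[dir])
    tibble::tibble(
      direction = dir,
      pf = peak_factor(f1$delta_v, f2$delta_v),
      nrmsd = nrmsd(c1$dense$v_cm_s, c2$dense$v_cm_s, dvr),
      corr = curve_correlation(c1$dense$v_cm_s, c2$dense$v_cm_s),
      dv_diff = f2$delta_v - f1$delta_v,
      dt_dias_ms = f2$t_dias_ms - f1$t_dias_ms,
      dv_seq1 = f1$delta_v, dv_seq2 = f2$delta_v
    )
  })
}

#' Cohort summary tables
#'
#' Aggregates per-subject comparison results into the five study tables:
#' peak factor (mean, sd), velocity-range difference (Bland-Altman),
#' nRMSD (mean, sd), correlation (mean, sd) and diastolic time-to-peak
#' difference (Bland-Altman), per arm and direction, each with a pooled
#' t-test p-value against the reference (reproducibility) arm.
#'
#' @param results Tibble of per-subject comparisons with columns
#'   `subject`, `arm` (e.g. `"ref"` or `"kt2"` .. `"kt7"`), `direction`,
#'   `pf`, `nrmsd`, `corr`, `dv_diff`, `dt_dias_ms`.
#' @param reference_arm Value of `arm` identifying the reproducibility
#'   comparisons (default `"ref"`).
#' @return Tibble with columns `metric`, `arm`, `direction`, `mean`,
#'   `sd`, `loa_lower`, `loa_upper` (Bland-Altman metrics only),
#'   `p_value` (`NA` for the reference arm itself), `n`.
#' @export
summarize_cohort <- function(results, reference_arm = "ref") {
  stopifnot(all(c("subject", "arm", "direction") %in% names(results)))
  metrics <- c(pf = "pf", dv_diff = "dv_diff", nrmsd = "nrmsd",
               corr = "corr", dt_dias_ms = "dt_dias_ms")
  ba_metrics <- c("dv_diff", "dt_dias_ms")
  long <- results |>
    tidyr::pivot_longer(dplyr::all_of(unname(metrics)),
                        names_to = "metric", values_to = "value")
  ref_vals <- long |> dplyr::filter(.data$arm == reference_arm)
  long |>
    dplyr::group_by(.data$metric, .data$arm, .data$direction) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      loa_lower = ifelse(.data$metric %in% ba_metrics,
                         .data$mean - 1.96 * .data$sd, NA_real_),
      loa_upper = ifelse(.data$metric %in% ba_metrics,
                         .data$mean + 1.96 * .data$sd, NA_real_),
      p_value = {
        if (.data$arm == reference_arm) NA_real_ else {
          rv <- ref_vals$value[ref_vals$metric == .data$metric &
                                 ref_vals$direction == .data$direction]
          gv <- long$value[long$metric == .data$metric &
                             long$arm == .data$arm &
                             long$direction == .data$direction]
          if (length(rv) >= 2 && length(gv) >= 2)
            pooled_t_test(rv, gv)$p_value else NA_real_
        }
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$metric, metrics), .data$arm, .data$direction)
}
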