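#' Plot a velocity curve
#'
#' Dense spline curve (line) with the sampled cardiac phases (points).
#'
#' @param object A [velocity_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.velocity_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object$samples,
                       ggplot2::aes(x = .data$t_ms, y = .data$v_cm_s))
  if (!is.null(object$dense))
    p <- p + ggplot2::geom_line(data = object$dense, colour = "grey40")
  p +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "time after R-wave [ms]",
                  y = sprintf("%s velocity [cm/s]", object$direction),
                  title = sprintf("%s myocardial velocity", object$direction)) +
    ggplot2::theme_minimal()
}

#' Plot cohort metrics against the k-t factor
#'
#' Mean +/- sd of a comparison metric per arm and direction.
#'
#' @param object A [run_experiment()] result.
#' @param metric One of `"pf"`, `"nrmsd"`, `"corr"`, `"dv_diff"`,
#'   `"dt_dias_ms"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tpm_experiment <- function(object, metric = "pf", ...) {
  tab <- dplyr::filter(object$summary, .data$metric == !!metric)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$arm, y = .data$mean,
                                    colour = .data$direction,
                                    group = .data$direction)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0.2, position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3),
                       alpha = 0.5) +
    ggplot2::labs(x = "acquisition arm", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a k-t sampling pattern
#'
#' Phase-encode line versus cardiac phase, sampled entries filled.
#'
#' @param pat A [make_kt_pattern()].
#' @return A ggplot object.
#' @export
plot_kt_pattern <- function(pat) {
  df <- pattern_table(pat)
  ggplot2::ggplot(dplyr::filter(df, .data$sampled),
                  ggplot2::aes(x = .data$phase, y = .data$line)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::labs(x = "cardiac phase", y = "phase-encode line (0-based)",
                  title = sprintf("k-t lattice, R = %d", pat$R)) +
    ggplot2::theme_minimal()
}
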