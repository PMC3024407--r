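#' Tidy and glance methods
#'
#' `tidy()` on a `tpm_experiment` returns the cohort summary tables;
#' on a `velocity_curve` the sampled curve. `glance()` on a
#' `tpm_experiment` returns a one-row overview.
#'
#' @param x A `tpm_experiment` or `velocity_curve`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method broom::tidy
tidy.tpm_experiment <- function(x, ...) x$summary

#' @rdname tidiers
#' @exportS3Method broom::tidy
tidy.velocity_curve <- function(x, ...) {
  dplyr::mutate(x$samples, direction = x$direction, .before = 1)
}

#' @rdname tidiers
#' @exportS3Method broom::glance
glance.tpm_experiment <- function(x, ...) {
  repro <- dplyr::filter(x$summary, .data$metric == "pf",
                         .data$arm == "ref")
  tibble::tibble(
    n_subjects = x$config$n_subjects,
    n_arms = length(unique(x$comparisons$arm)),
    kt_factors = paste(x$config$R_list, collapse = ","),
    noise_sd = x$config$noise_sd,
    mean_pf_repro = mean(repro$mean),
    seed = x$config$seed
  )
}
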