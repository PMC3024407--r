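#' Fourier-encode a cine to Cartesian k-space
#'
#' Applies the centered unitary 2-D discrete Fourier transform to every
#' image (per phase, per encoding segment) and adds independent complex
#' Gaussian noise. Rows of the k-space arrays are phase-encode lines
#' (k_y), columns frequency-encode samples (k_x); the DC line sits at
#' 0-based row index `n_pe %/% 2`.
#'
#' `noise_sd` is the standard deviation of a complex sample,
#' `sqrt(E|z|^2)`; real and imaginary parts each have sd
#' `noise_sd / sqrt(2)`. The unitary transform preserves this level in the
#' image domain.
#'
#' @param enc An [encode_velocity()] result.
#' @param noise_sd Complex-sample noise standard deviation (0 = noiseless).
#' @param seed Integer seed controlling the noise realization.
#' @return An object of class `kspace_series`: complex array `data`
#'   (`n_pe x n_freq x n_phases x n_encodings`), logical `sampled`
#'   (`n_pe x n_phases`, shared across encodings), `noise_sd`, and
#'   geometry fields carried over from `enc`.
#' @export
to_kspace <- function(enc, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(enc, "encoded_cine"), noise_sd >= 0)
  d <- dim(enc$images)
  nr <- d[1]; nc <- d[2]; nt <- d[3]; ne <- d[4]
  ksp <- array(complex(real = 0), d)
  for (e in seq_len(ne)) for (i in seq_len(nt))
    ksp[, , i, e] <- ft2c(enc$images[, , i, e])
  if (noise_sd > 0) {
    withr_seed(seed, {
      n <- length(ksp)
      ksp <- ksp + complex(real = stats::rnorm(n, sd = noise_sd / sqrt(2)),
                           imaginary = stats::rnorm(n, sd = noise_sd / sqrt(2)))
    })
    ksp <- array(ksp, d)
  }
  structure(list(
    data = ksp,
    sampled = matrix(TRUE, nr, nt),
    noise_sd = noise_sd,
    venc_cm_s = enc$venc_cm_s, matrix_size = c(nr, nc), n_phases = nt,
    pixel_mm = enc$pixel_mm, cycle_s = enc$cycle_s
  ), class = "kspace_series")
}

# evaluate `code` under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' @export
print.kspace_series <- function(x, ...) {
  cat(sprintf(
    "<kspace_series> %d x %d, %d phases, %d encodings, %.0f%% lines sampled\n",
    x$matrix_size[1], x$matrix_size[2], x$n_phases, dim(x$data)[4],
    100 * mean(x$sampled)))
  invisible(x)
}

#' Sheared k-t lattice sampling pattern
#'
#' Every cardiac phase samples every R-th phase-encode line, with the line
#' offset advancing by one per phase (`offsets[t] = (t - 1) mod R`,
#' 0-based lines). Over any R consecutive phases every line is sampled
#' exactly once (the lattice property). The phase count must be a multiple
#' of R so that undersampling is uniform across k-space.
#'
#' @param n_pe Number of phase-encode lines.
#' @param n_phases Number of cardiac phases (multiple of `R`).
#' @param R k-t factor.
#' @return An object of class `kt_pattern`: `R`, `n_pe`, `n_phases`,
#'   integer `offsets` (0-based, one per phase) and logical matrix
#'   `mask` (`n_pe x n_phases`).
#' @export
make_kt_pattern <- function(n_pe, n_phases, R) {
  stopifnot(n_pe >= 1, n_phases >= 1, R >= 1, R == round(R))
  if (n_phases %% R != 0)
    stop("n_phases must be a multiple of R")
  offsets <- (seq_len(n_phases) - 1L) %% R
  lines0 <- seq_len(n_pe) - 1L
  mask <- vapply(offsets, function(o) (lines0 - o) %% R == 0,
                 logical(n_pe))
  structure(list(R = as.integer(R), n_pe = as.integer(n_pe),
                 n_phases = as.integer(n_phases),
                 offsets = as.integer(offsets), mask = mask),
            class = "kt_pattern")
}

#' @export
print.kt_pattern <- function(x, ...) {
  cat(sprintf("<kt_pattern> R = %d, %d lines x %d phases\n",
              x$R, x$n_pe, x$n_phases))
  invisible(x)
}

#' Sampling pattern as a tidy table
#'
#' @param pat A [make_kt_pattern()] result.
#' @return Tibble with columns `phase` (1-based), `line` (0-based) and
#'   `sampled`, suitable for CSV export or plotting.
#' @export
pattern_table <- function(pat) {
  stopifnot(inherits(pat, "kt_pattern"))
  tidyr::expand_grid(phase = seq_len(pat$n_phases),
                     line = seq_len(pat$n_pe) - 1L) |>
    dplyr::mutate(sampled = pat$mask[cbind(.data$line + 1L, .data$phase)])
}

#' Apply a k-t sampling pattern to a k-space series
#'
#' Zeroes the unsampled phase-encode lines of every encoding and records
#' the pattern in the `sampled` mask; sampled lines are passed through
#' unchanged. All encodings share the schedule (they are acquired in
#' consecutive beats under the same lattice).
#'
#' @param k A [to_kspace()] result.
#' @param pat A [make_kt_pattern()] result with matching geometry.
#' @return A `kspace_series` with zeroed unsampled lines and the pattern
#'   attached as `$pattern`.
#' @export
undersample <- function(k, pat) {
  stopifnot(inherits(k, "kspace_series"), inherits(pat, "kt_pattern"))
  if (pat$n_pe != k$matrix_size[1] || pat$n_phases != k$n_phases)
    stop("pattern shape does not match k-space series")
  out <- k
  ne <- dim(k$data)[4]
  for (i in seq_len(k$n_phases)) {
    drop_lines <- which(!pat$mask[, i])
    if (length(drop_lines))
      out$data[drop_lines, , i, ] <- 0
  }
  out$sampled <- pat$mask
  out$pattern <- pat
  out
}

#' Extract the low-resolution training data
#'
#' Central block of `training_lines` phase-encode lines (spanning the DC
#' line), all phases, all encodings, noise included. Stands in for the
#' fully time-sampled low-resolution training stage of a k-t acquisition
#' (interleaved-training approximation).
#'
#' @param k A fully sampled [to_kspace()] result.
#' @param training_lines Number of central lines (11 by default; odd
#'   preferred so the block is symmetric about DC).
#' @return An object of class `training_set`: complex array `data`
#'   (`training_lines x n_freq x n_phases x n_encodings`), the 1-based
#'   `line_index` of the retained lines in the full grid, and geometry.
#' @export
acquire_training <- function(k, training_lines = 11) {
  stopifnot(inherits(k, "kspace_series"), training_lines >= 1)
  n_pe <- k$matrix_size[1]
  if (training_lines > n_pe)
    stop("training_lines exceeds the number of phase-encode lines")
  dc <- dc_index(n_pe)  # 0-based
  lines0 <- dc - training_lines %/% 2 + 0:(training_lines - 1)
  if (min(lines0) < 0 || max(lines0) > n_pe - 1)
    stop("training block does not fit the phase-encode grid")
  idx <- lines0 + 1L
  structure(list(
    data = k$data[idx, , , , drop = FALSE],
    line_index = idx, n_pe = n_pe,
    matrix_size = k$matrix_size, n_phases = k$n_phases,
    noise_sd = k$noise_sd
  ), class = "training_set")
}
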