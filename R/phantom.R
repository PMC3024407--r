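#' Dynamic short-axis left-ventricle phantom
#'
#' Builds a cine phantom: a myocardial annulus around a (suppressed) blood
#' pool, a time-invariant block of static tissue, and a ground-truth
#' three-component velocity field. The annulus wall translates radially
#' according to the displacement integral of the radial waveform (positive
#' radial velocity = inward = contraction), so masks and velocities are
#' mutually consistent. Every myocardial pixel carries in-plane velocity
#' of magnitude `radial waveform(t)` directed toward the centroid plus a
#' through-plane component equal to the longitudinal waveform
#' (apex-positive). Through-plane motion does not move pixels between
#' slices (thin-slice approximation). Static-tissue pixels have exactly
#' zero velocity at all phases.
#'
#' @param m A [motion_model()].
#' @param n_phases Number of cardiac phases (>= 2).
#' @param matrix_size `c(rows, cols)` of the image grid; rows are the
#'   phase-encode direction. Default 120 x 120 (scaled from the printed
#'   acquisition matrix so the grid divides evenly under the default k-t
#'   factor sweep).
#' @param pixel_mm In-plane pixel size in mm (default 2).
#' @param cycle_s Duration of the imaged part of the cycle in seconds
#'   (the acquisition window); phase `i` sits at
#'   `t_frac = (i - 1) / n_phases` of this window.
#' @param r_endo_mm,r_epi_mm End-diastolic endocardial / epicardial radii
#'   in mm.
#' @param centroid `c(row, col)` of the blood-pool centre in pixels;
#'   default is the grid centre.
#' @param static_rows Row range (2-vector) of the static-tissue slab.
#' @return An object of class `phantom_cine`: list with `n_phases`,
#'   `matrix_size`, `pixel_mm`, `cycle_s`, `myo_mask` / `blood_mask`
#'   (logical `rows x cols x n_phases`), `static_mask` (logical
#'   `rows x cols`), `velocity` (numeric `rows x cols x n_phases x 3`,
#'   components x = in-plane column direction, y = in-plane row direction,
#'   z = through-plane, cm/s), `centroid`, and the `motion_model`.
#' @examples
#' ph <- build_phantom(motion_model(), n_phases = 6,
#'                     matrix_size = c(48, 48))
#' @export
build_phantom <- function(m, n_phases,
                          matrix_size = c(120, 120), pixel_mm = 2,
                          cycle_s = 0.9,
                          r_endo_mm = 20, r_epi_mm = 36,
                          centroid = NULL,
                          static_rows = NULL) {
  stopifnot(inherits(m, "motion_model"), n_phases >= 2,
            length(matrix_size) == 2, r_endo_mm < r_epi_mm)
  nr <- as.integer(matrix_size[1]); nc <- as.integer(matrix_size[2])
  if (is.null(centroid)) centroid <- c((nr + 1) / 2, (nc + 1) / 2)
  px_cm <- pixel_mm / 10

  t_frac <- (seq_len(n_phases) - 1) / n_phases
  disp_cm <- waveform_displacement(t_frac, m, "radial", cycle_s)
  r_endo_px <- (r_endo_mm / pixel_mm) - disp_cm / px_cm
  r_epi_px <- (r_epi_mm / pixel_mm) - disp_cm / px_cm
  if (any(r_endo_px <= 2))
    stop("endocardial radius collapses; reduce radial motion")

  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- row_idx - centroid[1]
  dc <- col_idx - centroid[2]
  dist <- sqrt(dr^2 + dc^2)
  max_r <- max(r_epi_px)
  if (centroid[1] - max_r < 1 || centroid[1] + max_r > nr ||
      centroid[2] - max_r < 1 || centroid[2] + max_r > nc)
    stop("annulus does not fit inside the image matrix")

  # unit vectors pointing from each pixel toward the centroid
  safe <- pmax(dist, .Machine$double.eps)
  u_row <- -dr / safe
  u_col <- -dc / safe

  if (is.null(static_rows)) {
    bottom <- max(7L, as.integer(floor(centroid[1] - max_r)) - 2L)
    static_rows <- c(max(2L, bottom - 5L), bottom)
  }
  static_mask <- matrix(FALSE, nr, nc)
  static_mask[static_rows[1]:static_rows[2], 4:(nc - 3)] <- TRUE

  myo <- array(FALSE, c(nr, nc, n_phases))
  blood <- array(FALSE, c(nr, nc, n_phases))
  vel <- array(0, c(nr, nc, n_phases, 3))
  v_rad <- velocity_waveform(t_frac, m, "radial")
  v_long <- velocity_waveform(t_frac, m, "longitudinal")
  for (i in seq_len(n_phases)) {
    ring <- dist >= r_endo_px[i] & dist <= r_epi_px[i]
    pool <- dist <= (r_endo_px[i] - 1.5)
    ring <- ring & !static_mask
    pool <- pool & !static_mask
    myo[, , i] <- ring
    blood[, , i] <- pool
    vx <- matrix(0, nr, nc); vy <- matrix(0, nr, nc); vz <- matrix(0, nr, nc)
    vx[ring] <- v_rad[i] * u_col[ring]
    vy[ring] <- v_rad[i] * u_row[ring]
    vz[ring] <- v_long[i]
    vel[, , i, 1] <- vx
    vel[, , i, 2] <- vy
    vel[, , i, 3] <- vz
  }
  if (!any(static_mask)) stop("static mask is empty")

  structure(list(
    n_phases = as.integer(n_phases), matrix_size = c(nr, nc),
    pixel_mm = pixel_mm, cycle_s = cycle_s,
    myo_mask = myo, blood_mask = blood, static_mask = static_mask,
    velocity = vel, centroid = centroid, motion = m
  ), class = "phantom_cine")
}

#' @export
print.phantom_cine <- function(x, ...) {
  cat(sprintf("<phantom_cine> %d x %d, %d phases, pixel %g mm, cycle %g s\n",
              x$matrix_size[1], x$matrix_size[2], x$n_phases, x$pixel_mm,
              x$cycle_s))
  invisible(x)
}

#' Four-point velocity encoding of a phantom cine
#'
#' Forms the complex image stacks of a referenced four-point velocity
#' encoding experiment: a reference segment whose phase is the background
#' phase plane only, and one segment per spatial direction whose phase adds
#' `pi * v_e / venc`. Bipolar-gradient encoding makes spin phase
#' proportional to velocity; the background plane models the residual
#' (eddy-current-like) phase error as linear in space. Pixel magnitude is
#' taken from the tissue class and is identical across the four encodings;
#' blood is suppressed (black-blood contrast).
#'
#' Velocities at or beyond `venc` would wrap; this simulator treats them as
#' an error rather than aliasing them.
#'
#' @param ph A [build_phantom()] result.
#' @param venc_cm_s Encoding velocity (cm/s).
#' @param background_coeffs `c(offset, slope_row, slope_col)` of the
#'   background phase plane, radians and radians/pixel, evaluated as
#'   `offset + slope_row * (row - 1) + slope_col * (col - 1)`.
#' @param magnitudes Named list of tissue magnitudes:
#'   `myo`, `blood`, `static`, `air`.
#' @return An object of class `encoded_cine`: `images` is a complex array
#'   `rows x cols x n_phases x 4` with encoding order
#'   `(ref, x, y, z)`, plus `venc_cm_s`, `background_coeffs` and the
#'   phantom geometry fields.
#' @export
encode_velocity <- function(ph, venc_cm_s = 30,
                            background_coeffs = c(0, 0, 0),
                            magnitudes = list(myo = 1, blood = 0.02,
                                              static = 0.8, air = 0)) {
  stopifnot(inherits(ph, "phantom_cine"), venc_cm_s > 0,
            length(background_coeffs) == 3)
  if (max(abs(ph$velocity)) >= venc_cm_s)
    stop("phantom velocity reaches or exceeds VENC: would alias")
  nr <- ph$matrix_size[1]; nc <- ph$matrix_size[2]; nt <- ph$n_phases
  row_idx <- matrix(seq_len(nr) - 1, nr, nc)
  col_idx <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  bg <- background_coeffs[1] + background_coeffs[2] * row_idx +
    background_coeffs[3] * col_idx

  images <- array(complex(real = 0), c(nr, nc, nt, 4))
  for (i in seq_len(nt)) {
    mag <- matrix(magnitudes$air, nr, nc)
    mag[ph$static_mask] <- magnitudes$static
    mag[ph$myo_mask[, , i]] <- magnitudes$myo
    mag[ph$blood_mask[, , i]] <- magnitudes$blood
    images[, , i, 1] <- mag * exp(1i * bg)
    for (e in 1:3) {
      ph_enc <- bg + pi * ph$velocity[, , i, e] / venc_cm_s
      images[, , i, e + 1] <- mag * exp(1i * ph_enc)
    }
  }
  structure(list(
    images = images, venc_cm_s = venc_cm_s,
    background_coeffs = background_coeffs,
    matrix_size = ph$matrix_size, n_phases = nt,
    pixel_mm = ph$pixel_mm, cycle_s = ph$cycle_s
  ), class = "encoded_cine")
}

#' @export
print.encoded_cine <- function(x, ...) {
  cat(sprintf("<encoded_cine> %d x %d, %d phases, 4 encodings, VENC %g cm/s\n",
              x$matrix_size[1], x$matrix_size[2], x$n_phases, x$venc_cm_s))
  invisible(x)
}
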