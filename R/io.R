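#' Write / read an encoded cine as NIfTI stacks
#'
#' One magnitude and one phase 4-D NIfTI file per encoding segment
#' (`<prefix>_<segment>_mag.nii.gz`, `<prefix>_<segment>_phase.nii.gz`,
#' segments `ref`, `x`, `y`, `z`), plus a JSON sidecar
#' (`<prefix>.json`) carrying the VENC, background coefficients, sign
#' conventions and geometry, so the stacks are self-describing.
#'
#' @param enc An [encode_velocity()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return For the writer, `dir` invisibly; for the reader, an
#'   `encoded_cine` object.
#' @export
write_encoded_nifti <- function(enc, dir, prefix = "cine") {
  stopifnot(inherits(enc, "encoded_cine"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  segs <- c("ref", "x", "y", "z")
  for (e in seq_along(segs)) {
    vol <- enc$images[, , , e, drop = TRUE]
    RNifti::writeNifti(
      RNifti::asNifti(Mod(vol), pixdim = c(enc$pixel_mm, enc$pixel_mm, 1)),
      file.path(dir, sprintf("%s_%s_mag.nii.gz", prefix, segs[e])))
    RNifti::writeNifti(
      RNifti::asNifti(Arg(vol), pixdim = c(enc$pixel_mm, enc$pixel_mm, 1)),
      file.path(dir, sprintf("%s_%s_phase.nii.gz", prefix, segs[e])))
  }
  sidecar <- list(
    venc_cm_s = enc$venc_cm_s,
    background_coeffs = enc$background_coeffs,
    matrix_size = enc$matrix_size, n_phases = enc$n_phases,
    pixel_mm = enc$pixel_mm, cycle_s = enc$cycle_s,
    encodings = segs,
    sign_convention = paste("radial velocity positive toward blood-pool",
                            "centroid; longitudinal positive toward apex")
  )
  jsonlite::write_json(sidecar, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_encoded_nifti
#' @export
read_encoded_nifti <- function(dir, prefix = "cine") {
  sidecar <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                                 simplifyVector = TRUE)
  segs <- sidecar$encodings
  nr <- sidecar$matrix_size[1]; nc <- sidecar$matrix_size[2]
  nt <- sidecar$n_phases
  images <- array(complex(real = 0), c(nr, nc, nt, length(segs)))
  for (e in seq_along(segs)) {
    mag <- as.array(RNifti::readNifti(
      file.path(dir, sprintf("%s_%s_mag.nii.gz", prefix, segs[e]))))
    phs <- as.array(RNifti::readNifti(
      file.path(dir, sprintf("%s_%s_phase.nii.gz", prefix, segs[e]))))
    images[, , , e] <- mag * exp(1i * phs)
  }
  structure(list(images = images, venc_cm_s = sidecar$venc_cm_s,
                 background_coeffs = sidecar$background_coeffs,
                 matrix_size = c(nr, nc), n_phases = nt,
                 pixel_mm = sidecar$pixel_mm, cycle_s = sidecar$cycle_s),
            class = "encoded_cine")
}

#' Write phantom masks as NIfTI
#'
#' Myocardial and blood masks as 4-D (space x phase) integer volumes and
#' the static mask as a 3-D volume, with a JSON sidecar recording the
#' geometry and sign conventions.
#'
#' @param ph A [build_phantom()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_phantom_nifti <- function(ph, dir, prefix = "phantom") {
  stopifnot(inherits(ph, "phantom_cine"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(arr, name)
    RNifti::writeNifti(RNifti::asNifti(arr * 1L),
                       file.path(dir, sprintf("%s_%s.nii.gz", prefix, name)))
  wr(ph$myo_mask, "myo_mask")
  wr(ph$blood_mask, "blood_mask")
  wr(ph$static_mask, "static_mask")
  sidecar <- list(matrix_size = ph$matrix_size, n_phases = ph$n_phases,
                  pixel_mm = ph$pixel_mm, cycle_s = ph$cycle_s,
                  centroid = ph$centroid)
  jsonlite::write_json(sidecar, file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
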