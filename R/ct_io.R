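#' CT volume container
#'
#' Bundles a 3D grid of Hounsfield-unit (HU) values with its voxel geometry.
#' Array axis 1 is cranio-caudal (axial slice index, increasing caudally),
#' axis 2 is image row, axis 3 is image column. `spacing` is `c(dx, dy, dz)`
#' in mm, where `dx`/`dy` are the in-plane column/row spacings and `dz` the
#' slice increment.
#'
#' @param voxels 3D numeric array of HU values, `[slice, row, col]`.
#' @param spacing Numeric length 3, `c(dx, dy, dz)` in mm, all positive.
#' @param subject_id Character scalar identifying the subject.
#' @return An object of class `ct_volume`.
#' @export
#' @examples
#' vol <- ct_volume(array(-90, c(4, 4, 4)), spacing = c(2, 2, 3))
#' voxel_volume_liters(vol)
ct_volume <- function(voxels, spacing, subject_id = "subject") {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  rng <- range(voxels)
  if (rng[1] < HU_VALID_MIN || rng[2] > HU_VALID_MAX)
    stop("HU values outside the valid range [", HU_VALID_MIN, ", ",
         HU_VALID_MAX, "]; rescale or clamp the input")
  structure(list(voxels = voxels, spacing = spacing,
                 subject_id = as.character(subject_id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume '%s'> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU [%.0f, %.0f]\n",
    x$subject_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Load a CT volume from disk
#'
#' Reads a NIfTI-1 file or a DICOM series directory into a [ct_volume()],
#' applying HU rescaling (DICOM RescaleSlope/RescaleIntercept, NIfTI
#' scl_slope/scl_inter) and reading voxel spacing from the metadata. Values
#' outside `[-1100, 4000]` HU are clamped (air floor / metal cap). The
#' cranio-caudal axis becomes array axis 1; for NIfTI the on-disk third
#' axis is taken as cranio-caudal with index 1 most cranial.
#'
#' @param path File (`.nii`/`.nii.gz`) or DICOM directory.
#' @param format `"nifti"` or `"dicom_dir"`; the default guesses from
#'   `path`.
#' @param subject_id Subject label; defaults to the file/directory name.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path,
                        format = c("auto", "nifti", "dicom_dir"),
                        subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "dicom_dir") {
    if (!dir.exists(path)) stop("DICOM directory not found: ", path)
    r <- read_dicom_series(path)
    vox <- r$data
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    r <- read_nifti(path)
    # on-disk [x, y, z] -> internal [z, row = y, col = x]
    vox <- aperm(r$data, c(3L, 2L, 1L))
  }
  vox[vox < HU_VALID_MIN] <- HU_VALID_MIN
  vox[vox > HU_VALID_MAX] <- HU_VALID_MAX
  ct_volume(vox, r$spacing,
            subject_id = subject_id %||% basename(path))
}

#' Save a CT volume to disk
#'
#' Inverse of [load_volume()]: writes NIfTI-1 (float64, exact HU
#' round-trip) or a minimal DICOM series (int16 HU).
#'
#' @param vol A [ct_volume()].
#' @param path Output file or directory.
#' @param format `"nifti"` or `"dicom_dir"`; guessed from `path` by default.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path,
                        format = c("auto", "nifti", "dicom_dir")) {
  stopifnot(inherits(vol, "ct_volume"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "dicom_dir"
  if (format == "nifti") {
    write_nifti(aperm(vol$voxels, c(3L, 2L, 1L)), vol$spacing, path)
  } else {
    write_dicom_series(vol$voxels, vol$spacing, path)
  }
  invisible(path)
}

#' Anatomical landmark set
#'
#' Operator-supplied axial slice indices: the L3-L4 and L4-L5
#' intervertebral levels and the proximal/distal extent of the femur. The
#' protocol is semi-automatic; landmarks are never auto-detected.
#'
#' @param l3l4,l4l5 Axial indices of the L3-L4 and L4-L5 slices.
#' @param femur_proximal,femur_distal Axial indices delimiting the femur.
#'   With the cranio-caudal index increasing caudally the proximal index is
#'   the smaller one; the extent must have positive length.
#' @param n_slices Optional volume depth for bounds checking.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(l3l4, l4l5, femur_proximal, femur_distal,
                         n_slices = NULL) {
  idx <- c(l3l4 = l3l4, l4l5 = l4l5, femur_proximal = femur_proximal,
           femur_distal = femur_distal)
  if (any(idx != round(idx)) || any(idx < 1))
    stop("landmark indices must be positive integers")
  if (femur_proximal == femur_distal)
    stop("femoral extent must have positive length")
  if (!is.null(n_slices) && any(idx > n_slices))
    stop("landmark index outside volume bounds (n_slices = ", n_slices, ")")
  structure(as.list(idx), class = "landmark_set")
}

#' Read landmarks from a key:value text file
#'
#' One `key: value` pair per line; keys `l3l4`, `l4l5`, `femur_proximal`,
#' `femur_distal`. Blank lines and `#` comments are ignored.
#'
#' @param path Path to the landmark file.
#' @param n_slices Optional volume depth for bounds checking.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, n_slices = NULL) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  kv <- read_key_values(path)
  need <- c("l3l4", "l4l5", "femur_proximal", "femur_distal")
  missing <- setdiff(need, names(kv))
  if (length(missing))
    stop("landmark file ", path, " is missing: ",
         paste(missing, collapse = ", "))
  landmark_set(as.numeric(kv[["l3l4"]]), as.numeric(kv[["l4l5"]]),
               as.numeric(kv[["femur_proximal"]]),
               as.numeric(kv[["femur_distal"]]), n_slices = n_slices)
}

read_key_values <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed key:value line in ", path, ": ",
                     lines[bad][1])
  vals <- lapply(parts, function(p) trimws(paste(p[-1], collapse = ":")))
  names(vals) <- trimws(vapply(parts, `[[`, "", 1L))
  vals
}

#' Axial slice index at a femoral-length fraction
#'
#' Locates the axial slice at a given fraction of the maximum femoral
#' length, measured from the distal end of the femur: fraction 0.15 is at
#' the knee, 0.5 is the mid-thigh, 0.85 the gluteal region.
#'
#' @param landmarks A [landmark_set()].
#' @param fraction Number in `[0, 1]`, measured from the distal femur.
#' @return Integer slice index (fractional positions rounded to the
#'   nearest slice, halves away from the distal end).
#' @export
#' @examples
#' lm <- landmark_set(30, 40, femur_proximal = 100, femur_distal = 200)
#' femoral_fraction_slice(lm, 0.5)
femoral_fraction_slice <- function(landmarks, fraction) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("`fraction` must be a single number in [0, 1]")
  pos <- landmarks$femur_distal +
    fraction * (landmarks$femur_proximal - landmarks$femur_distal)
  # round half away from the distal end, so the mapping is monotone in
  # `fraction` regardless of the axial direction of the femur
  toward <- sign(landmarks$femur_proximal - landmarks$femur_distal)
  as.integer(if (toward > 0) floor(pos + 0.5) else ceiling(pos - 0.5))
}

#' Voxel volume in liters
#'
#' @param vol A [ct_volume()].
#' @return Volume of one voxel in liters (`dx*dy*dz` mm^3 / 1e6).
#' @export
voxel_volume_liters <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  prod(vol$spacing) / 1e6
}
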