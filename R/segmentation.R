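## Denoising, voxel classification and volumetry.

#' 3x3x3 median denoising
#'
#' Replaces every voxel by the median of its 3x3x3 neighbourhood (borders
#' reflected). Suppresses impulse noise without moving tissue edges by more
#' than one voxel; applied to the whole stack before both calibration and
#' classification.
#'
#' @param vol A [ct_volume()], at least 3 voxels along every axis.
#' @return A denoised [ct_volume()] with unchanged spacing.
#' @export
median_denoise <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  if (any(dim(vol$voxels) < 3L))
    stop("median_denoise() needs at least 3 voxels along every axis")
  out <- vol
  out$voxels <- .median3d_cpp(vol$voxels)
  out
}

#' Classify voxels into adipose and lean tissue
#'
#' Thresholds the (denoised) volume with a subject calibration: adipose
#' voxels have HU in `[-205, cutoff]`, lean voxels HU in
#' `[cutoff + 1, max HU of the scan]`. Voxels below -205 HU (air/lung) are
#' in neither mask. The two masks are disjoint and together exhaust
#' `[-205, max]`.
#'
#' @param vol A denoised [ct_volume()] (the caller is responsible for
#'   denoising first; [run_pipeline()] enforces the order).
#' @param cal A `density_calibration` from [calibrate()], or a single
#'   cutoff in HU.
#' @return An object of class `tissue_masks`: logical 3D arrays `at_mask`
#'   and `lt_mask` plus `source_spacing`.
#' @export
classify <- function(vol, cal) {
  stopifnot(inherits(vol, "ct_volume"))
  cutoff <- if (inherits(cal, "density_calibration")) cal$cutoff
            else as.numeric(cal)
  v <- vol$voxels
  at <- v >= HU_AT_FLOOR & v <= cutoff
  lt <- v > cutoff           # scan max is an upper bound by construction
  structure(list(at_mask = at, lt_mask = lt,
                 source_spacing = vol$spacing, cutoff = cutoff),
            class = "tissue_masks")
}

#' Total tissue volumes in liters
#'
#' @param masks A `tissue_masks` from [classify()].
#' @return Named numeric: `at_volume_L`, `lt_volume_L` (voxel count times
#'   voxel volume).
#' @export
total_volumes <- function(masks) {
  stopifnot(inherits(masks, "tissue_masks"))
  vox_l <- prod(masks$source_spacing) / 1e6
  c(at_volume_L = sum(masks$at_mask) * vox_l,
    lt_volume_L = sum(masks$lt_mask) * vox_l)
}

#' Tissue areas on the three prediction slices
#'
#' Measures AT and LT cross-sectional areas (cm^2) on the L3-L4, L4-L5 and
#' mid-thigh axial slices; the mid-thigh is located at 50% of femoral
#' length via [femoral_fraction_slice()].
#'
#' @param masks A `tissue_masks`.
#' @param landmarks A [landmark_set()].
#' @return Named numeric with `at_l3l4`, `at_l4l5`, `at_midthigh`,
#'   `lt_l3l4`, `lt_l4l5`, `lt_midthigh` in cm^2.
#' @export
measure_slice_areas <- function(masks, landmarks) {
  stopifnot(inherits(masks, "tissue_masks"),
            inherits(landmarks, "landmark_set"))
  nz <- dim(masks$at_mask)[1]
  mid <- femoral_fraction_slice(landmarks, 0.5)
  idx <- c(l3l4 = landmarks$l3l4, l4l5 = landmarks$l4l5, midthigh = mid)
  if (any(idx < 1L) || any(idx > nz))
    stop("slice landmark outside volume (depth ", nz, "): ",
         paste(names(idx)[idx < 1L | idx > nz], collapse = ", "))
  px_cm2 <- masks$source_spacing[1] * masks$source_spacing[2] / 100
  area <- function(mask, i) sum(mask[i, , ]) * px_cm2
  c(at_l3l4 = area(masks$at_mask, idx["l3l4"]),
    at_l4l5 = area(masks$at_mask, idx["l4l5"]),
    at_midthigh = area(masks$at_mask, idx["midthigh"]),
    lt_l3l4 = area(masks$lt_mask, idx["l3l4"]),
    lt_l4l5 = area(masks$lt_mask, idx["l4l5"]),
    lt_midthigh = area(masks$lt_mask, idx["midthigh"]))
}
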