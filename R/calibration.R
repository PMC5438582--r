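## Per-subject AT/LT density cutoff calibration.
##
## The cutoff between adipose tissue (AT) and lean tissue (LT) is read off
## eight line-profile histograms drawn on three axial slices (L4-L5, 85% and
## 15% of femoral length). Lines a, b, e, g run through pure AT depots
## (subcutaneous, visceral, subcutaneous again, intramuscular); lines c, d,
## f, h cross an AT/LT transition with the transition at mid-line. The eight
## per-line upper limits are averaged into a single HU cutoff. Calibrating
## per subject absorbs scanner-dependent HU bias, which is the point of the
## protocol: fixed literature windows (-190..-30 HU) misbehave once the
## scanner offset moves.

LINE_LABELS <- c("a", "b", "c", "d", "e", "f", "g", "h")
PURE_LABELS <- c("a", "b", "e", "g")
MIXED_LABELS <- c("c", "d", "f", "h")

# Fixed read-off constants (see the methods vignette).
CAL_PURE_PERCENTILE <- 0.98
CAL_KDE_BANDWIDTH <- 8      # HU, Gaussian kernel SD
CAL_GRID_MIN <- -205
CAL_GRID_MAX <- 150
CAL_CORRIDOR <- c(-26, 36)  # paper's observed range -16..26 widened by 1 SD

#' Line profile of HU samples
#'
#' @param values Numeric vector of HU samples along a drawn segment
#'   (at least 10).
#' @param kind `"pure_at"` (100% adipose) or `"mixed"` (crosses an AT/LT
#'   transition).
#' @param label Line label `a`..`h`; labels a, b, e, g must be pure, the
#'   rest mixed.
#' @param slice_level `"l4l5"`, `"femur85"` or `"femur15"`.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(values, kind = c("pure_at", "mixed"),
                         label = LINE_LABELS,
                         slice_level = c("l4l5", "femur85", "femur15")) {
  kind <- match.arg(kind)
  label <- match.arg(label)
  slice_level <- match.arg(slice_level)
  values <- as.numeric(values)
  if (length(values) < 10L)
    stop("a line profile needs at least 10 samples, got ", length(values))
  expected <- if (label %in% PURE_LABELS) "pure_at" else "mixed"
  if (kind != expected)
    stop("label '", label, "' must have kind '", expected, "'")
  structure(list(values = values, kind = kind, label = label,
                 slice_level = slice_level),
            class = "line_profile")
}

#' Sample a line profile from an axial slice
#'
#' Samples HU values at unit-pixel steps along the segment from `p0` to
#' `p1` (inclusive endpoints) using nearest-neighbour pixels, mirroring how
#' a histogram over the rasterised line behaves.
#'
#' @param slice2d 2D HU matrix `[row, col]`.
#' @param p0,p1 Numeric `(row, col)` endpoints, inside the slice.
#' @param label Line label `a`..`h` (fixes the kind).
#' @param slice_level Anatomical level of the slice.
#' @return A [line_profile()].
#' @export
sample_line_profile <- function(slice2d, p0, p1, label,
                                slice_level = c("l4l5", "femur85",
                                                "femur15")) {
  stopifnot(is.matrix(slice2d), length(p0) == 2L, length(p1) == 2L)
  if (all(p0 == p1)) stop("degenerate segment: p0 equals p1")
  len <- sqrt(sum((p1 - p0)^2))
  if (len < 10) stop("segment too short (", round(len, 2),
                     " px); need length >= 10")
  n <- as.integer(round(len)) + 1L
  t <- seq(0, 1, length.out = n)
  rows <- as.integer(round(p0[1] + t * (p1[1] - p0[1])))
  cols <- as.integer(round(p0[2] + t * (p1[2] - p0[2])))
  if (any(rows < 1L) || any(rows > nrow(slice2d)) ||
      any(cols < 1L) || any(cols > ncol(slice2d)))
    stop("line endpoints outside slice bounds")
  kind <- if (label %in% PURE_LABELS) "pure_at" else "mixed"
  line_profile(slice2d[cbind(rows, cols)], kind = kind, label = label,
               slice_level = match.arg(slice_level))
}

#' Upper density limit of a pure-AT line
#'
#' The per-line upper limit of a 100%-adipose profile, read as the 98th
#' percentile of its HU samples — a deterministic, hot-pixel-robust
#' surrogate for the visually read upper edge of the histogram.
#'
#' @param profile A [line_profile()] with kind `"pure_at"`.
#' @param percentile Read-off percentile (default 0.98).
#' @return Upper limit in HU.
#' @export
upper_limit_pure <- function(profile, percentile = CAL_PURE_PERCENTILE) {
  stopifnot(inherits(profile, "line_profile"))
  if (profile$kind != "pure_at")
    stop("upper_limit_pure() requires a pure_at profile, got '",
         profile$kind, "'")
  unname(quantile(profile$values, percentile))
}

#' Upper density limit of a mixed (transition) line
#'
#' The AT/LT transition density of a line crossing from adipose into lean
#' tissue, read as the antimode of a kernel-smoothed density of its HU
#' samples: Gaussian kernel (default bandwidth 8 HU) evaluated on a 1-HU
#' grid over \[-205, 150\]; the returned value is the density minimum
#' strictly between the two largest modes (mean position over ties). If the
#' smoothed density is unimodal the midpoint of the 25th and 75th
#' percentiles is used as a fallback.
#'
#' @param profile A [line_profile()] with kind `"mixed"`.
#' @param bandwidth Kernel SD in HU.
#' @return Transition density in HU.
#' @export
upper_limit_mixed <- function(profile, bandwidth = CAL_KDE_BANDWIDTH) {
  stopifnot(inherits(profile, "line_profile"))
  if (profile$kind != "mixed")
    stop("upper_limit_mixed() requires a mixed profile, got '",
         profile$kind, "'")
  x <- profile$values
  grid <- seq(CAL_GRID_MIN, CAL_GRID_MAX, by = 1)
  dens <- vapply(grid, function(g) sum(dnorm(g, mean = x, sd = bandwidth)),
                 0) / length(x)
  # local maxima on the grid (plateau-aware)
  n <- length(dens)
  is_max <- c(FALSE, dens[2:(n - 1)] >= dens[1:(n - 2)] &
                     dens[2:(n - 1)] > dens[3:n], FALSE)
  modes <- grid[is_max]
  mode_heights <- dens[is_max]
  if (length(modes) >= 2L) {
    top2 <- sort(modes[order(mode_heights, decreasing = TRUE)[1:2]])
    between <- grid > top2[1] & grid < top2[2]
    dmin <- min(dens[between])
    return(mean(grid[between][dens[between] <= dmin + 1e-12]))
  }
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  if (diff(q) <= 0)
    stop("cannot locate a transition: profile is unimodal with zero IQR")
  mean(q)
}

#' Calibrate the per-subject AT/LT cutoff
#'
#' Averages the eight per-line upper density limits (labels `a`..`h`, one
#' each) into the subject's AT/LT cutoff, rounded to integer HU. The
#' adipose window is then `[-205, cutoff]` and the lean window
#' `[cutoff + 1, max HU of the scan]`. A warning (not an error) is emitted
#' when the cutoff falls outside `[-26, 36]` HU, the empirically observed
#' corridor widened by one SD.
#'
#' @param profiles List of eight [line_profile()]s, one per label.
#' @return An object of class `density_calibration` with fields
#'   `per_line_upper_limits` (named, HU), `cutoff` (integer HU),
#'   `at_range` and `lt_lower`.
#' @export
calibrate <- function(profiles) {
  labels <- vapply(profiles, function(p) {
    stopifnot(inherits(p, "line_profile"))
    p$label
  }, "")
  if (length(profiles) != 8L || anyDuplicated(labels) ||
      !setequal(labels, LINE_LABELS))
    stop("calibrate() needs exactly one profile for each label a..h; got: ",
         paste(sort(labels), collapse = ", "))
  profiles <- profiles[order(match(labels, LINE_LABELS))]
  limits <- vapply(profiles, function(p) {
    if (p$kind == "pure_at") upper_limit_pure(p) else upper_limit_mixed(p)
  }, 0)
  names(limits) <- LINE_LABELS
  cutoff <- round(mean(limits))
  if (cutoff < CAL_CORRIDOR[1] || cutoff > CAL_CORRIDOR[2])
    warning("calibrated cutoff ", cutoff, " HU is outside the expected ",
            "corridor [", CAL_CORRIDOR[1], ", ", CAL_CORRIDOR[2], "] HU")
  structure(list(per_line_upper_limits = limits,
                 cutoff = as.integer(cutoff),
                 at_range = c(HU_AT_FLOOR, cutoff),
                 lt_lower = as.integer(cutoff + 1L)),
            class = "density_calibration")
}

#' @export
print.density_calibration <- function(x, ...) {
  cat("<density_calibration>\n")
  cat("  per-line upper limits (HU):\n")
  print(round(x$per_line_upper_limits, 1))
  cat(sprintf("  cutoff: %d HU  (AT: [%d, %d], LT: [%d, scan max])\n",
              x$cutoff, as.integer(x$at_range[1]), x$cutoff, x$lt_lower))
  invisible(x)
}

#' Read calibration line endpoints
#'
#' Reads the per-subject calibration-line file: a CSV with columns
#' `label, slice_level, p0_row, p0_col, p1_row, p1_col` (one row per label
#' `a`..`h`).
#'
#' @param path CSV path.
#' @return Data frame with one row per line.
#' @export
read_calibration_lines <- function(path) {
  if (!file.exists(path)) stop("calibration line file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "slice_level", "p0_row", "p0_col", "p1_row", "p1_col")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("calibration line file is missing columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Calibrate from a volume plus line definitions
#'
#' Convenience wrapper: resolves each line's slice (L4-L5 from the
#' landmarks, femoral levels via [femoral_fraction_slice()]), samples the
#' eight profiles on the (already denoised) volume and calls [calibrate()].
#'
#' @param vol A denoised [ct_volume()].
#' @param lines Data frame from [read_calibration_lines()].
#' @param landmarks A [landmark_set()].
#' @return A `density_calibration`.
#' @export
calibrate_volume <- function(vol, lines, landmarks) {
  stopifnot(inherits(vol, "ct_volume"), inherits(landmarks, "landmark_set"))
  slice_for <- function(level) {
    switch(level,
      l4l5 = landmarks$l4l5,
      femur85 = femoral_fraction_slice(landmarks, 0.85),
      femur15 = femoral_fraction_slice(landmarks, 0.15),
      stop("unknown slice_level '", level, "'"))
  }
  profiles <- lapply(seq_len(nrow(lines)), function(i) {
    ln <- lines[i, ]
    idx <- slice_for(ln$slice_level)
    if (idx < 1L || idx > dim(vol$voxels)[1])
      stop("calibration slice index ", idx, " outside volume")
    sample_line_profile(vol$voxels[idx, , ],
                        c(ln$p0_row, ln$p0_col), c(ln$p1_row, ln$p1_col),
                        label = ln$label, slice_level = ln$slice_level)
  })
  calibrate(profiles)
}
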