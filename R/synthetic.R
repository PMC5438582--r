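## Synthetic CT phantoms and cohort tables with known ground truth.
##
## The phantom is deliberately cylindrical, not anatomical: a torso section
## (bone core, muscle, subcutaneous AT shell, skin, plus visceral AT blob
## cylinders) stacked on a two-leg section (bone, muscle, thin AT shell,
## plus an intramuscular AT streak near the knee). That is enough to
## exercise every operator - the shell feeds calibration lines a/e/c/f,
## the blobs b/d, the streak g/h - while keeping closed-form ground truth.
##
## Three HU layers emulate how real scans behave under the 3x3x3 median
## filter: a spatially correlated per-tissue heterogeneity field (constant
## over 3-voxel blocks, carrying the tissue SD; the filter preserves it the
## way it preserves real tissue texture), iid voxel noise (which the filter
## is there to remove), and a one-voxel partial-volume ramp at every tissue
## interface. Ground-truth labels are recorded from the geometry (voxel
## centre rule) before any noise is added; a global `bias_hu` emulates the
## scanner offset that motivates per-subject calibration.

#' Phantom specification
#'
#' Geometry is expressed for a 128-voxel in-plane grid and scaled with the
#' requested shape; distributions are `c(mean, sd)` in HU.
#'
#' @param shape Grid `c(n_axial, n_row, n_col)`.
#' @param spacing Voxel spacing `c(dx, dy, dz)` mm.
#' @param at,muscle,bone,skin `c(mean, sd)` HU per tissue.
#' @param air_hu Air value (constant).
#' @param noise_sd SD of the iid voxel noise added after ground truth is
#'   recorded.
#' @param bias_hu Global additive scanner offset.
#' @param boundary_hu If given, all tissue means are shifted so that the
#'   population read-off of the calibration protocol
#'   ([expected_cutoff()]) equals this HU value.
#' @param block Edge length (voxels) of the correlated-heterogeneity
#'   blocks.
#' @param seed Integer seed; same seed, same phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L),
                         spacing = c(3, 3, 3),
                         at = c(-110, 30), muscle = c(55, 14),
                         bone = c(400, 120), skin = c(20, 10),
                         air_hu = -1000, noise_sd = 5, bias_hu = 0,
                         boundary_hu = NULL, block = 3L, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 16L),
            length(spacing) == 3L, all(spacing > 0))
  sds <- c(at[2], muscle[2], bone[2], skin[2], noise_sd)
  if (any(sds < 0)) stop("all SDs must be non-negative")
  if (at[1] + 3 * at[2] >= muscle[1] - 3 * muscle[2])
    stop("AT and muscle distributions must be separable ",
         "(AT mean + 3 SD < muscle mean - 3 SD)")
  spec <- structure(list(shape = shape, spacing = as.numeric(spacing),
                         at = at, muscle = muscle, bone = bone, skin = skin,
                         air_hu = air_hu, noise_sd = noise_sd,
                         bias_hu = bias_hu, block = as.integer(block),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  if (!is.null(boundary_hu)) {
    shift <- boundary_hu - expected_cutoff(spec)
    for (f in c("at", "muscle", "bone", "skin"))
      spec[[f]][1] <- spec[[f]][1] + shift
  }
  spec
}

#' Expected read-off of the calibration protocol
#'
#' The cutoff the eight-line protocol is expected to produce for a phantom
#' specification. Because the per-line upper limits are finite-sample
#' statistics of short, spatially correlated line profiles, the expected
#' read-off sits well below the population 98th percentile; this function
#' therefore simulates the protocol itself - eight lines with the
#' canonical sample counts and block structure, drawn from the
#' specification's tissue distributions - and averages the resulting
#' cutoffs over `reps` replicates. A fixed internal RNG stream makes the
#' result deterministic (the caller's RNG state is untouched).
#'
#' @param spec A [phantom_spec()].
#' @param reps Number of protocol replicates to average.
#' @return Expected cutoff in HU (bias included).
#' @export
expected_cutoff <- function(spec, reps = 200L) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(90210L)
  blk <- spec$block
  # simulate a median-filtered line profile: a straight line through a 3D
  # block-structured field (random block phase), iid noise added, the
  # package's own 3x3x3 filter applied, centre line extracted
  sim_line <- function(n, tissue_a, tissue_b = NULL, n_a = NULL) {
    dims <- c(n + 4L, 7L, 7L)
    phase <- sample.int(blk, 3L, replace = TRUE) - 1L
    bx <- function(len, ph) (seq_len(len) - 1L + ph) %/% blk + 1L
    i1 <- bx(dims[1], phase[1]); i2 <- bx(dims[2], phase[2])
    i3 <- bx(dims[3], phase[3])
    nb <- c(max(i1), max(i2), max(i3))
    field_for <- function(tissue)
      array(rnorm(prod(nb), tissue[1], tissue[2]), nb)[i1, i2, i3]
    patch <- field_for(tissue_a)
    if (!is.null(tissue_b)) {
      fb <- field_for(tissue_b)
      j <- n_a + 2L                       # transition at mid-line
      patch[(j + 1L):dims[1], , ] <- fb[(j + 1L):dims[1], , ]
      patch[j, , ] <- (patch[j, , ] + fb[j, , ]) / 2   # partial volume
    }
    patch <- patch + rnorm(length(patch), 0, spec$noise_sd)
    filt <- .median3d_cpp(patch)
    filt[3:(n + 2L), 4L, 4L]
  }
  # canonical sample counts of the eight lines at the reference geometry
  pure_n <- c(a = 31L, b = 14L, e = 31L, g = 12L)
  mixed_n <- list(c = c(at = 8L, lt = 7L), d = c(at = 8L, lt = 8L),
                  f = c(at = 8L, lt = 7L), h = c(at = 5L, lt = 7L))
  cuts <- vapply(seq_len(reps), function(r) {
    pure <- vapply(pure_n, function(n)
      unname(quantile(sim_line(n, spec$at), CAL_PURE_PERCENTILE)), 0)
    anti <- vapply(mixed_n, function(n) {
      prof <- line_profile(
        sim_line(n[["at"]] + n[["lt"]], spec$at, spec$muscle,
                 n_a = n[["at"]]),
        kind = "mixed", label = "c")
      upper_limit_mixed(prof)
    }, 0)
    mean(c(pure, anti))
  }, 0)
  mean(cuts) + spec$bias_hu
}

# Geometry helper: all radii/offsets in 128-grid pixels, scaled to shape.
phantom_geometry <- function(spec) {
  s <- min(spec$shape[2], spec$shape[3]) / 128
  nz <- spec$shape[1]
  zf <- function(f) as.integer(round(f * nz))
  list(
    s = s,
    c_row = (spec$shape[2] + 1) / 2, c_col = (spec$shape[3] + 1) / 2,
    torso_z = c(zf(0.086), zf(0.586)),
    legs_z = c(zf(0.594), zf(0.938)),
    knee_z = c(zf(0.82), zf(0.92)),
    torso = list(bone = 10 * s, muscle = 40 * s, at = 50 * s,
                 skin = 53 * s),
    blobs = list(list(dr = 20 * s, dc = 0, r = 8 * s),
                 list(dr = -14 * s, dc = -14 * s, r = 7 * s),
                 list(dr = -14 * s, dc = 14 * s, r = 7 * s)),
    leg_dc = 24 * s,            # leg centres at c_col -/+ leg_dc
    leg = list(bone = 4 * s, muscle = 18 * s, at = 22 * s,
               skin = 25 * s),
    streak = list(dc = 11 * s, r = 6.9 * s),   # in the left leg
    landmarks = list(l3l4 = zf(0.234), l4l5 = zf(0.3125),
                     femur_proximal = zf(0.47), femur_distal = zf(0.938))
  )
}

# fraction of a voxel inside radius R (1-voxel partial-volume ramp)
.frac_inside <- function(r, R) pmin(pmax(R - r + 0.5, 0), 1)

#' Generate a CT phantom with ground truth
#'
#' Builds the phantom volume described in [phantom_spec()], returning the
#' noisy biased volume, the ground-truth tissue masks and volumes recorded
#' before noise, the canonical landmark set, and canonical calibration
#' line endpoints for labels `a`..`h` placed in the correct tissue regions
#' by construction.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `volume` ([ct_volume()]), `truth` (list with `at_mask`,
#'   `lt_mask`, `at_volume_L`, `lt_volume_L`), `landmarks`
#'   ([landmark_set()]), `lines` (data frame for [calibrate_volume()]),
#'   and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  if (min(spec$shape[2:3]) < 96L || spec$shape[1] < 16L ||
      g$torso_z[1] < 1L || g$legs_z[2] > spec$shape[1] ||
      g$torso$skin >= min(spec$shape[2:3]) / 2)
    stop("geometrically impossible phantom spec: need at least 96 in-plane ",
         "voxels (canonical line geometry) and 16 axial slices")
  n1 <- spec$shape[1]; n2 <- spec$shape[2]; n3 <- spec$shape[3]
  set.seed(spec$seed)

  # per-tissue correlated heterogeneity: constant over `block`-voxel cubes
  bidx <- function(n) (seq_len(n) - 1L) %/% spec$block + 1L
  i1 <- bidx(n1); i2 <- bidx(n2); i3 <- bidx(n3)
  nb <- c(max(i1), max(i2), max(i3))
  field <- function(mean, sd) {
    coarse <- array(rnorm(prod(nb), mean, sd), dim = nb)
    coarse[i1, i2, i3]
  }
  hu_at <- field(spec$at[1], spec$at[2])
  hu_mu <- field(spec$muscle[1], spec$muscle[2])
  hu_bo <- field(spec$bone[1], spec$bone[2])
  hu_sk <- field(spec$skin[1], spec$skin[2])

  rr <- matrix(seq_len(n2), n2, n3) - g$c_row
  cc <- matrix(seq_len(n3), n2, n3, byrow = TRUE) - g$c_col
  radius <- function(dr, dc) sqrt((rr - dr)^2 + (cc - dc)^2)

  hu <- array(spec$air_hu, dim = c(n1, n2, n3))
  label <- array(0L, dim = c(n1, n2, n3))  # 0 air, 1 AT, 2 LT

  # blend nested rings (innermost first): returns hu plane + label plane
  build_section <- function(z_range, rings, z_extras = NULL) {
    r0 <- radius(rings$dr %||% 0, rings$dc %||% 0)
    for (z in z_range[1]:z_range[2]) {
      fb <- .frac_inside(r0, rings$bone)
      fm <- .frac_inside(r0, rings$muscle)
      fa <- .frac_inside(r0, rings$at)
      fs <- .frac_inside(r0, rings$skin)
      plane <- hu_bo[z, , ] * fb + hu_mu[z, , ] * (fm - fb) +
               hu_at[z, , ] * (fa - fm) + hu_sk[z, , ] * (fs - fa) +
               spec$air_hu * (1 - fs)
      lab <- ifelse(r0 < rings$bone, 2L,
             ifelse(r0 < rings$muscle, 2L,
             ifelse(r0 < rings$at, 1L,
             ifelse(r0 < rings$skin, 2L, 0L))))
      # AT inclusions (blobs / streak) overlaid inside the muscle ring
      for (ex in z_extras) {
        if (z < ex$z[1] || z > ex$z[2]) next
        ri <- radius(ex$dr, ex$dc)
        w <- .frac_inside(ri, ex$r)
        plane <- hu_at[z, , ] * w + plane * (1 - w)
        lab[ri < ex$r] <- 1L
      }
      hu[z, , ] <<- pmax(hu[z, , ], plane)   # sections do not overlap
      label[z, , ] <<- pmax(label[z, , ], lab)
    }
  }

  blob_extras <- lapply(g$blobs, function(b)
    list(dr = b$dr, dc = b$dc, r = b$r, z = g$torso_z))
  build_section(g$torso_z,
                c(g$torso, list(dr = 0, dc = 0)), blob_extras)
  streak <- list(dr = 0, dc = -g$leg_dc + g$streak$dc, r = g$streak$r,
                 z = g$knee_z)
  build_section(g$legs_z, c(g$leg, list(dr = 0, dc = -g$leg_dc)),
                list(streak))
  build_section(g$legs_z, c(g$leg, list(dr = 0, dc = g$leg_dc)), NULL)

  at_mask <- label == 1L
  lt_mask <- label == 2L
  vox_l <- prod(spec$spacing) / 1e6
  truth <- list(at_mask = at_mask, lt_mask = lt_mask,
                at_volume_L = sum(at_mask) * vox_l,
                lt_volume_L = sum(lt_mask) * vox_l)

  hu <- hu + spec$bias_hu
  if (spec$noise_sd > 0)
    hu <- hu + rnorm(length(hu), 0, spec$noise_sd)
  hu <- pmin(pmax(hu, HU_VALID_MIN), HU_VALID_MAX)

  lm <- landmark_set(g$landmarks$l3l4, g$landmarks$l4l5,
                     g$landmarks$femur_proximal, g$landmarks$femur_distal,
                     n_slices = n1)
  list(volume = ct_volume(hu, spec$spacing,
                          subject_id = paste0("phantom-", spec$seed)),
       truth = truth, landmarks = lm,
       lines = phantom_lines(g), spec = spec)
}

# Canonical calibration line endpoints (integer pixel coordinates).
phantom_lines <- function(g) {
  cr <- g$c_row; cl <- g$c_col
  mid_shell <- (g$torso$muscle + g$torso$at) / 2    # 45*s
  half_chord <- round(15 * g$s)
  blob1 <- g$blobs[[1]]
  streak_c <- cl - g$leg_dc + g$streak$dc
  rows <- function(...) as.integer(round(c(...)))
  df <- rbind(
    # a: tangential chord inside the subcutaneous shell at L4-L5
    data.frame(label = "a", slice_level = "l4l5",
               p0_row = rows(cr + mid_shell), p0_col = rows(cl - half_chord),
               p1_row = rows(cr + mid_shell), p1_col = rows(cl + half_chord)),
    # b: inside the first visceral blob
    data.frame(label = "b", slice_level = "l4l5",
               p0_row = rows(cr + blob1$dr), p0_col = rows(cl - 6.5 * g$s),
               p1_row = rows(cr + blob1$dr), p1_col = rows(cl + 6.5 * g$s)),
    # c: radial crossing of the muscle/subcutaneous boundary at L4-L5
    data.frame(label = "c", slice_level = "l4l5",
               p0_row = rows(cr + g$torso$muscle - 6.5 * g$s),
               p0_col = rows(cl),
               p1_row = rows(cr + g$torso$muscle + 7.5 * g$s),
               p1_col = rows(cl)),
    # d: horizontal crossing of the blob/muscle boundary
    data.frame(label = "d", slice_level = "l4l5",
               p0_row = rows(cr + blob1$dr),
               p0_col = rows(cl - blob1$r - 7.5 * g$s),
               p1_row = rows(cr + blob1$dr),
               p1_col = rows(cl + 0)),
    # e, f: same constructions at the gluteal (85% femur) level
    data.frame(label = "e", slice_level = "femur85",
               p0_row = rows(cr + mid_shell), p0_col = rows(cl - half_chord),
               p1_row = rows(cr + mid_shell), p1_col = rows(cl + half_chord)),
    data.frame(label = "f", slice_level = "femur85",
               p0_row = rows(cr + g$torso$muscle - 6.5 * g$s),
               p0_col = rows(cl),
               p1_row = rows(cr + g$torso$muscle + 7.5 * g$s),
               p1_col = rows(cl)),
    # g: inside the intramuscular streak at the knee level
    data.frame(label = "g", slice_level = "femur15",
               p0_row = rows(cr - 5.5 * g$s), p0_col = rows(streak_c - 0.5),
               p1_row = rows(cr + 5.5 * g$s), p1_col = rows(streak_c - 0.5)),
    # h: vertical crossing of the streak/muscle boundary
    data.frame(label = "h", slice_level = "femur15",
               p0_row = rows(cr - g$streak$r - 5.5 * g$s),
               p0_col = rows(streak_c - 0.5),
               p1_row = rows(cr - g$streak$r + 5.5 * g$s),
               p1_col = rows(streak_c - 0.5))
  )
  df$label <- as.character(df$label)
  df$slice_level <- as.character(df$slice_level)
  df
}

#' Cohort specification
#'
#' The generator emulates the published cohort: 41 subjects (36 male,
#' 5 female), latent whole-body AT and LT volumes drawn at the published
#' sample means/SDs, slice areas linked to the volumes through the
#' published equations with Gaussian residuals whose SDs reproduce the
#' printed mean absolute errors (`sd = |PE| * sqrt(pi/2)`), masses via the
#' 0.92 kg/L adipose density, and weight as the sum of the two masses.
#'
#' @param n Number of subjects.
#' @param n_female Number of female subjects.
#' @param at_volume,lt_volume `c(mean, sd)` liters of the latent volumes.
#' @param at_volume_range,lt_volume_range Truncation ranges (liters).
#' @param abs_pe Named residual scales: target mean absolute errors for
#'   the six slice-area relations.
#' @param lt_mass_per_L Lean mass per liter of lean volume.
#' @param stature `c(mean, sd)` cm.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 41L, n_female = 5L,
                        at_volume = c(22.7, 9.4),
                        lt_volume = c(40, 9.3),
                        at_volume_range = c(5.8, 43.3),
                        lt_volume_range = c(18.4, 58),
                        abs_pe = c(at_l3l4 = 2.20, at_l4l5 = 1.86,
                                   at_midthigh = 5.09,
                                   lt_l3l4 = 4.48, lt_l4l5 = 3.63,
                                   lt_midthigh = 2.52),
                        lt_mass_per_L = 47.5 / 40,
                        stature = c(171.7, 7.6), seed = 1L) {
  if (n < 3L) stop("need n >= 3")
  if (any(abs_pe < 0)) stop("residual scales must be non-negative")
  structure(list(n = as.integer(n), n_female = as.integer(n_female),
                 at_volume = at_volume, lt_volume = lt_volume,
                 at_volume_range = at_volume_range,
                 lt_volume_range = lt_volume_range,
                 abs_pe = abs_pe, lt_mass_per_L = lt_mass_per_L,
                 stature = stature, seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, range) {
  out <- rnorm(n, mean, sd)
  bad <- out < range[1] | out > range[2]
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < range[1] | out > range[2]
  }
  out
}

#' Generate a synthetic cohort table
#'
#' Draws a cohort with the structure described in [cohort_spec()]. Each
#' tissue has a designated primary slice relation - L4-L5 for AT and
#' mid-thigh for LT, the paper's best predictors - whose area is drawn
#' exogenously and whose volume is `V = m A + b + e` with the published
#' coefficients and `e ~ N(0, (|PE| sqrt(pi/2))^2)`, so OLS refits of the
#' primary relations are unbiased for the generating (printed) slope. The
#' remaining areas are obtained by inverting their published equations
#' around the same volume with their own residuals (classical
#' measurement-error structure: their refitted slopes carry the usual mild
#' attenuation, as fits on real data do). Residuals are redrawn in the
#' rare case an area would come out non-positive.
#'
#' @param spec A [cohort_spec()].
#' @return A cohort data frame (schema of [validate_cohort()]), with the
#'   generating truth attached as attribute `"truth"`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  reg <- equation_registry()
  eq_for <- function(tissue, level)
    reg[reg$source == "current_study" & reg$target_quantity == "volume_L" &
        reg$predictor_tissue == tissue & reg$predictor_level == level, ]
  res_sd <- function(key) spec$abs_pe[[key]] * sqrt(pi / 2)
  # primary relation: exogenous area, volume = printed equation + residual
  primary <- function(tissue, level, key, vol_mean, vol_sd, vol_range) {
    eq <- eq_for(tissue, level)
    sdres <- res_sd(key)
    sd_a <- sqrt(max(vol_sd^2 - sdres^2, (0.5 * vol_sd)^2)) / eq$slope
    a_range <- (vol_range - eq$intercept) / eq$slope
    a <- rnorm_trunc(n, (vol_mean - eq$intercept) / eq$slope, sd_a, a_range)
    v <- eq$slope * a + eq$intercept + rnorm(n, 0, sdres)
    list(area = a, volume = v)
  }
  # secondary relation: area from inverting the printed equation
  secondary <- function(v, tissue, level, key) {
    eq <- eq_for(tissue, level)
    sdres <- res_sd(key)
    e <- rnorm(n, 0, sdres)
    a <- (v - eq$intercept - e) / eq$slope
    bad <- a <= 0
    while (any(bad)) {
      e[bad] <- rnorm(sum(bad), 0, sdres)
      a[bad] <- (v[bad] - eq$intercept - e[bad]) / eq$slope
      bad <- a <= 0
    }
    a
  }
  at <- primary("AT", "l4l5", "at_l4l5", spec$at_volume[1],
                spec$at_volume[2], spec$at_volume_range)
  lt <- primary("LT", "midthigh", "lt_midthigh", spec$lt_volume[1],
                spec$lt_volume[2], spec$lt_volume_range)
  at_mass <- 0.92 * at$volume
  lt_mass <- spec$lt_mass_per_L * lt$volume
  sex <- sample(c(rep("F", spec$n_female), rep("M", n - spec$n_female)))
  cohort <- data.frame(
    id = sprintf("synth-%03d", seq_len(n)),
    sex = sex,
    weight_kg = at_mass + lt_mass,
    stature_cm = rnorm(n, spec$stature[1], spec$stature[2]),
    at_area_l3l4 = secondary(at$volume, "AT", "l3l4", "at_l3l4"),
    at_area_l4l5 = at$area,
    at_area_midthigh = secondary(at$volume, "AT", "midthigh",
                                 "at_midthigh"),
    lt_area_l3l4 = secondary(lt$volume, "LT", "l3l4", "lt_l3l4"),
    lt_area_l4l5 = secondary(lt$volume, "LT", "l4l5", "lt_l4l5"),
    lt_area_midthigh = lt$area,
    at_volume_L = at$volume, lt_volume_L = lt$volume,
    at_mass_kg = at_mass, lt_mass_kg = lt_mass,
    stringsAsFactors = FALSE
  )
  attr(cohort, "truth") <- list(spec = spec,
                                primary = c(AT = "l4l5", LT = "midthigh"))
  validate_cohort(cohort)
  cohort
}
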