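## Published single-slice prediction equations and volume/mass arithmetic.
##
## The registry stores the twelve printed equations exactly as published:
## the five whole-body AT-volume models (two sex-specific comparator models
## by Kvist and three new sex-pooled ones), the three LT-volume models, and
## the four mass models (two comparator, two new). Predictions are
## slope * area + intercept with areas in cm^2 and targets in liters or kg.

#' Prediction equation
#'
#' @param source `"current_study"`, `"kvist"` or `"mourtzakis"`.
#' @param sex_scope `"pooled"`, `"female"` or `"male"`.
#' @param predictor_tissue,predictor_level Tissue (`"AT"`/`"LT"`) and slice
#'   level (`"l3l4"`, `"l4l5"`, `"midthigh"`) of the measured area.
#' @param target_quantity `"volume_L"` or `"mass_kg"`.
#' @param target_tissue Tissue of the predicted quantity.
#' @param slope Per-cm^2 coefficient (must be positive).
#' @param intercept Intercept in liters or kg.
#' @return An object of class `prediction_equation`.
#' @export
prediction_equation <- function(source, sex_scope, predictor_tissue,
                                predictor_level, target_quantity,
                                target_tissue, slope, intercept) {
  source <- match.arg(source, c("current_study", "kvist", "mourtzakis"))
  sex_scope <- match.arg(sex_scope, c("pooled", "female", "male"))
  predictor_tissue <- match.arg(predictor_tissue, c("AT", "LT"))
  predictor_level <- match.arg(predictor_level,
                               c("l3l4", "l4l5", "midthigh"))
  target_quantity <- match.arg(target_quantity, c("volume_L", "mass_kg"))
  target_tissue <- match.arg(target_tissue, c("AT", "LT"))
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  structure(list(source = source, sex_scope = sex_scope,
                 predictor_tissue = predictor_tissue,
                 predictor_level = predictor_level,
                 target_quantity = target_quantity,
                 target_tissue = target_tissue,
                 slope = slope, intercept = intercept),
            class = "prediction_equation")
}

#' @export
print.prediction_equation <- function(x, ...) {
  cat(sprintf("<prediction_equation %s/%s> %s = %g * %s_%s %+g\n",
              x$source, x$sex_scope,
              paste0(x$target_tissue, " ", x$target_quantity),
              x$slope, x$predictor_tissue, x$predictor_level, x$intercept))
  invisible(x)
}

#' Registry of the published prediction equations
#'
#' All twelve published models, coefficients exactly as printed.
#'
#' @return A data frame with one row per equation and an `id` column of the
#'   form `source:target_tissue:target_quantity:predictor_level`
#'   (sex-specific comparators carry a `:female`/`:male` suffix).
#' @export
equation_registry <- function() {
  rows <- list(
    # whole-body AT volume (liters) from AT areas
    list("kvist", "female", "AT", "l4l5", "volume_L", "AT", 0.0778, -0.59),
    list("kvist", "male",   "AT", "l4l5", "volume_L", "AT", 0.0693,  0.09),
    list("current_study", "pooled", "AT", "l3l4", "volume_L", "AT",
         0.069, 4.691),
    list("current_study", "pooled", "AT", "l4l5", "volume_L", "AT",
         0.074, 2.737),
    list("current_study", "pooled", "AT", "midthigh", "volume_L", "AT",
         0.173, 5.543),
    # whole-body LT volume (liters) from LT areas
    list("current_study", "pooled", "LT", "l3l4", "volume_L", "LT",
         0.147, 8.866),
    list("current_study", "pooled", "LT", "l4l5", "volume_L", "LT",
         0.162, 5.586),
    list("current_study", "pooled", "LT", "midthigh", "volume_L", "LT",
         0.108, 13.021),
    # whole-body masses (kg); the comparators predict DXA fat mass /
    # fat-free mass from L3-L4 areas
    list("mourtzakis", "pooled", "AT", "l3l4", "mass_kg", "AT",
         0.042, 11.2),
    list("mourtzakis", "pooled", "LT", "l3l4", "mass_kg", "LT",
         0.14, 0.72),
    list("current_study", "pooled", "AT", "l4l5", "mass_kg", "AT",
         0.0677, 2.5177),
    list("current_study", "pooled", "LT", "l4l5", "mass_kg", "LT",
         0.1839, 14.6903)
  )
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(source = r[[1]], sex_scope = r[[2]], predictor_tissue = r[[3]],
               predictor_level = r[[4]], target_quantity = r[[5]],
               target_tissue = r[[6]], slope = r[[7]], intercept = r[[8]],
               stringsAsFactors = FALSE)))
  suffix <- ifelse(df$sex_scope == "pooled", "",
                   paste0(":", df$sex_scope))
  df$id <- paste0(df$source, ":", df$target_tissue, ":",
                  df$target_quantity, ":", df$predictor_level, suffix)
  df[, c("id", setdiff(names(df), "id"))]
}

#' Fetch one equation from the registry
#'
#' @param id Registry id, e.g.
#'   `"current_study:AT:volume_L:l4l5"` or `"kvist:AT:volume_L:l4l5:female"`.
#' @return A [prediction_equation()].
#' @export
get_equation <- function(id) {
  reg <- equation_registry()
  i <- match(id, reg$id)
  if (is.na(i))
    stop("unknown equation id '", id, "'; available:\n  ",
         paste(reg$id, collapse = "\n  "))
  r <- reg[i, ]
  prediction_equation(r$source, r$sex_scope, r$predictor_tissue,
                      r$predictor_level, r$target_quantity,
                      r$target_tissue, r$slope, r$intercept)
}

#' Predict a whole-body quantity from a slice area
#'
#' Evaluates `slope * area + intercept`. Negative predictions (possible for
#' comparator equations with negative intercepts at very small areas) are
#' returned with a warning, never clamped.
#'
#' @param eq A [prediction_equation()] or registry id string.
#' @param area_cm2 Slice area(s) in cm^2, non-negative.
#' @return Predicted volume (L) or mass (kg).
#' @export
predict_slice <- function(eq, area_cm2) {
  if (is.character(eq)) eq <- get_equation(eq)
  stopifnot(inherits(eq, "prediction_equation"))
  if (any(!is.finite(area_cm2)) || any(area_cm2 < 0))
    stop("areas must be non-negative")
  out <- eq$slope * area_cm2 + eq$intercept
  if (any(out < 0))
    warning("negative prediction from equation ", eq$source,
            " at area ", paste(area_cm2[out < 0], collapse = ", "), " cm^2")
  out
}

#' @export
predict.prediction_equation <- function(object, area_cm2, ...) {
  predict_slice(object, area_cm2)
}

#' Adipose mass from volume
#'
#' Converts an AT volume to mass with the density of fat, 0.92 kg/L.
#'
#' @param v_L Volume in liters, non-negative.
#' @return Mass in kg.
#' @export
at_mass_from_volume <- function(v_L) {
  if (any(!is.finite(v_L)) || any(v_L < 0))
    stop("volume must be non-negative")
  0.92 * v_L
}

#' Lean mass from body weight
#'
#' LT mass is obtained by subtracting the AT mass from the known body
#' weight.
#'
#' @param weight_kg Body weight, kg.
#' @param at_mass_kg Adipose mass, kg; must not exceed the weight.
#' @return LT mass in kg.
#' @export
lt_mass_from_weight <- function(weight_kg, at_mass_kg) {
  if (any(at_mass_kg < 0) || any(at_mass_kg > weight_kg))
    stop("AT mass must lie in [0, weight]")
  weight_kg - at_mass_kg
}

#' Serial-slice area series
#'
#' @param areas Ordered tissue areas (cm^2) on serial axial scans.
#' @param gaps Distances between adjacent scans (cm);
#'   `length(gaps) == length(areas) - 1`.
#' @return An object of class `slice_series`.
#' @export
slice_series <- function(areas, gaps) {
  areas <- as.numeric(areas); gaps <- as.numeric(gaps)
  if (length(gaps) != length(areas) - 1L)
    stop("need length(gaps) == length(areas) - 1")
  if (any(gaps <= 0)) stop("all gaps must be positive")
  if (any(areas < 0)) stop("areas must be non-negative")
  structure(list(areas = areas, gaps = gaps), class = "slice_series")
}

#' Trapezoidal volume from serial slice areas
#'
#' The classic multi-slice volume estimate
#' \eqn{V = \sum_i a_i (b_i + c_i) / 2}, where \eqn{a_i} is the distance
#' between adjacent scans and \eqn{b_i}, \eqn{c_i} their tissue areas:
#' a trapezoidal sum over adjacent slice pairs, converted to liters.
#'
#' @param series A [slice_series()] (areas cm^2, gaps cm).
#' @return Volume in liters.
#' @export
kvist_volume <- function(series) {
  stopifnot(inherits(series, "slice_series"))
  a <- series$areas
  n <- length(a)
  sum(series$gaps * (a[-n] + a[-1]) / 2) / 1000
}
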