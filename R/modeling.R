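## Model fitting and evaluation: OLS with residual diagnostics, the error
## metrics used for all published comparisons, a paired signed-rank test,
## and leave-one-out cross-validation.

COHORT_COLUMNS <- c("id", "sex", "weight_kg", "stature_cm",
                    "at_area_l3l4", "at_area_l4l5", "at_area_midthigh",
                    "lt_area_l3l4", "lt_area_l4l5", "lt_area_midthigh",
                    "at_volume_L", "lt_volume_L",
                    "at_mass_kg", "lt_mass_kg")

#' Validate a cohort table
#'
#' Checks the per-subject cohort data frame against the documented schema:
#' the columns in `ctcomp:::COHORT_COLUMNS`, at least 3 rows, no missing
#' predictors/targets, and (where all fields are present) mass/volume
#' consistency: `at_mass_kg == 0.92 * at_volume_L` and
#' `weight_kg == at_mass_kg + lt_mass_kg`, within `tol`.
#'
#' @param cohort Data frame.
#' @param tol Relative tolerance for the consistency checks.
#' @return `cohort`, invisibly; errors describe the first violation.
#' @export
validate_cohort <- function(cohort, tol = 1e-6) {
  missing <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing))
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(cohort) < 3L) stop("cohort needs at least 3 subjects")
  num <- setdiff(COHORT_COLUMNS, c("id", "sex"))
  for (cn in num)
    if (any(!is.finite(cohort[[cn]])))
      stop("missing or non-finite values in cohort column '", cn, "'")
  scale <- pmax(abs(cohort$at_mass_kg), 1)
  if (any(abs(cohort$at_mass_kg - 0.92 * cohort$at_volume_L) > tol * scale))
    stop("cohort masses inconsistent with 0.92 kg/L adipose density")
  wscale <- pmax(abs(cohort$weight_kg), 1)
  if (any(abs(cohort$weight_kg -
              (cohort$at_mass_kg + cohort$lt_mass_kg)) > tol * wscale))
    stop("cohort weights inconsistent with at_mass + lt_mass")
  invisible(cohort)
}

#' Ordinary least squares fit with regression diagnostics
#'
#' Fits `y = slope * x + intercept` by least squares and attaches the
#' diagnostics used to vet every published equation: the Durbin-Watson
#' statistic for residual autocorrelation, the (studentised)
#' Breusch-Pagan test for heteroscedasticity, the ANOVA F-test of the
#' linear fit, normal Q-Q coordinates of the residuals, and the in-sample
#' error metrics `|PE|` and `%PE`.
#'
#' @param x Predictor (slice areas, cm^2).
#' @param y Target (volume L or mass kg).
#' @return An object of class `ols_fit` with `slope`, `intercept`,
#'   `fitted`, `residuals`, `diagnostics` (list: `durbin_watson`,
#'   `breusch_pagan_p`, `anova_f_p`, `qq`) and `errors`
#'   (list: `abs_pe`, `pct_pe`).
#' @export
fit_ols <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (var(x) == 0) stop("zero-variance predictor")
  fit <- lm(y ~ x)
  e <- unname(stats::residuals(fit))
  yhat <- unname(stats::fitted(fit))
  # Durbin-Watson in data order
  dw <- sum(diff(e)^2) / sum(e^2)
  # studentised Breusch-Pagan: n * R^2 of e^2 on x, chi^2 with 1 df
  aux <- lm(I(e^2) ~ x)
  bp_stat <- n * summary(aux)$r.squared
  bp_p <- pchisq(bp_stat, df = 1L, lower.tail = FALSE)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  f_p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  qq <- stats::qqnorm(e, plot.it = FALSE)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    fitted = yhat, residuals = e, n = n,
    diagnostics = list(durbin_watson = dw, breusch_pagan_p = bp_p,
                       anova_f_p = f_p,
                       qq = data.frame(theoretical = qq$x, sample = qq$y)),
    errors = list(abs_pe = abs_pred_error(y, yhat),
                  pct_pe = pct_pred_error(y, yhat))
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit n=%d> y = %.4g * x %+.4g\n", x$n, x$slope,
              x$intercept))
  cat(sprintf("  |PE| %.3g, %%PE %.3g; DW %.3g, BP p %.3g, ANOVA p %.3g\n",
              x$errors$abs_pe, x$errors$pct_pe,
              x$diagnostics$durbin_watson, x$diagnostics$breusch_pagan_p,
              x$diagnostics$anova_f_p))
  invisible(x)
}

#' @export
predict.ols_fit <- function(object, x, ...) {
  object$slope * as.numeric(x) + object$intercept
}

#' Mean absolute prediction error
#'
#' `|PE|`: the mean of `|observed - predicted|`.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A non-negative scalar in the units of the observations.
#' @export
abs_pred_error <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (!length(observed)) stop("need at least one observation")
  mean(abs(observed - predicted))
}

#' Mean percent prediction error
#'
#' `%PE`: per-subject `(observed - predicted) / predicted * 100`, averaged
#' as a magnitude (the absolute value is taken per subject; every published
#' value is an error magnitude). Set `signed = TRUE` for the raw signed
#' mean.
#'
#' @param observed,predicted Equal-length numeric vectors; `predicted`
#'   must be nonzero everywhere.
#' @param signed Return the signed mean instead of the mean magnitude.
#' @return Percent error.
#' @export
pct_pred_error <- function(observed, predicted, signed = FALSE) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (any(predicted == 0)) stop("predicted values must be nonzero")
  pe <- (observed - predicted) / predicted * 100
  if (signed) mean(pe) else mean(abs(pe))
}

#' Paired comparison of absolute errors (Wilcoxon signed-rank)
#'
#' Two-sided paired Wilcoxon signed-rank test between two error vectors,
#' as used to compare sex-specific against sex-pooled equations. Zero
#' differences are dropped (classic convention); the exact tie-aware
#' distribution is enumerated for up to 25 nonzero differences, above that
#' a normal approximation with continuity and tie correction is used. If
#' all differences are zero the p-value is 1 by convention.
#'
#' @param errors_a,errors_b Equal-length numeric vectors (n >= 5).
#' @return Two-sided p-value.
#' @export
compare_paired_abs_errors <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("error vectors must have equal length")
  if (length(errors_a) < 5L) stop("need at least 5 pairs")
  d <- errors_a - errors_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    # exact distribution of W by convolution over the (tie-averaged) ranks;
    # doubling makes half-integer ranks integral
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L)   # dist[k+1] = #subsets with 2W = k
    dist[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(total + 1L - ri)])
      dist <- dist + shifted
    }
    probs <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Leave-one-out cross-validated mean absolute error
#'
#' For each subject: fit the model on the remaining n-1 subjects, predict
#' the held-out subject, and average the absolute errors. Deterministic
#' given the data; performs exactly n fits.
#'
#' @param cohort A cohort data frame (see [validate_cohort()] for the
#'   schema; only the columns the spec functions use are required).
#' @param model_spec A list with elements `fit(data)` returning a model
#'   and `predict(model, newdata)` returning predictions, plus `target`
#'   naming the target column. [ols_model_spec()] and [svmr_model_spec()]
#'   build these.
#' @return Leave-one-out mean absolute error.
#' @export
loocv_mae <- function(cohort, model_spec) {
  n <- nrow(cohort)
  if (n < 3L) stop("need at least 3 subjects for LOOCV")
  errs <- vapply(seq_len(n), function(i) {
    m <- model_spec$fit(cohort[-i, , drop = FALSE])
    pred <- model_spec$predict(m, cohort[i, , drop = FALSE])
    abs(cohort[[model_spec$target]][i] - pred)
  }, 0)
  mean(errs)
}

#' OLS model specification for cross-validation
#'
#' @param predictor,target Cohort column names.
#' @return A `model_spec` list for [loocv_mae()].
#' @export
ols_model_spec <- function(predictor, target) {
  list(
    fit = function(data) fit_ols(data[[predictor]], data[[target]]),
    predict = function(model, newdata) predict(model, newdata[[predictor]]),
    target = target
  )
}

#' Reproduce the published model fits from a cohort table
#'
#' Refits every current-study single-slice relation (three AT-volume
#' equations, three LT-volume equations, the two L4-L5 mass equations) by
#' OLS on a cohort table, reports slope/intercept and the error metrics
#' used for the published comparisons, evaluates the comparator equations
#' on the same data, and fits the multislice SVR predictors with
#' leave-one-out cross-validation. This is the pipeline one would point at
#' the paper's raw per-subject data; in this package it is exercised on
#' synthetic cohorts.
#'
#' @param cohort A cohort data frame ([validate_cohort()] schema).
#' @param loocv Also compute LOOCV MAEs for the SVR models (slower).
#' @return A list with `single_slice` (data frame: relation, slope,
#'   intercept, abs_pe, pct_pe, anova_f_p), `comparators` (data frame:
#'   equation id, abs_pe, pct_pe) and `svmr` (data frame: target,
#'   training_mae, loocv_mae).
#' @export
reproduce_published_fits <- function(cohort, loocv = TRUE) {
  validate_cohort(cohort)
  rels <- list(
    list("AT", "l3l4", "at_volume_L"), list("AT", "l4l5", "at_volume_L"),
    list("AT", "midthigh", "at_volume_L"),
    list("LT", "l3l4", "lt_volume_L"), list("LT", "l4l5", "lt_volume_L"),
    list("LT", "midthigh", "lt_volume_L"),
    list("AT", "l4l5", "at_mass_kg"), list("LT", "l4l5", "lt_mass_kg"))
  single <- do.call(rbind, lapply(rels, function(r) {
    xcol <- paste0(tolower(r[[1]]), "_area_", r[[2]])
    f <- fit_ols(cohort[[xcol]], cohort[[r[[3]]]])
    data.frame(predictor = xcol, target = r[[3]], slope = f$slope,
               intercept = f$intercept, abs_pe = f$errors$abs_pe,
               pct_pe = f$errors$pct_pe,
               anova_f_p = f$diagnostics$anova_f_p)
  }))
  reg <- equation_registry()
  comp <- reg[reg$source != "current_study", ]
  comparators <- do.call(rbind, lapply(seq_len(nrow(comp)), function(i) {
    r <- comp[i, ]
    xcol <- paste0(tolower(r$predictor_tissue), "_area_", r$predictor_level)
    ycol <- if (r$target_quantity == "volume_L") {
      paste0(tolower(r$target_tissue), "_volume_L")
    } else paste0(tolower(r$target_tissue), "_mass_kg")
    rows <- if (r$sex_scope == "pooled") rep(TRUE, nrow(cohort))
            else cohort$sex == (if (r$sex_scope == "female") "F" else "M")
    pred <- suppressWarnings(
      predict_slice(get_equation(r$id), cohort[[xcol]][rows]))
    data.frame(id = r$id, n = sum(rows),
               abs_pe = abs_pred_error(cohort[[ycol]][rows], pred),
               pct_pe = pct_pred_error(cohort[[ycol]][rows], pred))
  }))
  svmr <- do.call(rbind, lapply(c("at_volume", "lt_volume"), function(tg) {
    m <- fit_svmr(cohort, tg)
    data.frame(target = tg,
               training_mae = abs_pred_error(cohort[[m$target_column]],
                                             predict(m, cohort)),
               loocv_mae = if (loocv) loocv_mae(cohort, svmr_model_spec(tg))
                           else NA_real_)
  }))
  list(single_slice = single, comparators = comparators, svmr = svmr)
}
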