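## Linear epsilon-SVR via SMO on the dual.
##
## No SVM package ships with the supported stack, so the solver lives here.
## The dual of epsilon-SVR in the beta = alpha - alpha* parameterisation is
##
##   maximise  -1/2 beta' K beta - epsilon * sum|beta_i| + sum y_i beta_i
##   s.t.      sum beta_i = 0,  |beta_i| <= C
##
## with K the (linear) Gram matrix. SMO updates a pair (i, j) by
## beta_i += t, beta_j -= t, which preserves the equality constraint; the
## one-dimensional objective in t is piecewise quadratic with kinks at
## t = -beta_i and t = beta_j, so the exact pairwise optimum is found by
## evaluating the stationary point of each smooth piece plus the kinks and
## box ends. Features (and by default the target, matching the reference
## implementation the published analysis used) are standardised before
## solving.

svr_smo <- function(K, y, C, eps, tol = 1e-8, max_iter = 200000L) {
  n <- length(y)
  beta <- numeric(n)
  f <- numeric(n)               # f_i = sum_j beta_j K_ij (no offset)
  diagK <- diag(K)
  for (iter in seq_len(max_iter)) {
    resid <- y - f
    # directional derivatives of the dual objective (subgradient at 0)
    g_up <- resid - ifelse(beta >= 0, eps, -eps)   # along +e_i
    g_dn <- -resid - ifelse(beta <= 0, eps, -eps)  # along -e_i
    g_up[beta >= C] <- -Inf
    g_dn[beta <= -C] <- -Inf
    i <- which.max(g_up)
    j <- which.max(g_dn)
    if (i == j || g_up[i] + g_dn[j] <= tol) break
    eta <- diagK[i] + diagK[j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    g <- (y[i] - y[j]) - (f[i] - f[j])
    lo <- max(-C - beta[i], beta[j] - C)
    hi <- min(C - beta[i], beta[j] + C)
    # exact maximiser of the piecewise-quadratic 1D objective: stationary
    # points of each smooth piece, the kinks, and the box ends
    cand <- unique(pmin(pmax(
      c(lo, hi, -beta[i], beta[j], (g - eps * c(-2, 0, 2)) / eta), lo), hi))
    gains <- g * cand - 0.5 * eta * cand^2 -
      eps * (abs(beta[i] + cand) + abs(beta[j] - cand) -
             abs(beta[i]) - abs(beta[j]))
    k <- which.max(gains)
    if (gains[k] <= tol * 1e-4) break
    t <- cand[k]
    beta[i] <- beta[i] + t
    beta[j] <- beta[j] - t
    f <- f + t * (K[, i] - K[, j])
  }
  # offset from the KKT conditions of unbounded support vectors
  free <- abs(beta) > 1e-8 & abs(beta) < C - 1e-8
  b <- if (any(free)) {
    mean(y[free] - f[free] - eps * sign(beta[free]))
  } else {
    median(y - f)
  }
  list(beta = beta, b = b, f = f)
}

#' Fit a linear epsilon-SVR multislice predictor
#'
#' Predicts a whole-body tissue volume from the three tissue-matched slice
#' areas (L3-L4, L4-L5, mid-thigh) with a linear-kernel epsilon-SVR.
#' Features and target are standardised to zero mean / unit variance
#' before solving (reference-implementation behaviour); predictions are
#' returned on the original scale. Hyperparameters default to the
#' reference defaults `cost = 1`, `epsilon = 0.1`. `features = "all"`
#' uses all six areas of both tissues.
#'
#' @param cohort Cohort data frame with the area and volume columns.
#' @param target `"at_volume"` or `"lt_volume"`.
#' @param features `"matched"` (three areas of the target tissue, the
#'   default) or `"all"` (all six areas).
#' @param cost Box constraint C.
#' @param epsilon Tube half-width (in standardised target units).
#' @return An object of class `svmr_fit`; use `predict()` with new cohort
#'   rows.
#' @export
fit_svmr <- function(cohort, target = c("at_volume", "lt_volume"),
                     features = c("matched", "all"),
                     cost = 1, epsilon = 0.1) {
  target <- match.arg(target)
  features <- match.arg(features)
  if (nrow(cohort) < 10L) stop("need at least 10 subjects to fit the SVR")
  tissue <- if (target == "at_volume") "at" else "lt"
  feats <- if (features == "matched") {
    paste0(tissue, "_area_", c("l3l4", "l4l5", "midthigh"))
  } else {
    c(paste0("at_area_", c("l3l4", "l4l5", "midthigh")),
      paste0("lt_area_", c("l3l4", "l4l5", "midthigh")))
  }
  ycol <- paste0(tissue, "_volume_L")
  missing <- setdiff(c(feats, ycol), names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(cohort[, feats, drop = FALSE])
  y <- cohort[[ycol]]
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, sd)
  if (any(x_scale == 0)) stop("degenerate (constant) feature: ",
                              paste(feats[x_scale == 0], collapse = ", "))
  y_center <- mean(y); y_scale <- sd(y)
  if (y_scale == 0) stop("constant target")
  Xs <- scale(X, center = x_center, scale = x_scale)
  ys <- (y - y_center) / y_scale
  sol <- svr_smo(Xs %*% t(Xs), ys, C = cost, eps = epsilon)
  w <- drop(t(Xs) %*% sol$beta)   # weights in standardised space
  structure(list(w = w, b = sol$b, features = feats, target = target,
                 target_column = ycol,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 cost = cost, epsilon = epsilon,
                 n_sv = sum(abs(sol$beta) > 1e-8)),
            class = "svmr_fit")
}

#' @export
print.svmr_fit <- function(x, ...) {
  cat(sprintf(
    "<svmr_fit %s ~ %s> linear kernel, C=%g, eps=%g, %d support vectors\n",
    x$target, paste(x$features, collapse = " + "), x$cost, x$epsilon,
    x$n_sv))
  invisible(x)
}

#' @export
predict.svmr_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Xs <- scale(X, center = object$x_center, scale = object$x_scale)
  drop(Xs %*% object$w + object$b) * object$y_scale + object$y_center
}

#' SVR model specification for cross-validation
#'
#' @param target `"at_volume"` or `"lt_volume"`.
#' @param features,cost,epsilon Passed to [fit_svmr()].
#' @return A `model_spec` list for [loocv_mae()].
#' @export
svmr_model_spec <- function(target = c("at_volume", "lt_volume"),
                            features = c("matched", "all"),
                            cost = 1, epsilon = 0.1) {
  target <- match.arg(target)
  features <- match.arg(features)
  tissue <- if (target == "at_volume") "at" else "lt"
  list(
    fit = function(data) fit_svmr(data, target = target,
                                  features = features,
                                  cost = cost, epsilon = epsilon),
    predict = function(model, newdata) predict(model, newdata),
    target = paste0(tissue, "_volume_L")
  )
}
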