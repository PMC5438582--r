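## Repeatability statistics: intra-class correlation and Bland-Altman
## limits of agreement for two raters measuring the same volumes.

#' Paired ratings container
#'
#' @param subject Subject identifiers.
#' @param rater_a,rater_b Numeric measurements of the same quantity
#'   (liters) by two raters (or two sessions of one rater).
#' @return An object of class `ratings_pair`.
#' @export
ratings_pair <- function(subject, rater_a, rater_b) {
  if (length(rater_a) != length(rater_b) ||
      length(subject) != length(rater_a))
    stop("subject, rater_a and rater_b must have equal length")
  if (length(rater_a) < 3L) stop("need at least 3 subjects")
  structure(list(subject = subject, rater_a = as.numeric(rater_a),
                 rater_b = as.numeric(rater_b)),
            class = "ratings_pair")
}

#' Intra-class correlation coefficient
#'
#' Single-measure ICC for a two-column rating table, from the variance
#' components of the one-way (`ICC(1,1)`) or two-way random-effects
#' absolute-agreement (`ICC(A,1)`) model:
#' \deqn{ICC_{oneway} = \frac{MSB - MSW}{MSB + (k-1) MSW}}
#' \deqn{ICC_{agreement} = \frac{MSR - MSE}{MSR + (k-1) MSE +
#'   \frac{k}{n}(MSC - MSE)}}
#' with `k = 2` raters, `MSB`/`MSW` the between/within-subject mean
#' squares, and `MSR`/`MSC`/`MSE` the subject/rater/error mean squares of
#' the two-way layout.
#'
#' @param ratings A [ratings_pair()].
#' @param form `"twoway_agreement"` (default) or `"oneway"`.
#' @return The ICC value.
#' @export
icc <- function(ratings, form = c("twoway_agreement", "oneway")) {
  stopifnot(inherits(ratings, "ratings_pair"))
  form <- match.arg(form)
  a <- ratings$rater_a; b <- ratings$rater_b
  n <- length(a); k <- 2L
  vals <- c(a, b)
  if (var(vals) == 0) stop("zero total variance: ICC undefined")
  subj_means <- (a + b) / 2
  grand <- mean(vals)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)         # between subjects
  msw <- sum((a - subj_means)^2 + (b - subj_means)^2) / n  # within subjects
  if (form == "oneway")
    return((msb - msw) / (msb + (k - 1) * msw))
  rater_means <- c(mean(a), mean(b))
  msc <- n * sum((rater_means - grand)^2) / (k - 1)
  sse <- sum((a - subj_means - rater_means[1] + grand)^2 +
             (b - subj_means - rater_means[2] + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msb - mse) / (msb + (k - 1) * mse + k / n * (msc - mse))
}

#' Bland-Altman agreement analysis
#'
#' Bias and 95% limits of agreement for paired measurements:
#' `bias = mean(a - b)`, limits `bias +- 1.96 * SD(a - b)` (the classic
#' 1.96 multiplier, not a t quantile). Per-subject means and differences
#' are returned as plotting coordinates.
#'
#' @param ratings A [ratings_pair()].
#' @return A list with `bias`, `lower`, `upper`, and a data frame `points`
#'   (`mean`, `difference`).
#' @export
bland_altman <- function(ratings) {
  stopifnot(inherits(ratings, "ratings_pair"))
  d <- ratings$rater_a - ratings$rater_b
  m <- (ratings$rater_a + ratings$rater_b) / 2
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       points = data.frame(mean = m, difference = d))
}
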