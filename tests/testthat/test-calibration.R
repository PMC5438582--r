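test_that("line sampling is nearest-neighbour with inclusive endpoints", {
  sl <- matrix(-90, 80, 80)
  p <- sample_line_profile(sl, c(10, 10), c(10, 60), label = "a")
  expect_true(all(p$values == -90))
  expect_length(p$values, 51L)   # length-50 segment, inclusive endpoints

  # two-valued phantom split at the column midline
  sl2 <- matrix(-90, 60, 60)
  sl2[, 31:60] <- 55
  p2 <- sample_line_profile(sl2, c(10, 11), c(50, 51), label = "c")
  cols <- round(seq(11, 51, length.out = length(p2$values)))
  expect_identical(p2$values, ifelse(cols <= 30, -90, 55))

  expect_error(sample_line_profile(sl, c(5, 5), c(5, 5), label = "a"),
               "degenerate")
  expect_error(sample_line_profile(sl, c(5, 5), c(5, 9), label = "a"),
               "short")
  expect_error(line_profile(rep(-90, 50), "mixed", "a"), "pure_at")
})

test_that("pure-AT upper limit is the 98th percentile", {
  p <- line_profile(rep(-80, 100), "pure_at", "a")
  expect_equal(upper_limit_pure(p), -80)
  p2 <- line_profile(seq(-100, -51), "pure_at", "b")
  expect_equal(upper_limit_pure(p2), quantile(seq(-100, -51), 0.98,
                                              names = FALSE))
  expect_equal(upper_limit_pure(p2), -51.98, tolerance = 1e-10)
  set.seed(11)
  draw <- rnorm(200, -90, 20)
  p3 <- line_profile(draw, "pure_at", "e")
  expect_equal(upper_limit_pure(p3), quantile(draw, 0.98, names = FALSE))
  expect_gt(upper_limit_pure(p3), -60)
  expect_lt(upper_limit_pure(p3), -30)
  expect_error(upper_limit_pure(line_profile(draw, "mixed", "c")), "pure")
})

test_that("mixed-line antimode finds the transition density", {
  # two spikes: symmetric smoothing puts the antimode at the midpoint
  p <- line_profile(c(rep(-90, 50), rep(55, 50)), "mixed", "c")
  a <- upper_limit_mixed(p)
  expect_gt(a, -90); expect_lt(a, 55)
  expect_equal(a, -17.5, tolerance = 0.51)

  # Gaussian mixture: oracle = direct grid scan of the smoothed density
  set.seed(5)
  x <- c(rnorm(200, -90, 15), rnorm(200, 55, 15))
  pm <- line_profile(x, "mixed", "f")
  am <- upper_limit_mixed(pm)
  expect_gt(am, -40); expect_lt(am, 10)
  grid <- seq(-205, 150, by = 1)
  dens <- sapply(grid, function(g) mean(dnorm(g, x, 8)))
  inner <- grid > -80 & grid < 40
  oracle <- grid[inner][which.min(dens[inner])]
  expect_equal(am, oracle, tolerance = 1.01)

  expect_error(upper_limit_mixed(line_profile(rep(5, 20), "mixed", "h")),
               "zero IQR")
})

test_that("calibrate averages eight limits into an integer cutoff", {
  profs <- constant_profiles(pure_hu = -3, at_hu = -3.0001, lt_hu = -2.9999)
  # all eight limits approximately -3
  cal <- calibrate(profs)
  expect_identical(cal$cutoff, -3L)
  expect_equal(cal$at_range, c(-205, -3))
  expect_identical(cal$lt_lower, -2L)

  # printed corridor endpoints: mean of {-16 x4, 26 x4} is 5
  lim <- c(-16, -16, 26, 26)
  profs2 <- lapply(seq_along(LINE_LABELS <- c("a", "b", "e", "g")),
                   function(i) line_profile(rep(lim[i], 20), "pure_at",
                                            LINE_LABELS[i]))
  mixed <- lapply(list(c("c", -16), c("d", -16), c("f", 26), c("h", 26)),
    function(z) {
      v <- as.numeric(z[2])
      line_profile(c(rep(v - 30, 25), rep(v + 30, 25)), "mixed", z[1])
    })
  cal2 <- calibrate(c(profs2, mixed))
  expect_identical(cal2$cutoff, 5L)

  expect_error(calibrate(profs[-1]), "a..h")
  expect_error(calibrate(c(profs[-1], profs[2])), "a..h")
})

test_that("cutoff is permutation invariant and translation equivariant", {
  set.seed(21)
  base <- constant_profiles(pure_hu = -40, at_hu = -90, lt_hu = 55)
  # add variation so the profiles are not all identical
  base <- lapply(base, function(p) {
    p$values <- p$values + rnorm(length(p$values), 0, 5)
    p
  })
  cal <- suppressWarnings(calibrate(base))
  perm <- suppressWarnings(calibrate(base[c(5, 3, 1, 8, 2, 7, 4, 6)]))
  expect_identical(perm$cutoff, cal$cutoff)
  for (k in c(-20, 7, 15)) {
    shifted <- lapply(base, function(p) { p$values <- p$values + k; p })
    calk <- suppressWarnings(calibrate(shifted))
    expect_lte(abs(calk$cutoff - (cal$cutoff + k)), 1)
  }
})

test_that("calibrate warns outside the expected corridor", {
  profs <- constant_profiles(pure_hu = -80, at_hu = -80.1, lt_hu = -79.9)
  expect_warning(calibrate(profs), "corridor")
})
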