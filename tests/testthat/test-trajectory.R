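ages9 <- seq(14.5, 23.5, length.out = 9)

test_that("AIC selects linear on linear truth and spline on curved truth", {
  lin_hits <- sapply(1:20, function(s) {
    set.seed(s)
    fit_trajectory(ages9, 2 * ages9 + rnorm(9, 0, 0.01))$chosen == "linear"
  })
  expect_gte(sum(lin_hits), 18)
  spl_hits <- sapply(1:20, function(s) {
    set.seed(100 + s)
    f <- fit_trajectory(ages9, (ages9 - 19)^2 + rnorm(9, 0, 0.05))
    f$chosen == "spline" &&
      abs(trajectory_params(f)$age_min - 19) <= 0.5
  })
  expect_gte(sum(spl_hits), 18)
})

test_that("constant series yield no change and p near 1", {
  f <- suppressWarnings(fit_trajectory(ages9, rep(2, 9)))
  expect_equal(f$linear$coef[[2]], 0, tolerance = 1e-12)
  expect_lt(trajectory_params(f)$delta_max, 1e-8)
  p <- if (f$chosen == "spline") f$spline$p else f$linear$p
  expect_gt(p, 0.9)
})

test_that("trajectory parameters read off the dense curve", {
  fake <- structure(list(curve = c(5, 3, 1, 2, 3),
                         grid = c(14, 16, 18, 20, 22),
                         chosen = "spline"),
                    class = "trajectory")
  p <- trajectory_params(fake)
  expect_equal(p$delta_max, 4)
  expect_equal(p$age_min, 18)
  expect_equal(p$direction, "decreasing")
  expect_false(p$boundary)

  up <- structure(list(curve = 1:5, grid = c(14, 16, 18, 20, 22),
                       chosen = "linear"),
                  class = "trajectory")
  pu <- trajectory_params(up)
  expect_equal(pu$age_min, 14)
  expect_true(pu$boundary)
  expect_equal(pu$direction, "increasing")
  expect_equal(pu$shape, "linear")
})

test_that("delta_max is shift-invariant and age_min scale-invariant", {
  set.seed(5)
  y <- (ages9 - 19.5)^2 + rnorm(9, 0, 0.1)
  f1 <- fit_trajectory(ages9, y)
  f2 <- fit_trajectory(ages9, y + 100)
  f3 <- fit_trajectory(ages9, y * 7)
  p1 <- trajectory_params(f1)
  expect_equal(p1$delta_max, trajectory_params(f2)$delta_max,
               tolerance = 1e-6)
  expect_equal(p1$age_min, trajectory_params(f3)$age_min,
               tolerance = 0.011)
})

test_that("spline edf honors the cap however wiggly the data", {
  set.seed(6)
  for (i in 1:10) {
    y <- sin(ages9 * 2) + rnorm(9, 0, 0.2)
    f <- fit_trajectory(ages9, y)
    if (!is.null(f$spline)) expect_lte(f$spline$edf, 3.5 + 1e-6)
  }
})

test_that("model object methods are coherent", {
  set.seed(7)
  y <- (ages9 - 19)^2 + rnorm(9, 0, 0.1)
  f <- fit_trajectory(ages9, y)
  expect_s3_class(f, "trajectory")
  expect_equal(fitted(f) + residuals(f), y, tolerance = 1e-10)
  expect_equal(predict(f, ages9), fitted(f))
  s <- summary(f)
  expect_output(print(s), "age at minimum")
  expect_silent(grDevices::pdf(NULL))
  plot(f)
  grDevices::dev.off()
  expect_warning(fit_trajectory(ages9[1:5], y[1:5]), "too few points")
  expect_error(fit_trajectory(ages9[c(1, 1, 2, 3, 4)], y[1:5]),
               "strictly increasing")
})

test_that("bootstrap CI collapses on identical replicates and matches percentiles", {
  set.seed(8)
  y <- (ages9 - 19.5)^2 + rnorm(9, 0, 0.05)
  f <- fit_trajectory(ages9, y)
  pt <- trajectory_params(f)$age_min
  same <- matrix(rep(y, 120), nrow = 120, byrow = TRUE)
  ci <- bootstrap_age_min_ci(same, ages9, f)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$lower, pt, tolerance = 0.02)

  # replicates with analytically known minima: CI ~ percentile of the minima
  set.seed(9)
  mins <- runif(150, 18, 20)
  reps <- t(sapply(mins, function(m) (ages9 - m)^2))
  ci2 <- bootstrap_age_min_ci(reps, ages9, f)
  expect_equal(ci2$lower, quantile(mins, 0.025, names = FALSE),
               tolerance = 0.25)
  expect_equal(ci2$upper, quantile(mins, 0.975, names = FALSE),
               tolerance = 0.25)
  expect_warning(bootstrap_age_min_ci(same[1:20, ], ages9, f),
                 "fewer than 100")
})

test_that("nodal significance controls the FDR and flags planted change", {
  # null calibration: flat trajectories
  fracs <- sapply(1:20, function(s) {
    set.seed(200 + s)
    fits <- lapply(1:40, function(r) {
      suppressWarnings(fit_trajectory(ages9, rnorm(9)))
    })
    mean(nodal_significance(fits, alpha = 0.05)$significant)
  })
  expect_lt(mean(fracs), 0.1)

  # one strong region among nulls
  hits <- sapply(1:20, function(s) {
    set.seed(300 + s)
    fits <- c(list(fit_trajectory(ages9, 10 * (ages9 - 19)^2 +
                                    rnorm(9, 0, 0.5))),
              lapply(1:49, function(r) {
                suppressWarnings(fit_trajectory(ages9, rnorm(9)))
              }))
    tab <- nodal_significance(fits, alpha = 0.05)
    tab$significant[1]
  })
  expect_gte(sum(hits), 18)

  # alpha = 1: everything significant
  fits <- lapply(1:5, function(r) {
    suppressWarnings(fit_trajectory(ages9, rnorm(9)))
  })
  expect_true(all(nodal_significance(fits, alpha = 1)$significant))
})

test_that("linear rates are OLS slopes", {
  expect_equal(linear_rate(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(linear_rate(rep(5, 4), 1:4), 0)
  set.seed(10)
  x <- seq(0, 8, 1); y <- -2.5 * x + rnorm(9, 0, 0.1)
  se <- summary(lm(y ~ x))$coefficients[2, 2]
  expect_lt(abs(linear_rate(y, x) + 2.5), 3 * se)
  expect_error(linear_rate(1:3, rep(2, 3)), "constant")
})
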