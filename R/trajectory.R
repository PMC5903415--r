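#' Fit a developmental trajectory to a windowed metric series
#'
#' Fits both a linear model and a complexity-constrained smoothing spline to
#' a metric observed at the median ages of a series of age windows, and
#' selects between them by AIC. The spline is a penalized cubic smoother
#' with a 6-function basis, knots placed at quantiles of the ages, and the
#' smoothing parameter optimized by REML. The spline term's effective
#' degrees of freedom (the trace of its smoother matrix, as standard
#' software reports it) are capped at `edf_max` by inflating the smoothing
#' parameter, keeping the accepted curve approximately as smooth as a
#' low-order polynomial trend. Each model is compared against the
#' intercept-only model by an F-type test with edf-based degrees of
#' freedom.
#'
#' @param x strictly increasing predictor (window median ages, years).
#' @param y metric values, one per window.
#' @param edf_max cap on the spline term's effective degrees of freedom
#'   (default 3.5).
#' @param n_basis number of cubic B-spline basis functions (default 6).
#' @param grid_step spacing (years) of the dense grid on which the fitted
#'   curve is evaluated.
#' @return A `trajectory` object: the data, both fits with their AIC/BIC/edf
#'   and p-values versus the constant model, the chosen model class
#'   (`"linear"` or `"spline"`), and the dense fitted curve.
#' @examples
#' x <- seq(14.5, 23.5, length.out = 9)
#' fit <- fit_trajectory(x, (x - 19)^2 + rnorm(9, 0, 0.1))
#' trajectory_params(fit)$age_min
#' @export
fit_trajectory <- function(x, y, edf_max = 3.5, n_basis = 6L,
                           grid_step = 0.01) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 5) stop("need at least 5 points, got ", length(x))
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  n <- length(x)
  rss0 <- sum((y - mean(y))^2)

  lin <- stats::lm(y ~ x)
  lin_rss <- sum(stats::resid(lin)^2)
  linear <- list(coef = stats::coef(lin), rss = lin_rss, edf = 2,
                 aic = gauss_aic(n, lin_rss, 2),
                 bic = gauss_bic(n, lin_rss, 2),
                 p = ftest_vs_constant(rss0, lin_rss, 2, n))

  spline <- NULL
  if (n > n_basis) {
    spline <- tryCatch(fit_capped_spline(x, y, edf_max, n_basis),
                       error = function(e) {
                         warning("spline fit failed (", conditionMessage(e),
                                 "); linear fit only")
                         NULL
                       })
  }
  if (!is.null(spline)) {
    # AIC/BIC count intercept + the smoothing-uncertainty-corrected edf,
    # which guards against spurious wiggle when REML leaves the boundary
    spline$aic <- gauss_aic(n, spline$rss, 1 + spline$edf_corrected)
    spline$bic <- gauss_bic(n, spline$rss, 1 + spline$edf_corrected)
    spline$p <- ftest_vs_constant(rss0, spline$rss, 1 + spline$edf, n)
  } else if (n <= n_basis) {
    warning("too few points for the ", n_basis,
            "-basis spline; linear fit only")
  }

  chosen <- if (!is.null(spline) && spline$aic < linear$aic) "spline" else
    "linear"
  grid <- seq(min(x), max(x), by = grid_step)
  curve <- if (chosen == "spline") {
    as.numeric(mgcv::predict.gam(spline$gam, newdata = data.frame(x = grid)))
  } else {
    linear$coef[1] + linear$coef[2] * grid
  }

  structure(list(x = x, y = y, linear = linear, spline = spline,
                 chosen = chosen, grid = grid, curve = curve,
                 edf_max = edf_max, n_basis = n_basis,
                 grid_step = grid_step),
            class = "trajectory")
}

gauss_aic <- function(n, rss, edf) n * log(rss / n) + 2 * (edf + 1)
gauss_bic <- function(n, rss, edf) n * log(rss / n) + log(n) * (edf + 1)

ftest_vs_constant <- function(rss0, rss1, edf, n) {
  df1 <- edf - 1
  df2 <- n - edf
  if (df2 <= 0) return(NA_real_)
  if (rss0 <= 0) return(1)          # constant data: no evidence of change
  if (rss1 <= 0) return(0)          # perfect fit of non-constant data
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  stats::pf(max(f, 0), df1, df2, lower.tail = FALSE)
}

# REML cubic-spline smoother (rank-6 basis, knots at covariate quantiles).
# The smooth term's effective df (trace of its smoother matrix, as reported
# by summary.gam) is capped at edf_max by inflating the smoothing parameter;
# basis functions are never dropped.
fit_capped_spline <- function(x, y, edf_max, n_basis) {
  dat <- data.frame(x = x, y = y)
  refit <- function(sp = NULL) {
    mgcv::gam(y ~ s(x, bs = "cr", k = n_basis), data = dat, sp = sp,
              method = "REML")
  }
  fit <- refit()
  edf_s <- function(f) sum(f$edf)
  if (edf_s(fit) > edf_max) {
    sp <- max(fit$sp, 1e-8)
    for (i in 1:60) {
      sp <- sp * 4
      fit2 <- refit(sp)
      if (edf_s(fit2) <= edf_max) break
    }
    # tighten by bisection between the last two sp values
    lo <- sp / 4; hi <- sp; fit <- fit2
    for (i in 1:30) {
      mid <- sqrt(lo * hi)
      fitm <- refit(mid)
      if (edf_s(fitm) <= edf_max) { hi <- mid; fit <- fitm } else lo <- mid
    }
  }
  edf_c <- if (is.null(fit$edf2)) sum(fit$edf) else sum(fit$edf2)
  list(gam = fit, rss = sum(stats::resid(fit)^2), edf = edf_s(fit),
       edf_corrected = max(edf_c, edf_s(fit)),
       sp = if (length(fit$sp)) fit$sp else fit$full.sp)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory fit over %d windows, ages %.2f-%.2f\n",
              length(x$x), min(x$x), max(x$x)))
  cat(sprintf("  linear: AIC %.2f (p = %.3g)\n", x$linear$aic, x$linear$p))
  if (!is.null(x$spline)) {
    cat(sprintf("  spline: AIC %.2f, edf %.2f (p = %.3g)\n",
                x$spline$aic, x$spline$edf, x$spline$p))
  }
  cat("  chosen:", x$chosen, "\n")
  invisible(x)
}

#' @export
summary.trajectory <- function(object, ...) {
  pars <- trajectory_params(object)
  out <- c(list(chosen = object$chosen, n = length(object$x),
                aic_linear = object$linear$aic,
                aic_spline = if (is.null(object$spline)) NA_real_ else
                  object$spline$aic,
                edf = if (object$chosen == "spline") object$spline$edf else 2,
                p = if (object$chosen == "spline") object$spline$p else
                  object$linear$p),
           pars)
  class(out) <- "summary.trajectory"
  out
}

#' @export
print.summary.trajectory <- function(x, ...) {
  cat(sprintf(paste0("%s trajectory (n = %d, edf = %.2f, p = %.3g): ",
                     "%s, delta_max = %.3g, age at minimum = %.2f%s\n"),
              x$chosen, x$n, x$edf, x$p, x$direction, x$delta_max,
              x$age_min, if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' @export
coef.trajectory <- function(object, ...) {
  if (object$chosen == "linear") object$linear$coef else
    stats::coef(object$spline$gam)
}

#' @export
predict.trajectory <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  if (object$chosen == "spline") {
    as.numeric(mgcv::predict.gam(object$spline$gam,
                                 newdata = data.frame(x = xx)))
  } else {
    object$linear$coef[[1]] + object$linear$coef[[2]] * xx
  }
}

#' @export
fitted.trajectory <- function(object, ...) predict.trajectory(object)

#' @export
residuals.trajectory <- function(object, ...) {
  object$y - fitted.trajectory(object)
}

#' @export
plot.trajectory <- function(x, xlab = "median age (years)", ylab = "metric",
                            ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = 19, ...)
  graphics::lines(x$grid, x$curve, lwd = 2)
  pars <- trajectory_params(x)
  graphics::points(pars$age_min, min(x$curve), pch = 21, bg = "white",
                   cex = 1.3)
  invisible(x)
}

#' Change parameters of a fitted trajectory
#'
#' Evaluates the chosen model's dense fitted curve and extracts the maximum
#' change `delta_max` (absolute difference between the curve maximum and
#' minimum), the age at the curve minimum `age_min`, the direction of
#' maximum change (decreasing if the maximum precedes the minimum in age),
#' and the shape class (the chosen model).
#'
#' @param fit a `trajectory`.
#' @return list(delta_max, age_min, age_max, direction, shape, boundary):
#'   `boundary` flags an `age_min` at an endpoint of the age range.
#' @export
trajectory_params <- function(fit) {
  stopifnot(inherits(fit, "trajectory"))
  i_min <- which.min(fit$curve)
  i_max <- which.max(fit$curve)
  age_min <- fit$grid[i_min]
  age_max <- fit$grid[i_max]
  list(delta_max = fit$curve[i_max] - fit$curve[i_min],
       age_min = age_min,
       age_max = age_max,
       direction = if (age_max < age_min) "decreasing" else "increasing",
       shape = if (fit$chosen == "spline") "nonlinear" else "linear",
       boundary = i_min %in% c(1L, length(fit$grid)))
}

#' Bootstrap percentile confidence interval for the age at minimum
#'
#' Refits the chosen trajectory model to each bootstrap replicate of the
#' windowed metric series and returns the percentile interval of the
#' resulting ages-at-minimum.
#'
#' @param boot_series replicates x windows matrix of bootstrap metric values
#'   (one row per bootstrap replicate, columns ordered as `x`).
#' @param x window median ages.
#' @param fit the point-estimate `trajectory` whose chosen model class is
#'   refitted per replicate.
#' @param level confidence level (default 0.95).
#' @param smoothing `"fixed"` (default) refits spline replicates at the
#'   point fit's smoothing parameter, so every replicate inherits its
#'   (cap-compliant) effective df; `"reml"` re-optimizes and re-caps the
#'   smoothing per replicate.
#' @return list(lower, upper, age_mins) with the replicate ages-at-minimum.
#' @export
bootstrap_age_min_ci <- function(boot_series, x, fit, level = 0.95,
                                 smoothing = c("fixed", "reml")) {
  smoothing <- match.arg(smoothing)
  stopifnot(inherits(fit, "trajectory"), ncol(boot_series) == length(x))
  if (nrow(boot_series) < 100) {
    warning("fewer than 100 bootstrap replicates: CI may be unstable")
  }
  grid <- fit$grid
  sp_fix <- if (fit$chosen == "spline") fit$spline$sp else NULL
  age_mins <- apply(boot_series, 1, function(yb) {
    if (stats::var(yb) == 0) {
      # flat replicate: minimum location taken at the flat curve's start
      return(grid[1])
    }
    curve <- if (fit$chosen == "spline") {
      sf <- if (smoothing == "fixed" && length(sp_fix)) {
        list(gam = mgcv::gam(y ~ s(x, bs = "cr", k = fit$n_basis),
                             data = data.frame(x = x, y = yb), sp = sp_fix,
                             method = "REML"))
      } else {
        fit_capped_spline(x, yb, fit$edf_max, fit$n_basis)
      }
      as.numeric(mgcv::predict.gam(sf$gam, newdata = data.frame(x = grid)))
    } else {
      cf <- stats::coef(stats::lm(yb ~ x))
      cf[1] + cf[2] * grid
    }
    grid[which.min(curve)]
  })
  qs <- stats::quantile(age_mins, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lower = qs[1], upper = qs[2], age_mins = age_mins)
}

#' FDR significance and classification of regional change parameters
#'
#' Benjamini-Hochberg-adjusts the per-region trajectory p-values (chosen
#' model versus constant), flags regions with adjusted p below `alpha`, and
#' carries each region's linear/nonlinear and increasing/decreasing
#' classification.
#'
#' @param fits named list of per-region `trajectory` objects.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data frame: region, p, p_fdr, significant, shape, direction,
#'   delta_max, age_min, boundary.
#' @export
nodal_significance <- function(fits, alpha = 0.05) {
  p <- vapply(fits, function(f) {
    if (f$chosen == "spline") f$spline$p else f$linear$p
  }, numeric(1))
  p_fdr <- stats::p.adjust(p, method = "BH")
  pars <- lapply(fits, trajectory_params)
  data.frame(
    region = if (is.null(names(fits))) seq_along(fits) else names(fits),
    p = p, p_fdr = p_fdr, significant = p_fdr < alpha,
    shape = vapply(pars, `[[`, character(1), "shape"),
    direction = vapply(pars, `[[`, character(1), "direction"),
    delta_max = vapply(pars, `[[`, numeric(1), "delta_max"),
    age_min = vapply(pars, `[[`, numeric(1), "age_min"),
    boundary = vapply(pars, `[[`, logical(1), "boundary"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Ordinary least-squares rate of change
#'
#' @param y response values.
#' @param x predictor (ages); must not be constant.
#' @return the OLS slope of `y` on `x`, per unit of `x`.
#' @export
linear_rate <- function(y, x) {
  if (length(y) != length(x) || length(x) < 2) stop("need >= 2 paired points")
  if (stats::var(x) == 0) stop("x is constant; slope undefined")
  stats::cov(x, y) / stats::var(x)
}
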