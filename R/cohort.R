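#' Age-dependent block covariance model for a synthetic cohort
#'
#' Defines how the inter-regional correlation structure of regional cortical
#' thickness varies with age. Correlations are block-constant over planted
#' modules: `within_r(age)` inside a module, `between_r(age)` elsewhere. The
#' default parameterization is quadratic in age around a minimum at
#' `age_at_min`, emulating a global correlation curve that declines through
#' mid-adolescence and rises slightly afterwards.
#'
#' @param within_base,within_curv within-module correlation at the minimum and
#'   its quadratic curvature per squared year.
#' @param between_base,between_curv same for between-module pairs.
#' @param age_at_min age (years) at which correlations are weakest.
#' @param noise_sd per-region residual standard deviation of cortical
#'   thickness (mm); recycled over regions.
#' @param loading_range range of per-region loading factors `c_i`; the
#'   correlation of regions i and j is `c_i * c_j * r_block(age)`, so
#'   pairwise strengths are heterogeneous and windowed edge retention varies
#'   smoothly with age. `c(1, 1)` gives homogeneous blocks.
#' @param within_fn,between_fn optional arbitrary functions age -> r that
#'   override the quadratic parameterization (parameters are then recorded
#'   as `NA` in serialized ground truth).
#' @return A `covariance_model` with callable `within_r` / `between_r`.
#' @examples
#' m <- covariance_model()
#' m$within_r(19.5)   # within-module correlation at the trajectory minimum
#' @export
covariance_model <- function(within_base = 0.50, within_curv = 0.012,
                             between_base = 0.28, between_curv = 0.012,
                             age_at_min = 19.5, noise_sd = 0.12,
                             loading_range = c(0.6, 1),
                             within_fn = NULL, between_fn = NULL) {
  params <- list(within_base = within_base, within_curv = within_curv,
                 between_base = between_base, between_curv = between_curv,
                 age_at_min = age_at_min, noise_sd = noise_sd,
                 loading_min = loading_range[1],
                 loading_max = loading_range[2])
  if (!is.null(within_fn) || !is.null(between_fn)) {
    params[c("within_base", "within_curv", "between_base",
             "between_curv")] <- NA_real_
  }
  w <- within_fn %||%
    function(age) within_base + within_curv * (age - age_at_min)^2
  b <- between_fn %||%
    function(age) between_base + between_curv * (age - age_at_min)^2
  structure(list(within_r = w, between_r = b, age_at_min = age_at_min,
                 noise_sd = noise_sd, loading_range = loading_range,
                 params = params),
            class = "covariance_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# block correlation matrix implied by the model at one age, scaled by the
# regional loading factors, PSD-repaired by eigenvalue clipping at 0 and
# re-normalization to unit diagonal
model_correlation <- function(model, age, modules, loadings = NULL) {
  rw <- model$within_r(age)
  rb <- model$between_r(age)
  if (any(abs(c(rw, rb)) > 1)) {
    stop("covariance model yields |r| > 1 at age ", age)
  }
  same <- outer(modules, modules, "==")
  R <- ifelse(same, rw, rb)
  if (!is.null(loadings)) R <- R * tcrossprod(loadings)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    v <- pmax(ev$values, 0)
    R <- ev$vectors %*% (v * t(ev$vectors))
    d <- sqrt(diag(R))
    if (any(d == 0)) stop("correlation matrix not repairable at age ", age)
    R <- R / tcrossprod(d)
  }
  R
}

#' Generate a synthetic cortical cohort with known ground truth
#'
#' Draws a cross-sectional cohort whose regional cortical thickness (and
#' optionally magnetization-transfer, MT) values follow the statistical
#' structure the sliding-window analysis assumes: ages sampled
#' stratified-uniform over contiguous age strata; each participant's regional
#' vector drawn from a multivariate normal whose correlation matrix is the
#' covariance model evaluated at that participant's own age; regional means
#' follow linear-in-age thinning (CT) and myelination (MT) trends.
#'
#' @param n_participants cohort size.
#' @param regions a `region_set` from [generate_regions()].
#' @param model a [covariance_model()].
#' @param age_range numeric length 2, years.
#' @param n_strata number of contiguous recruitment strata.
#' @param seed integer seed; the dataset is deterministic given it.
#' @param ct_baseline_mean,ct_baseline_sd mean/sd of per-region baseline
#'   thickness at the youngest age (mm).
#' @param ct_slope_mean,ct_slope_sd distribution of true regional thinning
#'   rates (mm/year; negative means thinning).
#' @param mt_depths character vector of MT depth labels to simulate
#'   (e.g. `c("30%","70%","wm1")`), or `NULL` for no MT maps.
#' @param mt_slope_mean,mt_slope_sd distribution of true regional myelination
#'   rates (percentage units/year), shared across depths.
#' @return A `cortical_cohort`: list with `thickness`
#'   (participants x regions), `participants` (id, age, sex), `regions`,
#'   optional `mt` (named list of participants x regions matrices), and
#'   `ground_truth` (true slopes, model parameters, planted modules).
#' @examples
#' reg <- generate_regions(20, 2, seed = 1)
#' coh <- generate_cohort(50, reg, covariance_model(), seed = 1)
#' dim(coh$thickness)
#' @export
generate_cohort <- function(n_participants, regions, model = covariance_model(),
                            age_range = c(14, 24), n_strata = 5L, seed = 1L,
                            ct_baseline_mean = 2.7, ct_baseline_sd = 0.15,
                            ct_slope_mean = -0.02, ct_slope_sd = 0.01,
                            mt_depths = NULL,
                            mt_slope_mean = 0.6, mt_slope_sd = 0.3) {
  stopifnot(n_participants >= 2, inherits(regions, "region_set"))
  n_regions <- nrow(regions)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  # stratified-uniform ages: contiguous equal strata of the age range,
  # per-stratum counts as equal as possible (max - min <= 1)
  breaks <- seq(age_range[1], age_range[2], length.out = n_strata + 1)
  counts <- rep(n_participants %/% n_strata, n_strata)
  extra <- n_participants %% n_strata
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  ages <- unlist(lapply(seq_len(n_strata), function(s) {
    stats::runif(counts[s], breaks[s], breaks[s + 1])
  }))
  ages <- sort(ages)
  sex <- sample(c("F", "M"), n_participants, replace = TRUE)

  baseline <- stats::rnorm(n_regions, ct_baseline_mean, ct_baseline_sd)
  ct_slope <- stats::rnorm(n_regions, ct_slope_mean, ct_slope_sd)
  noise_sd <- rep_len(model$noise_sd, n_regions)
  loadings <- stats::runif(n_regions, model$loading_range[1],
                           model$loading_range[2])

  # each participant drawn at their own age's correlation matrix
  thickness <- matrix(NA_real_, n_participants, n_regions)
  for (p in seq_len(n_participants)) {
    R <- model_correlation(model, ages[p], regions$module, loadings)
    L <- tryCatch(chol(R), error = function(e) {
      ev <- eigen(R, symmetric = TRUE)
      t(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors)))
    })
    z <- drop(stats::rnorm(n_regions) %*% L)
    thickness[p, ] <- baseline + ct_slope * (ages[p] - age_range[1]) +
      noise_sd * z
  }
  colnames(thickness) <- region_col_names(regions)

  mt <- NULL
  mt_slopes <- NULL
  if (!is.null(mt_depths)) {
    mt_slopes <- matrix(stats::rnorm(n_regions * length(mt_depths),
                                     mt_slope_mean, mt_slope_sd),
                        n_regions, length(mt_depths),
                        dimnames = list(NULL, mt_depths))
    mt_baseline <- stats::rnorm(n_regions, 85, 3)
    mt <- lapply(mt_depths, function(d) {
      m <- outer(ages - age_range[1], mt_slopes[, d]) +
        matrix(mt_baseline, n_participants, n_regions, byrow = TRUE) +
        matrix(stats::rnorm(n_participants * n_regions, 0, 1.5),
               n_participants, n_regions)
      colnames(m) <- region_col_names(regions)
      m
    })
    names(mt) <- mt_depths
  }

  structure(list(
    thickness = thickness,
    participants = data.frame(id = sprintf("sub-%03d", seq_len(n_participants)),
                              age = ages, sex = sex,
                              stringsAsFactors = FALSE),
    regions = regions,
    mt = mt,
    ground_truth = list(
      model_params = model$params,
      age_at_min = model$age_at_min,
      ct_baseline = baseline,
      ct_slope = ct_slope,
      loadings = loadings,
      mt_slope = mt_slopes,
      planted_module = regions$module,
      seed = seed,
      age_range = age_range,
      n_strata = n_strata
    )
  ), class = "cortical_cohort")
}

region_col_names <- function(regions) sprintf("r%03d", regions$region_id)

#' @export
print.cortical_cohort <- function(x, ...) {
  cat(sprintf(paste0("Cortical cohort: %d participants aged %.1f-%.1f, ",
                     "%d regions%s\n"),
              nrow(x$thickness), min(x$participants$age),
              max(x$participants$age), ncol(x$thickness),
              if (is.null(x$mt)) "" else
                sprintf(", MT at %d depths", length(x$mt))))
  invisible(x)
}
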