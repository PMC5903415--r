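#' Generate a synthetic cortical region set on two hemispheric spheres
#'
#' Places an even number of regions quasi-uniformly on two unit spheres (one
#' per hemisphere) using a Fibonacci lattice, mirrors the left-hemisphere
#' layout into the right hemisphere through the sagittal (x = 0) plane, and
#' assigns module labels in spatially contiguous patches so that planted
#' community structure carries realistic spatial autocorrelation.
#'
#' @param n_regions even total number of regions (half per hemisphere).
#' @param n_modules number of planted modules, at most `n_regions / 2`.
#' @param seed integer seed controlling module seed-region placement.
#' @param brain_radius nominal radius (mm) used to scale sphere coordinates
#'   into anatomical centroids.
#' @return A `region_set`: a data frame with one row per region and columns
#'   `region_id`, `hemisphere` ("left"/"right"), centroid coordinates
#'   `x`,`y`,`z` (mm), unit-sphere coordinates `sx`,`sy`,`sz`, and the
#'   planted `module` label. Left/right rows are mirror pairs.
#' @examples
#' reg <- generate_regions(100, n_modules = 4, seed = 1)
#' table(reg$hemisphere)
#' @export
generate_regions <- function(n_regions, n_modules, seed = 1L,
                             brain_radius = 50) {
  if (n_regions %% 2L != 0L) {
    stop("n_regions must be even (half per hemisphere), got ", n_regions)
  }
  if (n_modules < 1L || n_modules > n_regions / 2L) {
    stop("n_modules must be in [1, n_regions/2], got ", n_modules)
  }
  n_hemi <- n_regions %/% 2L

  # Fibonacci lattice on the unit sphere for the left hemisphere
  i <- seq_len(n_hemi) - 0.5
  phi <- acos(1 - 2 * i / n_hemi)               # polar angle
  theta <- pi * (1 + sqrt(5)) * i               # golden-angle azimuth
  left <- cbind(sx = sin(phi) * cos(theta),
                sy = sin(phi) * sin(theta),
                sz = cos(phi))
  right <- left
  right[, "sx"] <- -right[, "sx"]               # sagittal mirror image

  # contiguous module patches: nearest module seed by great-circle distance,
  # grown on the left hemisphere and mirrored to the right
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  seed_idx <- sample.int(n_hemi, n_modules)
  dots <- left %*% t(left[seed_idx, , drop = FALSE])
  module_left <- max.col(dots, ties.method = "first")
  # relabel contiguously from 1 in case a seed captured no region
  module_left <- match(module_left, sort(unique(module_left)))

  sphere <- rbind(left, right)
  out <- data.frame(
    region_id = seq_len(n_regions),
    hemisphere = rep(c("left", "right"), each = n_hemi),
    x = brain_radius * sphere[, "sx"],
    y = brain_radius * sphere[, "sy"],
    z = brain_radius * sphere[, "sz"],
    sx = sphere[, "sx"], sy = sphere[, "sy"], sz = sphere[, "sz"],
    module = rep(module_left, 2L),
    stringsAsFactors = FALSE
  )
  class(out) <- c("region_set", "data.frame")
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("Region set: %d regions (%d per hemisphere), %d planted modules\n",
              nrow(x), nrow(x) %/% 2L, length(unique(x$module))))
  NextMethod()
}

# great-circle distance matrix between unit sphere coordinates
great_circle_dist <- function(coords_a, coords_b = coords_a) {
  d <- coords_a %*% t(coords_b)
  acos(pmin(pmax(d, -1), 1))   # pmin/pmax keep the first argument's dim
}

sphere_coords <- function(regions) {
  as.matrix(regions[, c("sx", "sy", "sz")])
}

centroid_coords <- function(regions) {
  as.matrix(regions[, c("x", "y", "z")])
}
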