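#' Uniformly random 3-D rotation
#'
#' Draws a rotation matrix uniformly over SO(3) by QR-orthonormalizing a
#' Gaussian matrix, sign-correcting the factorization, and flipping one
#' column if needed so the determinant is +1.
#'
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so repeated calls give independent rotations).
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  # fix the sign ambiguity so Q is Haar-distributed
  q <- q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

#' Spatial permutation of regions by spherical rotation
#'
#' Applies one random rotation to the left-hemisphere sphere coordinates and
#' its sagittal mirror image (conjugation by the x -> -x reflection) to the
#' right hemisphere, then reassigns each region the value of the nearest
#' original region (great-circle distance) within the same hemisphere. The
#' mapping preserves spatial contiguity and hemispheric symmetry of the
#' permuted map and may be non-injective.
#'
#' @param regions a `region_set` with unit-sphere coordinates.
#' @param rotation optional 3 x 3 rotation (drawn from the current RNG
#'   stream if omitted).
#' @return integer vector `perm` such that `map[perm]` is the rotated map;
#'   `perm[i]` is always in region `i`'s hemisphere.
#' @export
spin_permute <- function(regions, rotation = NULL) {
  sph <- sphere_coords(regions)
  if (anyNA(sph)) stop("sphere coordinates missing for some regions")
  if (is.null(rotation)) rotation <- random_rotation()
  mirror <- diag(c(-1, 1, 1))
  rot_right <- mirror %*% rotation %*% mirror
  perm <- integer(nrow(regions))
  for (h in c("left", "right")) {
    idx <- which(regions$hemisphere == h)
    R <- if (h == "left") rotation else rot_right
    rotated <- sph[idx, , drop = FALSE] %*% t(R)
    # nearest original region by great-circle distance = max dot product
    nearest <- max.col(rotated %*% t(sph[idx, , drop = FALSE]),
                       ties.method = "first")
    perm[idx] <- idx[nearest]
  }
  perm
}

#' Spin permutation test for the correlation of two cortical maps
#'
#' Compares the empirical Spearman correlation of two regional maps against
#' a null distribution built by spherically rotating the second map
#' `n_perm` times. The permutation p-value uses the add-one rule
#' `(1 + #\{|rho_null| >= |rho_emp|\}) / (n_perm + 1)` (two-sided), so it is
#' never exactly zero. The parametric Spearman p-value is reported
#' alongside.
#'
#' @param map_a,map_b per-region maps; `map_b` is the map that is rotated.
#' @param regions a `region_set`.
#' @param n_perm number of rotations (default 10000).
#' @param seed integer seed.
#' @return A `spin_result`: list(rho_emp, p_perm, p_spearman, null_rhos,
#'   n_perm).
#' @export
spin_pvalue <- function(map_a, map_b, regions, n_perm = 10000L, seed = 1L) {
  stopifnot(n_perm >= 1)
  if (length(map_a) != nrow(regions) || length(map_b) != nrow(regions)) {
    stop("maps must cover all regions")
  }
  if (stats::var(map_a) == 0 || stats::var(map_b) == 0) {
    stop("constant map: Spearman correlation undefined")
  }
  rank_a <- rank(map_a)
  rho_emp <- stats::cor(rank_a, rank(map_b))
  p_spearman <- suppressWarnings(
    stats::cor.test(map_a, map_b, method = "spearman")$p.value)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  null_rhos <- vapply(seq_len(n_perm), function(i) {
    perm <- spin_permute(regions)
    rb <- rank(map_b[perm])
    if (stats::var(rb) == 0) return(0)  # mapping collapsed to one value
    stats::cor(rank_a, rb)
  }, numeric(1))
  p_perm <- (1 + sum(abs(null_rhos) >= abs(rho_emp))) / (n_perm + 1)
  structure(list(rho_emp = rho_emp, p_perm = p_perm,
                 p_spearman = p_spearman, null_rhos = null_rhos,
                 n_perm = n_perm),
            class = "spin_result")
}

#' @export
print.spin_result <- function(x, ...) {
  cat(sprintf("Spin test: rho = %.3f, p_perm = %.4g (%d rotations), p_spearman = %.4g\n",
              x$rho_emp, x$p_perm, x$n_perm, x$p_spearman))
  invisible(x)
}
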