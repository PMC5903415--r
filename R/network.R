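#' Pearson correlation matrix over a participant subset
#'
#' Cross-correlates regional values (raw, with no covariate adjustment)
#' across the participants in `subset`.
#'
#' @param values participants x regions numeric matrix.
#' @param subset integer indices of the participants to use (default all).
#' @return A `corr_matrix`: list with `weights` (symmetric region x region
#'   Pearson r, unit diagonal), `n_participants`, and `subset`.
#' @export
correlation_matrix <- function(values, subset = seq_len(nrow(values))) {
  if (length(subset) < 3) stop("need at least 3 participants, got ",
                               length(subset))
  x <- values[subset, , drop = FALSE]
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(x)[v == 0] %||% which(v == 0)
    stop("zero-variance region(s) over this subset: ",
         paste(bad, collapse = ", "))
  }
  w <- stats::cor(x)
  structure(list(weights = w, n_participants = length(subset),
                 subset = subset),
            class = "corr_matrix")
}

#' Decompose the mean correlation into covariance and scale components
#'
#' Reports, over all off-diagonal region pairs, the mean inter-regional
#' covariance and the mean product of regional standard deviations — the
#' numerator and denominator of the Pearson coefficient — together with the
#' ratio of the two means (which differs in general from the mean
#' correlation).
#'
#' @inheritParams correlation_matrix
#' @return list(mean_covariance, mean_sd_product, ratio).
#' @export
decompose_correlation <- function(values, subset = seq_len(nrow(values))) {
  if (length(subset) < 3) stop("need at least 3 participants")
  x <- values[subset, , drop = FALSE]
  cv <- stats::cov(x)
  s <- sqrt(diag(cv))
  if (any(s == 0)) stop("zero-variance region(s) over this subset")
  off <- upper.tri(cv)
  sd_prod <- tcrossprod(s)
  list(mean_covariance = mean(cv[off]),
       mean_sd_product = mean(sd_prod[off]),
       ratio = mean(cv[off]) / mean(sd_prod[off]))
}

#' Bootstrap sign-consistency p-values for every edge
#'
#' Resamples the participant subset with replacement `n_boot` times,
#' re-estimating the whole correlation matrix per resample (edges share
#' resamples), and tests each edge for a consistently nonzero correlation.
#' With `smoothing = "none"` (default) the two-tailed p-value is
#' `2 * min(#\{r* <= 0\}, #\{r* >= 0\}) / n_boot`, so an edge whose sign is
#' perfectly consistent across resamples gets p = 0 and survives any FDR
#' level — which is what lets thresholded networks reach low edge densities.
#' With `smoothing = "add_one"` the counts and denominator get the classic
#' +1 correction, `2 * min(#\{r* <= 0\} + 1, #\{r* >= 0\} + 1) / (n_boot + 1)`,
#' which avoids exact zeros at the price of a p floor of `2/(n_boot + 1)`
#' (at that floor, Benjamini-Hochberg retention at small alpha becomes
#' all-or-nothing). A region with zero variance inside a resample yields a
#' neutral `r* = 0` for its edges (counted in both tails); the number of
#' such degenerate resamples is recorded in attribute `"n_degenerate"`.
#'
#' @inheritParams correlation_matrix
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param seed integer seed; results are deterministic given it.
#' @param smoothing `"none"` or `"add_one"` (see Details).
#' @return symmetric matrix of two-tailed p-values (diagonal `NA`).
#' @export
bootstrap_edge_pvalues <- function(values, subset = seq_len(nrow(values)),
                                   n_boot = 1000L, seed = 1L,
                                   smoothing = c("none", "add_one")) {
  smoothing <- match.arg(smoothing)
  if (length(subset) < 3) stop("need at least 3 participants")
  if (n_boot < 2) stop("n_boot must be >= 2")
  x <- values[subset, , drop = FALSE]
  n <- nrow(x)
  p_reg <- ncol(x)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  n_nonpos <- matrix(0L, p_reg, p_reg)
  n_nonneg <- matrix(0L, p_reg, p_reg)
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- suppressWarnings(stats::cor(x[idx, , drop = FALSE]))
    if (anyNA(r)) {               # zero-variance region in this resample
      n_degenerate <- n_degenerate + 1L
      r[is.na(r)] <- 0
    }
    n_nonpos <- n_nonpos + (r <= 0)
    n_nonneg <- n_nonneg + (r >= 0)
  }
  p <- if (smoothing == "add_one") {
    2 * pmin(n_nonpos + 1L, n_nonneg + 1L) / (n_boot + 1)
  } else {
    2 * pmin(n_nonpos, n_nonneg) / n_boot
  }
  p <- pmin(p, 1)
  diag(p) <- NA_real_
  dimnames(p) <- list(colnames(x), colnames(x))
  attr(p, "n_degenerate") <- n_degenerate
  p
}

#' Benjamini-Hochberg adjustment of edge p-values
#'
#' @param p vector (or symmetric matrix; the upper triangle is adjusted and
#'   mirrored) of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the same shape.
#' @export
fdr_adjust <- function(p) {
  if (is.matrix(p)) {
    up <- upper.tri(p)
    q <- p
    q[up] <- fdr_adjust(p[up])
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    return(q)
  }
  if (anyNA(p)) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold a correlation network by FDR-adjusted bootstrap p-values
#'
#' Retains edges with `p_adj < alpha`; retained edges keep the observed
#' (full-subset) correlation as weight, all other edges are set to zero.
#'
#' @param corr a `corr_matrix`.
#' @param p_adj symmetric matrix of FDR-adjusted p-values.
#' @param alpha retention level (default 0.01, two-tailed).
#' @param p optional matrix of raw p-values, carried along for export.
#' @return A `thresholded_network`: `weights` (zeroed where not retained),
#'   logical `mask`, `p`, `p_adj`, `alpha`, counts of positive/negative
#'   retained edges, and provenance (`n_participants`, `subset`).
#' @export
threshold_network <- function(corr, p_adj, alpha = 0.01, p = NULL) {
  stopifnot(inherits(corr, "corr_matrix"))
  w <- corr$weights
  if (!all(dim(p_adj) == dim(w))) stop("dimension mismatch between ",
                                       "correlations and p-values")
  mask <- !is.na(p_adj) & p_adj < alpha
  diag(mask) <- FALSE
  wt <- ifelse(mask, w, 0)
  diag(wt) <- 0
  up <- upper.tri(mask)
  structure(list(weights = wt, mask = mask, observed = w, p = p,
                 p_adj = p_adj, alpha = alpha,
                 n_retained_pos = sum(mask[up] & w[up] > 0),
                 n_retained_neg = sum(mask[up] & w[up] < 0),
                 n_participants = corr$n_participants,
                 subset = corr$subset),
            class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  n <- nrow(x$weights)
  poss <- n * (n - 1) / 2
  cat(sprintf(paste0("Thresholded network: %d regions, %d/%d edges retained ",
                     "(%.1f%%; %d+, %d-) at alpha = %g\n"),
              n, x$n_retained_pos + x$n_retained_neg, poss,
              100 * (x$n_retained_pos + x$n_retained_neg) / poss,
              x$n_retained_pos, x$n_retained_neg, x$alpha))
  invisible(x)
}

#' One-call bootstrap-thresholded network for a participant subset
#'
#' Convenience wrapper chaining [correlation_matrix()],
#' [bootstrap_edge_pvalues()], [fdr_adjust()] and [threshold_network()].
#'
#' @inheritParams bootstrap_edge_pvalues
#' @inheritParams threshold_network
#' @return A `thresholded_network`.
#' @export
build_network <- function(values, subset = seq_len(nrow(values)),
                          n_boot = 1000L, alpha = 0.01, seed = 1L) {
  corr <- correlation_matrix(values, subset)
  p <- bootstrap_edge_pvalues(values, subset, n_boot = n_boot, seed = seed)
  p_adj <- fdr_adjust(p)
  threshold_network(corr, p_adj, alpha = alpha, p = p)
}

#' Export a thresholded network as an edge list
#' @param net a `thresholded_network`.
#' @return data frame (region_i, region_j, r, p, p_adj, retained), one row
#'   per region pair.
#' @export
edge_list <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  n <- nrow(net$mask)
  up <- which(upper.tri(net$mask), arr.ind = TRUE)
  data.frame(region_i = up[, 1], region_j = up[, 2],
             r = net$observed[up],
             p = if (is.null(net$p)) NA_real_ else net$p[up],
             p_adj = net$p_adj[up],
             retained = net$mask[up])
}
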