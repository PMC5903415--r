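#' Louvain community partition at a given resolution
#'
#' Runs the multiresolution Louvain modularity algorithm on the positive part
#' of a symmetric weight matrix (negative weights are excluded from the
#' modularity; the null model is the standard Newman-Girvan term scaled by
#' the resolution `gamma`).
#'
#' @param weights symmetric region x region weight matrix (e.g. retained
#'   correlations); the diagonal is ignored.
#' @param gamma resolution parameter; larger values yield more modules.
#' @param seed integer seed (Louvain is stochastic).
#' @return A `community_partition`: list with integer `labels` (contiguous
#'   from 1), `gamma`, `n_runs = 1`, `is_consensus = FALSE`.
#' @export
louvain_partition <- function(weights, gamma = 1, seed = 1L) {
  w <- check_weights(weights)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  labels <- louvain_run(w, gamma)
  new_partition(labels, gamma, n_runs = 1L, is_consensus = FALSE)
}

check_weights <- function(weights) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("weight matrix must be symmetric")
  }
  w <- pmax(weights, 0)                     # positive weights only
  diag(w) <- 0
  w
}

# one Louvain run on a pre-checked nonnegative matrix; uses current RNG state
louvain_run <- function(w, gamma) {
  if (all(w == 0)) {
    warning("all-zero network: returning a single module")
    return(rep(1L, nrow(w)))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_louvain(g, resolution = gamma)
  as.integer(igraph::membership(cl))
}

new_partition <- function(labels, gamma, n_runs, is_consensus) {
  labels <- match(labels, sort(unique(labels)))  # contiguous from 1
  structure(list(labels = labels, gamma = gamma, n_runs = n_runs,
                 is_consensus = is_consensus),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d regions, %d modules (gamma = %g%s)\n",
              length(x$labels), max(x$labels), x$gamma,
              if (x$is_consensus) sprintf(", consensus of %d runs", x$n_runs)
              else ""))
  invisible(x)
}

#' Versatility curve over a resolution grid
#'
#' For each resolution `gamma`, runs Louvain `n_runs` times and measures how
#' inconsistently nodes are co-assigned across runs: with `p_ij` the
#' proportion of runs in which nodes i and j share a module, the nodal
#' versatility is `mean_j(4 * p_ij * (1 - p_ij))` — 0 when affiliation is
#' perfectly consistent, maximal when a pair is split 50:50. Resolutions at
#' local minima of the (lightly smoothed) mean-versatility curve are
#' recommended for the final partition.
#'
#' @inheritParams louvain_partition
#' @param gamma_grid increasing vector of resolutions.
#' @param n_runs Louvain runs per resolution (>= 2).
#' @param smooth_window odd moving-average length for locating minima.
#' @return A `versatility_curve` data frame: gamma, mean_versatility,
#'   modal_module_count; attribute `"recommended"` holds the gammas at local
#'   minima of the smoothed curve.
#' @export
versatility_curve <- function(weights, gamma_grid = seq(0.5, 4, by = 0.25),
                              n_runs = 50L, seed = 1L, smooth_window = 3L) {
  stopifnot(n_runs >= 2)
  w <- check_weights(weights)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  res <- lapply(gamma_grid, function(g) {
    runs <- replicate(n_runs, louvain_run(w, g))
    list(v = mean(nodal_versatility(runs)),
         k = modal_count(apply(runs, 2, max)))
  })
  v <- vapply(res, `[[`, numeric(1), "v")
  k <- vapply(res, `[[`, numeric(1), "k")
  if (all(v == 0) && all(k == 1)) {
    warning("single-module partitions at every resolution")
  }
  sm <- stats::filter(v, rep(1 / smooth_window, smooth_window), sides = 2)
  sm[is.na(sm)] <- v[is.na(sm)]
  interior <- which(diff(sign(diff(sm))) > 0) + 1L
  out <- data.frame(gamma = gamma_grid, mean_versatility = v,
                    modal_module_count = k)
  attr(out, "recommended") <- gamma_grid[interior]
  class(out) <- c("versatility_curve", "data.frame")
  out
}

# runs: nodes x n_runs label matrix
nodal_versatility <- function(runs) {
  n <- nrow(runs)
  p <- matrix(0, n, n)
  for (b in seq_len(ncol(runs))) {
    p <- p + outer(runs[, b], runs[, b], "==")
  }
  p <- p / ncol(runs)
  vmat <- 4 * p * (1 - p)
  diag(vmat) <- NA
  rowMeans(vmat, na.rm = TRUE)
}

modal_count <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Consensus community partition
#'
#' Lancichinetti-Fortunato consensus clustering: run Louvain `n_runs` times,
#' build the node co-assignment matrix, zero entries below `tau`, re-cluster
#' the consensus matrix, and iterate until all runs agree (identical labels
#' up to relabeling).
#'
#' @inheritParams louvain_partition
#' @param n_runs Louvain runs per iteration.
#' @param tau consensus threshold in (0, 1); co-assignment proportions below
#'   it are zeroed before re-clustering.
#' @param max_iter iteration cap; non-convergence returns the last partition
#'   with a warning.
#' @return A `community_partition` with `is_consensus = TRUE`.
#' @export
consensus_partition <- function(weights, gamma = 1, n_runs = 100L, tau = 0.5,
                                seed = 1L, max_iter = 20L) {
  stopifnot(tau > 0, tau < 1, n_runs >= 1)
  w <- check_weights(weights)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  n <- nrow(w)
  current <- w
  g <- gamma                       # consensus matrices re-clustered at 1
  for (iter in seq_len(max_iter)) {
    runs <- matrix(0L, n, n_runs)
    for (b in seq_len(n_runs)) runs[, b] <- louvain_run(current, g)
    if (all_runs_agree(runs)) {
      return(new_partition(runs[, 1], gamma, n_runs, is_consensus = TRUE))
    }
    p <- matrix(0, n, n)
    for (b in seq_len(n_runs)) p <- p + outer(runs[, b], runs[, b], "==")
    p <- p / n_runs
    p[p < tau] <- 0
    diag(p) <- 0
    current <- p
    g <- 1
  }
  warning("consensus did not converge in ", max_iter, " iterations")
  new_partition(runs[, 1], gamma, n_runs, is_consensus = TRUE)
}

all_runs_agree <- function(runs) {
  ref <- runs[, 1]
  for (b in seq_len(ncol(runs))[-1]) {
    if (nmi(ref, runs[, b]) < 1 - 1e-12) return(FALSE)
  }
  TRUE
}

#' Normalized mutual information between two partitions
#'
#' `NMI = 2 I(A;B) / (H(A) + H(B))` from the label contingency table;
#' invariant to relabeling, 1 iff the partitions are identical up to
#' relabeling. When both partitions are a single module (both entropies
#' zero) the 0/0 case is defined as 1 by convention.
#'
#' @param a,b label vectors of equal length, or `community_partition`s.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (inherits(a, "community_partition")) a <- a$labels
  if (inherits(b, "community_partition")) b <- b$labels
  if (length(a) != length(b)) stop("partitions must cover the same regions")
  tab <- table(a, b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  ha <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hb <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  if (ha == 0 && hb == 0) return(1)        # single module vs single module
  pjk <- tab / n
  ratio <- pjk / outer(pj, pk)
  mi <- sum(pjk[pjk > 0] * log(ratio[pjk > 0]))
  2 * mi / (ha + hb)
}
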