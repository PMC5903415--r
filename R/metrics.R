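#' Nodal and global metrics of a thresholded correlation network
#'
#' Nodal: degree (count of retained edges), weighted degree (sum of retained
#' edge weights), nodal strength (mean unthresholded correlation of the
#' node's row, diagonal excluded), and nodal connection distance (mean
#' Euclidean length in mm of the node's retained edges; `NA` for isolated
#' nodes). Global: mean unthresholded correlation over the upper triangle,
#' edge density as a percentage of possible edges, and mean Euclidean length
#' over all retained edges.
#'
#' @param net a `thresholded_network`.
#' @param corr the matching unthresholded `corr_matrix` (defaults to the
#'   observed correlations stored in `net`).
#' @param centroids regions x 3 matrix of centroid coordinates (mm), or a
#'   `region_set`.
#' @return list with `nodal` (data frame: region, degree, weighted_degree,
#'   strength, distance) and `global` (list: mean_correlation, density_pct,
#'   mean_distance, n_edges).
#' @export
network_metrics <- function(net, corr = NULL, centroids = NULL) {
  stopifnot(inherits(net, "thresholded_network"))
  w_obs <- if (is.null(corr)) net$observed else corr$weights
  if (!all(dim(w_obs) == dim(net$mask))) stop("dimension mismatch")
  n <- nrow(net$mask)
  mask <- net$mask

  degree <- rowSums(mask)
  weighted_degree <- rowSums(net$weights)
  strength <- (rowSums(w_obs) - diag(w_obs)) / (n - 1)

  dist_nodal <- rep(NA_real_, n)
  mean_dist <- NA_real_
  if (!is.null(centroids)) {
    if (inherits(centroids, "region_set")) {
      centroids <- centroid_coords(centroids)
    }
    if (nrow(centroids) != n) stop("dimension mismatch: ", nrow(centroids),
                                   " centroids vs ", n, " regions")
    D <- as.matrix(stats::dist(centroids))
    has_edge <- degree > 0
    dist_nodal[has_edge] <- rowSums(D * mask)[has_edge] / degree[has_edge]
    up <- upper.tri(mask)
    if (any(mask[up])) mean_dist <- mean(D[up][mask[up]])
  }

  up <- upper.tri(mask)
  list(
    nodal = data.frame(region = seq_len(n), degree = degree,
                       weighted_degree = weighted_degree,
                       strength = strength, distance = dist_nodal),
    global = list(mean_correlation = mean(w_obs[up]),
                  density_pct = 100 * sum(mask[up]) / sum(up),
                  mean_distance = mean_dist,
                  n_edges = sum(mask[up]))
  )
}

#' Within- and between-community edge density matrix
#'
#' For every community and pair of communities, the ratio of retained edges
#' to the maximum possible number of edges in that edge set: `m*(m-1)/2`
#' within a community of size `m`, `m_a*m_b` between two communities.
#'
#' @param net a `thresholded_network`.
#' @param labels integer/character community label per region.
#' @return symmetric community x community density matrix in `[0, 1]`;
#'   within-community entries for singleton communities are `NA`.
#' @export
community_density <- function(net, labels) {
  stopifnot(inherits(net, "thresholded_network"))
  n <- nrow(net$mask)
  if (length(labels) != n) stop("every region needs a community label")
  if (anyNA(labels)) stop("every region needs a community label")
  comms <- sort(unique(labels))
  k <- length(comms)
  D <- matrix(NA_real_, k, k, dimnames = list(comms, comms))
  for (a in seq_len(k)) {
    ia <- which(labels == comms[a])
    for (b in a:k) {
      if (a == b) {
        m <- length(ia)
        if (m < 2) next                       # singleton: undefined
        possible <- m * (m - 1) / 2
        retained <- sum(net$mask[ia, ia]) / 2
      } else {
        ib <- which(labels == comms[b])
        possible <- length(ia) * length(ib)
        retained <- sum(net$mask[ia, ib])
      }
      D[a, b] <- D[b, a] <- retained / possible
    }
  }
  D
}

#' Long-format per-window metric table
#' @param metric_list list of [network_metrics()] results, one per window.
#' @param median_ages per-window median ages.
#' @return data frame (window_index, median_age, metric, value) for the
#'   global metrics.
#' @export
global_metric_table <- function(metric_list, median_ages) {
  do.call(rbind, lapply(seq_along(metric_list), function(i) {
    g <- metric_list[[i]]$global
    data.frame(window_index = i, median_age = median_ages[i],
               metric = names(g), value = unlist(g), row.names = NULL)
  }))
}
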