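#' Sliding-window development analysis of a cortical cohort
#'
#' Runs the core age-resolved analysis: builds overlapping age windows,
#' estimates and bootstrap-thresholds a correlation network per window,
#' computes global and nodal metrics, and fits developmental trajectories to
#' the global metric series (mean correlation, edge density, connection
#' distance) and, optionally, to every region's degree series.
#'
#' @param cohort a `cortical_cohort` (or any list with `thickness`,
#'   `participants$age`, `regions`).
#' @param width,step,mode,n_strata windowing settings (see
#'   [make_windows()]).
#' @param n_boot,alpha bootstrap thresholding settings (see
#'   [build_network()]).
#' @param nodal also fit per-region degree trajectories and their FDR
#'   significance.
#' @param alpha_trajectory FDR level for nodal significance.
#' @param seed master seed; per-window bootstrap seeds are derived from it
#'   as `seed + 1000 * window_index`.
#' @return A `window_analysis`: windows, per-window `networks`, `metrics`,
#'   the `global` data frame (median_age x metric), `trajectories` (list of
#'   `trajectory` fits for mean_correlation, density_pct, mean_distance),
#'   and optionally `nodal_fits` / `nodal_table`.
#' @export
sliding_window_analysis <- function(cohort, width = 60L, step = 30L,
                                    mode = "stratum", n_strata = 5L,
                                    n_boot = 1000L, alpha = 0.01,
                                    nodal = FALSE, alpha_trajectory = 0.05,
                                    seed = 1L) {
  ages <- cohort$participants$age
  windows <- make_windows(ages, width = width, step = step, mode = mode,
                          n_strata = n_strata)
  med <- window_median_ages(windows)
  centroids <- centroid_coords(cohort$regions)

  networks <- lapply(windows, function(w) {
    build_network(cohort$thickness, w$indices, n_boot = n_boot,
                  alpha = alpha, seed = seed + 1000L * w$window_index)
  })
  metrics <- lapply(networks, network_metrics, centroids = centroids)

  glob <- data.frame(
    window_index = seq_along(windows),
    median_age = med,
    mean_correlation = vapply(metrics, function(m)
      m$global$mean_correlation, numeric(1)),
    density_pct = vapply(metrics, function(m) m$global$density_pct,
                         numeric(1)),
    mean_distance = vapply(metrics, function(m) m$global$mean_distance,
                           numeric(1))
  )

  fit_series <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) >= 5) fit_trajectory(med[ok], y[ok]) else NULL
  }
  trajectories <- list(
    mean_correlation = fit_series(glob$mean_correlation),
    density_pct = fit_series(glob$density_pct),
    mean_distance = fit_series(glob$mean_distance)
  )

  nodal_fits <- NULL
  nodal_table <- NULL
  if (nodal) {
    deg <- vapply(metrics, function(m) m$nodal$degree,
                  numeric(nrow(cohort$regions)))
    nodal_fits <- lapply(seq_len(nrow(deg)), function(r) {
      fit_trajectory(med, deg[r, ])
    })
    names(nodal_fits) <- region_col_names(cohort$regions)
    nodal_table <- nodal_significance(nodal_fits, alpha = alpha_trajectory)
  }

  structure(list(windows = windows, networks = networks, metrics = metrics,
                 global = glob, trajectories = trajectories,
                 nodal_fits = nodal_fits, nodal_table = nodal_table,
                 settings = list(width = width, step = step, mode = mode,
                                 n_strata = n_strata, n_boot = n_boot,
                                 alpha = alpha, seed = seed)),
            class = "window_analysis")
}

#' @export
print.window_analysis <- function(x, ...) {
  cat(sprintf("Sliding-window analysis: %d windows, %d regions\n",
              length(x$windows), nrow(x$networks[[1]]$weights)))
  cat(sprintf("  density %.1f%% -> %.1f%% across windows\n",
              x$global$density_pct[1],
              x$global$density_pct[nrow(x$global)]))
  if (!is.null(x$trajectories$density_pct)) {
    p <- trajectory_params(x$trajectories$density_pct)
    cat(sprintf("  density trajectory: %s %s, age at minimum %.2f y\n",
                p$shape, p$direction, p$age_min))
  }
  invisible(x)
}

#' Per-window bootstrap replicate series of global metrics
#'
#' Re-estimates the global metric series on bootstrap resamples of each
#' window (resampling participants with replacement and rebuilding the
#' thresholded network per resample), for use with
#' [bootstrap_age_min_ci()].
#'
#' @param cohort a `cortical_cohort`.
#' @param analysis the `window_analysis` whose windows are replicated.
#' @param n_rep number of bootstrap replicates of the whole series.
#' @param metric which global metric to extract: `"mean_correlation"` or
#'   `"density_pct"`.
#' @param n_boot bootstrap count used inside each replicate's thresholding
#'   (only for `"density_pct"`).
#' @param seed integer seed.
#' @return `n_rep` x n_windows matrix of metric replicates.
#' @export
bootstrap_global_series <- function(cohort, analysis, n_rep = 200L,
                                    metric = c("mean_correlation",
                                               "density_pct"),
                                    n_boot = 200L, seed = 1L) {
  metric <- match.arg(metric)
  windows <- analysis$windows
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  out <- matrix(NA_real_, n_rep, length(windows))
  for (b in seq_len(n_rep)) {
    for (i in seq_along(windows)) {
      idx <- windows[[i]]$indices
      res <- sample(idx, length(idx), replace = TRUE)
      if (metric == "mean_correlation") {
        r <- suppressWarnings(stats::cor(cohort$thickness[res, ,
                                                          drop = FALSE]))
        r[is.na(r)] <- 0
        out[b, i] <- mean(r[upper.tri(r)])
      } else {
        net <- build_network(cohort$thickness, res,
                             n_boot = n_boot,
                             alpha = analysis$settings$alpha,
                             seed = sample.int(2^31 - 1, 1))
        up <- upper.tri(net$mask)
        out[b, i] <- 100 * sum(net$mask[up]) / sum(up)
      }
    }
  }
  out
}

#' Run the full pipeline and write result tables
#'
#' End-to-end orchestration: load (or accept) a dataset, run the
#' sliding-window analysis, partition the age-invariant network into
#' consensus communities, compute within/between-community densities per
#' window, and write every result as delimited text under `out_dir`. All
#' stage seeds are derived from the master seed as
#' `master_seed + 1000 * stage_number`, and the configuration is echoed to
#' `config.yaml` so a rerun with the same inputs reproduces identical
#' outputs.
#'
#' @param cohort a `cortical_cohort` or a path readable by
#'   [read_dataset()].
#' @param out_dir output directory (created if missing).
#' @param width,step,mode,n_strata,n_boot,alpha,seed as in
#'   [sliding_window_analysis()].
#' @param gamma resolution for the consensus partition of the age-invariant
#'   network.
#' @param n_runs Louvain runs per consensus iteration.
#' @param nodal fit per-region degree trajectories.
#' @return invisibly, a list with the `window_analysis`, the age-invariant
#'   `thresholded_network`, its consensus `community_partition`, and the
#'   per-window community density array.
#' @export
run_pipeline <- function(cohort, out_dir, width = 60L, step = 30L,
                         mode = "stratum", n_strata = 5L, n_boot = 1000L,
                         alpha = 0.01, gamma = 1, n_runs = 100L,
                         nodal = FALSE, seed = 1L) {
  if (is.character(cohort)) cohort <- read_dataset(cohort)
  if (width > nrow(cohort$thickness)) {
    stop("windowing failed: window width ", width, " exceeds cohort size ",
         nrow(cohort$thickness))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  settings <- list(width = width, step = step, mode = mode,
                   n_strata = n_strata, n_boot = n_boot, alpha = alpha,
                   gamma = gamma, n_runs = n_runs, seed = seed)
  yaml::write_yaml(settings, file.path(out_dir, "config.yaml"))

  # stage 1: age-invariant network over all participants
  invariant <- build_network(cohort$thickness, n_boot = n_boot,
                             alpha = alpha, seed = seed + 1000L)
  utils::write.table(edge_list(invariant),
                     file.path(out_dir, "invariant_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 2: consensus communities of the age-invariant network
  partition <- consensus_partition(invariant$weights, gamma = gamma,
                                   n_runs = n_runs, seed = seed + 2000L)
  utils::write.table(data.frame(region_id = cohort$regions$region_id,
                                module = partition$labels),
                     file.path(out_dir, "communities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 3: sliding-window analysis and trajectories
  analysis <- sliding_window_analysis(cohort, width = width, step = step,
                                      mode = mode, n_strata = n_strata,
                                      n_boot = n_boot, alpha = alpha,
                                      nodal = nodal, seed = seed + 3000L)
  utils::write.table(analysis$global,
                     file.path(out_dir, "global_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(window_table(analysis$windows,
                                  cohort$participants$age,
                                  cohort$participants$id),
                     file.path(out_dir, "windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(analysis$nodal_table)) {
    utils::write.table(analysis$nodal_table,
                       file.path(out_dir, "nodal_trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stage 4: community density per window
  comm_density <- lapply(analysis$networks, community_density,
                         labels = partition$labels)
  dens_tab <- do.call(rbind, lapply(seq_along(comm_density), function(i) {
    D <- comm_density[[i]]
    idx <- which(upper.tri(D, diag = TRUE), arr.ind = TRUE)
    data.frame(window_index = i,
               median_age = analysis$global$median_age[i],
               community_a = idx[, 1], community_b = idx[, 2],
               density = D[idx])
  }))
  utils::write.table(dens_tab, file.path(out_dir, "community_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  trajectory_summaries <- do.call(rbind, lapply(
    names(analysis$trajectories), function(nm) {
      f <- analysis$trajectories[[nm]]
      if (is.null(f)) return(NULL)
      p <- trajectory_params(f)
      data.frame(metric = nm, chosen = f$chosen,
                 delta_max = p$delta_max, age_min = p$age_min,
                 direction = p$direction, boundary = p$boundary)
    }))
  utils::write.table(trajectory_summaries,
                     file.path(out_dir, "global_trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(analysis = analysis, invariant = invariant,
                 partition = partition, community_density = comm_density,
                 settings = settings))
}
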