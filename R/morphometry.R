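#' Regional rates of change from cross-sectional data
#'
#' Per-region slope of an ordinary least-squares fit of the morphometric
#' value (cortical thickness in mm, or MT in percentage units) on age.
#'
#' @param values participants x regions matrix.
#' @param ages per-participant ages in decimal years.
#' @return numeric vector of slopes, one per region, in value units per year.
#' @export
regional_rates <- function(values, ages) {
  if (nrow(values) != length(ages)) stop("ages must match rows of values")
  if (nrow(values) < 3) stop("need at least 3 participants")
  if (stats::var(ages) == 0) stop("ages are constant; rates undefined")
  a <- ages - mean(ages)
  drop(crossprod(a, sweep(values, 2, colMeans(values)))) / sum(a^2)
}

#' Depth profile of the association between myelination rate and a
#' network-change map
#'
#' For each cortical depth, Spearman-correlates the per-region MT rate of
#' change with a per-region network change parameter (e.g. the maximum
#' change in degree), optionally attaching a spin-permutation p-value that
#' respects the spatial autocorrelation of both maps.
#'
#' @param mt_rates regions x depths matrix of MT slopes (columns named by
#'   depth label).
#' @param change_map per-region network change parameter.
#' @param regions optional `region_set`; when supplied, a spin test is run
#'   per depth.
#' @param n_perm,seed spin-test settings (see [spin_pvalue()]).
#' @return data frame (depth, rho, p_spearman, p_perm); `p_perm` is `NA`
#'   when no regions are supplied.
#' @export
depth_profile_association <- function(mt_rates, change_map, regions = NULL,
                                      n_perm = 1000L, seed = 1L) {
  if (nrow(mt_rates) != length(change_map)) {
    stop("mt_rates and change_map must cover the same regions")
  }
  depths <- colnames(mt_rates) %||% as.character(seq_len(ncol(mt_rates)))
  out <- do.call(rbind, lapply(seq_len(ncol(mt_rates)), function(j) {
    mj <- mt_rates[, j]
    if (all(is.na(mj))) {
      warning("missing MT map at depth ", depths[j], "; skipped")
      return(data.frame(depth = depths[j], rho = NA_real_,
                        p_spearman = NA_real_, p_perm = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(mj, change_map,
                                           method = "spearman"))
    p_perm <- NA_real_
    if (!is.null(regions)) {
      sr <- spin_pvalue(change_map, mj, regions, n_perm = n_perm,
                        seed = seed + j)
      p_perm <- sr$p_perm
    }
    data.frame(depth = depths[j], rho = unname(ct$estimate),
               p_spearman = ct$p.value, p_perm = p_perm,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
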