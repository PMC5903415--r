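#' Build overlapping age-defined participant windows
#'
#' Participants are sorted by age (ties broken by stable input order) and
#' grouped into overlapping windows in one of two modes. In `"index"` mode,
#' windows of `width` participants start at positions 1, 1+step, 1+2*step, ...;
#' with `anchor_final = TRUE` a final window covering the oldest `width`
#' participants is appended when the regular grid does not reach them. In
#' `"stratum"` mode the age-sorted cohort is split into `n_strata` contiguous
#' strata and the windows are the strata themselves plus, for each adjacent
#' pair, the older half of the first joined with the younger half of the
#' second — yielding `2 * n_strata - 1` half-overlapping windows that
#' interpolate the recruitment strata.
#'
#' @param ages numeric vector of ages in decimal years.
#' @param width window width in number of participants (index mode).
#' @param step step size in number of participants (index mode).
#' @param mode `"stratum"` (default) or `"index"`.
#' @param n_strata number of strata (stratum mode).
#' @param anchor_final append a final flush window in index mode.
#' @return An `age_windows` object: list of windows, each with `indices`
#'   (positions into the original `ages`, sorted by age), `median_age`, and
#'   `window_index`.
#' @examples
#' w <- make_windows(runif(300, 14, 24), width = 60, step = 30, mode = "index")
#' length(w)
#' @export
make_windows <- function(ages, width = 60L, step = 30L,
                         mode = c("stratum", "index"), n_strata = 5L,
                         anchor_final = FALSE) {
  mode <- match.arg(mode)
  n <- length(ages)
  ord <- order(ages)                     # stable: ties keep input order

  if (mode == "index") {
    if (width > n) stop("window width ", width, " exceeds cohort size ", n)
    if (step < 1L || step > width) stop("need 1 <= step <= width")
    starts <- seq(1L, n - width + 1L, by = step)
    if (anchor_final && starts[length(starts)] + width - 1L < n) {
      starts <- c(starts, n - width + 1L)
    }
    members <- lapply(starts, function(s) ord[s:(s + width - 1L)])
  } else {
    if (n < n_strata) stop("fewer participants than strata")
    sizes <- stratum_sizes(n, n_strata)
    if (max(sizes) - min(sizes) > 2L) {
      warning("stratum sizes differ by more than 2 (",
              paste(sizes, collapse = ","), ")")
    }
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    strata <- lapply(seq_len(n_strata), function(s) ord[starts[s]:ends[s]])
    members <- vector("list", 2L * n_strata - 1L)
    members[seq(1L, by = 2L, length.out = n_strata)] <- strata
    for (s in seq_len(n_strata - 1L)) {
      a <- strata[[s]]; b <- strata[[s + 1L]]
      # odd strata put the extra participant in the younger half
      older_a <- a[(ceiling(length(a) / 2) + 1L):length(a)]
      younger_b <- b[seq_len(ceiling(length(b) / 2))]
      members[[2L * s]] <- c(older_a, younger_b)
    }
  }

  windows <- lapply(seq_along(members), function(i) {
    idx <- members[[i]]
    structure(list(indices = idx,
                   median_age = stats::median(ages[idx]),
                   window_index = i),
              class = "window_spec")
  })
  med <- vapply(windows, `[[`, numeric(1), "median_age")
  if (is.unsorted(med)) {               # defensive; both modes build in order
    windows <- windows[order(med)]
    for (i in seq_along(windows)) windows[[i]]$window_index <- i
  }
  structure(windows, class = "age_windows")
}

stratum_sizes <- function(n, n_strata) {
  sizes <- rep(n %/% n_strata, n_strata)
  extra <- n %% n_strata
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Median ages of a window list
#' @param windows an `age_windows` object.
#' @return numeric vector of per-window median ages.
#' @export
window_median_ages <- function(windows) {
  stopifnot(length(windows) > 0)
  vapply(windows, `[[`, numeric(1), "median_age")
}

#' @export
print.age_windows <- function(x, ...) {
  sizes <- vapply(x, function(w) length(w$indices), integer(1))
  cat(sprintf("%d age windows, sizes %s, median ages %.2f-%.2f\n",
              length(x), paste(range(sizes), collapse = "-"),
              min(window_median_ages(x)), max(window_median_ages(x))))
  invisible(x)
}

#' Export window membership as a long table
#' @param windows an `age_windows` object.
#' @param ages the age vector used to build the windows.
#' @param ids optional participant identifiers.
#' @return data frame (window_index, participant, age).
#' @export
window_table <- function(windows, ages, ids = seq_along(ages)) {
  do.call(rbind, lapply(windows, function(w) {
    data.frame(window_index = w$window_index, participant = ids[w$indices],
               age = ages[w$indices], stringsAsFactors = FALSE)
  }))
}
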