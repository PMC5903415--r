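# independent brute-force reference implementations used as oracles;
# deliberately naive, never shared with package internals

bf_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

bf_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  hj <- function(labs, u) {
    p <- sapply(u, function(l) sum(labs == l)) / n
    -sum(p * log(p))
  }
  ha <- hj(a, ua); hb <- hj(b, ub)
  if (ha == 0 && hb == 0) return(1)
  mi <- 0
  for (la in ua) for (lb in ub) {
    pab <- sum(a == la & b == lb) / n
    if (pab > 0) {
      mi <- mi + pab * log(pab / (sum(a == la) / n * sum(b == lb) / n))
    }
  }
  2 * mi / (ha + hb)
}

# block-correlated Gaussian data without going through the cohort generator
make_block_data <- function(n, n_regions, n_blocks, r_within, r_between = 0,
                            seed = 1) {
  set.seed(seed)
  blocks <- rep(seq_len(n_blocks), length.out = n_regions)
  blocks <- sort(blocks)
  g <- rnorm(n)
  x <- matrix(NA_real_, n, n_regions)
  for (k in seq_len(n_blocks)) {
    fk <- rnorm(n)
    for (j in which(blocks == k)) {
      x[, j] <- sqrt(r_between) * g +
        sqrt(max(r_within - r_between, 0)) * fk +
        sqrt(1 - max(r_within, r_between)) * rnorm(n)
    }
  }
  list(x = x, blocks = blocks)
}

tiny_regions <- function(n = 20, m = 2, seed = 1) {
  generate_regions(n, m, seed = seed)
}

# smooth spatial map over the sphere: isotropic random field (sum of random
# plane waves), so its ensemble is invariant under rotations, evaluated on
# the left hemisphere and mirrored to the right (the spin test's mirrored
# rotation presumes approximately bilaterally symmetric maps); mild white
# noise on top, also symmetric
smooth_map <- function(regions, seed, waves = 8, freq = 3, nugget = 0.2) {
  set.seed(seed)
  left <- regions$hemisphere == "left"
  co <- as.matrix(regions[left, c("sx", "sy", "sz")])
  f <- numeric(nrow(co))
  for (k in seq_len(waves)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    phase <- co %*% u * freq
    f <- f + rnorm(1) * cos(phase) + rnorm(1) * sin(phase)
  }
  half <- drop(f) / sqrt(waves) + nugget * rnorm(nrow(co))
  out <- numeric(nrow(regions))
  out[left] <- half
  out[!left] <- half                     # mirror pairs share row order
  out
}
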