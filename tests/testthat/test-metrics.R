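# build a thresholded_network by hand from a mask and weights
fake_net <- function(mask, weights = NULL) {
  n <- nrow(mask)
  if (is.null(weights)) weights <- mask * 0.5
  structure(list(weights = weights * mask, mask = mask, observed = weights,
                 p_adj = 1 - mask, alpha = 0.5,
                 n_retained_pos = sum(mask[upper.tri(mask)] & TRUE),
                 n_retained_neg = 0L, n_participants = NA, subset = NULL),
            class = "thresholded_network")
}

full_mask <- function(n) {
  m <- matrix(TRUE, n, n); diag(m) <- FALSE; m
}

test_that("complete and partial retained graphs give exact metrics", {
  net <- fake_net(full_mask(4))
  m <- network_metrics(net)
  expect_equal(m$global$density_pct, 100)
  expect_equal(m$nodal$degree, rep(3, 4))

  mask <- matrix(FALSE, 4, 4)
  for (e in list(c(1, 2), c(3, 4), c(1, 3))) {
    mask[e[1], e[2]] <- mask[e[2], e[1]] <- TRUE
  }
  m2 <- network_metrics(fake_net(mask))
  expect_equal(m2$global$density_pct, 50)
  expect_equal(m2$nodal$degree, c(2, 1, 2, 1))
})

test_that("connection distance is Euclidean between centroids", {
  mask <- matrix(FALSE, 2, 2)
  mask[1, 2] <- mask[2, 1] <- TRUE
  cent <- rbind(c(0, 0, 0), c(3, 4, 0))
  m <- network_metrics(fake_net(mask), centroids = cent)
  expect_equal(m$global$mean_distance, 5)
  expect_equal(m$nodal$distance, c(5, 5))
  # isolated nodes: undefined distance
  m0 <- network_metrics(fake_net(matrix(FALSE, 3, 3)),
                        centroids = diag(3))
  expect_true(all(is.na(m0$nodal$distance)))
  expect_true(is.na(m0$global$mean_distance))
})

test_that("nodal strength uses the unthresholded row without the diagonal", {
  w <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3, 3)
  net <- fake_net(matrix(FALSE, 3, 3), weights = w)
  m <- network_metrics(net)
  expect_equal(m$nodal$strength, c(.35, .45, .3))
  expect_equal(m$global$mean_correlation, mean(c(.5, .2, .4)))
})

test_that("community densities match exhaustive enumeration", {
  labels <- c(1, 1, 1, 2, 2)
  mask <- matrix(FALSE, 5, 5)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5))) {
    mask[e[1], e[2]] <- mask[e[2], e[1]] <- TRUE
  }
  D <- community_density(fake_net(mask), labels)
  expect_equal(D, matrix(c(1, 0, 0, 1), 2, 2,
                         dimnames = list(1:2, 1:2)))
  # empty network
  D0 <- community_density(fake_net(matrix(FALSE, 5, 5)), labels)
  expect_true(all(D0 == 0))
  # random network against pairwise enumeration oracle
  set.seed(1)
  mask <- matrix(FALSE, 10, 10)
  for (i in 1:9) for (j in (i + 1):10) {
    mask[i, j] <- mask[j, i] <- runif(1) < 0.4
  }
  labs <- sample(1:3, 10, replace = TRUE)
  labs[1:3] <- 1:3                   # ensure all communities present
  D <- community_density(fake_net(mask), labs)
  for (a in 1:3) for (b in a:3) {
    ret <- 0; poss <- 0
    for (i in 1:9) for (j in (i + 1):10) {
      in_set <- (labs[i] == a & labs[j] == b) | (labs[i] == b & labs[j] == a)
      if (in_set) { poss <- poss + 1; ret <- ret + mask[i, j] }
    }
    expect_equal(D[a, b], ret / poss)
  }
})

test_that("density and degree obey conservation identities", {
  set.seed(2)
  mask <- matrix(FALSE, 12, 12)
  for (i in 1:11) for (j in (i + 1):12) {
    mask[i, j] <- mask[j, i] <- runif(1) < 0.3
  }
  labs <- rep(1:3, each = 4)
  net <- fake_net(mask)
  m <- network_metrics(net)
  D <- community_density(net, labs)
  sizes <- table(labs)
  total <- 0
  for (a in 1:3) for (b in a:3) {
    poss <- if (a == b) sizes[a] * (sizes[a] - 1) / 2 else
      sizes[a] * sizes[b]
    total <- total + D[a, b] * poss
  }
  expect_equal(as.numeric(total), m$global$n_edges)
  expect_equal(sum(m$nodal$degree), 2 * m$global$n_edges)
  expect_equal(m$global$density_pct,
               as.numeric(100 * total / (12 * 11 / 2)))
})

test_that("singleton communities have undefined within-density", {
  mask <- full_mask(3)
  D <- community_density(fake_net(mask), c(1, 1, 2))
  expect_true(is.na(D["2", "2"]))
  expect_equal(D["1", "2"], 1)
  expect_error(community_density(fake_net(mask), c(1, NA, 2)), "label")
})
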