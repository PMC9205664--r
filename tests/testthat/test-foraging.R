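test_that("toroidal distance wraps around both axes", {
  expect_equal(toroidal_distance(c(3, 3), c(3, 3), c(10, 10)), 0)
  # wraparound adjacency on a 201-cell axis at 10 m cells
  expect_equal(toroidal_distance(c(1, 1), c(201, 1), c(201, 201)), 10)
  expect_equal(toroidal_distance(c(1, 1), c(1, 201), c(201, 201)), 10)
  # random pairs against the nine-shifted-copies oracle
  set.seed(42)
  for (i in 1:25) {
    nr <- sample(3:15, 1); nc <- sample(3:15, 1)
    a <- c(sample(nr, 1), sample(nc, 1)); b <- c(sample(nr, 1), sample(nc, 1))
    expect_equal(toroidal_distance(a, b, c(nr, nc)),
                 brute_torus_dist(a[1], a[2], b[1], b[2], nr, nc),
                 tolerance = 1e-12)
  }
})

test_that("visitation splits equally between two symmetric floral cells", {
  F <- matrix(0, 7, 7)
  F[4, 2] <- 0.5; F[4, 6] <- 0.5  # equidistant from the center
  nests <- cbind(row = 4, col = 4)
  vf <- visitation_rates(1, F, nests)
  vr <- matrix(vf$VR[1, ], 7, 7)
  expect_equal(vr[4, 2], 0.5, tolerance = 1e-12)
  expect_equal(vr[4, 6], 0.5, tolerance = 1e-12)
  expect_equal(sum(vr), 1, tolerance = 1e-12)
})

test_that("visitation conserves foragers and matches the brute-force oracle", {
  set.seed(7)
  for (rep in 1:4) {
    F <- matrix(runif(25), 5, 5) * rbinom(25, 1, 0.6)
    nests <- cbind(row = sample(5, 2), col = sample(5, 2))
    X <- c(3, 1.5)
    vf <- visitation_rates(X, F, nests, cell_size_m = 10,
                           params = foraging_params(gamma = 30))
    oracle <- brute_visitation(X, F, nests, cell_size_m = 10, gamma = 30)
    expect_equal(vf$VR, oracle, tolerance = 1e-12)
    if (any(F > 0)) expect_equal(rowSums(vf$VR), X, tolerance = 1e-12)
  }
  # no reachable resources: visitation is zero, not NaN
  vf0 <- visitation_rates(2, matrix(0, 5, 5), cbind(row = 2, col = 2))
  expect_true(all(vf0$VR == 0))
})

test_that("visitation to a cell increases with its own floral value", {
  F <- matrix(runif(49, 0.2, 0.8), 7, 7)
  nests <- cbind(row = 2, col = 2)
  vf1 <- visitation_rates(1, F, nests)
  F2 <- F; F2[5, 5] <- F[5, 5] * 2
  vf2 <- visitation_rates(1, F2, nests)
  j <- (5 - 1) * 7 + 5
  expect_gt(vf2$VR[1, j], vf1$VR[1, j])
})

test_that("independent-mode collection matches the direct equations", {
  # single nest, single floral cell: all X visits land there, each worth F
  F <- matrix(0, 6, 6); F[3, 5] <- 0.7
  vf <- visitation_rates(4, F, cbind(row = 2, col = 2))
  res <- collect_resources(vf, F, mode = "independent")
  expect_equal(res$r, 0.7 * 4, tolerance = 1e-12)
  expect_equal(res$R, res$r)
  # zero floral landscape collects nothing
  vf0 <- visitation_rates(4, matrix(0, 6, 6), cbind(row = 2, col = 2))
  expect_equal(collect_resources(vf0, matrix(0, 6, 6))$R, 0)
  expect_error(collect_resources(structure(list(VR = matrix(0, 0, 36)),
                                           class = "visitation_field"),
                                 matrix(0, 6, 6), mode = "independent"),
               "no nests")
})

test_that("shared-cell competition halves the take of two symmetric nests", {
  # two nests symmetric about the single floral cell, enough foragers that
  # the cell's stock is fully harvested and split equally
  F <- matrix(0, 9, 9); F[5, 5] <- 1
  nests <- cbind(row = c(5, 5), col = c(3, 7))
  vf <- visitation_rates(c(10, 10), F, nests)
  shared <- collect_resources(vf, F, mode = "shared_cell")
  expect_equal(shared$r[1], shared$r[2], tolerance = 1e-12)
  # total extraction capped at the cell's floral value
  expect_equal(sum(shared$r), 1, tolerance = 1e-12)
  solo <- collect_resources(visitation_rates(10, F, nests[1, , drop = FALSE]),
                            F, mode = "shared_cell")
  expect_equal(shared$r[1], solo$r / 2, tolerance = 1e-12)
})

test_that("pollination potential saturates and respects its bounds", {
  F <- matrix(runif(36, 0, 1), 6, 6)
  crop <- matrix(TRUE, 6, 6)
  # zero visitation -> zero potential
  expect_equal(pollination_potential(rep(0, 36), F, crop), 0)
  # large kappa -> potential approaches the total crop floral value
  V <- rep(0.5, 36)
  expect_equal(pollination_potential(V, F, crop, pollination_params(kappa = 1e8)),
               sum(F), tolerance = 1e-6)
  # bound holds for any kappa
  for (k in c(0.1, 1, 10)) {
    p <- pollination_potential(V, F, crop, pollination_params(kappa = k))
    expect_lte(p, sum(F))
    expect_gte(p, 0)
  }
  # hand evaluation on a 2-cell toy: F = (0.4, 0.8), V = (0.2, 0.1), kappa 1
  Ft <- matrix(c(0.4, 0.8), 1, 2)
  pt <- pollination_potential(c(0.2, 0.1), Ft, matrix(TRUE, 1, 2))
  expect_equal(pt, 0.4 * (1 - exp(-0.2 / 0.4)) + 0.8 * (1 - exp(-0.1 / 0.8)),
               tolerance = 1e-12)
  expect_equal(season_score(c(1.5, 2, 0.5)), 4)
})

test_that("the convolution engine agrees with the dense implementation", {
  set.seed(11)
  cls <- matrix(sample(0:3, 12 * 12, replace = TRUE), 12, 12)
  nests <- cbind(row = c(2, 7, 11), col = c(3, 9, 5))
  grid <- manual_landscape(cls, nests = nests)
  series <- build_floral_series(grid, weeks = 25:29)
  fpar <- foraging_params(gamma = 40)
  ppar <- pollination_params(kappa = 1)
  for (den in c("nest", "target")) {
    fpar$denominator <- den
    ctx <- beescape:::.season_context(grid, series, fpar, ppar)
    for (ti in seq_along(series$weeks)) {
      F <- series$F[, , ti]
      if (all(F == 0)) next
      X <- 2.5
      fast <- beescape:::.week_forage(ctx, ti, X)
      vf <- visitation_rates(X, F, nests, params = fpar)
      dense <- collect_resources(vf, F, mode = "shared_cell")
      expect_equal(fast$r, dense$r, tolerance = 1e-9)
      expect_equal(fast$R, dense$R, tolerance = 1e-9)
      crop <- matrix(cls %in% 2:3, 12, 12)
      expect_equal(fast$P, pollination_potential(vf, F, crop, ppar),
                   tolerance = 1e-9)
    }
  }
})

test_that("collected resources are invariant under torus translation", {
  set.seed(13)
  cls <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  nests <- cbind(row = c(2, 6), col = c(4, 9))
  shift <- function(m, dr, dc) {
    m[((seq_len(10) - 1 - dr) %% 10) + 1, ((seq_len(10) - 1 - dc) %% 10) + 1]
  }
  grid <- manual_landscape(cls, nests = nests)
  series <- build_floral_series(grid, weeks = 28)
  F <- series$F[, , 1]
  vf <- visitation_rates(2, F, nests)
  r0 <- collect_resources(vf, F)$r
  dr <- 3; dc <- 7
  nests2 <- cbind(row = ((nests[, 1] - 1 + dr) %% 10) + 1,
                  col = ((nests[, 2] - 1 + dc) %% 10) + 1)
  F2 <- shift(F, dr, dc)
  vf2 <- visitation_rates(2, F2, nests2)
  expect_equal(collect_resources(vf2, F2)$r, r0, tolerance = 1e-12)
})

test_that("kernel cutoff zeroes weights beyond max_radius", {
  K <- dispersal_kernel(21, 21, cell_size_m = 10, gamma = 100, max_radius = 50)
  dr <- pmin(0:20, 21 - (0:20))
  d <- 10 * sqrt(outer(dr^2, dr^2, `+`))
  expect_true(all(K[d > 50] == 0))
  expect_true(all(K[d <= 50] == exp(-d[d <= 50] / 100)))
})
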