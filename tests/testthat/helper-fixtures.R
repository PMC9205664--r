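# Small landscapes and hand-built fixtures shared across the suite.

# A fast small landscape: 40 x 40 cells (400 x 400 m), same class structure
# as the default, for structural tests that do not depend on the study's
# full 2010 m extent.
small_landscape <- function(seed = 1, snh = 0.10, nest_density = 2000,
                            side = 400) {
  cfg <- landscape_config(side_length_m = side, cell_size_m = 10,
                          snh_proportion = snh,
                          snh_patch_area_m2 = 2000,
                          crop_patch_area_m2 = 500,
                          nest_density = nest_density, seed = seed)
  place_nests(generate_landscape(cfg))
}

# A bee_landscape built directly from a class matrix (bypasses generation),
# for exact hand-set fixtures.
manual_landscape <- function(classes, cell_size_m = 10, nests = NULL) {
  grid <- structure(list(classes = classes, cell_size_m = cell_size_m,
                         config = NULL,
                         realized = list(snh = mean(classes == 1)),
                         nests = NULL),
                    class = "bee_landscape")
  if (!is.null(nests)) {
    nr <- nrow(classes)
    cells <- (nests[, 2] - 1L) * nr + nests[, 1]
    grid$nests <- data.frame(cell = cells, row = nests[, 1], col = nests[, 2],
                             x_m = (nests[, 2] - 0.5) * cell_size_m,
                             y_m = (nests[, 1] - 0.5) * cell_size_m)
  }
  grid
}

# Brute-force visitation oracle: direct triple-loop evaluation of the
# foraging equation on a tiny grid, independent of the package's vectorized
# and convolution implementations.
brute_visitation <- function(X, F, nests, cell_size_m = 10, gamma = 250) {
  nr <- nrow(F); nc <- ncol(F)
  n <- nrow(nests)
  X <- rep_len(X, n)
  VR <- matrix(0, n, nr * nc)
  for (k in seq_len(n)) {
    denom <- 0
    for (ur in 1:nr) for (uc in 1:nc) {
      d <- brute_torus_dist(nests[k, 1], nests[k, 2], ur, uc, nr, nc, cell_size_m)
      denom <- denom + F[ur, uc] * exp(-d / gamma)
    }
    if (denom == 0) next
    for (jr in 1:nr) for (jc in 1:nc) {
      d <- brute_torus_dist(nests[k, 1], nests[k, 2], jr, jc, nr, nc, cell_size_m)
      VR[k, (jc - 1) * nr + jr] <- X[k] * F[jr, jc] * exp(-d / gamma) / denom
    }
  }
  VR
}

# Toroidal distance by explicit minimization over the nine shifted copies
# of the grid (independent of the package's coordinate-wise formula).
brute_torus_dist <- function(r1, c1, r2, c2, nr, nc, cell_size_m = 10) {
  best <- Inf
  for (sr in c(-1, 0, 1)) for (sc in c(-1, 0, 1)) {
    d <- sqrt((r1 - (r2 + sr * nr))^2 + (c1 - (c2 + sc * nc))^2)
    best <- min(best, d)
  }
  best * cell_size_m
}
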