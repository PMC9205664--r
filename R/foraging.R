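#' Foraging parameters
#'
#' Central-place foraging kernel settings. Foragers leave their nest and
#' visit cells with a probability proportional to the cell's floral value
#' weighted by an exponential decay of toroidal distance, normalized over
#' all cells reachable from the nest.
#'
#' @param gamma Mean foraging dispersal distance in meters.
#' @param max_radius Kernel cutoff in meters; cells beyond it are
#'   unreachable and the kernel is renormalized over the rest. Default
#'   `Inf` (the whole torus is reachable; at a 2 km landscape this is the
#'   practical case for bumblebee-scale `gamma`).
#' @param competition `"shared_cell"` (default): a cell's floral resource is
#'   a finite weekly stock split among all visiting nests in proportion to
#'   their visitation, capping the total extraction from cell j at F_j once
#'   the summed visitation exceeds one visit per week. This produces the
#'   density dependence where more nests in a landscape collect fewer
#'   resources per colony. `"independent"`: every nest collects F_j per
#'   visit regardless of other nests (the literal reading of the collection
#'   equations, with no between-nest competition).
#' @param denominator `"nest"` (default): the kernel normalization for
#'   foragers from nest i weighs each reachable cell u by its distance to
#'   the nest, d(i, u), as in central-place foraging. `"target"`: the
#'   variant normalizing by d(u, j), the distance to the visited cell.
#' @return An object of class `foraging_params`.
#' @export
foraging_params <- function(gamma = 250, max_radius = Inf,
                            competition = c("shared_cell", "independent"),
                            denominator = c("nest", "target")) {
  if (gamma <= 0) stop("gamma must be positive")
  if (max_radius <= 0) stop("max_radius must be positive")
  structure(list(gamma = gamma, max_radius = max_radius,
                 competition = match.arg(competition),
                 denominator = match.arg(denominator)),
            class = "foraging_params")
}

#' Pollination potential parameters
#'
#' @param kappa Dimensionless saturation rate: how quickly the visitation
#'   rate per unit of crop floral resource approaches the maximum
#'   pollination potential of a cell.
#' @param crop_codes Habitat codes counted as crop for pollination.
#' @return An object of class `pollination_params`.
#' @export
pollination_params <- function(kappa = 1,
                               crop_codes = c(.HABITATS[["early_mfc"]],
                                              .HABITATS[["late_mfc"]])) {
  if (kappa <= 0) stop("kappa must be positive")
  structure(list(kappa = kappa, crop_codes = crop_codes),
            class = "pollination_params")
}

#' Toroidal distance between cells
#'
#' Euclidean distance between cell centers on a torus: along each axis the
#' shorter of the direct and the wrapped-around offset is used.
#'
#' @param a,b Cell coordinates as `(row, col)` vectors or two-column
#'   matrices (1-based indices); rows are paired (recycled if needed).
#' @param dims `c(nrows, ncols)` of the grid.
#' @param cell_size_m Cell size in meters.
#' @return Distance(s) in meters.
#' @export
toroidal_distance <- function(a, b, dims, cell_size_m = 10) {
  a <- matrix(a, ncol = 2); b <- matrix(b, ncol = 2)
  dr <- abs(a[, 1] - b[, 1]); dr <- pmin(dr, dims[1] - dr)
  dc <- abs(a[, 2] - b[, 2]); dc <- pmin(dc, dims[2] - dc)
  cell_size_m * sqrt(dr^2 + dc^2)
}

#' Exponential dispersal kernel on the torus
#'
#' Matrix of kernel weights `exp(-d / gamma)` for every offset from a focal
#' cell, with toroidal wraparound; entry `[1, 1]` is the zero offset. Used
#' both directly and as the convolution kernel of the fast foraging engine.
#'
#' @param nr,nc Grid dimensions.
#' @param cell_size_m Cell size in meters.
#' @param gamma Mean dispersal distance in meters.
#' @param max_radius Cutoff distance in meters (weights beyond it are 0).
#' @return An `nr x nc` matrix of weights.
#' @export
dispersal_kernel <- function(nr, nc, cell_size_m = 10, gamma = 250,
                             max_radius = Inf) {
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  d <- cell_size_m * sqrt(outer(dr^2, dc^2, `+`))
  K <- exp(-d / gamma)
  K[d > max_radius] <- 0
  K
}

# Kernel weights from one nest at (r0, c0) to every cell, as a matrix.
.nest_kernel <- function(r0, c0, nr, nc, cell_size_m, gamma, max_radius) {
  dr <- abs(seq_len(nr) - r0); dr <- pmin(dr, nr - dr)
  dc <- abs(seq_len(nc) - c0); dc <- pmin(dc, nc - dc)
  d <- cell_size_m * sqrt(outer(dr^2, dc^2, `+`))
  K <- exp(-d / gamma)
  K[d > max_radius] <- 0
  K
}

# Circular convolution with a precomputed fft of the (symmetric) kernel;
# clamps the tiny negative rounding noise of the inverse transform.
.circ_conv <- function(A, fftK) {
  pmax(Re(fft(fft(A) * fftK, inverse = TRUE)) / length(A), 0)
}

#' Visitation rates from nests to cells
#'
#' For foragers X_i leaving the nest in cell i, the rate at which cell j is
#' visited in a week is
#' `VR_ij = X_i * F_j exp(-d_ij / gamma) / sum_u F_u exp(-d_iu / gamma)`,
#' the exponential-kernel attractiveness of cell j relative to all cells u
#' reachable from the nest. If no reachable cell has floral resources the
#' nest's visitation is zero. With `denominator = "target"` the
#' normalization uses d(u, j) instead.
#'
#' This dense implementation materializes the full nests-by-cells matrix
#' and is intended for small grids and for verification; [run_season()]
#' uses an equivalent convolution-based engine.
#'
#' @param X Foragers per nest (scalar or vector of length `nrow(nests)`).
#' @param F Floral value matrix (one week's map).
#' @param nests Two-column matrix or data frame of nest `(row, col)`
#'   indices.
#' @param cell_size_m Cell size in meters.
#' @param params A [foraging_params()].
#' @return An object of class `visitation_field`: list with `VR` (nests x
#'   cells matrix, cells in column-major order), `inbound` (per-cell total
#'   visitation), `nests`, `X` and `params`.
#' @export
visitation_rates <- function(X, F, nests, cell_size_m = 10,
                             params = foraging_params()) {
  nests <- as.matrix(nests[, c("row", "col"), drop = FALSE])
  storage.mode(nests) <- "integer"
  n <- nrow(nests)
  X <- rep_len(X, n)
  if (any(X < 0) || any(F < 0)) stop("X and F must be non-negative")
  nr <- nrow(F); nc <- ncol(F)
  Fv <- as.vector(F)
  VR <- matrix(0, nrow = n, ncol = nr * nc)
  if (params$denominator == "target") {
    fftK <- fft(dispersal_kernel(nr, nc, cell_size_m, params$gamma,
                                 params$max_radius))
    denom_j <- as.vector(.circ_conv(F, fftK))
  }
  for (k in seq_len(n)) {
    Kk <- as.vector(.nest_kernel(nests[k, 1], nests[k, 2], nr, nc,
                                 cell_size_m, params$gamma, params$max_radius))
    attract <- Fv * Kk
    if (params$denominator == "nest") {
      s <- sum(attract)
      if (s > 0) VR[k, ] <- X[k] * attract / s
    } else {
      ok <- denom_j > 0
      VR[k, ok] <- X[k] * attract[ok] / denom_j[ok]
    }
  }
  structure(list(VR = VR, inbound = colSums(VR), nests = nests, X = X,
                 dims = c(nr, nc), params = params),
            class = "visitation_field")
}

#' Resources collected per nest
#'
#' In `"independent"` mode the nest in cell i collects
#' `r_i = sum_j F_j VR_ij` (each visit returns the full floral value of the
#' visited cell). In `"shared_cell"` mode a cell's floral resource is a
#' finite weekly stock: with total inbound visitation V_j, each visit
#' returns `F_j * min(1, 1 / V_j)`, so the total extraction from cell j is
#' `F_j * min(V_j, 1)` and is split among nests in proportion to their
#' visitation. The landscape average per nest is `R = mean(r_i)`.
#'
#' @param field A `visitation_field`.
#' @param F Floral value matrix matching the field.
#' @param mode Overrides the competition mode in the field's params.
#' @return An object of class `foraging_result`: list with `r` (per-nest
#'   resources), `R` (landscape mean per nest) and `N` (nest count).
#' @export
collect_resources <- function(field, F, mode = NULL) {
  mode <- mode %||% field$params$competition
  N <- nrow(field$VR)
  if (N == 0) stop("no nests in the landscape: R is undefined")
  Fv <- as.vector(F)
  w <- if (mode == "shared_cell") {
    V <- field$inbound
    Fv * ifelse(V > 1, 1 / V, 1)
  } else Fv
  r <- as.vector(field$VR %*% w)
  structure(list(r = r, R = mean(r), N = N, mode = mode),
            class = "foraging_result")
}

#' Pollination potential of the crop cells for one week
#'
#' `P_t = sum_i F_i (1 - exp(-kappa V_i / F_i))` over crop cells i with
#' floral resources, where V_i is the total inbound visitation of cell i.
#' The saturating form means pollination per cell is bounded by the cell's
#' floral value; kappa controls how quickly visits saturate a flower stock.
#'
#' @param field A `visitation_field`, or a per-cell inbound visitation
#'   vector.
#' @param F Floral value matrix for the week.
#' @param crop_mask Logical matrix (or vector) marking crop cells.
#' @param params A [pollination_params()] (only `kappa` is used here).
#' @return The scalar P_t.
#' @export
pollination_potential <- function(field, F, crop_mask,
                                  params = pollination_params()) {
  V <- if (inherits(field, "visitation_field")) field$inbound else as.vector(field)
  Fv <- as.vector(F)
  idx <- as.vector(crop_mask) & Fv > 0
  sum(Fv[idx] * (1 - exp(-params$kappa * V[idx] / Fv[idx])))
}

#' Seasonal pollination score
#'
#' The total pollination potential `PS = sum_t P_t` over the weekly values
#' of a season: how much the crops in the landscape can benefit from
#' pollinator visits over the whole season.
#'
#' @param P Vector of weekly pollination potentials.
#' @return The scalar PS.
#' @export
season_score <- function(P) sum(P)

# ---------------------------------------------------------------------------
# Convolution engine used by run_season(): because the exponential kernel on
# the torus is translation invariant, every sum over cells weighted by
# kernel distance to a focal cell is a circular convolution, evaluated for
# all focal cells at once by 2D FFT. With the mean-field colony (identical
# X at every nest) one convolution per week suffices for the dynamics.

# Precompute everything that depends only on landscape + floral series +
# kernel: weekly F maps, their kernel convolutions S (the normalization
# denominator field), and the per-week nest "visitation basis" such that
# the inbound visitation is V = X * Vb.
.season_context <- function(grid, series, fpar, ppar) {
  nr <- nrow(grid$classes); nc <- ncol(grid$classes)
  stopifnot(dim(series$F)[1] == nr, dim(series$F)[2] == nc)
  fftK <- fft(dispersal_kernel(nr, nc, grid$cell_size_m, fpar$gamma,
                               fpar$max_radius))
  nT <- length(series$weeks)
  nests <- grid$nests
  nest_idx <- if (!is.null(nests)) nests$cell else integer(0)
  crop <- matrix(grid$classes %in% ppar$crop_codes, nr, nc)
  Fw <- vector("list", nT); S <- vector("list", nT); Vb <- vector("list", nT)
  active <- logical(nT)
  for (ti in seq_len(nT)) {
    Fm <- series$F[, , ti]
    if (any(Fm > 0) && length(nest_idx)) {
      active[ti] <- TRUE
      Fw[[ti]] <- Fm
      Sm <- .circ_conv(Fm, fftK)
      S[[ti]] <- Sm
      M <- matrix(0, nr, nc)
      if (fpar$denominator == "nest") {
        sn <- Sm[nest_idx]
        M[nest_idx] <- ifelse(sn > 0, 1 / sn, 0)
        Vb[[ti]] <- .circ_conv(M, fftK) * Fm  # V_j = X * F_j * sum_i K_ij / S_i
      } else {
        M[nest_idx] <- 1
        Cm <- .circ_conv(M, fftK)
        Vb[[ti]] <- ifelse(Sm > 0, Fm * Cm / Sm, 0)
      }
    }
  }
  list(nr = nr, nc = nc, fftK = fftK, nT = nT, active = active,
       Fw = Fw, S = S, Vb = Vb, nest_idx = nest_idx, crop = crop,
       fpar = fpar, ppar = ppar)
}

# One week of foraging for the mean-field colony with X foragers per nest.
# Returns the landscape-average resources per nest R and the pollination
# potential P of the crop cells.
.week_forage <- function(ctx, ti, X) {
  if (!ctx$active[ti] || X <= 0 || !length(ctx$nest_idx))
    return(list(R = 0, P = 0))
  Fm <- ctx$Fw[[ti]]
  V <- X * ctx$Vb[[ti]]
  cf <- if (ctx$fpar$competition == "shared_cell") 1 / pmax(V, 1) else 1
  if (ctx$fpar$denominator == "nest") {
    G <- .circ_conv(Fm * Fm * cf, ctx$fftK)
    sn <- ctx$S[[ti]][ctx$nest_idx]
    r <- ifelse(sn > 0, X * G[ctx$nest_idx] / sn, 0)
  } else {
    Sm <- ctx$S[[ti]]
    H <- ifelse(Sm > 0, Fm * Fm * cf / Sm, 0)
    r <- X * .circ_conv(H, ctx$fftK)[ctx$nest_idx]
  }
  idx <- ctx$crop & Fm > 0
  P <- sum(Fm[idx] * (1 - exp(-ctx$ppar$kappa * V[idx] / Fm[idx])))
  list(R = mean(r), P = P, r = r)
}
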