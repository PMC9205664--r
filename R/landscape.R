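# Integer habitat codes used in the class raster. The raster is a plain
# integer matrix (rows x cols, column-major as usual in R); code 0 is the
# non-bee matrix, i.e. land that offers neither nesting nor floral resources.
.HABITATS <- c(nonbee = 0L, snh = 1L, early_mfc = 2L, late_mfc = 3L)

#' Habitat class codes
#'
#' Named integer codes used in the landscape class raster: `nonbee` (0),
#' `snh` (1, semi-natural habitat), `early_mfc` (2, early-flowering
#' mass-flowering crop) and `late_mfc` (3, late-flowering crop).
#'
#' @return A named integer vector.
#' @export
habitat_codes <- function() .HABITATS

#' Landscape generator configuration
#'
#' Parameters controlling the artificial landscape: grid extent and
#' resolution, target habitat composition, patch sizes and nest density.
#' Semi-natural habitat (SNH) and the two mass-flowering crops together make
#' up `bee_habitat_total` of the landscape; the crop area is what remains of
#' that total after SNH, split into early and late flowering crop by
#' `early_mfc_share`.
#'
#' @param side_length_m Side of the square landscape in meters.
#' @param cell_size_m Cell size in meters; `side_length_m` must be divisible
#'   by it.
#' @param snh_proportion Target fraction of the landscape covered by SNH.
#' @param snh_patch_area_m2 Mean area of one SNH patch, in square meters.
#' @param bee_habitat_total Fraction of the landscape covered by bee habitat
#'   (SNH plus flowering crops).
#' @param early_mfc_share Fraction of the crop area assigned to the
#'   early-flowering crop (the rest is late-flowering).
#' @param crop_patch_area_m2 Mean area of one crop field patch, in square
#'   meters.
#' @param nest_density Nests per square kilometer of SNH.
#' @param seed Optional RNG seed making landscape generation reproducible.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(side_length_m = 2010,
                             cell_size_m = 10,
                             snh_proportion = 0.10,
                             snh_patch_area_m2 = 10000,
                             bee_habitat_total = 0.60,
                             early_mfc_share = 0.5,
                             crop_patch_area_m2 = 500,
                             nest_density = 121,
                             seed = NULL) {
  if (side_length_m %% cell_size_m != 0)
    stop("side_length_m must be divisible by cell_size_m")
  if (snh_proportion < 0 || snh_proportion > 1)
    stop("snh_proportion must lie in [0, 1]")
  if (bee_habitat_total < 0 || bee_habitat_total > 1)
    stop("bee_habitat_total must lie in [0, 1]")
  if (snh_proportion > bee_habitat_total)
    stop("snh_proportion cannot exceed bee_habitat_total")
  if (early_mfc_share < 0 || early_mfc_share > 1)
    stop("early_mfc_share must lie in [0, 1]")
  if (snh_patch_area_m2 <= 0 || crop_patch_area_m2 <= 0)
    stop("patch areas must be positive")
  if (nest_density < 0) stop("nest_density must be non-negative")
  structure(list(side_length_m = side_length_m,
                 cell_size_m = cell_size_m,
                 snh_proportion = snh_proportion,
                 snh_patch_area_m2 = snh_patch_area_m2,
                 bee_habitat_total = bee_habitat_total,
                 early_mfc_share = early_mfc_share,
                 crop_patch_area_m2 = crop_patch_area_m2,
                 nest_density = nest_density,
                 seed = seed),
            class = "landscape_config")
}

# 4-neighbourhood of one cell id (1-based, column-major) on the torus.
.torus_nbrs <- function(id, nr, nc) {
  r <- (id - 1L) %% nr + 1L
  cc <- (id - 1L) %/% nr
  c(if (r == 1L) id + nr - 1L else id - 1L,
    if (r == nr) id - nr + 1L else id + 1L,
    if (cc == 0L) id + (nc - 1L) * nr else id - nr,
    if (cc == nc - 1L) id - (nc - 1L) * nr else id + nr)
}

# Grow one connected patch of `size` cells of class `code` from `seedcell`
# by repeated uniform draws from the unassigned frontier; claims only cells
# still in the matrix (code 0). Returns the updated class vector and the
# number of cells actually claimed (less than `size` if growth is crowded
# out by previously assigned patches).
.grow_patch <- function(cls, seedcell, size, code, nr, nc) {
  cls[seedcell] <- code
  n <- 1L
  frontier <- .torus_nbrs(seedcell, nr, nc)
  while (n < size) {
    frontier <- frontier[cls[frontier] == 0L]
    if (!length(frontier)) break
    k <- frontier[sample.int(length(frontier), 1L)]
    cls[k] <- code
    n <- n + 1L
    frontier <- c(frontier, .torus_nbrs(k, nr, nc))
  }
  list(cls = cls, n = n)
}

#' Generate an artificial landscape raster
#'
#' Builds a square toroidal raster of the four habitat classes by growing
#' connected patches from random seed cells (region growing): first SNH
#' patches of about `snh_patch_area_m2` each until the SNH target is met,
#' then crop field patches of about `crop_patch_area_m2` each until bee
#' habitat (SNH + crops) reaches `bee_habitat_total` of the grid. Each crop
#' patch is labelled early- or late-flowering at random, in proportion to
#' the remaining quota for each type, so that the early crop makes up about
#' `early_mfc_share` of the crop area. Remaining cells are non-bee matrix.
#' Realized class proportions are recorded alongside the targets, because
#' crowding during patch growth can leave small shortfalls.
#'
#' @param cfg A [landscape_config()].
#' @return An object of class `bee_landscape`: a list with the integer
#'   `classes` matrix, `cell_size_m`, the generating `config`, a `realized`
#'   list of achieved proportions, and (after [place_nests()]) a `nests`
#'   data frame.
#' @examples
#' land <- generate_landscape(landscape_config(seed = 1))
#' table(land$classes)
#' @export
generate_landscape <- function(cfg) {
  if (!inherits(cfg, "landscape_config"))
    stop("cfg must be a landscape_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_side <- as.integer(cfg$side_length_m / cfg$cell_size_m)
  nr <- nc <- n_side
  ncell <- nr * nc
  cell_area <- cfg$cell_size_m^2
  target_snh <- round(cfg$snh_proportion * ncell)
  target_bee <- round(cfg$bee_habitat_total * ncell)
  if (target_bee > ncell)
    stop("requested habitat proportions exceed the grid")

  cls <- integer(ncell)
  # shuffled queue of candidate seed cells; advanced lazily past taken cells
  queue <- sample.int(ncell)
  qi <- 1L
  next_free <- function() {
    while (qi <= ncell && cls[queue[qi]] != 0L) qi <<- qi + 1L
    if (qi > ncell) NA_integer_ else queue[qi]
  }

  snh_patch_cells <- max(1L, as.integer(round(cfg$snh_patch_area_m2 / cell_area)))
  crop_patch_cells <- max(1L, as.integer(round(cfg$crop_patch_area_m2 / cell_area)))

  done <- 0L
  while (done < target_snh) {
    s <- next_free()
    if (is.na(s)) break
    g <- .grow_patch(cls, s, min(snh_patch_cells, target_snh - done),
                     .HABITATS[["snh"]], nr, nc)
    cls <- g$cls
    done <- done + g$n
  }
  n_snh <- done

  crop_target <- max(0L, target_bee - n_snh)
  early_target <- round(cfg$early_mfc_share * crop_target)
  n_early <- 0L
  n_crop <- 0L
  while (n_crop < crop_target) {
    s <- next_free()
    if (is.na(s)) break
    rem_early <- early_target - n_early
    rem_late <- (crop_target - early_target) - (n_crop - n_early)
    p_early <- if (rem_early + rem_late <= 0) 0 else rem_early / (rem_early + rem_late)
    code <- if (runif(1) < p_early) .HABITATS[["early_mfc"]] else .HABITATS[["late_mfc"]]
    g <- .grow_patch(cls, s, min(crop_patch_cells, crop_target - n_crop), code, nr, nc)
    cls <- g$cls
    n_crop <- n_crop + g$n
    if (code == .HABITATS[["early_mfc"]]) n_early <- n_early + g$n
  }

  classes <- matrix(cls, nrow = nr, ncol = nc)
  realized <- list(
    snh = n_snh / ncell,
    crop = n_crop / ncell,
    early_mfc = n_early / ncell,
    late_mfc = (n_crop - n_early) / ncell,
    nonbee = (ncell - n_snh - n_crop) / ncell,
    early_mfc_share = if (n_crop > 0) n_early / n_crop else NA_real_
  )
  structure(list(classes = classes,
                 cell_size_m = cfg$cell_size_m,
                 config = cfg,
                 realized = realized,
                 nests = NULL),
            class = "bee_landscape")
}

#' Place bumblebee nests in semi-natural habitat
#'
#' Draws nest cells uniformly without replacement among SNH cells, at most
#' one nest per cell. The nest count is `nest_density` times the SNH area in
#' square kilometers, rounded, so the number of nests is proportional to the
#' amount of SNH in the landscape. The allocation is fixed for a season.
#'
#' @param grid A `bee_landscape`.
#' @param nest_density Nests per square kilometer of SNH; defaults to the
#'   value in the landscape's config.
#' @param seed Optional RNG seed for the placement draw.
#' @return The landscape with a `nests` data frame (`cell`, `row`, `col`,
#'   `x_m`, `y_m`) attached.
#' @export
place_nests <- function(grid, nest_density = NULL, seed = NULL) {
  if (!inherits(grid, "bee_landscape")) stop("grid must be a bee_landscape")
  nest_density <- nest_density %||% grid$config$nest_density
  if (!is.null(seed)) set.seed(seed)
  snh_cells <- which(grid$classes == .HABITATS[["snh"]])
  area_km2 <- length(snh_cells) * grid$cell_size_m^2 / 1e6
  n <- round(nest_density * area_km2)
  if (n > length(snh_cells))
    stop("nest count (", n, ") exceeds the number of SNH cells (",
         length(snh_cells), ")")
  cells <- if (n > 0) sort(sample(snh_cells, n)) else integer(0)
  nr <- nrow(grid$classes)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  grid$nests <- data.frame(
    cell = cells, row = row, col = col,
    x_m = (col - 0.5) * grid$cell_size_m,
    y_m = (row - 0.5) * grid$cell_size_m
  )
  grid$nest_density <- nest_density
  grid
}

#' @export
print.bee_landscape <- function(x, ...) {
  d <- dim(x$classes)
  cat("bee_landscape: ", d[1], "x", d[2], " cells at ", x$cell_size_m,
      " m (", d[1] * x$cell_size_m / 1000, " km side, toroidal)\n", sep = "")
  r <- x$realized
  cat(sprintf("  realized cover: SNH %.1f%%, early MFC %.1f%%, late MFC %.1f%%, non-bee %.1f%%\n",
              100 * r$snh, 100 * r$early_mfc, 100 * r$late_mfc, 100 * r$nonbee))
  if (!is.null(x$nests))
    cat("  nests: ", nrow(x$nests), " (one queen each)\n", sep = "")
  else cat("  nests: not placed\n")
  invisible(x)
}

#' Export / import a landscape as an ESRI ASCII grid
#'
#' Writes the integer class raster in the plain-text ESRI ASCII grid format
#' (readable by GIS software and raster packages). `read_asc_grid()` reads
#' such a file back into a minimal `bee_landscape` (classes and cell size
#' only; config, realized proportions and nests are not stored in the
#' format).
#'
#' @param grid A `bee_landscape`.
#' @param file Path to write to / read from.
#' @return `write_asc_grid()` returns `file` invisibly; `read_asc_grid()`
#'   returns a `bee_landscape`.
#' @export
write_asc_grid <- function(grid, file) {
  m <- grid$classes
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("NCOLS", ncol(m)),
               paste("NROWS", nrow(m)),
               "XLLCORNER 0", "YLLCORNER 0",
               paste("CELLSIZE", grid$cell_size_m),
               "NODATA_VALUE -9999"), con)
  # ASCII grids are written top row first
  for (i in seq_len(nrow(m)))
    writeLines(paste(m[nrow(m) - i + 1L, ], collapse = " "), con)
  invisible(file)
}

#' @rdname write_asc_grid
#' @export
read_asc_grid <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(lines[1:6], "\\s+")
  vals <- setNames(vapply(hdr, function(x) as.numeric(x[2]), 0),
                   tolower(vapply(hdr, `[`, "", 1)))
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- lapply(lines[7:(6 + nr)], function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rev(body))
  structure(list(classes = m, cell_size_m = vals[["cellsize"]],
                 config = NULL,
                 realized = list(snh = mean(m == .HABITATS[["snh"]])),
                 nests = NULL),
            class = "bee_landscape")
}

#' Export nest locations as CSV
#'
#' @param grid A `bee_landscape` with nests placed.
#' @param file Path of the CSV file to write.
#' @return `file`, invisibly.
#' @export
write_nests_csv <- function(grid, file) {
  if (is.null(grid$nests)) stop("no nests placed; call place_nests() first")
  write.csv(grid$nests, file, row.names = FALSE)
  invisible(file)
}
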