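#' Generalized seasonal progression parameters
#'
#' The season is summarized by a progression running from 0 to 100,
#' mimicking cumulative growing degree days (GDD) in a northern-hemisphere
#' year with a sigmoid of day-of-year: `100 * pnorm((day - midpoint_day) /
#' scale_days)`. All phenological events in the model (flowering windows,
#' queen emergence, worker take-over, queen production, drought onset) are
#' expressed on this 0-100 scale, so swapping in an observed GDD series
#' shifts every event consistently.
#'
#' @param midpoint_day Day of year at which the progression reaches 50.
#' @param scale_days Spread of the sigmoid in days.
#' @return An object of class `progression_params`.
#' @export
progression_params <- function(midpoint_day = 200, scale_days = 65) {
  if (scale_days <= 0) stop("scale_days must be positive")
  structure(list(midpoint_day = midpoint_day, scale_days = scale_days),
            class = "progression_params")
}

#' Seasonal progression for a day of the year
#'
#' Sigmoid (standard normal CDF) progression from 0 to 100 units; monotone
#' non-decreasing in `day`.
#'
#' @param day Day of year (vectorized).
#' @param params A [progression_params()].
#' @return Progression in (0, 100).
#' @examples
#' seasonal_progression(200)  # 50 at the midpoint
#' @export
seasonal_progression <- function(day, params = progression_params()) {
  100 * pnorm((day - params$midpoint_day) / params$scale_days)
}

#' Build a progression function from daily temperatures
#'
#' Alternative to the theoretical sigmoid: accumulates degree days above a
#' base temperature from a daily mean temperature series and rescales the
#' cumulative sum to the 0-100 progression range, so the rest of the model
#' is unchanged.
#'
#' @param temps_c Numeric vector of daily mean temperatures (deg C), one per
#'   day of year starting at day 1.
#' @param base_c Base temperature for degree-day accumulation.
#' @return A function `day -> progression units` usable wherever the
#'   sigmoid progression is used, with a `progression_params`-compatible
#'   shape via its `"table"` attribute.
#' @export
gdd_progression <- function(temps_c, base_c = 5) {
  if (!length(temps_c)) stop("empty temperature series")
  cum <- cumsum(pmax(temps_c - base_c, 0))
  if (cum[length(cum)] <= 0) stop("no degree days accumulated above base")
  tab <- 100 * cum / cum[length(cum)]
  f <- function(day) {
    day <- pmin(pmax(as.integer(round(day)), 1L), length(tab))
    tab[day]
  }
  attr(f, "table") <- tab
  f
}

# Evaluate progression given either progression_params or a function.
.prog <- function(day, progression) {
  if (is.function(progression)) progression(day)
  else seasonal_progression(day, progression)
}

#' Per-habitat flowering phenology table
#'
#' Each bee habitat flowers between a start and an end expressed on the
#' seasonal-progression scale, with a parabolic flowering curve peaking at
#' the window midpoint at the habitat's maximum floral value `f_max` (a
#' dimensionless value in \[0, 1\] capturing how the habitats' resources
#' relate to each other: early crop > late crop > SNH). SNH flowers at a low
#' level across almost the whole season; the two crops provide shorter,
#' taller pulses. The non-bee matrix has `f_max = 0`.
#'
#' @param snh,early_mfc,late_mfc Named numeric vectors with elements
#'   `start`, `end` (progression units) and `f_max`.
#' @return A data frame with one row per habitat code.
#' @export
habitat_phenology <- function(snh = c(start = 10, end = 96, f_max = 0.34),
                              early_mfc = c(start = 24, end = 55, f_max = 1.0),
                              late_mfc = c(start = 30, end = 62, f_max = 0.7)) {
  rows <- list(nonbee = c(start = 0, end = 100, f_max = 0),
               snh = snh, early_mfc = early_mfc, late_mfc = late_mfc)
  for (nm in names(rows)) {
    r <- rows[[nm]]
    if (!all(c("start", "end", "f_max") %in% names(r)))
      stop("phenology for ", nm, " needs start, end and f_max")
    if (r[["start"]] >= r[["end"]])
      stop("degenerate flowering window for ", nm)
    if (r[["f_max"]] < 0 || r[["f_max"]] > 1)
      stop("f_max must lie in [0, 1]")
  }
  data.frame(habitat = names(rows),
             code = .HABITATS[names(rows)],
             gdd_start = vapply(rows, `[[`, 0, "start"),
             gdd_end = vapply(rows, `[[`, 0, "end"),
             f_max = vapply(rows, `[[`, 0, "f_max"),
             row.names = NULL)
}

#' Standardized position of a day within a flowering window
#'
#' Maps the seasonal progression of `day` linearly onto \[0, 1\] between the
#' window's start and end, clamped outside the window.
#'
#' @param day Day of year (vectorized).
#' @param gdd_start,gdd_end Window bounds in progression units.
#' @param progression A [progression_params()] or a progression function.
#' @return z in \[0, 1\].
#' @export
standardize_day <- function(day, gdd_start, gdd_end,
                            progression = progression_params()) {
  if (gdd_end <= gdd_start) stop("degenerate flowering window")
  z <- (.prog(day, progression) - gdd_start) / (gdd_end - gdd_start)
  pmin(pmax(z, 0), 1)
}

#' Floral resource value of a habitat on a given day
#'
#' Parabolic flowering curve `(1 - 4 (z - 1/2)^2) * f_max` over the
#' standardized window position z: zero at and outside the window edges,
#' peaking at `f_max` at the window midpoint.
#'
#' @inheritParams standardize_day
#' @param f_max Peak floral value of the habitat.
#' @return Floral value in \[0, `f_max`\].
#' @export
floral_value <- function(day, gdd_start, gdd_end, f_max,
                         progression = progression_params()) {
  z <- standardize_day(day, gdd_start, gdd_end, progression)
  (1 - 4 * (z - 0.5)^2) * f_max
}

#' Representative day of a model week
#'
#' Week `t` covers days `7 (t - 1) + 1 ... 7 t`; its floral map is evaluated
#' at the mid-week day `7 (t - 1) + 4`.
#'
#' @param week Week index (vectorized).
#' @return Day of year.
#' @export
week_mid_day <- function(week) 7 * (week - 1) + 4

#' Build the weekly floral map series for a landscape
#'
#' Evaluates each habitat's flowering curve at the representative day of
#' every week and maps the values onto the class raster, giving the floral
#' value F(t, i) of every cell i in every week t. Deterministic given the
#' landscape.
#'
#' @param grid A `bee_landscape`.
#' @param phenology A [habitat_phenology()] table covering every class
#'   present in the grid.
#' @param weeks Integer vector of week indices to evaluate.
#' @param progression A [progression_params()] or progression function.
#' @return An object of class `floral_series`: list with `weeks`, `days`,
#'   a `nr x nc x length(weeks)` array `F`, and the phenology/progression
#'   used. `drought` is `NULL` until [apply_drought()] is used.
#' @export
build_floral_series <- function(grid, phenology = habitat_phenology(),
                                weeks = 1:52,
                                progression = progression_params()) {
  if (!inherits(grid, "bee_landscape")) stop("grid must be a bee_landscape")
  present <- sort(unique(as.vector(grid$classes)))
  if (!all(present %in% phenology$code))
    stop("missing phenology for habitat code(s): ",
         paste(setdiff(present, phenology$code), collapse = ", "))
  days <- week_mid_day(weeks)
  nr <- nrow(grid$classes); nc <- ncol(grid$classes)
  # floral value per habitat code (row) and week (col)
  codes <- sort(phenology$code)
  fv <- vapply(codes, function(cd) {
    p <- phenology[phenology$code == cd, ]
    if (p$f_max == 0) rep(0, length(days))
    else floral_value(days, p$gdd_start, p$gdd_end, p$f_max, progression)
  }, numeric(length(days)))
  fv <- matrix(fv, nrow = length(days))  # weeks x codes
  lookup <- match(as.vector(grid$classes), codes)
  F <- array(0, dim = c(nr, nc, length(weeks)))
  for (ti in seq_along(weeks))
    F[, , ti] <- fv[ti, lookup]
  structure(list(weeks = weeks, days = days, F = F,
                 phenology = phenology, progression = progression,
                 drought = NULL),
            class = "floral_series")
}

#' @export
print.floral_series <- function(x, ...) {
  d <- dim(x$F)
  cat("floral_series: ", d[1], "x", d[2], " cells, weeks ",
      min(x$weeks), "-", max(x$weeks), "\n", sep = "")
  cat(sprintf("  total seasonal floral resource sum: %.1f\n", sum(x$F)))
  if (!is.null(x$drought))
    cat("  drought applied: weeks ",
        paste(range(x$drought$window), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Drought scenario
#'
#' A drought penalizes the weekly growth of floral resources during a
#' window of consecutive weeks: where the unperturbed weekly increment of a
#' cell's floral value is positive it is multiplied by
#' `positive_growth_factor` (default 0.08, i.e. growth close to zero), and
#' where it is negative the decline is amplified by
#' `negative_growth_multiplier` (default 1.5, i.e. a 50% larger reduction).
#' The window starts at a fixed point early in the season, given on the
#' seasonal-progression scale.
#'
#' @param start_gdd Progression units at which the drought starts (the first
#'   week whose representative day reaches this value).
#' @param duration_weeks Length of the drought in weeks (0 is the degenerate
#'   no-op scenario).
#' @param positive_growth_factor Multiplier applied to positive weekly
#'   increments during the drought.
#' @param negative_growth_multiplier Multiplier applied to negative weekly
#'   increments during the drought.
#' @return An object of class `drought_scenario`.
#' @export
drought_scenario <- function(start_gdd = 28, duration_weeks = 4,
                             positive_growth_factor = 0.08,
                             negative_growth_multiplier = 1.5) {
  if (duration_weeks < 0) stop("duration_weeks must be >= 0")
  if (positive_growth_factor < 0 || positive_growth_factor > 1)
    stop("positive_growth_factor must lie in [0, 1]")
  if (negative_growth_multiplier < 1)
    stop("negative_growth_multiplier must be >= 1")
  structure(list(start_gdd = start_gdd,
                 duration_weeks = as.integer(duration_weeks),
                 positive_growth_factor = positive_growth_factor,
                 negative_growth_multiplier = negative_growth_multiplier),
            class = "drought_scenario")
}

#' Apply a drought perturbation to a floral series
#'
#' Rebuilds the series from the unperturbed weekly increments g(t) =
#' F(t) - F(t-1): inside the drought window the applied increment is
#' `positive_growth_factor * g` for g >= 0 and
#' `negative_growth_multiplier * g` for g < 0; outside the window the
#' unperturbed increments are re-applied from the (possibly depressed)
#' level, so after the drought the curve runs parallel below the control,
#' floored at zero. The perturbed series never exceeds the control in any
#' cell or week.
#'
#' @param series A `floral_series` (unperturbed control).
#' @param scenario A [drought_scenario()].
#' @return A new `floral_series` with the perturbed maps and the scenario
#'   recorded in `$drought`.
#' @export
apply_drought <- function(series, scenario = drought_scenario()) {
  if (!inherits(series, "floral_series")) stop("series must be a floral_series")
  if (!inherits(scenario, "drought_scenario")) stop("scenario must be a drought_scenario")
  nT <- length(series$weeks)
  prog <- .prog(series$days, series$progression)
  w0 <- which(prog >= scenario$start_gdd)[1]
  if (is.na(w0) || scenario$duration_weeks == 0) {
    series$drought <- list(scenario = scenario, window = integer(0))
    return(series)
  }
  win <- seq.int(w0, min(w0 + scenario$duration_weeks - 1L, nT))
  Fc <- series$F
  Fd <- Fc
  for (t in 2:nT) {
    g <- Fc[, , t] - Fc[, , t - 1]
    inc <- if (t %in% win) {
      ifelse(g >= 0, scenario$positive_growth_factor * g,
             scenario$negative_growth_multiplier * g)
    } else g
    Fd[, , t] <- pmax(0, Fd[, , t - 1] + inc)
  }
  series$F <- Fd
  series$drought <- list(scenario = scenario, window = series$weeks[win])
  series
}

#' Total seasonal floral resource
#'
#' Sum of F(t, i) over all cells and weeks of a series; a scalar summary
#' used to compare control and drought conditions.
#'
#' @param series A `floral_series`.
#' @return A number.
#' @export
total_floral_resource <- function(series) sum(series$F)
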