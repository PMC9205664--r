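#' Latin hypercube simulation design
#'
#' Draws the landscape design points of the simulation study: within each
#' iteration, a latin hypercube sample stratifies the three design factors
#' (SNH patch area, SNH proportion, drought duration) so that every
#' 1/n-quantile bin of every factor contains exactly one point. Drought
#' duration is discretized to whole weeks. The share of the crop area that
#' flowers early is an independent uniform draw per landscape, recorded
#' with the design. Each landscape also receives its own RNG seed, so a
#' design fully determines the experiment.
#'
#' @param n_combinations Design points per iteration.
#' @param n_iterations Independent latin hypercube draws.
#' @param snh_patch_area Range (m^2) of the SNH patch area factor.
#' @param snh_proportion Range of the SNH proportion factor.
#' @param drought_duration Integer range (weeks) of the drought duration
#'   factor.
#' @param seed Master RNG seed.
#' @return A data frame of class `lhs_design` with one row per landscape:
#'   `landscape_id`, `iteration`, `combination`, the factor values,
#'   `early_mfc_share` and `seed`.
#' @examples
#' d <- lhs_design(seed = 1)
#' nrow(d)  # 20 x 5 = 100 landscapes
#' @export
lhs_design <- function(n_combinations = 20, n_iterations = 5,
                       snh_patch_area = c(5000, 15000),
                       snh_proportion = c(0.05, 0.25),
                       drought_duration = c(1L, 4L),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ndur <- drought_duration[2] - drought_duration[1] + 1L
  out <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    u <- lhs::randomLHS(n_combinations, 3)
    out[[it]] <- data.frame(
      iteration = it,
      combination = seq_len(n_combinations),
      snh_patch_area_m2 = snh_patch_area[1] + u[, 1] * diff(snh_patch_area),
      snh_proportion = snh_proportion[1] + u[, 2] * diff(snh_proportion),
      drought_duration_weeks = drought_duration[1] + pmin(floor(u[, 3] * ndur),
                                                          ndur - 1L),
      early_mfc_share = runif(n_combinations)
    )
  }
  d <- do.call(rbind, out)
  d$landscape_id <- seq_len(nrow(d))
  d$seed <- sample.int(.Machine$integer.max, nrow(d))
  class(d) <- c("lhs_design", "data.frame")
  d
}

# Landscape + control/drought floral series for one design point; the
# building blocks shared by run_experiment() and local_sensitivity().
.build_scenario <- function(row, config) {
  cfg <- landscape_config(
    side_length_m = config$landscape$side_length_m,
    cell_size_m = config$landscape$cell_size_m,
    snh_proportion = row$snh_proportion,
    snh_patch_area_m2 = row$snh_patch_area_m2,
    bee_habitat_total = config$landscape$bee_habitat_total,
    early_mfc_share = row$early_mfc_share,
    crop_patch_area_m2 = config$landscape$crop_patch_area_m2,
    nest_density = config$landscape$nest_density,
    seed = row$seed)
  grid <- generate_landscape(cfg)       # seeds the RNG stream for the pair
  grid <- place_nests(grid)             # continues the same stream
  series <- build_floral_series(grid, config$phenology, config$weeks,
                                config$progression)
  sc <- config$drought
  sc$duration_weeks <- as.integer(row$drought_duration_weeks)
  dry <- apply_drought(series, sc)
  list(grid = grid, control = series, drought = dry)
}

# Paired control/drought season outputs for one prepared scenario. `ctxs`
# optionally carries precomputed foraging contexts for both series.
.run_pair <- function(scen, config, ctxs = NULL) {
  ctrl <- run_season(scen$grid, scen$control, config$colony, config$foraging,
                     config$pollination, keep_trajectory = FALSE,
                     context = ctxs$control)
  dry <- run_season(scen$grid, scen$drought, config$colony, config$foraging,
                    config$pollination, b3_ref_max_R = ctrl$max_R,
                    keep_trajectory = FALSE, context = ctxs$drought)
  list(control = ctrl, drought = dry)
}

.result_row <- function(row, grid, res, drought_flag) {
  data.frame(
    landscape_id = row$landscape_id,
    drought = drought_flag,
    snh_patch_area_m2 = row$snh_patch_area_m2,
    snh_proportion_target = row$snh_proportion,
    drought_duration_weeks = row$drought_duration_weeks,
    early_mfc_share_target = row$early_mfc_share,
    seed = row$seed,
    realized_snh = grid$realized$snh,
    realized_early_mfc = grid$realized$early_mfc,
    realized_early_mfc_share = grid$realized$early_mfc_share,
    n_nests = res$n_nests,
    MaxW = res$MaxW, TQ = res$TQ, PS = res$PS,
    total_workers = res$total_workers,
    status = "ok", error = NA_character_
  )
}

.error_row <- function(row, msg, drought_flag) {
  data.frame(landscape_id = row$landscape_id, drought = drought_flag,
             snh_patch_area_m2 = row$snh_patch_area_m2,
             snh_proportion_target = row$snh_proportion,
             drought_duration_weeks = row$drought_duration_weeks,
             early_mfc_share_target = row$early_mfc_share, seed = row$seed,
             realized_snh = NA_real_, realized_early_mfc = NA_real_,
             realized_early_mfc_share = NA_real_, n_nests = NA_integer_,
             MaxW = NA_real_, TQ = NA_real_, PS = NA_real_,
             total_workers = NA_real_, status = "error", error = msg)
}

#' Run the paired drought / no-drought simulation experiment
#'
#' For every design point: generate the landscape and floral series once,
#' run the season without drought, apply the drought perturbation of the
#' design's duration and rerun. The two members of a pair share the
#' landscape raster, the nest allocation and the unperturbed phenology, so
#' the drought contrast is purely the resource perturbation (a case-control
#' setup). Failed runs are recorded with their error message rather than
#' dropped.
#'
#' @param design An [lhs_design()] data frame (or any data frame with the
#'   same columns).
#' @param config A [beescape_config()].
#' @param verbose Print one line per landscape.
#' @return A data frame of class `experiment_table` with two rows (control,
#'   drought) per landscape: design variables, realized proportions, nest
#'   count and the season outputs MaxW, TQ, PS and total workers produced.
#' @export
run_experiment <- function(design, config = beescape_config(),
                           verbose = FALSE) {
  rows <- vector("list", 2L * nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    res <- tryCatch({
      scen <- .build_scenario(row, config)
      pair <- .run_pair(scen, config)
      list(.result_row(row, scen$grid, pair$control, FALSE),
           .result_row(row, scen$grid, pair$drought, TRUE))
    }, error = function(e) {
      list(.error_row(row, conditionMessage(e), FALSE),
           .error_row(row, conditionMessage(e), TRUE))
    })
    rows[[2L * i - 1L]] <- res[[1]]
    rows[[2L * i]] <- res[[2]]
    if (verbose)
      message(sprintf("landscape %d/%d: SNH %.1f%%, %d nests",
                      i, nrow(design), 100 * res[[1]]$realized_snh,
                      res[[1]]$n_nests))
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    landscape_id = integer(0), drought = logical(0),
    snh_patch_area_m2 = numeric(0), snh_proportion_target = numeric(0),
    drought_duration_weeks = numeric(0), early_mfc_share_target = numeric(0),
    seed = integer(0), realized_snh = numeric(0),
    realized_early_mfc = numeric(0), realized_early_mfc_share = numeric(0),
    n_nests = integer(0), MaxW = numeric(0), TQ = numeric(0), PS = numeric(0),
    total_workers = numeric(0), status = character(0), error = character(0))
  rownames(out) <- NULL
  class(out) <- c("experiment_table", "data.frame")
  attr(out, "config") <- config
  out
}

#' Descriptive case-control drought contrasts
#'
#' Pairs the control and drought rows of an experiment table by landscape
#' and summarizes the paired differences (drought minus control) of each
#' season output. Inference on the design (mixed models with landscape as
#' a grouping factor) is deliberately left to standard modelling routines;
#' see [model_frame()].
#'
#' @param table An `experiment_table`.
#' @return A data frame with one row per output: means under control and
#'   drought, and the mean, sd and range of the paired differences.
#' @export
case_control_summary <- function(table) {
  ok <- table[table$status == "ok", ]
  ctrl <- ok[!ok$drought, ]
  dry <- ok[ok$drought, ]
  if (!identical(sort(ctrl$landscape_id), sort(dry$landscape_id)))
    stop("unpaired rows: every landscape needs a control and a drought run")
  dry <- dry[match(ctrl$landscape_id, dry$landscape_id), ]
  outs <- c("MaxW", "TQ", "PS", "total_workers")
  do.call(rbind, lapply(outs, function(o) {
    d <- dry[[o]] - ctrl[[o]]
    data.frame(output = o,
               mean_control = mean(ctrl[[o]]), mean_drought = mean(dry[[o]]),
               mean_diff = mean(d), sd_diff = sd(d),
               min_diff = min(d), max_diff = max(d))
  }))
}

#' Model-ready covariate table for external regression
#'
#' Reshapes an experiment table into the covariate structure used to
#' analyse the design: realized SNH fraction, realized early-crop fraction
#' of the landscape (linear and quadratic), the drought indicator and the
#' landscape id as a grouping factor, next to the three outputs. Feed this
#' to any standard mixed-model routine (e.g. `lme4::lmer(MaxW ~ snh * drought
#' + mfc * drought + I(mfc^2) * drought + (1 | landscape_id), data)`).
#'
#' @param table An `experiment_table`.
#' @return A plain data frame.
#' @export
model_frame <- function(table) {
  ok <- table[table$status == "ok", ]
  data.frame(landscape_id = factor(ok$landscape_id),
             drought = as.integer(ok$drought),
             snh = ok$realized_snh,
             mfc = ok$realized_early_mfc,
             mfc2 = ok$realized_early_mfc^2,
             MaxW = ok$MaxW, TQ = ok$TQ, PS = ok$PS,
             total_workers = ok$total_workers)
}

#' Write an experiment table and its manifest
#'
#' @param table An `experiment_table`.
#' @param outdir Directory to create/write into.
#' @param seeds Seeds recorded in the manifest.
#' @return `outdir`, invisibly.
#' @export
write_experiment <- function(table, outdir, seeds = unique(table$seed)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(table, file.path(outdir, "experiment.csv"), row.names = FALSE)
  cfg <- attr(table, "config") %||% beescape_config()
  write_manifest(cfg, seeds, file.path(outdir, "manifest.json"))
  invisible(outdir)
}
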