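#' Full model configuration
#'
#' Bundles the per-module parameter objects into a single nested list, the
#' unit handled by the experiment and sensitivity machinery and by the YAML
#' configuration file. Every model symbol is a named key.
#'
#' @param landscape A [landscape_config()] template (the experiment design
#'   overrides the design factors per landscape).
#' @param phenology A [habitat_phenology()] table.
#' @param progression A [progression_params()] or progression function.
#' @param foraging A [foraging_params()].
#' @param colony A [colony_params()].
#' @param pollination A [pollination_params()].
#' @param drought A [drought_scenario()] (the experiment design overrides
#'   the duration per landscape).
#' @param weeks Week indices simulated.
#' @return An object of class `beescape_config`.
#' @export
beescape_config <- function(landscape = landscape_config(),
                            phenology = habitat_phenology(),
                            progression = progression_params(),
                            foraging = foraging_params(),
                            colony = colony_params(),
                            pollination = pollination_params(),
                            drought = drought_scenario(),
                            weeks = 1:52) {
  structure(list(landscape = landscape, phenology = phenology,
                 progression = progression, foraging = foraging,
                 colony = colony, pollination = pollination,
                 drought = drought, weeks = weeks),
            class = "beescape_config")
}

# Rebuild one parameter object from defaults + a named list of overrides.
.rebuild <- function(constructor, defaults, overrides) {
  args <- modifyList(unclass(defaults), overrides)
  args <- args[names(args) %in% names(formals(constructor))]
  do.call(constructor, args)
}

#' Read a model configuration from a YAML file
#'
#' Any key omitted from the file keeps its package default. Blocks mirror
#' the constructors: `landscape`, `phenology` (sub-blocks `snh`,
#' `early_mfc`, `late_mfc` with `start`, `end`, `f_max`), `progression`,
#' `foraging`, `colony`, `pollination`, `drought`, and `weeks` (`from`,
#' `to`).
#'
#' @param file Path to a YAML file.
#' @return A `beescape_config`.
#' @export
read_config <- function(file) {
  y <- yaml::read_yaml(file)
  cfg <- beescape_config()
  if (!is.null(y$landscape))
    cfg$landscape <- .rebuild(landscape_config, cfg$landscape, y$landscape)
  if (!is.null(y$phenology)) {
    ph <- y$phenology
    args <- list()
    for (h in c("snh", "early_mfc", "late_mfc"))
      if (!is.null(ph[[h]])) args[[h]] <- unlist(ph[[h]])
    cfg$phenology <- do.call(habitat_phenology, args)
  }
  if (!is.null(y$progression))
    cfg$progression <- .rebuild(progression_params, cfg$progression, y$progression)
  if (!is.null(y$foraging))
    cfg$foraging <- .rebuild(foraging_params, cfg$foraging, y$foraging)
  if (!is.null(y$colony))
    cfg$colony <- .rebuild(colony_params, cfg$colony, y$colony)
  if (!is.null(y$pollination))
    cfg$pollination <- .rebuild(pollination_params, cfg$pollination, y$pollination)
  if (!is.null(y$drought))
    cfg$drought <- .rebuild(drought_scenario, cfg$drought, y$drought)
  if (!is.null(y$weeks))
    cfg$weeks <- seq.int(y$weeks$from %||% 1L, y$weeks$to %||% 52L)
  cfg
}

#' Write a run manifest
#'
#' Records the configuration, the seeds used and the package version as
#' JSON next to a run's outputs, so any table can be traced back to the
#' exact settings that produced it.
#'
#' @param config A `beescape_config`.
#' @param seeds Integer seeds used by the run.
#' @param file Path of the JSON file to write.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(config, seeds, file) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  cfg <- strip(config)
  cfg$progression <- if (is.function(config$progression)) "gdd_table"
                     else unclass(config$progression)
  jsonlite::write_json(
    list(package = "beescape",
         version = as.character(utils::packageVersion("beescape")),
         seeds = seeds, config = cfg),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(file)
}
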