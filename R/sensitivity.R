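# Population-model parameters eligible for the local sensitivity analysis.
# The floral f_max values characterize the input to the population model
# rather than the population model itself and are therefore excluded; the
# nest density is included because it sets the initial population size.
.SENS_PARAMS <- c("delta", "alpha", "beta", "psi", "mu", "phi", "epsilon",
                  "pw", "nest_density")

# Apply a fractional change to one population parameter inside a config.
.perturb_config <- function(config, param, frac) {
  if (frac == 0) return(config)
  if (param == "nest_density") {
    config$landscape$nest_density <- config$landscape$nest_density * (1 + frac)
  } else {
    val <- config$colony[[param]] * (1 + frac)
    args <- unclass(config$colony)
    args[[param]] <- val
    config$colony <- do.call(colony_params, args)
  }
  config
}

# Additive-model effect sizes of the design variables on each output:
# coefficients of SNH fraction, early-crop fraction and drought in a linear
# model without interactions, fitted to the paired experiment table.
.effect_sizes <- function(table) {
  mf <- model_frame(table)
  outs <- c("MaxW", "TQ", "PS")
  effs <- c("snh", "mfc", "drought")
  res <- expand.grid(effect = effs, output = outs, stringsAsFactors = FALSE)
  res$estimate <- NA_real_
  for (o in outs) {
    fit <- lm(mf[[o]] ~ snh + mfc + drought, data = mf)
    cf <- coef(fit)
    for (e in effs)
      res$estimate[res$output == o & res$effect == e] <- cf[[e]]
  }
  res
}

#' One-at-a-time local sensitivity analysis
#'
#' Varies each population parameter by the fractional changes in `deltas`
#' (default -10%, 0, +10%) around its nominal value, one at a time, reruns
#' a reduced simulation experiment at every perturbation with common random
#' numbers (the same design, landscapes and seeds throughout, so only the
#' parameter changes), and re-estimates the effects of SNH, early crop and
#' drought on MaxW, TQ and PS with an additive linear model. The
#' sensitivity score of a parameter for one (effect, output) pair is the
#' elasticity
#' `S = slope(effect estimate ~ fractional change) / effect at nominal`:
#' S = 1 means the effect estimate scales one-for-one with the parameter,
#' S = 0 means the parameter does not influence that effect. S is reported
#' as `NA` when the nominal effect is numerically zero. By construction S
#' is invariant to the output's units.
#'
#' @param config A [beescape_config()] with the nominal parameter values.
#' @param design An [lhs_design()]; by default a single-iteration design of
#'   `n_landscapes` points drawn with `seed`.
#' @param parameters Subset of the population parameters to analyse.
#' @param deltas Fractional perturbation grid; must contain 0.
#' @param n_landscapes Size of the default reduced design.
#' @param seed Master seed for the default design.
#' @param runner Function `(config, design) -> experiment_table`, replaced
#'   in tests; the default runs the scenarios once per design point and
#'   reuses the landscape and floral series across all perturbations.
#' @return A data frame of class `sensitivity_result` with columns
#'   `parameter`, `effect`, `output`, `S`, `slope` and `nominal_effect`,
#'   plus a `"ranking"` attribute with the mean |S| per parameter.
#' @export
local_sensitivity <- function(config = beescape_config(),
                              design = NULL,
                              parameters = .SENS_PARAMS,
                              deltas = c(-0.1, 0, 0.1),
                              n_landscapes = 20,
                              seed = NULL,
                              runner = NULL) {
  stopifnot(0 %in% deltas, length(deltas) >= 2)
  parameters <- match.arg(parameters, .SENS_PARAMS, several.ok = TRUE)
  if (is.null(design))
    design <- lhs_design(n_combinations = n_landscapes, n_iterations = 1,
                         seed = seed)

  if (is.null(runner)) {
    tables <- .sensitivity_tables(config, design, parameters, deltas)
  } else {
    tables <- list()
    for (p in parameters) for (d in deltas) {
      key <- if (d == 0) ".nominal" else paste(p, d, sep = "@")
      if (is.null(tables[[key]]))
        tables[[key]] <- runner(.perturb_config(config, p, d), design)
    }
  }

  nominal <- .effect_sizes(tables[[".nominal"]])
  rows <- list()
  for (p in parameters) {
    est <- lapply(deltas, function(d) {
      key <- if (d == 0) ".nominal" else paste(p, d, sep = "@")
      .effect_sizes(tables[[key]])
    })
    for (i in seq_len(nrow(nominal))) {
      eff <- vapply(est, function(e) e$estimate[i], 0)
      slope <- coef(lm(eff ~ deltas))[["deltas"]]
      nom <- nominal$estimate[i]
      S <- if (is.finite(nom) && abs(nom) > 1e-12) slope / nom else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, effect = nominal$effect[i], output = nominal$output[i],
        S = S, slope = slope, nominal_effect = nom)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_result", "data.frame")
  rk <- sort(tapply(abs(out$S), out$parameter, mean, na.rm = TRUE),
             decreasing = TRUE)
  attr(out, "ranking") <- rk
  out
}

# Default runner: iterate design points in the outer loop so each
# landscape, its floral series and the control/drought pair contexts are
# built once and scored under every parameter perturbation (common random
# numbers across perturbations). Only a nest-density perturbation needs the
# nests re-placed, which is done by replaying the pair's RNG stream.
.sensitivity_tables <- function(config, design, parameters, deltas) {
  keys <- ".nominal"
  for (p in parameters) for (d in deltas) if (d != 0)
    keys <- c(keys, paste(p, d, sep = "@"))
  configs <- list(.nominal = config)
  for (k in keys[-1]) {
    parts <- strsplit(k, "@", fixed = TRUE)[[1]]
    configs[[k]] <- .perturb_config(config, parts[1], as.numeric(parts[2]))
  }
  rows <- setNames(vector("list", length(keys)), keys)
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    scen <- .build_scenario(row, config)
    ctxs <- list(
      control = .season_context(scen$grid, scen$control, config$foraging,
                                config$pollination),
      drought = .season_context(scen$grid, scen$drought, config$foraging,
                                config$pollination))
    for (k in keys) {
      cfg_k <- configs[[k]]
      scen_k <- scen
      ctxs_k <- ctxs
      if (cfg_k$landscape$nest_density != config$landscape$nest_density) {
        # replay the pair's stream so the raster stays identical and only
        # the nest draw changes with the density
        scen_k <- .build_scenario(row, cfg_k)
        ctxs_k <- NULL
      }
      pair <- .run_pair(scen_k, cfg_k, ctxs_k)
      rows[[k]][[i]] <- rbind(
        .result_row(row, scen_k$grid, pair$control, FALSE),
        .result_row(row, scen_k$grid, pair$drought, TRUE))
    }
  }
  lapply(rows, function(r) {
    out <- do.call(rbind, r)
    rownames(out) <- NULL
    class(out) <- c("experiment_table", "data.frame")
    out
  })
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("sensitivity_result: elasticity S per (parameter, effect, output)\n")
  cat("mean |S| ranking:\n")
  rk <- attr(x, "ranking")
  for (i in seq_along(rk))
    cat(sprintf("  %2d. %-12s %.3f\n", i, names(rk)[i], rk[i]))
  invisible(x)
}

#' Write sensitivity scores to CSV
#'
#' @param result A `sensitivity_result`.
#' @param file Path of the CSV file.
#' @return `file`, invisibly.
#' @export
write_sensitivity_csv <- function(result, file) {
  write.csv(as.data.frame(result), file, row.names = FALSE)
  invisible(file)
}
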