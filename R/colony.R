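#' Colony population parameters
#'
#' Parameters of the within-season stage-structured model of the average
#' colony. The season is divided into five stages: A1 (overwintered queens
#' foraging, no workers yet), A2 (queens foraging, workers produced), B1
#' (workers foraging and produced), B2 (workers foraging, daughter queens
#' produced alongside workers) and B3 (decline: nothing produced, survival
#' decays). Stage A1 ends after a fixed number of weeks; A2 to B1 and B1 to
#' B2 are triggered when the seasonal progression reaches `mu` and `psi`;
#' B3 starts once no resources have been gathered for two consecutive
#' weeks.
#'
#' Defaults are calibrated so that the example landscape with 10%
#' semi-natural habitat yields roughly 49 nests, about 585 workers produced
#' per colony per season without drought and a peak weekly production near
#' the production ceiling `alpha`; see the package vignette for the
#' calibration rationale.
#'
#' @param phi Progression units at which overwintered queens emerge.
#' @param mu Progression units at which workers take over foraging
#'   (`mu > phi`).
#' @param psi Progression units at which daughter-queen production starts
#'   (`psi > mu`).
#' @param alpha Maximum number of individuals produced per nest per week
#'   (production plateau).
#' @param beta Resource level at which weekly production reaches
#'   `1 - exp(-1)` of the plateau (half-saturation scale of the plateau
#'   function, in resource units).
#' @param delta Weekly survival fraction of workers and queens during
#'   stages A2-B2.
#' @param epsilon Fraction of stage-B2 production that is workers; the rest
#'   (`1 - epsilon`) are daughter queens.
#' @param pw Fraction of workers that forage in stages B1-B3.
#' @param a1_duration_weeks Weeks spent in stage A1 before worker
#'   production begins.
#' @param b3_rel_tol Relative tolerance defining "no resources gathered": a
#'   weekly R below `b3_rel_tol` times the seasonal maximum R counts as
#'   zero for the B3 trigger.
#' @param b3_survival_decay Weekly multiplicative decline of the survival
#'   fraction during stage B3.
#' @return An object of class `colony_params`.
#' @export
colony_params <- function(phi = 10, mu = 30, psi = 55,
                          alpha = 50, beta = 5, delta = 0.7,
                          epsilon = 0.74, pw = 0.5,
                          a1_duration_weeks = 2,
                          b3_rel_tol = 1e-3,
                          b3_survival_decay = 0.8) {
  if (!(phi < mu && mu < psi))
    stop("stage thresholds must satisfy phi < mu < psi")
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (pw < 0 || pw > 1) stop("pw must lie in [0, 1]")
  if (b3_survival_decay <= 0 || b3_survival_decay > 1)
    stop("b3_survival_decay must lie in (0, 1]")
  structure(list(phi = phi, mu = mu, psi = psi, alpha = alpha, beta = beta,
                 delta = delta, epsilon = epsilon, pw = pw,
                 a1_duration_weeks = as.integer(a1_duration_weeks),
                 b3_rel_tol = b3_rel_tol,
                 b3_survival_decay = b3_survival_decay),
            class = "colony_params")
}

#' Weekly worker production (plateau function)
#'
#' `w = alpha * (1 - exp(-(R1 + R2) / (2 beta)))`: production this week
#' saturates at `alpha` with the mean of the resources gathered in the two
#' previous weeks, on the scale `beta`.
#'
#' @param R1,R2 Resources gathered per nest in the previous two weeks
#'   (missing history enters as 0).
#' @param alpha,beta Plateau parameters, see [colony_params()].
#' @return Individuals produced per nest this week, in `[0, alpha)`.
#' @export
production <- function(R1, R2, alpha, beta) {
  alpha * (1 - exp(-(R1 + R2) / (2 * beta)))
}

#' Initial colony state
#'
#' The average colony starts the season as a single overwintered queen per
#' nest in stage A1.
#'
#' @return An object of class `colony_state` with stage, workers `W`,
#'   daughter queens `Q`, the resource history, production accumulators and
#'   stage bookkeeping.
#' @export
colony_state <- function() {
  structure(list(stage = "A1", W = 0, Q = 0,
                 R_hist = c(0, 0),   # R(t-1), R(t-2)
                 weeks_in_stage = 0L, n_R = 0L, max_R_seen = 0,
                 b3_weeks = 0L,
                 cum_workers = 0, cum_queens = 0,
                 last_w = 0, last_workers_produced = 0,
                 last_queens_produced = 0),
            class = "colony_state")
}

#' Advance the colony stage at the start of a week
#'
#' Applies the stage transitions in priority order, chaining where several
#' thresholds are passed in the same week: A1 to A2 after the fixed A1
#' duration; A2 to B1 once the seasonal progression reaches `mu`; B1 to B2
#' once it reaches `psi`; and B1/B2 to B3 once the resources gathered in
#' the two previous weeks are both below `b3_tol`. The decline trigger is
#' only armed from stage B1 onward and once some resources have actually
#' been gathered, so that the low queen-foraging returns of the early
#' season cannot end it prematurely. Transitions are irreversible within a
#' season.
#'
#' @param state A `colony_state`.
#' @param progression Seasonal progression (0-100) of the current week.
#' @param params A [colony_params()].
#' @param b3_tol Absolute resource tolerance for the decline trigger
#'   (typically `b3_rel_tol` times the maximum weekly R of the control run
#'   on the same landscape).
#' @return The state with the stage (and stage clock) updated.
#' @export
advance_stage <- function(state, progression, params, b3_tol = 0) {
  advanced <- TRUE
  while (advanced) {
    advanced <- FALSE
    if (state$stage == "A1" && state$weeks_in_stage >= params$a1_duration_weeks) {
      state$stage <- "A2"; state$weeks_in_stage <- 0L; advanced <- TRUE
    } else if (state$stage == "A2" && progression >= params$mu) {
      state$stage <- "B1"; state$weeks_in_stage <- 0L; advanced <- TRUE
    } else if (state$stage == "B1" && progression >= params$psi) {
      state$stage <- "B2"; state$weeks_in_stage <- 0L; advanced <- TRUE
    }
  }
  if (state$stage %in% c("B1", "B2") &&
      state$n_R >= 2L && state$max_R_seen > 0 &&
      state$R_hist[1] < b3_tol && state$R_hist[2] < b3_tol) {
    state$stage <- "B3"; state$weeks_in_stage <- 0L
  }
  state
}

#' Foragers per nest for the current stage
#'
#' One overwintered queen forages per nest during A1 and A2; from B1 on a
#' fraction `pw` of the standing workers forage.
#'
#' @param state A `colony_state`.
#' @param params A [colony_params()].
#' @return Foragers per nest (X).
#' @export
foragers <- function(state, params) {
  if (state$stage %in% c("A1", "A2")) 1 else params$pw * state$W
}

#' One week of colony dynamics
#'
#' Computes this week's production from the resource history (the two
#' previous weeks), applies survival and the stage-specific caste split,
#' and pushes the current week's resources `R_t` into the history.
#' In A2 and B1 all production is workers (`W' = delta W + w`); in B2
#' production is split `epsilon : (1 - epsilon)` between workers and
#' daughter queens; in B3 nothing is produced and the survival fraction
#' decays multiplicatively each week. Production accumulators record the
#' produced (undecayed) individuals.
#'
#' @param state A `colony_state` (already stage-advanced for this week).
#' @param R_t Resources gathered per nest this week.
#' @param params A [colony_params()].
#' @return The updated `colony_state`.
#' @export
step_week <- function(state, R_t, params) {
  w <- if (state$stage %in% c("A2", "B1", "B2")) {
    production(state$R_hist[1], state$R_hist[2], params$alpha, params$beta)
  } else 0
  pw_w <- 0; pq_w <- 0
  if (state$stage %in% c("A2", "B1")) {
    state$W <- params$delta * state$W + w
    pw_w <- w
  } else if (state$stage == "B2") {
    state$W <- params$delta * state$W + params$epsilon * w
    state$Q <- params$delta * state$Q + (1 - params$epsilon) * w
    pw_w <- params$epsilon * w
    pq_w <- (1 - params$epsilon) * w
  } else if (state$stage == "B3") {
    state$b3_weeks <- state$b3_weeks + 1L
    d_t <- params$delta * params$b3_survival_decay^state$b3_weeks
    state$W <- d_t * state$W
    state$Q <- d_t * state$Q
  }
  state$cum_workers <- state$cum_workers + pw_w
  state$cum_queens <- state$cum_queens + pq_w
  state$last_w <- w
  state$last_workers_produced <- pw_w
  state$last_queens_produced <- pq_w
  state$R_hist <- c(R_t, state$R_hist[1])
  state$n_R <- state$n_R + 1L
  state$max_R_seen <- max(state$max_R_seen, R_t)
  state$weeks_in_stage <- state$weeks_in_stage + 1L
  state
}

#' Run a full season on a landscape
#'
#' Weekly loop from queen emergence (the first week whose seasonal
#' progression reaches `phi`) to the end of the floral series. Each week:
#' the colony stage is advanced, the foragers per nest are determined
#' (identical across nests; the model tracks the average colony), the
#' foraging engine returns the landscape-average resources per nest R(t)
#' and the crop pollination potential P(t), and the colony state is
#' updated.
#'
#' @param grid A `bee_landscape` with nests placed.
#' @param series A `floral_series` for the same grid.
#' @param colony A [colony_params()].
#' @param foraging A [foraging_params()].
#' @param pollination A [pollination_params()].
#' @param b3_ref_max_R Reference maximum weekly R for the decline trigger
#'   (use the control run's maximum when simulating the drought member of
#'   a case-control pair); by default the run's own running maximum.
#' @param keep_trajectory Keep the weekly trajectory data frame.
#' @param context Precomputed foraging context for this grid/series/kernel
#'   (internal use: lets repeated runs over the same landscape, e.g. the
#'   sensitivity analysis, skip the kernel convolutions).
#' @return An object of class `season_result` with `MaxW` (maximum weekly
#'   worker production per nest), `TQ` (total daughter queens produced per
#'   nest), `PS` (seasonal pollination score), `total_workers` (seasonal
#'   worker production per nest), `max_standing_workers` (peak standing
#'   worker stock, the alternative population-size reading), `max_R`,
#'   `n_nests`, and the weekly `trajectory`.
#' @export
run_season <- function(grid, series,
                       colony = colony_params(),
                       foraging = foraging_params(),
                       pollination = pollination_params(),
                       b3_ref_max_R = NULL,
                       keep_trajectory = TRUE,
                       context = NULL) {
  if (!inherits(grid, "bee_landscape")) stop("grid must be a bee_landscape")
  if (!inherits(series, "floral_series")) stop("series must be a floral_series")
  n_nests <- if (is.null(grid$nests)) 0L else nrow(grid$nests)
  empty <- function() {
    structure(list(MaxW = 0, TQ = 0, PS = 0, total_workers = 0,
                   max_standing_workers = 0, max_R = 0, n_nests = n_nests,
                   trajectory = NULL),
              class = "season_result")
  }
  if (n_nests == 0L) {
    warning("no nests in the landscape; season outputs are 0")
    return(empty())
  }
  prog <- .prog(series$days, series$progression)
  we <- which(prog >= colony$phi)[1]
  if (is.na(we)) return(empty())

  ctx <- context %||% .season_context(grid, series, foraging, pollination)
  state <- colony_state()
  nT <- ctx$nT
  n_steps <- nT - we + 1L
  traj <- if (keep_trajectory) {
    data.frame(week = series$weeks[we:nT], day = series$days[we:nT],
               progression = prog[we:nT],
               stage = character(n_steps), X = numeric(n_steps),
               R = numeric(n_steps), w = numeric(n_steps),
               workers_produced = numeric(n_steps),
               queens_produced = numeric(n_steps),
               W = numeric(n_steps), Q = numeric(n_steps),
               P = numeric(n_steps))
  } else NULL
  P_all <- numeric(n_steps)
  maxW <- 0; max_stand <- 0; max_R <- 0
  for (k in seq_len(n_steps)) {
    ti <- we + k - 1L
    tol <- colony$b3_rel_tol * (b3_ref_max_R %||% state$max_R_seen)
    state <- advance_stage(state, prog[ti], colony, tol)
    X <- foragers(state, colony)
    fr <- .week_forage(ctx, ti, X)
    state <- step_week(state, fr$R, colony)
    P_all[k] <- fr$P
    maxW <- max(maxW, state$last_workers_produced)
    max_stand <- max(max_stand, state$W)
    max_R <- max(max_R, fr$R)
    if (keep_trajectory) {
      traj$stage[k] <- state$stage; traj$X[k] <- X; traj$R[k] <- fr$R
      traj$w[k] <- state$last_w
      traj$workers_produced[k] <- state$last_workers_produced
      traj$queens_produced[k] <- state$last_queens_produced
      traj$W[k] <- state$W; traj$Q[k] <- state$Q; traj$P[k] <- fr$P
    }
  }
  structure(list(MaxW = maxW, TQ = state$cum_queens, PS = season_score(P_all),
                 total_workers = state$cum_workers,
                 max_standing_workers = max_stand, max_R = max_R,
                 n_nests = n_nests, trajectory = traj),
            class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat("season_result (", x$n_nests, " nests)\n", sep = "")
  cat(sprintf("  MaxW (peak weekly worker production/nest): %.2f\n", x$MaxW))
  cat(sprintf("  total workers produced/nest:               %.2f\n", x$total_workers))
  cat(sprintf("  TQ (daughter queens produced/nest):        %.2f\n", x$TQ))
  cat(sprintf("  PS (seasonal pollination score):           %.2f\n", x$PS))
  invisible(x)
}

#' Write the weekly trajectory of a season to CSV
#'
#' @param result A `season_result` run with `keep_trajectory = TRUE`.
#' @param file Path of the CSV file.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(result, file) {
  if (is.null(result$trajectory)) stop("season was run without a trajectory")
  write.csv(result$trajectory, file, row.names = FALSE)
  invisible(file)
}
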