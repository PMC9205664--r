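test_that("the production plateau matches its closed forms", {
  expect_equal(production(0, 0, 50, 5), 0)
  # at R1 + R2 = 2 beta, w = alpha (1 - 1/e)
  expect_equal(production(6, 4, 50, 5), 50 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(production(6, 4, 50, 5), 31.60603, tolerance = 1e-5)
  # saturates below alpha
  expect_lt(production(100, 100, 50, 5), 50)
  expect_equal(production(1e6, 1e6, 50, 5), 50, tolerance = 1e-6)
  expect_error(colony_params(phi = 40, mu = 30), "phi < mu < psi")
  expect_error(colony_params(delta = 1.2), "delta")
})

test_that("stage transitions follow the priority order", {
  cp <- colony_params()
  s <- colony_state()
  # A1 holds for the configured duration, then A2
  expect_identical(advance_stage(s, 15, cp)$stage, "A1")
  s$weeks_in_stage <- 2L
  expect_identical(advance_stage(s, 15, cp)$stage, "A2")
  # below mu three weeks after emergence the colony is still in A2
  s2 <- advance_stage(s, cp$mu - 1, cp)
  expect_identical(s2$stage, "A2")
  # reaching mu moves to B1; reaching psi moves to B2 (chained if both passed)
  expect_identical(advance_stage(s, cp$mu, cp)$stage, "B1")
  expect_identical(advance_stage(s, cp$psi, cp)$stage, "B2")
  # two consecutive negligible-R weeks during worker stages trigger B3
  s3 <- advance_stage(s, cp$mu, cp)
  s3$n_R <- 10L; s3$max_R_seen <- 8; s3$R_hist <- c(0.001, 0.002)
  expect_identical(advance_stage(s3, 70, cp, b3_tol = 0.008)$stage, "B3")
  # but not while the queen is still the only forager
  s4 <- s; s4$n_R <- 3L; s4$max_R_seen <- 8; s4$R_hist <- c(0, 0)
  expect_identical(advance_stage(s4, 20, cp, b3_tol = 0.008)$stage, "A2")
})

test_that("weekly updates split production by stage and decay in B3", {
  cp <- colony_params(alpha = 50, beta = 5, delta = 0.9, epsilon = 0.7)
  s <- colony_state()
  s$stage <- "B2"; s$W <- 100; s$Q <- 10
  s$R_hist <- c(1e9, 1e9)  # w -> alpha = 50... but strictly below
  s2 <- step_week(s, 3, cp)
  w <- production(1e9, 1e9, 50, 5)
  expect_equal(s2$W, 0.9 * 100 + 0.7 * w)
  expect_equal(s2$Q, 0.9 * 10 + 0.3 * w)
  expect_equal(s2$last_workers_produced, 0.7 * w)
  expect_equal(s2$last_queens_produced, 0.3 * w)
  expect_equal(s2$R_hist, c(3, 1e9))
  # B3: nothing produced, survival decays multiplicatively, W and Q -> 0
  s3 <- s; s3$stage <- "B3"
  for (i in 1:30) s3 <- step_week(s3, 0, cp)
  expect_equal(s3$last_w, 0)
  expect_lt(s3$W, 1e-6)
  expect_lt(s3$Q, 1e-6)
  expect_true(s3$W >= 0 && s3$Q >= 0)
})

test_that("a hand-computed two-week recursion matches step_week", {
  # spreadsheet-style oracle of the update equations
  cp <- colony_params(alpha = 40, beta = 2, delta = 0.8, epsilon = 0.6)
  s <- colony_state(); s$stage <- "A2"
  s$R_hist <- c(1, 0.5)
  s <- step_week(s, 2, cp)
  w1 <- 40 * (1 - exp(-(1 + 0.5) / 4))
  expect_equal(s$W, w1, tolerance = 1e-12)
  s$stage <- "B1"
  s <- step_week(s, 4, cp)
  w2 <- 40 * (1 - exp(-(2 + 1) / 4))
  expect_equal(s$W, 0.8 * w1 + w2, tolerance = 1e-12)
  expect_equal(s$cum_workers, w1 + w2, tolerance = 1e-12)
  expect_identical(s$Q, 0)
})

test_that("foragers are one queen early and pw workers later", {
  cp <- colony_params(pw = 0.4)
  s <- colony_state(); s$W <- 50
  for (st in c("A1", "A2")) { s$stage <- st; expect_equal(foragers(s, cp), 1) }
  for (st in c("B1", "B2", "B3")) { s$stage <- st; expect_equal(foragers(s, cp), 50 * 0.4) }
})

test_that("a season without floral resources produces nothing", {
  land <- small_landscape(seed = 31)
  series <- build_floral_series(land)
  series$F[] <- 0
  res <- run_season(land, series)
  expect_equal(res$MaxW, 0)
  expect_equal(res$TQ, 0)
  expect_equal(res$PS, 0)
  expect_equal(res$total_workers, 0)
  # no nests: outputs defined as zero with a warning
  land0 <- generate_landscape(landscape_config(snh_proportion = 0,
                                               bee_habitat_total = 0.5, seed = 1,
                                               side_length_m = 400))
  land0 <- place_nests(land0)
  expect_warning(res0 <- run_season(land0, build_floral_series(land0)), "no nests")
  expect_equal(res0$MaxW, 0)
})

test_that("season trajectories respect the structural invariants", {
  land <- small_landscape(seed = 32)
  series <- build_floral_series(land)
  cp <- colony_params()
  res <- run_season(land, series, cp)
  tr <- res$trajectory
  # production stays below the plateau; stocks stay non-negative
  expect_true(all(tr$w >= 0 & tr$w < cp$alpha))
  expect_lt(res$MaxW, cp$alpha)
  expect_true(all(tr$W >= 0 & tr$Q >= 0))
  # no queens before stage B2
  expect_true(all(tr$Q[tr$stage %in% c("A1", "A2", "B1")] == 0))
  # stages appear in order and never revert
  order_seen <- match(unique(tr$stage), c("A1", "A2", "B1", "B2", "B3"))
  expect_true(all(diff(order_seen) > 0))
  # single worker peak then decline; queens rise after psi
  expect_gt(res$TQ, 0)
  first_b2 <- which(tr$stage == "B2")[1]
  expect_gt(tr$progression[first_b2], cp$psi - 5)
  # reruns are bit-identical
  res2 <- run_season(land, series, cp)
  expect_identical(res$trajectory, res2$trajectory)
})

test_that("scaling floral resources up never reduces the season outputs", {
  land <- small_landscape(seed = 33)
  series <- build_floral_series(land)
  low <- series; low$F <- series$F * 0.5
  high <- series
  r_low <- run_season(land, low, keep_trajectory = FALSE)
  r_high <- run_season(land, high, keep_trajectory = FALSE)
  expect_gte(r_high$MaxW, r_low$MaxW)
  expect_gte(r_high$TQ, r_low$TQ)
  expect_gte(r_high$PS, r_low$PS)
  expect_gte(r_high$total_workers, r_low$total_workers)
})

test_that("drought season outputs never exceed the control's", {
  for (seed in c(34, 35)) {
    land <- small_landscape(seed = seed)
    series <- build_floral_series(land)
    ctrl <- run_season(land, series, keep_trajectory = FALSE)
    for (dur in c(2, 4)) {
      dry_series <- apply_drought(series, drought_scenario(duration_weeks = dur))
      dry <- run_season(land, dry_series, b3_ref_max_R = ctrl$max_R,
                        keep_trajectory = FALSE)
      expect_lte(dry$MaxW, ctrl$MaxW + 1e-9)
      expect_lte(dry$TQ, ctrl$TQ + 1e-9)
      expect_lte(dry$PS, ctrl$PS + 1e-9)
      expect_lte(dry$total_workers, ctrl$total_workers + 1e-9)
    }
  }
})
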