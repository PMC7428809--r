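test_that("identical parameters and seed give bit-identical runs", {
  p <- sim_params(grid_rows = 2, grid_cols = 2, max_days = 400)
  a <- run_simulation(p, seed = 9, record_events = TRUE)
  b <- run_simulation(p, seed = 9, record_events = TRUE)
  expect_identical(a[setdiff(names(a), "params")],
                   b[setdiff(names(b), "params")])
  c <- run_simulation(p, seed = 10, record_events = TRUE)
  expect_false(identical(a$events, c$events))
})

test_that("without any mutational path the run is censored at the horizon", {
  p <- quiet_params(max_days = 3000)
  run <- run_simulation(p, seed = 4)
  expect_identical(run$endpoint, "censored")
  expect_identical(run$endpoint_time, 3000)
  expect_identical(sum(run$mutation_counts), 0)
})

test_that("event log times are non-decreasing and population accounting is exact", {
  p <- sim_params(grid_rows = 2, grid_cols = 2, max_days = 500,
                  mutation_rate = 0.01, tsg_mutation_rate = 0)
  run <- run_simulation(p, seed = 3, record_events = TRUE)
  ev <- run$events
  expect_gt(nrow(ev), 1000)
  expect_true(all(diff(ev$time) >= 0))
  delta <- ifelse(ev$event_kind == "symmetric_division", 1L,
                  ifelse(ev$event_kind == "cell_loss", -1L, 0L))
  n0 <- p$crypt_size * p$grid_rows * p$grid_cols
  expect_identical(n0 + sum(delta), run$n_living_cells)
  # per-crypt census column agrees with a replay of that crypt's events
  one <- ev[ev$q == 0 & ev$r == 0 &
              ev$event_kind %in% c("symmetric_division", "cell_loss"), ]
  replay <- p$crypt_size + cumsum(ifelse(one$event_kind == "symmetric_division",
                                         1L, -1L))
  expect_identical(one$n_cells_after, replay)
})

test_that("event kind frequencies match the competing-clock rates", {
  # feedback disabled via a huge deviation scale; floors off so the clocks
  # are exactly exponential: kinds arrive in proportion sym : asym : loss
  p <- quiet_params(max_days = 500, crypt_deviation = 1e12,
                    division_min_time = 0)
  counts <- c(symmetric_division = 0, asymmetric_division = 0, cell_loss = 0)
  for (s in 1:3) {
    run <- run_simulation(p, seed = s, record_events = TRUE)
    counts <- counts + table(factor(run$events$event_kind, levels = names(counts)))
  }
  n <- sum(counts)
  probs <- c(0.05, 1.0, 0.04878) / (0.05 + 1.0 + 0.04878)
  for (i in 1:3) {
    se <- sqrt(probs[i] * (1 - probs[i]) / n)
    expect_lt(abs(counts[i] / n - probs[i]), 4 * se)
  }
})

test_that("no division is scheduled sooner than the minimum division time", {
  p <- quiet_params(max_days = 200, division_min_time = 0.05)
  run <- run_simulation(p, seed = 12, record_events = TRUE)
  ev <- run$events
  div <- ev$event_kind %in% c("symmetric_division", "asymmetric_division")
  # the floor is a guarantee on each cell's own division clock: a cell's
  # clock is always (re)drawn no earlier than its previous division, so
  # consecutive divisions of one cell can never be closer than the floor
  per_cell <- split(ev$time[div], ev$cell_id[div])
  spacing <- unlist(lapply(per_cell, diff), use.names = FALSE)
  expect_true(all(spacing >= 0.05 - 1e-12))
})

test_that("a TSG path exists: high hit rates end runs in initiation", {
  p <- sim_params(grid_rows = 2, grid_cols = 2, max_days = 29220,
                  mutation_rate = 0, tsg_mutation_rate = 0.02,
                  tsg_mutation_rate_max = 0.02)
  run <- run_simulation(p, seed = 5, record_events = TRUE)
  expect_identical(run$endpoint, "initiation")
  expect_false(run$initiating_cell_was_mutator)  # no mutator path configured
  expect_lt(run$endpoint_time, 29220)
  expect_true(all(run$snapshot$max_tsg_hits <= p$tsg_hits_for_initiation))
})

test_that("single-cell crypts make the tissue fragile, ten-cell crypts stable", {
  p1 <- sim_params(grid_rows = 3, grid_cols = 3, crypt_size = 1,
                   max_days = 29220)
  small <- summarize_runs(run_replicates(p1, 10, base_seed = 1))
  # whole-tissue extinction happens, and surviving tissues are degraded
  expect_gt(sum(small$endpoint == "tissue_death"), 0)
  expect_lt(mean(small$n_living_crypts_final), 9)
  p10 <- sim_params(grid_rows = 3, grid_cols = 3, crypt_size = 10,
                    max_days = 2000)
  big <- summarize_runs(run_replicates(p10, 5, base_seed = 1))
  expect_true(all(big$endpoint != "tissue_death"))
  expect_true(all(big$n_living_crypts_final == 9))
})

test_that("uncontrolled proliferation is detectable when enabled", {
  p <- sim_params(grid_rows = 1, grid_cols = 1, uncontrolled_threshold = 1.3,
                  mutation_rate = 0, tsg_mutation_rate = 0, max_days = 5000)
  run <- run_simulation(p, seed = 2, enable_uncontrolled = TRUE)
  expect_identical(run$endpoint, "uncontrolled_proliferation")
  # same configuration without the switch runs to the horizon
  off <- run_simulation(p, seed = 2)
  expect_identical(off$endpoint, "censored")
})

test_that("replicates derive distinct reproducible seeds", {
  p <- quiet_params(max_days = 300)
  runs <- run_replicates(p, 3, base_seed = 7)
  expect_identical(vapply(runs, function(x) x$seed, 1), c(7, 8, 9))
  again <- run_replicates(p, 3, base_seed = 7)
  expect_identical(summarize_runs(runs), summarize_runs(again))
  expect_error(run_replicates(p, 0), "n_replicates")
  f <- withr::local_tempfile(fileext = ".csv")
  run_replicates(p, 2, base_seed = 1, out_file = f)
  expect_identical(nrow(utils::read.csv(f)), 2L)
})

test_that("time-averaged census matches a direct integral of the trajectory", {
  p <- quiet_params(max_days = 300)
  run <- run_simulation(p, seed = 8, record_events = TRUE)
  traj <- population_trajectory(run)
  # direct Riemann integral over the step function on [100, 300]
  times <- c(traj$time, 300)
  w <- pmax(pmin(times[-1], 300) - pmax(times[-length(times)], 100), 0)
  expect_equal(time_averaged_cells(run, 100, 300),
               sum(traj$n_cells * w) / 200, tolerance = 1e-12)
  expect_error(population_trajectory(run_simulation(p, 8)), "record_events")
})
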