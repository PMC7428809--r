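test_that("product-limit survival and hazard match hand computation", {
  # events at t = 2 and 5, censored at 3 and 7
  tab <- km_cumulative_hazard(c(2, 3, 5, 7), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tab$time, c(2, 3, 5, 7))
  expect_equal(tab$n_at_risk, c(4, 3, 2, 1))
  expect_equal(tab$survival[tab$time == 2], 0.75)
  expect_equal(tab$survival[tab$time == 5], 0.375)
  expect_equal(tab$cumulative_hazard[tab$time == 5], -log(0.375),
               tolerance = 1e-12)
})

test_that("degenerate survival inputs behave as documented", {
  all_cens <- km_cumulative_hazard(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(all_cens$survival == 1))
  expect_true(all(all_cens$cumulative_hazard == 0))
  single <- km_cumulative_hazard(1, TRUE)
  expect_identical(single$survival, 0)
  expect_identical(single$cumulative_hazard, Inf)
  expect_error(km_cumulative_hazard(numeric(0), logical(0)), "no subjects")
  expect_error(km_cumulative_hazard(c(1, 2), TRUE), "equal length")
})

test_that("survival table invariants hold on random censored samples", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:20, 1)
    times <- sample(1:8, n, replace = TRUE)    # forces ties
    events <- stats::runif(n) < 0.7
    tab <- km_cumulative_hazard(times, events)
    expect_true(all(diff(tab$time) > 0))
    expect_true(all(diff(tab$survival) <= 1e-15))
    expect_true(all(diff(tab$cumulative_hazard) >= -1e-15))
    pos <- tab$survival > 0
    expect_equal(tab$cumulative_hazard[pos], -log(tab$survival[pos]),
                 tolerance = 1e-12)
  }
})

test_that("Nelson-Aalen option accumulates d over n at risk", {
  tab <- km_cumulative_hazard(c(2, 3, 5, 7), c(TRUE, FALSE, TRUE, FALSE),
                              method = "nelson-aalen")
  expect_equal(tab$cumulative_hazard[tab$time == 5], 1 / 4 + 1 / 2)
})

test_that("mutator fixation counts only fully mutator crypts among the living", {
  snap <- data.frame(q = 0:4, r = 0, alive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                     n_cells = c(10, 10, 10, 10, 0),
                     n_mutator = c(10, 9, 0, 10, 0))
  expect_equal(mutator_fixed_fraction(snap), 0.5)
  none <- snap; none$n_mutator <- 0
  expect_equal(mutator_fixed_fraction(none), 0)
  dead <- snap; dead$alive <- FALSE
  expect_warning(out <- mutator_fixed_fraction(dead), "no living crypts")
  expect_true(is.na(out))
})

test_that("mutator agreement by distance matches brute force on small tissues", {
  # three mutually adjacent crypts, statuses fixed / fixed / not
  snap <- data.frame(q = c(0, 1, 0), r = c(0, 0, 1), alive = TRUE,
                     n_cells = 5, n_mutator = c(5, 5, 0))
  ag <- mutator_agreement_by_distance(snap)
  expect_equal(ag$distance, 1)
  expect_equal(ag$n_pairs, 3L)
  expect_equal(ag$agreement, 1 / 3)
  # all fixed: agreement 1 in every distance class
  uni <- data.frame(q = c(0, 1, 2, 0), r = c(0, 0, 0, 1), alive = TRUE,
                    n_cells = 3, n_mutator = 3)
  agu <- mutator_agreement_by_distance(uni)
  expect_true(all(agu$agreement == 1))
  expect_equal(sum(agu$n_pairs), choose(4, 2))
  expect_error(mutator_agreement_by_distance(snap[1, ]), "2 living crypts")
})

test_that("agreement is invariant under lattice relabeling", {
  set.seed(13)
  snap <- data.frame(q = rep(0:3, each = 4), r = rep(0:3, 4), alive = TRUE,
                     n_cells = 4,
                     n_mutator = sample(c(0, 4), 16, replace = TRUE))
  base <- mutator_agreement_by_distance(snap)
  # 180-degree rotation of the axial plane: (q, r) -> (-q, -r)
  rot <- snap; rot$q <- -snap$q; rot$r <- -snap$r
  expect_equal(mutator_agreement_by_distance(rot), base)
})

test_that("crypt fitness is the genotype-intrinsic rate gap", {
  p <- sim_params()
  expect_equal(crypt_fitness(make_crypt(10), p), 0.05 - 0.04878,
               tolerance = 1e-12)
  del <- make_crypt(10, mutate_with = function(cell) {
    cell$n_deleterious_div <- 1L; cell
  })
  expect_equal(crypt_fitness(del, p), 0.05 / 1.01 - 0.04878, tolerance = 1e-12)
  balanced <- make_crypt(10, mutate_with = function(cell) {
    cell$n_deleterious_div <- 1L; cell$n_beneficial_div <- 1L; cell
  })
  expect_equal(crypt_fitness(balanced, p), 0.05 - 0.04878, tolerance = 1e-12)
  expect_error(crypt_fitness(new_crypt(list(), c(0, 0)), p), "dead crypt")
})

test_that("snapshot-based fitness agrees with the cell-level definition", {
  p <- sim_params(grid_rows = 2, grid_cols = 2, max_days = 2000,
                  mutation_rate = 0.01, tsg_mutation_rate = 0)
  run <- run_simulation(p, seed = 21)
  fit <- tissue_crypt_fitness(run)
  expect_identical(nrow(fit), sum(run$snapshot$alive))
  # unmutated baseline bound: fitness near the base gap, shifted by load
  expect_true(all(is.finite(fit$fitness)))
  snap <- run$snapshot[run$snapshot$alive, ]
  manual <- p$base_division_rate * snap$mean_div_fitness -
    p$base_loss_rate * snap$mean_loss_fitness
  expect_equal(fit$fitness, manual)
})

test_that("turnover and burden metrics summarize the logs arithmetically", {
  run <- list(
    endpoint = "censored", endpoint_time = 3000,
    mutation_counts = c(a = 100, b = 200),
    n_symmetric_divisions = 1500, n_asymmetric_divisions = 30000,
    cell_time_integral = 250 * 3000, crypt_time_integral = 25 * 3000,
    turnover = data.frame(
      event = c("crypt_birth", "crypt_birth", "crypt_death"),
      time = c(100, 200, 150),
      lifespan = c(NA, NA, 150)))
  m <- turnover_and_burden_metrics(run)
  expect_identical(m$crypt_births, 2L)
  expect_identical(m$crypt_deaths, 1L)
  expect_equal(m$mean_crypt_lifespan, 150)
  expect_equal(m$mutations_per_day, 0.1)
  expect_equal(m$divisions_per_day, 10.5)
  expect_equal(m$mean_cells_per_crypt, 10)
  empty <- run
  empty$turnover <- run$turnover[0, ]
  m0 <- turnover_and_burden_metrics(empty)
  expect_identical(m0$crypt_births, 0L)
  expect_true(is.na(m0$mean_crypt_lifespan))
})
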