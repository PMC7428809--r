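test_that("fitness multipliers are the constant factor to the signed power", {
  expect_equal(fitness_multiplier(1, 0, 1.01), 1.01, tolerance = 1e-15)
  expect_equal(fitness_multiplier(0, 0, 1.01), 1)
  expect_equal(fitness_multiplier(2, 1, 1.01), 1.01, tolerance = 1e-12)
  expect_error(fitness_multiplier(-1, 0, 1.01))
  expect_error(fitness_multiplier(0.5, 0, 1.01))
  expect_error(fitness_multiplier(1, 0, 0))
})

test_that("one extra beneficial mutation multiplies fitness by k", {
  k <- 1.01
  for (a in 0:6) for (b in 0:6) {
    expect_equal(fitness_multiplier(a + 1, b, k) /
                   fitness_multiplier(a, b, k), k, tolerance = 1e-12)
  }
})

test_that("effective rates reproduce the feedback laws by hand", {
  p <- sim_params()
  cell <- stem_cell()

  at_target <- effective_rates(cell, n_cells = 10, n_dead_neighbors = 0, p)
  expect_equal(at_target$symmetric_division_rate, 0.05, tolerance = 1e-12)
  expect_equal(at_target$asymmetric_division_rate, 1.0, tolerance = 1e-12)
  expect_equal(at_target$loss_rate, 0.04878, tolerance = 1e-12)

  # two excess cells at deviation 2 double the loss rate
  over <- effective_rates(cell, n_cells = 12, n_dead_neighbors = 0, p)
  expect_equal(over$loss_rate, 0.09756, tolerance = 1e-12)
  expect_equal(over$symmetric_division_rate, 0.05, tolerance = 1e-12)

  # four missing cells at deviation 2 quadruple the division rate
  under <- effective_rates(cell, n_cells = 6, n_dead_neighbors = 0, p)
  expect_equal(under$symmetric_division_rate, 0.2, tolerance = 1e-12)
  expect_equal(under$loss_rate, 0.04878, tolerance = 1e-12)

  # a dead neighbor doubles division and suppresses the loss feedback
  released <- effective_rates(cell, n_cells = 10, n_dead_neighbors = 1, p)
  expect_equal(released$symmetric_division_rate, 0.1, tolerance = 1e-12)
  over_released <- effective_rates(cell, n_cells = 12, n_dead_neighbors = 1, p)
  expect_equal(over_released$loss_rate, 0.04878, tolerance = 1e-12)
})

test_that("genotype shifts rates in the documented directions", {
  p <- sim_params()
  del_div <- effective_rates(stem_cell(n_deleterious_div = 1), 10, 0, p)
  expect_equal(del_div$symmetric_division_rate, 0.05 / 1.01, tolerance = 1e-12)
  del_surv <- effective_rates(stem_cell(n_deleterious_surv = 1), 10, 0, p)
  expect_equal(del_surv$loss_rate, 0.04878 * 1.01, tolerance = 1e-12)
  ben_surv <- effective_rates(stem_cell(n_beneficial_surv = 1), 10, 0, p)
  expect_equal(ben_surv$loss_rate, 0.04878 / 1.01, tolerance = 1e-12)
})

test_that("rate laws are monotone in population and in deleterious load", {
  p <- sim_params()
  cell <- stem_cell()
  sym <- sapply(1:30, function(n) {
    effective_rates(cell, n, 0, p)$symmetric_division_rate
  })
  loss <- sapply(1:30, function(n) effective_rates(cell, n, 0, p)$loss_rate)
  expect_true(all(diff(sym) <= 0))
  expect_true(all(diff(loss) >= 0))
  by_load <- sapply(0:10, function(m) {
    effective_rates(stem_cell(n_deleterious_div = m), 10, 0, p)$symmetric_division_rate
  })
  expect_true(all(diff(by_load) < 0))
})

test_that("mutation probabilities scale with mutator status and respect the caps", {
  p <- sim_params()
  expect_equal(cell_mutation_rate(stem_cell(), p),
               c(general = 5e-4, tsg = 5e-7))
  expect_equal(cell_mutation_rate(stem_cell(is_mutator = TRUE), p),
               c(general = 5e-2, tsg = 5e-5))
  p10 <- sim_params(mutator_factor = 10)
  expect_equal(cell_mutation_rate(stem_cell(is_mutator = TRUE), p10),
               c(general = 5e-3, tsg = 5e-6))
  # caps hold for arbitrary factors
  for (f in c(1, 10, 1e3, 1e6)) {
    pf <- sim_params(mutator_factor = f)
    r <- cell_mutation_rate(stem_cell(is_mutator = TRUE), pf)
    expect_lte(r[["general"]], pf$mutation_rate_max)
    expect_lte(r[["tsg"]], pf$tsg_mutation_rate_max)
  }
})

test_that("loss time is the minimum of competing exponential clocks", {
  set.seed(11)
  expect_identical(sample_loss_time(0, 0), Inf)
  # degenerate min: one clock, exponential with its rate
  x <- replicate(2e4, sample_loss_time(0.2, 0))
  expect_gt(suppressWarnings(stats::ks.test(x, "pexp", 0.2))$p.value, 0.01)
  # two clocks: mean matches 1/(a + b) within 3 standard errors
  a <- 0.3; b <- 0.7
  y <- replicate(2e4, sample_loss_time(a, b))
  se <- 1 / (a + b) / sqrt(length(y))
  expect_lt(abs(mean(y) - 1 / (a + b)), 3 * se)
  # floor applies
  z <- replicate(100, sample_loss_time(100, 100, loss_min_time = 0.5))
  expect_true(all(z >= 0.5))
})

test_that("mutation category frequencies follow the configured proportions", {
  set.seed(7)
  draw_categories <- function(p, n = 2e4) {
    cats <- replicate(n, {
      ev <- sample_mutation(stem_cell(), p)$events
      if (nrow(ev) == 0) "none" else ev$category[1]
    })
    table(factor(cats, levels = c("deleterious_div", "deleterious_surv",
                                  "beneficial_div", "beneficial_surv",
                                  "mutator")))
  }
  # every opportunity mutates: categories split 25/25/20/20/10
  p <- sim_params(mutation_rate = 1, mutation_rate_max = 1,
                  deleterious_fraction = 0.5)
  tab <- draw_categories(p)
  expect_gt(stats::chisq.test(tab, p = c(.25, .25, .2, .2, .1))$p.value, 1e-3)
  # 95% deleterious: mutator probability drops to 1%
  p95 <- sim_params(mutation_rate = 1, mutation_rate_max = 1,
                    deleterious_fraction = 0.95)
  tab95 <- draw_categories(p95)
  expect_gt(stats::chisq.test(tab95, p = c(.475, .475, .02, .02, .01))$p.value, 1e-3)
})

test_that("mutation draws honor zero rates, mutator idempotence and the TSG cap", {
  p0 <- sim_params(mutation_rate = 0, tsg_mutation_rate = 0)
  set.seed(1)
  for (i in 1:50) {
    expect_identical(nrow(sample_mutation(stem_cell(), p0)$events), 0L)
  }
  # a mutator event on an existing mutator changes nothing further
  pm <- sim_params(mutation_rate = 1, mutation_rate_max = 1,
                   deleterious_fraction = 0, beneficial_split = c(0, 0, 1))
  set.seed(2)
  out <- sample_mutation(stem_cell(is_mutator = TRUE), pm)
  expect_true(out$cell$is_mutator)
  expect_identical(out$cell$n_beneficial_div, 0L)
  # tsg_hits saturates at tsg_hits_for_initiation
  pt <- sim_params(mutation_rate = 0, tsg_mutation_rate = 1,
                   tsg_mutation_rate_max = 1)
  cell <- stem_cell(tsg_hits = 2)
  set.seed(3)
  expect_identical(sample_mutation(cell, pt)$cell$tsg_hits, 2L)
})
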