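#' Stem-cell state
#'
#' A stem cell is described by its accumulated mutation counts per category,
#' its mutator status, and the number of hits to the tumor suppressor gene.
#' Counts only ever accumulate over a cell's lifetime.
#'
#' @param n_beneficial_div,n_beneficial_surv Counts of beneficial mutations
#'   affecting the division and loss rates.
#' @param n_deleterious_div,n_deleterious_surv Counts of deleterious
#'   mutations affecting the division and loss rates.
#' @param is_mutator Whether the cell carries the (single-hit) mutator
#'   phenotype.
#' @param tsg_hits Inactivated alleles of the tumor suppressor gene (0, 1 or
#'   2 under the defaults; the first hit is neutral).
#' @param unique_id Identifier, arbitrary.
#' @param birth_time Time (days) the cell was created.
#' @return An object of class `stem_cell`.
#' @examples
#' stem_cell(is_mutator = TRUE, tsg_hits = 1)
#' @export
stem_cell <- function(n_beneficial_div = 0, n_beneficial_surv = 0,
                      n_deleterious_div = 0, n_deleterious_surv = 0,
                      is_mutator = FALSE, tsg_hits = 0,
                      unique_id = 0L, birth_time = 0) {
  counts <- c(n_beneficial_div, n_beneficial_surv,
              n_deleterious_div, n_deleterious_surv, tsg_hits)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("mutation counts and tsg_hits must be non-negative integers")
  }
  structure(list(n_beneficial_div = as.integer(n_beneficial_div),
                 n_beneficial_surv = as.integer(n_beneficial_surv),
                 n_deleterious_div = as.integer(n_deleterious_div),
                 n_deleterious_surv = as.integer(n_deleterious_surv),
                 is_mutator = isTRUE(is_mutator),
                 tsg_hits = as.integer(tsg_hits),
                 unique_id = unique_id,
                 birth_time = birth_time),
            class = "stem_cell")
}

#' Multiplicative fitness of accumulated mutations
#'
#' Each beneficial mutation multiplies the affected rate by the constant
#' factor `k_fitness`, each deleterious mutation by its reciprocal, so the
#' combined effect of `n_beneficial` and `n_deleterious` mutations is
#' `k_fitness^n_beneficial * (1/k_fitness)^n_deleterious`.
#'
#' @param n_beneficial,n_deleterious Non-negative integer mutation counts.
#' @param k_fitness Per-mutation fitness factor (> 0).
#' @return The strictly positive multiplier.
#' @examples
#' fitness_multiplier(1, 0, 1.01)  # 1.01
#' fitness_multiplier(2, 1, 1.01)  # 1.01: one pair cancels
#' @export
fitness_multiplier <- function(n_beneficial, n_deleterious, k_fitness) {
  if (any(n_beneficial < 0) || any(n_deleterious < 0) ||
      any(n_beneficial != round(n_beneficial)) ||
      any(n_deleterious != round(n_deleterious))) {
    stop("mutation counts must be non-negative integers")
  }
  if (any(k_fitness <= 0)) stop("k_fitness must be > 0")
  k_fitness^n_beneficial * (1 / k_fitness)^n_deleterious
}

#' Effective per-cell event rates under homeostatic feedback
#'
#' Computes the symmetric division, asymmetric division and loss rates of a
#' stem cell given its genotype, its crypt's current population, and the
#' number of adjacent dead crypt slots.
#'
#' The symmetric division rate is the base rate times the cell's division
#' fitness, times the division feedback
#' `division_effect_base^(max(0, crypt_size - n_cells)/crypt_deviation)`,
#' times `dead_neighbor_division_multiplier` once per dead neighbor. The
#' asymmetric rate is `asym_to_sym_ratio` times the symmetric rate. The loss
#' rate is the base loss rate times the cell's survival (loss) fitness --
#' deleterious survival mutations multiply it by `fitness_factor`,
#' beneficial ones by its reciprocal -- times the loss feedback
#' `loss_effect_base^(max(0, n_cells - crypt_size)/crypt_deviation)`, which
#' is suppressed entirely while the crypt has any dead neighbor.
#'
#' @param cell A [stem_cell()].
#' @param n_cells Current number of living stem cells in the cell's crypt
#'   (>= 1).
#' @param n_dead_neighbors Number of adjacent dead crypt slots (>= 0).
#' @param p A [sim_params()] object.
#' @return A list with components `symmetric_division_rate`,
#'   `asymmetric_division_rate` and `loss_rate` (per day).
#' @examples
#' p <- sim_params()
#' effective_rates(stem_cell(), n_cells = 12, n_dead_neighbors = 0, p)$loss_rate
#' # 0.09756: one excess cell doubles the loss feedback at crypt_deviation 2
#' @export
effective_rates <- function(cell, n_cells, n_dead_neighbors, p) {
  stopifnot(n_cells >= 1, n_dead_neighbors >= 0)
  k <- p$fitness_factor
  fit_div <- fitness_multiplier(cell$n_beneficial_div, cell$n_deleterious_div, k)
  div_feedback <- p$division_effect_base ^
    (max(0, p$crypt_size - n_cells) / p$crypt_deviation)
  sym <- p$base_division_rate * fit_div * div_feedback *
    p$dead_neighbor_division_multiplier ^ n_dead_neighbors
  fit_loss <- k ^ cell$n_deleterious_surv * (1 / k) ^ cell$n_beneficial_surv
  loss_feedback <- if (n_dead_neighbors > 0) 1 else
    p$loss_effect_base ^ (max(0, n_cells - p$crypt_size) / p$crypt_deviation)
  list(symmetric_division_rate = sym,
       asymmetric_division_rate = p$asym_to_sym_ratio * sym,
       loss_rate = p$base_loss_rate * fit_loss * loss_feedback)
}

#' Competing-clock loss time
#'
#' Time to stem-cell loss as the minimum of a background clock and a
#' feedback clock, each exponential with the given rate, floored at
#' `loss_min_time`. Equivalent in distribution to a single exponential with
#' the summed rates. A rate of zero removes that clock; if both rates are
#' zero the event never happens and `Inf` is returned.
#'
#' @param loss_rate_background,loss_rate_feedback Non-negative rates per day.
#' @param loss_min_time Floor (days) on the sampled time, default 0.
#' @return A single waiting time in days (possibly `Inf`).
#' @export
sample_loss_time <- function(loss_rate_background, loss_rate_feedback,
                             loss_min_time = 0) {
  stopifnot(loss_rate_background >= 0, loss_rate_feedback >= 0)
  draw <- function(r) if (r > 0) stats::rexp(1, r) else Inf
  t <- min(draw(loss_rate_background), draw(loss_rate_feedback))
  max(t, loss_min_time)
}

#' Per-cell mutation probabilities
#'
#' The general (fitness/mutator) and TSG mutation probabilities per division
#' opportunity, scaled `mutator_factor`-fold in mutator cells and capped at
#' `mutation_rate_max` and `tsg_mutation_rate_max`.
#'
#' @param cell A [stem_cell()].
#' @param p A [sim_params()] object.
#' @return Named numeric vector `c(general = , tsg = )`.
#' @examples
#' p <- sim_params()
#' cell_mutation_rate(stem_cell(), p)                    # 5e-4, 5e-7
#' cell_mutation_rate(stem_cell(is_mutator = TRUE), p)   # caps bind: 5e-2, 5e-5
#' @export
cell_mutation_rate <- function(cell, p) {
  f <- if (isTRUE(cell$is_mutator)) p$mutator_factor else 1
  c(general = min(p$mutation_rate * f, p$mutation_rate_max),
    tsg = min(p$tsg_mutation_rate * f, p$tsg_mutation_rate_max))
}

#' Sample the mutations acquired at one division opportunity
#'
#' With the cell's general mutation probability, one fitness/mutator event
#' is drawn: deleterious with probability `deleterious_fraction` (then split
#' between division and survival effects by `deleterious_split`), otherwise
#' beneficial-category (split by `beneficial_split` between division,
#' survival, and the mutator phenotype). Independently, with the cell's TSG
#' probability, a `tsg_hit` event is drawn. The updated cell reflects the
#' events: a mutator event on an existing mutator changes nothing further,
#' and `tsg_hits` never exceeds `tsg_hits_for_initiation`.
#'
#' @param cell A [stem_cell()].
#' @param p A [sim_params()] object.
#' @param time Event time recorded on the emitted events.
#' @param crypt_coordinate Optional `c(q, r)` recorded on the events.
#' @return A list with `cell` (the updated [stem_cell()]) and `events`, a
#'   data frame with columns `category`, `time`, `cell_id`, `q`, `r`
#'   (zero rows if nothing was drawn).
#' @export
sample_mutation <- function(cell, p, time = 0, crypt_coordinate = c(NA, NA)) {
  cats <- character(0)
  rates <- cell_mutation_rate(cell, p)
  if (stats::runif(1) < rates[["general"]]) {
    if (stats::runif(1) < p$deleterious_fraction) {
      cat <- if (stats::runif(1) < p$deleterious_split[1])
        "deleterious_div" else "deleterious_surv"
    } else {
      u <- stats::runif(1)
      cat <- if (u < p$beneficial_split[1]) "beneficial_div"
      else if (u < p$beneficial_split[1] + p$beneficial_split[2]) "beneficial_surv"
      else "mutator"
    }
    cats <- c(cats, cat)
    switch(cat,
      deleterious_div = { cell$n_deleterious_div <- cell$n_deleterious_div + 1L },
      deleterious_surv = { cell$n_deleterious_surv <- cell$n_deleterious_surv + 1L },
      beneficial_div = { cell$n_beneficial_div <- cell$n_beneficial_div + 1L },
      beneficial_surv = { cell$n_beneficial_surv <- cell$n_beneficial_surv + 1L },
      mutator = { cell$is_mutator <- TRUE }
    )
  }
  if (stats::runif(1) < rates[["tsg"]]) {
    cats <- c(cats, "tsg_hit")
    cell$tsg_hits <- min(cell$tsg_hits + 1L, p$tsg_hits_for_initiation)
  }
  events <- data.frame(category = cats,
                       time = rep(time, length(cats)),
                       cell_id = rep(cell$unique_id, length(cats)),
                       q = rep(crypt_coordinate[1], length(cats)),
                       r = rep(crypt_coordinate[2], length(cats)),
                       stringsAsFactors = FALSE)
  list(cell = cell, events = events)
}
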