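#' Kaplan-Meier based cumulative hazard of tumor initiation
#'
#' Product-limit survival over the replicate endpoint times, with the
#' cumulative hazard taken as `H(t) = -log(S_KM(t))`. The Nelson-Aalen
#' estimator (`H(t) = sum d_i / n_i`) is available for comparison. When the
#' survival estimate reaches 0 the hazard is `Inf` (a jump to infinity is
#' the correct degenerate product-limit value; cap it downstream if a finite
#' sentinel is needed for plotting).
#'
#' @param times Non-negative endpoint times, one per subject (replicate).
#' @param event_flags Logical (or 0/1): `TRUE` if the subject experienced
#'   the event (initiation), `FALSE` if censored.
#' @param method `"km"` (default) or `"nelson-aalen"` for the hazard
#'   column.
#' @return A data frame, one row per distinct observed time, with columns
#'   `time`, `n_at_risk`, `n_events`, `n_censored`, `survival`,
#'   `cumulative_hazard`.
#' @examples
#' km_cumulative_hazard(c(2, 3, 5, 7), c(TRUE, FALSE, TRUE, FALSE))
#' @export
km_cumulative_hazard <- function(times, event_flags,
                                 method = c("km", "nelson-aalen")) {
  method <- match.arg(method)
  if (length(times) == 0) stop("no subjects supplied")
  if (length(times) != length(event_flags)) {
    stop("times and event_flags must have equal length")
  }
  if (any(times < 0)) stop("times must be >= 0")
  fit <- survival::survfit(
    survival::Surv(times, as.integer(as.logical(event_flags))) ~ 1,
    ctype = 1)
  surv <- fit$surv
  haz <- if (method == "km") {
    ifelse(surv > 0, -log(surv), Inf)
  } else {
    cumsum(ifelse(fit$n.risk > 0, fit$n.event / fit$n.risk, 0))
  }
  data.frame(time = fit$time,
             n_at_risk = fit$n.risk,
             n_events = fit$n.event,
             n_censored = fit$n.censor,
             survival = surv,
             cumulative_hazard = haz)
}

.living_crypts <- function(snapshot) {
  snapshot[snapshot$alive & snapshot$n_cells > 0, , drop = FALSE]
}

.as_snapshot <- function(x) {
  if (inherits(x, "crypt_run")) x$snapshot else x
}

#' Fraction of crypts with the mutator phenotype fixed
#'
#' A crypt counts as mutator-fixed when every one of its living stem cells
#' carries the mutator phenotype; a crypt with even one wild-type cell does
#' not. The fraction is over living crypts at the end of the run.
#'
#' @param x A `crypt_run` or its final-tissue `snapshot` data frame.
#' @return Proportion in `[0, 1]`, or `NA` (with a warning) if no crypt is
#'   alive.
#' @export
mutator_fixed_fraction <- function(x) {
  snap <- .living_crypts(.as_snapshot(x))
  if (nrow(snap) == 0) {
    warning("no living crypts: mutator-fixed fraction undefined")
    return(NA_real_)
  }
  mean(snap$n_mutator == snap$n_cells)
}

#' Mutator agreement by lattice distance class
#'
#' Two living crypts are in mutator agreement when both or neither have the
#' mutator phenotype fixed. For each exact hexagonal distance `d >= 1` this
#' returns the fraction of unordered living-crypt pairs at that distance in
#' agreement; distance classes with no pairs are omitted.
#'
#' @inheritParams mutator_fixed_fraction
#' @return A data frame with columns `distance`, `n_pairs`, `agreement`.
#' @export
mutator_agreement_by_distance <- function(x) {
  snap <- .living_crypts(.as_snapshot(x))
  if (nrow(snap) < 2) stop("need at least 2 living crypts")
  fixed <- snap$n_mutator == snap$n_cells
  pairs <- utils::combn(nrow(snap), 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  d <- hex_distance(snap$q[i], snap$r[i], snap$q[j], snap$r[j])
  agree <- fixed[i] == fixed[j]
  out <- stats::aggregate(agree, by = list(distance = d),
                   FUN = function(a) c(n = length(a), agreement = mean(a)))
  data.frame(distance = out$distance,
             n_pairs = as.integer(out$x[, "n"]),
             agreement = out$x[, "agreement"])
}

#' Genotype-intrinsic crypt fitness
#'
#' Mean over a crypt's living stem cells of the difference between the
#' genotype-determined division and loss rates,
#' `base_division_rate * k^(n_ben_div - n_del_div) -
#'  base_loss_rate * k^(n_del_surv - n_ben_surv)`.
#' Transient homeostatic feedback and dead-neighbor factors are excluded:
#' this is the heritable fitness of the crypt's current genotypes, which is
#' comparable across tissue architectures whatever their momentary feedback
#' state.
#'
#' @param crypt A [new_crypt()] object (alive).
#' @param p A [sim_params()] object.
#' @return The per-day rate difference.
#' @examples
#' p <- sim_params()
#' cr <- new_crypt(replicate(10, stem_cell(), simplify = FALSE), c(0, 0))
#' crypt_fitness(cr, p)  # 0.05 - 0.04878 = 0.00122
#' @export
crypt_fitness <- function(crypt, p) {
  if (!crypt$alive || length(crypt$cells) == 0) {
    stop("crypt_fitness is undefined for a dead crypt")
  }
  k <- p$fitness_factor
  per_cell <- vapply(crypt$cells, function(cell) {
    p$base_division_rate *
      fitness_multiplier(cell$n_beneficial_div, cell$n_deleterious_div, k) -
      p$base_loss_rate *
      k^cell$n_deleterious_surv * (1 / k)^cell$n_beneficial_surv
  }, numeric(1))
  mean(per_cell)
}

#' Per-crypt genotype fitness from a run snapshot
#'
#' Same quantity as [crypt_fitness()], computed for every living crypt in a
#' finished run from the snapshot's mean genotype fitness multipliers.
#'
#' @inheritParams mutator_fixed_fraction
#' @param p Parameters; defaults to the run's own.
#' @return A data frame with columns `q`, `r`, `n_cells`, `fitness`.
#' @export
tissue_crypt_fitness <- function(x, p = NULL) {
  if (is.null(p)) {
    if (!inherits(x, "crypt_run")) stop("supply p when x is a bare snapshot")
    p <- x$params
  }
  snap <- .living_crypts(.as_snapshot(x))
  data.frame(q = snap$q, r = snap$r, n_cells = snap$n_cells,
             fitness = p$base_division_rate * snap$mean_div_fitness -
               p$base_loss_rate * snap$mean_loss_fitness)
}

#' Crypt turnover and mutational burden summary
#'
#' Aggregates a finished run into the quantities used to compare tissue
#' architectures: crypt births and deaths, mean crypt lifespan, mutation
#' and division throughput, and the time-weighted mean number of living
#' stem cells per living crypt.
#'
#' @param run A `crypt_run` object.
#' @return A one-row data frame with columns `crypt_births`,
#'   `crypt_deaths`, `mean_crypt_lifespan` (`NA` when no crypt died),
#'   `mutations_per_day`, `divisions_per_day`, `mean_cells_per_crypt`.
#' @export
turnover_and_burden_metrics <- function(run) {
  turn <- run$turnover
  births <- sum(turn$event == "crypt_birth")
  deaths <- sum(turn$event == "crypt_death")
  lifespan <- if (deaths > 0) {
    mean(turn$lifespan[turn$event == "crypt_death"])
  } else NA_real_
  t_end <- run$endpoint_time
  data.frame(
    crypt_births = births,
    crypt_deaths = deaths,
    mean_crypt_lifespan = lifespan,
    mutations_per_day = sum(run$mutation_counts) / t_end,
    divisions_per_day =
      (run$n_symmetric_divisions + run$n_asymmetric_divisions) / t_end,
    mean_cells_per_crypt = run$cell_time_integral / run$crypt_time_integral)
}
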