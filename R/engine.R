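#' Run one simulation replicate
#'
#' Initializes every lattice slot with a crypt of `crypt_size` unmutated
#' stem cells and executes the discrete-event loop -- symmetric and
#' asymmetric divisions, losses, mutation draws, crypt extinction,
#' dead-neighbor release and bifurcation -- until one of the endpoints:
#'
#' * `initiation`: some stem cell accumulates `tsg_hits_for_initiation`
#'   hits to the tumor suppressor gene;
#' * `tissue_death`: every crypt has gone extinct;
#' * `uncontrolled_proliferation` (only if `enable_uncontrolled = TRUE`):
#'   some crypt reaches `uncontrolled_threshold * crypt_size` cells;
#' * `censored`: the horizon `max_days` is reached first.
#'
#' Identical `(params, seed)` give bit-identical results; the engine uses
#' its own deterministic generator, so R's RNG state is neither read nor
#' modified.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed for the run.
#' @param record_events Keep the full per-event log? Off by default: logs
#'   grow with millions of events on long runs. The turnover log and the
#'   aggregate counters are always kept.
#' @param enable_uncontrolled Treat uncontrolled proliferation as an
#'   endpoint (off by default; the threshold is still a parameter either
#'   way).
#' @return An object of class `crypt_run`: a list with `endpoint`,
#'   `endpoint_time` (days), `initiating_cell_was_mutator`, event counters
#'   (`n_symmetric_divisions`, `n_asymmetric_divisions`, `n_losses`,
#'   `mutation_counts`), time integrals of living cells and crypts,
#'   `snapshot` (one row per slot: coordinates, alive flag, `n_cells`,
#'   `n_mutator`, summed mutation counts, mean genotype fitness
#'   multipliers), `turnover` (crypt birth/death log), optionally `events`,
#'   plus the `params` and `seed` used.
#' @examples
#' p <- sim_params(grid_rows = 2, grid_cols = 2, max_days = 200)
#' run <- run_simulation(p, seed = 1)
#' run$endpoint
#' @export
run_simulation <- function(params, seed, record_events = FALSE,
                           enable_uncontrolled = FALSE) {
  viol <- validate_params(params)
  if (length(viol) > 0) {
    stop("invalid simulation parameters:\n  ", paste(viol, collapse = "\n  "))
  }
  seed <- as.numeric(seed)
  stopifnot(length(seed) == 1, is.finite(seed))
  res <- .run_engine(unclass(params), seed, isTRUE(record_events),
                     isTRUE(enable_uncontrolled))
  res$params <- params
  res$seed <- seed
  class(res) <- "crypt_run"
  res
}

#' @export
print.crypt_run <- function(x, ...) {
  cat(sprintf("<crypt_run> endpoint %s at day %.1f (seed %g)\n",
              x$endpoint, x$endpoint_time, x$seed))
  cat(sprintf("  %d/%d crypts alive, %d stem cells; %s divisions, %s losses\n",
              x$n_living_crypts, nrow(x$snapshot), x$n_living_cells,
              format(x$n_symmetric_divisions + x$n_asymmetric_divisions,
                     big.mark = ","),
              format(x$n_losses, big.mark = ",")))
  cat(sprintf("  mutations: %s\n",
              paste(names(x$mutation_counts), x$mutation_counts,
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Run independent replicates
#'
#' Runs `n_replicates` independent simulations with mutually distinct seeds
#' derived as `base_seed + 0:(n_replicates - 1)`, so a pair
#' `(params, base_seed)` always regenerates the same collection.
#'
#' @inheritParams run_simulation
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Seed of the first replicate.
#' @param out_file Optional path: per-replicate summary rows are streamed
#'   (appended) to this CSV as runs finish.
#' @param ... Passed on to [run_simulation()].
#' @return A list of `crypt_run` objects, in replicate order.
#' @seealso [summarize_runs()] to tabulate endpoints across replicates.
#' @export
run_replicates <- function(params, n_replicates, base_seed = 1,
                           out_file = NULL, ...) {
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1) {
    stop("n_replicates must be >= 1")
  }
  runs <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    runs[[i]] <- run_simulation(params, seed = base_seed + i - 1, ...)
    if (!is.null(out_file)) {
      row <- summarize_runs(runs[i])
      new_file <- !file.exists(out_file)
      utils::write.table(row, out_file, sep = ",", row.names = FALSE,
                         col.names = new_file, append = !new_file)
    }
  }
  runs
}

#' Summarize replicates, one row per run
#'
#' @param runs A list of `crypt_run` objects.
#' @return A data frame with columns `seed`, `endpoint`,
#'   `endpoint_time_days`, `initiating_cell_was_mutator`,
#'   `n_living_crypts_final`, `mutator_fixed_crypts_final`,
#'   `total_mutations` and `total_divisions`.
#' @export
summarize_runs <- function(runs) {
  do.call(rbind, lapply(runs, function(x) {
    snap <- x$snapshot
    living <- snap$alive & snap$n_cells > 0
    data.frame(
      seed = x$seed,
      endpoint = x$endpoint,
      endpoint_time_days = x$endpoint_time,
      initiating_cell_was_mutator = x$initiating_cell_was_mutator,
      n_living_crypts_final = sum(living),
      mutator_fixed_crypts_final =
        sum(living & snap$n_mutator == snap$n_cells),
      total_mutations = sum(x$mutation_counts),
      total_divisions = x$n_symmetric_divisions + x$n_asymmetric_divisions,
      stringsAsFactors = FALSE)
  }))
}

#' Step-function population trajectory from a recorded event log
#'
#' Reconstructs the total number of living stem cells over time from a run
#' recorded with `record_events = TRUE`.
#'
#' @param run A `crypt_run` with an event log.
#' @return A data frame with columns `time` and `n_cells` (value from that
#'   time until the next row), starting at time 0 with the initial census.
#' @export
population_trajectory <- function(run) {
  if (is.null(run$events)) {
    stop("run was not recorded with record_events = TRUE")
  }
  ev <- run$events
  delta <- ifelse(ev$event_kind == "symmetric_division", 1L,
                  ifelse(ev$event_kind == "cell_loss", -1L, 0L))
  n0 <- run$params$crypt_size * run$params$grid_rows * run$params$grid_cols
  keep <- delta != 0L
  data.frame(time = c(0, ev$time[keep]),
             n_cells = n0 + c(0L, cumsum(delta[keep])))
}

#' Time-averaged stem-cell count over a window
#'
#' Time-weighted mean of the total living stem-cell count between `from`
#' and `to`, from a recorded run.
#'
#' @inheritParams population_trajectory
#' @param from,to Window bounds in days (`to` defaults to the endpoint
#'   time).
#' @return The time-weighted average population.
#' @export
time_averaged_cells <- function(run, from = 0, to = run$endpoint_time) {
  traj <- population_trajectory(run)
  stopifnot(to > from)
  to <- min(to, run$endpoint_time)
  times <- c(traj$time, run$endpoint_time)
  lo <- pmax(times[-length(times)], from)
  hi <- pmin(times[-1], to)
  w <- pmax(hi - lo, 0)
  sum(traj$n_cells * w) / sum(w)
}
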