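#' Choose a near-square lattice holding a fixed number of stem cells
#'
#' For sweeps over cells-per-crypt in which the total number of stem cells
#' in the tissue is held constant, the lattice is resized so that
#' `rows * cols * crypt_size = total_cells`. The crypt count must divide the
#' total exactly (no approximation); among the factorizations of the crypt
#' count the most-square one is chosen, with `rows <= cols`.
#'
#' @param total_cells Total stem cells in the tissue.
#' @param crypt_size Stem cells per crypt.
#' @return `c(grid_rows, grid_cols)`.
#' @examples
#' grid_for_total(250, 10)  # 5 x 5
#' grid_for_total(250, 2)   # 5 x 25
#' @export
grid_for_total <- function(total_cells, crypt_size) {
  if (total_cells %% crypt_size != 0) {
    stop("crypt_size ", crypt_size, " does not divide total_cells ",
         total_cells, " into a whole number of crypts")
  }
  n <- total_cells %/% crypt_size
  rows <- max(which(n %% seq_len(floor(sqrt(n))) == 0))
  c(grid_rows = as.integer(rows), grid_cols = as.integer(n %/% rows))
}

# virtual sweep key: scales division and loss rates jointly
.apply_sweep_value <- function(p, key, value, mode, total_cells) {
  if (key == "turnover_multiplier") {
    p$base_division_rate <- p$base_division_rate * value
    p$base_loss_rate <- p$base_loss_rate * value
  } else {
    p[[key]] <- if (is.integer(p[[key]])) as.integer(value) else value
  }
  if (key == "crypt_size" && mode == "fixed_total_stem_cells") {
    g <- grid_for_total(total_cells, value)
    p$grid_rows <- g[[1]]
    p$grid_cols <- g[[2]]
  }
  viol <- validate_params(p)
  if (length(viol) > 0) {
    stop("sweep value ", value, " for ", key, " is invalid:\n  ",
         paste(viol, collapse = "\n  "))
  }
  p
}

#' Define a one-factor-at-a-time parameter sweep
#'
#' @param base_params The [sim_params()] every condition starts from.
#' @param vary Named list of value vectors, e.g.
#'   `list(deleterious_fraction = c(0.5, 0.75, 0.95))`. Keys must be
#'   parameter names, or the virtual key `turnover_multiplier` which scales
#'   `base_division_rate` and `base_loss_rate` jointly.
#' @param replicates Replicates per condition.
#' @param base_seed First replicate seed (shared across conditions, so
#'   conditions are compared under common random numbers).
#' @param mode `"fixed_crypt_count"` keeps the lattice as in `base_params`;
#'   `"fixed_total_stem_cells"` resizes the lattice on `crypt_size`
#'   conditions so the tissue-wide stem-cell total stays at the baseline
#'   value (see [grid_for_total()]).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(base_params, vary, replicates = 50, base_seed = 1,
                       mode = c("fixed_crypt_count", "fixed_total_stem_cells")) {
  mode <- match.arg(mode)
  if (!is.list(vary) || is.null(names(vary)) || any(names(vary) == "")) {
    stop("vary must be a named list of value vectors")
  }
  known <- c(names(formals(sim_params)), "turnover_multiplier")
  unknown <- setdiff(names(vary), known)
  if (length(unknown) > 0) {
    stop("unknown sweep key(s): ", paste(unknown, collapse = ", "))
  }
  if (any(lengths(vary) == 0)) stop("empty value list in vary")
  structure(list(base_params = base_params, vary = vary,
                 replicates = as.integer(replicates),
                 base_seed = base_seed, mode = mode,
                 total_cells = base_params$grid_rows * base_params$grid_cols *
                   base_params$crypt_size),
            class = "sweep_spec")
}

#' Execute a parameter sweep
#'
#' Runs [run_replicates()] for every `key = value` condition of the spec
#' (one factor at a time against the shared baseline) and, if `out_dir` is
#' given, writes per-condition outputs: the replicate summary
#' (`summary_<key>_<value>.csv`), the survival table of time to initiation
#' (`survival_<key>_<value>.csv`), and a `manifest.yaml` recording the base
#' parameters, sweep values, seeds and package version -- enough to
#' regenerate every output.
#'
#' @param spec A [sweep_spec()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param ... Passed to [run_simulation()].
#' @return Invisibly, a data frame with one row per condition: the varied
#'   key and value, replicate count, the fraction of runs reaching each
#'   endpoint, mean mutator-fixed fraction, mean crypt births and deaths,
#'   mean mutations per day and mean crypt fitness; the per-condition run
#'   lists are attached as the `"runs"` attribute.
#' @export
run_sweep <- function(spec, out_dir = NULL, ...) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  rows <- list()
  all_runs <- list()
  for (key in names(spec$vary)) {
    for (value in spec$vary[[key]]) {
      p <- .apply_sweep_value(spec$base_params, key, value, spec$mode,
                              spec$total_cells)
      runs <- run_replicates(p, spec$replicates, spec$base_seed, ...)
      cond <- sprintf("%s_%g", key, value)
      all_runs[[cond]] <- runs
      summ <- summarize_runs(runs)
      surv <- km_cumulative_hazard(summ$endpoint_time_days,
                                   summ$endpoint == "initiation")
      fix <- vapply(runs, function(x) {
        suppressWarnings(mutator_fixed_fraction(x))
      }, numeric(1))
      burden <- do.call(rbind, lapply(runs, turnover_and_burden_metrics))
      fitness <- vapply(runs, function(x) {
        f <- tissue_crypt_fitness(x)
        if (nrow(f) == 0) NA_real_ else mean(f$fitness)
      }, numeric(1))
      rows[[cond]] <- data.frame(
        key = key, value = value, replicates = spec$replicates,
        frac_initiation = mean(summ$endpoint == "initiation"),
        frac_tissue_death = mean(summ$endpoint == "tissue_death"),
        frac_censored = mean(summ$endpoint == "censored"),
        mean_mutator_fixed_fraction = mean(fix, na.rm = TRUE),
        mean_crypt_births = mean(burden$crypt_births),
        mean_crypt_deaths = mean(burden$crypt_deaths),
        mean_mutations_per_day = mean(burden$mutations_per_day),
        mean_crypt_fitness = mean(fitness, na.rm = TRUE),
        stringsAsFactors = FALSE)
      if (!is.null(out_dir)) {
        utils::write.csv(summ,
                         file.path(out_dir, paste0("summary_", cond, ".csv")),
                         row.names = FALSE)
        utils::write.csv(surv,
                         file.path(out_dir, paste0("survival_", cond, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "conditions.csv"),
                     row.names = FALSE)
    manifest <- paste0(
      "package: cryptsim ", as.character(utils::packageVersion("cryptsim")),
      "\nreplicates: ", spec$replicates,
      "\nbase_seed: ", spec$base_seed,
      "\nmode: ", spec$mode,
      "\nvary:\n",
      paste(sprintf("  %s: [%s]", names(spec$vary),
                    vapply(spec$vary, paste, "", collapse = ", ")),
            collapse = "\n"),
      "\nbase_params:\n",
      paste0("  ", gsub("\n", "\n  ",
                        sub("\n$", "", serialize_params(spec$base_params)))),
      "\n")
    writeLines(manifest, file.path(out_dir, "manifest.yaml"))
  }
  attr(out, "runs") <- all_runs
  invisible(out)
}
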