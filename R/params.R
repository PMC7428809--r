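#' Simulation parameters
#'
#' Container for every model parameter, with the baseline defaults used
#' throughout the package. Rates are per cell per day, times in days.
#'
#' @param max_days Time horizon of a run in days (80 years by default).
#' @param base_division_rate Baseline symmetric division rate per stem cell
#'   per day. Asymmetric divisions occur at `asym_to_sym_ratio` times this
#'   rate and provide mutation opportunities without changing the population.
#' @param asym_to_sym_ratio Ratio of asymmetric to symmetric division rates.
#' @param base_loss_rate Baseline stem-cell loss (death/differentiation) rate.
#' @param mutation_rate Probability of a fitness/mutator mutation per stem
#'   cell division opportunity.
#' @param mutation_rate_max Cap on the general mutation probability after
#'   mutator scaling.
#' @param tsg_mutation_rate Probability per division opportunity of a hit to
#'   the tumor suppressor gene.
#' @param tsg_mutation_rate_max Cap on the TSG hit probability after mutator
#'   scaling.
#' @param mutator_factor Multiplier applied to both mutation probabilities in
#'   cells carrying the mutator phenotype.
#' @param ta_cells_per_stem Transient-amplifying cells associated with each
#'   stem cell; reporting only, never enters the dynamics.
#' @param division_min_time Floor (days) on each sampled division waiting
#'   time.
#' @param loss_min_time Floor (days) on each sampled loss waiting time.
#' @param crypt_size Homeostatic target number of stem cells per crypt.
#' @param crypt_deviation Scale (in cells) of the homeostatic feedback
#'   exponent: the feedback multiplier is
#'   `base^(deviation_from_target / crypt_deviation)`.
#' @param bifurcation_factor A crypt bifurcates into an adjacent dead slot
#'   once its population reaches `bifurcation_factor * crypt_size`.
#' @param loss_effect_base Base of the loss-feedback exponential.
#' @param division_effect_base Base of the division-feedback exponential.
#' @param dead_neighbor_division_multiplier Division-rate multiplier applied
#'   once per adjacent dead crypt; while any neighbor is dead the crypt's
#'   loss feedback is also suppressed.
#' @param uncontrolled_threshold A crypt reaching this multiple of
#'   `crypt_size` counts as uncontrolled proliferation (endpoint disabled by
#'   default, see [run_simulation()]).
#' @param tsg_hits_for_initiation TSG hits in a single cell that define tumor
#'   initiation; the first hit is neutral.
#' @param deleterious_fraction Proportion of non-neutral mutations that are
#'   deleterious.
#' @param beneficial_split Proportions of beneficial mutations affecting
#'   division, survival, and causing the mutator phenotype; must sum to 1.
#' @param deleterious_split Proportions of deleterious mutations affecting
#'   division and survival; must sum to 1.
#' @param fitness_factor Multiplicative per-mutation fitness effect
#'   `k_fitness`; a beneficial division mutation multiplies the division rate
#'   by this factor, a deleterious one by its reciprocal (and symmetrically
#'   for loss rates, where deleterious survival mutations increase loss).
#'   The reciprocal is always computed as `1/fitness_factor`, never stored.
#' @param grid_rows,grid_cols Dimensions of the axial hexagonal lattice of
#'   crypt slots.
#'
#' @return An object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params()
#' p$base_division_rate
#' sim_params(crypt_size = 20, deleterious_fraction = 0.75)
#' @export
sim_params <- function(max_days = 29220,
                       base_division_rate = 0.05,
                       asym_to_sym_ratio = 20,
                       base_loss_rate = 0.04878,
                       mutation_rate = 5e-4,
                       mutation_rate_max = 5e-2,
                       tsg_mutation_rate = 5e-7,
                       tsg_mutation_rate_max = 5e-5,
                       mutator_factor = 100,
                       ta_cells_per_stem = 2048,
                       division_min_time = 0.05,
                       loss_min_time = 0,
                       crypt_size = 10,
                       crypt_deviation = 2.0,
                       bifurcation_factor = 2.0,
                       loss_effect_base = 2.0,
                       division_effect_base = 2.0,
                       dead_neighbor_division_multiplier = 2,
                       uncontrolled_threshold = 4,
                       tsg_hits_for_initiation = 2,
                       deleterious_fraction = 0.5,
                       beneficial_split = c(0.4, 0.4, 0.2),
                       deleterious_split = c(0.5, 0.5),
                       fitness_factor = 1.01,
                       grid_rows = 5,
                       grid_cols = 5) {
  p <- list(
    max_days = max_days,
    base_division_rate = base_division_rate,
    asym_to_sym_ratio = asym_to_sym_ratio,
    base_loss_rate = base_loss_rate,
    mutation_rate = mutation_rate,
    mutation_rate_max = mutation_rate_max,
    tsg_mutation_rate = tsg_mutation_rate,
    tsg_mutation_rate_max = tsg_mutation_rate_max,
    mutator_factor = mutator_factor,
    ta_cells_per_stem = ta_cells_per_stem,
    division_min_time = division_min_time,
    loss_min_time = loss_min_time,
    crypt_size = as.integer(crypt_size),
    crypt_deviation = crypt_deviation,
    bifurcation_factor = bifurcation_factor,
    loss_effect_base = loss_effect_base,
    division_effect_base = division_effect_base,
    dead_neighbor_division_multiplier = dead_neighbor_division_multiplier,
    uncontrolled_threshold = uncontrolled_threshold,
    tsg_hits_for_initiation = as.integer(tsg_hits_for_initiation),
    deleterious_fraction = deleterious_fraction,
    beneficial_split = as.numeric(beneficial_split),
    deleterious_split = as.numeric(deleterious_split),
    fitness_factor = fitness_factor,
    grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols)
  )
  class(p) <- "sim_params"
  viol <- validate_params(p)
  if (length(viol) > 0) {
    stop("invalid simulation parameters:\n  ", paste(viol, collapse = "\n  "))
  }
  p
}

#' Validate simulation parameters
#'
#' Checks every parameter invariant and returns the violations found rather
#' than throwing, so callers can report all problems at once.
#'
#' @param p A `sim_params` object (or a plain named list with the same
#'   fields).
#' @return A character vector of violation descriptions, each naming the
#'   offending field; empty if `p` is valid.
#' @examples
#' validate_params(sim_params())           # character(0)
#' p <- unclass(sim_params()); p$base_loss_rate <- -1
#' validate_params(p)
#' @export
validate_params <- function(p) {
  v <- character(0)
  num1 <- function(field) {
    x <- p[[field]]
    is.numeric(x) && length(x) == 1 && is.finite(x)
  }
  nonneg <- c("max_days", "base_division_rate", "asym_to_sym_ratio",
              "base_loss_rate", "mutator_factor", "ta_cells_per_stem",
              "division_min_time", "loss_min_time", "crypt_deviation",
              "bifurcation_factor", "loss_effect_base", "division_effect_base",
              "dead_neighbor_division_multiplier", "uncontrolled_threshold",
              "tsg_hits_for_initiation")
  for (f in nonneg) {
    if (!num1(f)) { v <- c(v, paste0(f, " must be a finite number")); next }
    if (p[[f]] < 0) v <- c(v, paste0(f, " must be >= 0"))
  }
  probs <- c("mutation_rate", "mutation_rate_max", "tsg_mutation_rate",
             "tsg_mutation_rate_max", "deleterious_fraction")
  for (f in probs) {
    if (!num1(f)) { v <- c(v, paste0(f, " must be a finite number")); next }
    if (p[[f]] < 0 || p[[f]] > 1) v <- c(v, paste0(f, " must be in [0, 1]"))
  }
  if (num1("fitness_factor")) {
    if (p$fitness_factor <= 0) v <- c(v, "fitness_factor must be > 0")
  } else v <- c(v, "fitness_factor must be a finite number")
  if (num1("crypt_deviation") && p$crypt_deviation <= 0)
    v <- c(v, "crypt_deviation must be > 0")
  if (num1("crypt_size")) {
    if (p$crypt_size < 1) v <- c(v, "crypt_size must be >= 1")
  } else v <- c(v, "crypt_size must be a finite number")
  for (f in c("grid_rows", "grid_cols")) {
    if (!num1(f) || p[[f]] < 1) v <- c(v, paste0(f, " must be >= 1"))
  }
  if (is.numeric(p$beneficial_split) && length(p$beneficial_split) == 3) {
    if (any(p$beneficial_split < 0) ||
        abs(sum(p$beneficial_split) - 1) > 1e-12)
      v <- c(v, "beneficial_split must be 3 non-negative proportions summing to 1")
  } else v <- c(v, "beneficial_split must be a numeric vector of length 3")
  if (is.numeric(p$deleterious_split) && length(p$deleterious_split) == 2) {
    if (any(p$deleterious_split < 0) ||
        abs(sum(p$deleterious_split) - 1) > 1e-12)
      v <- c(v, "deleterious_split must be 2 non-negative proportions summing to 1")
  } else v <- c(v, "deleterious_split must be a numeric vector of length 2")
  if (num1("mutation_rate") && num1("mutator_factor") &&
      p$mutator_factor < 1)
    v <- c(v, "mutator_factor must be >= 1 (a mutator never lowers the rate)")
  v
}

# keys handled by load_params() beyond the model parameters proper
.run_setting_keys <- c("replicates", "seed", "out_dir")

#' Load simulation parameters from a YAML configuration
#'
#' Reads a flat key-value document; keys are the argument names of
#' [sim_params()], and any key left out takes its default. The run settings
#' `replicates`, `seed` and `out_dir` may also appear and are attached as the
#' `"run_settings"` attribute. Unknown keys are an error.
#'
#' @param config Path to a YAML file, or a YAML string.
#' @return A validated `sim_params` object.
#' @examples
#' load_params("crypt_size: 20\ndeleterious_fraction: 0.75")
#' @seealso [serialize_params()] for the exact inverse.
#' @export
load_params <- function(config) {
  doc <- if (length(config) == 1 && file.exists(config)) {
    yaml::read_yaml(config)
  } else {
    yaml::yaml.load(paste(config, collapse = "\n"))
  }
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("configuration must be a key-value document")
  known <- names(formals(sim_params))
  unknown <- setdiff(names(doc), c(known, .run_setting_keys))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  settings <- doc[intersect(names(doc), .run_setting_keys)]
  doc <- doc[intersect(names(doc), known)]
  p <- do.call(sim_params, doc)
  if (length(settings) > 0) attr(p, "run_settings") <- settings
  p
}

#' Serialize simulation parameters to YAML
#'
#' Emits one `key: value` line per parameter with full floating-point
#' precision, so that `load_params(serialize_params(p))` reproduces `p`
#' exactly field by field. Used to embed provenance in output file headers.
#'
#' @param p A `sim_params` object.
#' @return A single YAML string.
#' @export
serialize_params <- function(p) {
  fmt <- function(x) {
    if (is.integer(x)) return(paste(x, collapse = ", "))
    one <- function(z) {
      s <- format(z, digits = 17)
      # keep doubles typed as doubles through the YAML round trip
      if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
      s
    }
    paste(vapply(x, one, ""), collapse = ", ")
  }
  lines <- vapply(names(unclass(p)), function(k) {
    x <- p[[k]]
    if (length(x) > 1) sprintf("%s: [%s]", k, fmt(x)) else sprintf("%s: %s", k, fmt(x))
  }, "")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (crypt metapopulation model)\n")
  cat(sprintf("  lattice %d x %d slots, %d stem cells per crypt, horizon %.0f days\n",
              x$grid_rows, x$grid_cols, x$crypt_size, x$max_days))
  cat(sprintf("  division %.4g/day (asym:sym %g), loss %.4g/day\n",
              x$base_division_rate, x$asym_to_sym_ratio, x$base_loss_rate))
  cat(sprintf("  mutation %.3g/division (cap %.3g), TSG %.3g (cap %.3g), mutator x%g\n",
              x$mutation_rate, x$mutation_rate_max, x$tsg_mutation_rate,
              x$tsg_mutation_rate_max, x$mutator_factor))
  cat(sprintf("  deleterious fraction %.3g, fitness factor %g\n",
              x$deleterious_fraction, x$fitness_factor))
  invisible(x)
}
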