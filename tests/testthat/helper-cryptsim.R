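# shared fixtures: small, fast parameter sets built in code

# single crypt, no mutations, no feedback beyond defaults
quiet_params <- function(...) {
  sim_params(grid_rows = 1, grid_cols = 1, mutation_rate = 0,
             tsg_mutation_rate = 0, ...)
}

# independent product-limit oracle: explicit loop over sorted distinct times
km_oracle <- function(times, events) {
  ord <- order(times)
  times <- times[ord]
  events <- as.logical(events)[ord]
  ut <- sort(unique(times))
  n <- length(times)
  s <- 1
  out <- data.frame(time = ut, n_at_risk = NA_real_, n_events = NA_real_,
                    survival = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / at_risk)
    out$n_at_risk[i] <- at_risk
    out$n_events[i] <- d
    out$survival[i] <- s
  }
  out
}

# restricted mean time to event: area under the KM survival curve to horizon
restricted_mean_event_time <- function(times, events, horizon) {
  tab <- km_cumulative_hazard(times, events)
  ev <- tab[tab$n_events > 0, , drop = FALSE]
  tt <- c(0, ev$time, horizon)
  ss <- c(1, ev$survival)
  sum(ss * diff(tt))
}

# a crypt of n cells with distinct ids, optionally pre-mutated
make_crypt <- function(n, coordinate = c(0, 0), mutate_with = identity) {
  cells <- lapply(seq_len(n), function(i) mutate_with(stem_cell(unique_id = i)))
  new_crypt(cells, coordinate)
}
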