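# Independent oracles and small fixture builders used across the suite.

# Exhaustive minimum-cost partial matching between two event lists under the
# same gating/cost model as match_adjacent: every event may stay unmatched at
# unmatched_cost. Branch-and-bound over all injective partial matchings;
# feasible only for a handful of events per side.
brute_force_match_cost <- function(events_a, events_b, params) {
  cost <- ssmrMAR:::pair_costs(events_a, events_b, params)
  na <- nrow(cost)
  nb <- ncol(cost)
  u <- params$unmatched_cost
  best <- Inf
  rec <- function(i, used_b, acc) {
    if (acc >= best) return(invisible())
    if (i > na) {
      total <- acc + (nb - sum(used_b)) * u
      if (total < best) best <<- total
      return(invisible())
    }
    rec(i + 1L, used_b, acc + u)
    for (j in seq_len(nb)) {
      if (!used_b[j] && is.finite(cost[i, j])) {
        used_b[j] <- TRUE
        rec(i + 1L, used_b, acc + cost[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), 0)
  best
}

# Total cost actually achieved by match_adjacent (pairs + unmatched penalty).
achieved_match_cost <- function(mres, params) {
  sum(mres$pairs$cost) +
    params$unmatched_cost *
      (length(mres$unmatched_a) + length(mres$unmatched_b))
}

random_match_instance <- function(n_a, n_b, params) {
  mk <- function(n, sensor) {
    data.frame(event_id = sprintf("s%d_%02d", sensor, seq_len(n)),
               sensor_index = rep(sensor, n),
               time_s = sort(stats::runif(n, 0, 400)) + sensor * 105,
               signal = stats::rnorm(n, 50, 10),
               stringsAsFactors = FALSE)
  }
  list(a = mk(n_a, 0L), b = mk(n_b, 1L))
}

# Event groupings as sorted "id|id|..." strings, for set comparison between
# recovered traces and ground truth (trace labels are arbitrary).
grouping_signature <- function(long_traces) {
  sort(unname(vapply(split(long_traces$event_id, long_traces$trace_id),
                     function(ids) paste(sort(ids), collapse = "|"),
                     character(1))), method = "radix")
}

# Draw per-cell MAR records directly from population-level distributions
# (no sensor simulation); used for statistical-calibration checks where the
# quantity under test is the downstream statistics, not the instrument model.
sample_records <- function(n, mass_mean = 50, mass_sd = 10,
                           mar_mean = 5, mar_sd = 2, drug_effect = 0) {
  mass <- stats::rnorm(n, mass_mean, mass_sd)
  while (any(mass <= 0)) mass[mass <= 0] <- stats::rnorm(sum(mass <= 0),
                                                         mass_mean, mass_sd)
  mar <- apply_drug_effect(stats::rnorm(n, mar_mean, mar_sd), drug_effect)
  data.frame(trace_id = sprintf("r%04d", seq_len(n)),
             mean_mass_pg = mass,
             mar_pg_per_h = mar,
             mar_per_mass_per_h = mar / mass,
             n_points = 10L,
             residual_sd_pg = 0,
             is_negative = mar < 0,
             valid = TRUE,
             stringsAsFactors = FALSE)
}

# Four points per class whose sample mean is exactly `mu` and whose sample
# covariance is exactly isotropic: mu +/- (a, 0), mu +/- (0, a).
isotropic_class <- function(mu, a = 1) {
  rbind(mu + c(a, 0), mu - c(a, 0), mu + c(0, a), mu - c(0, a))
}
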