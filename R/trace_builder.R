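#' Matching parameters for adjacent-sensor event linking
#'
#' Controls the gated bipartite assignment that links detections of the same
#' object at adjacent sensors. A candidate pair with inter-sensor delay
#' outside `transit_window` is forbidden outright; within the window its
#' cost is the sum of two normalized residuals,
#' \deqn{c = w_t \frac{|\Delta t - \mathrm{mid}|}{\mathrm{halfwidth}} +
#'       w_m \frac{|\Delta s|}{\mathrm{tol}},}
#' where mid and halfwidth describe `transit_window`, and unmatched events
#' pay `unmatched_cost` each, so a pair is only kept when it beats leaving
#' both events unlinked.
#'
#' @param transit_window Length-2 numeric `(min_s, max_s)` allowed
#'   inter-sensor delay, seconds.
#' @param mass_tolerance Signal-mismatch scale, pg. Should be a few times
#'   the per-pair measurement noise (sqrt(2) x single-measurement SD).
#' @param time_weight,mass_weight Dimensionless cost weights.
#' @param unmatched_cost Cost of leaving one event unlinked, normalized
#'   units.
#' @return An object of class `ssmr_match_params`.
#' @seealso [default_match_params()] to derive the window from a device.
#' @export
match_params <- function(transit_window = c(73, 137),
                         mass_tolerance = 0.25,
                         time_weight = 1,
                         mass_weight = 1,
                         unmatched_cost = 4) {
  if (!is.numeric(transit_window) || length(transit_window) != 2L ||
      !all(is.finite(transit_window)) ||
      transit_window[1L] >= transit_window[2L])
    stop_config("'transit_window' must be (min_s, max_s) with min < max")
  check_scalar(mass_tolerance, "mass_tolerance", lower = 0, allow_lower = FALSE)
  check_scalar(time_weight, "time_weight", lower = 0)
  check_scalar(mass_weight, "mass_weight", lower = 0)
  check_scalar(unmatched_cost, "unmatched_cost", lower = 0, allow_lower = FALSE)
  structure(list(transit_window = as.numeric(transit_window),
                 mass_tolerance = mass_tolerance,
                 time_weight = time_weight,
                 mass_weight = mass_weight,
                 unmatched_cost = unmatched_cost),
            class = "ssmr_match_params")
}

#' @rdname match_params
#' @param device A [device_config()]; the window becomes the mean transit
#'   time plus/minus 4 transit-time SDs.
#' @export
default_match_params <- function(device, mass_tolerance = 0.25,
                                 time_weight = 1, mass_weight = 1,
                                 unmatched_cost = 4) {
  if (!inherits(device, "ssmr_device"))
    stop_config("'device' must be created by device_config()")
  win <- device$transit_time_mean + c(-4, 4) * device$transit_time_sd
  win[1L] <- max(win[1L], 0)
  match_params(transit_window = win, mass_tolerance = mass_tolerance,
               time_weight = time_weight, mass_weight = mass_weight,
               unmatched_cost = unmatched_cost)
}

sort_events <- function(events) {
  events[order(events$time_s, events$event_id), , drop = FALSE]
}

# Pairwise cost matrix (rows = events_a, cols = events_b); Inf = forbidden.
pair_costs <- function(events_a, events_b, params) {
  dt <- outer(events_a$time_s, events_b$time_s, function(a, b) b - a)
  ds <- abs(outer(events_a$signal, events_b$signal, function(a, b) b - a))
  win <- params$transit_window
  mid <- mean(win)
  halfwidth <- diff(win) / 2
  cost <- params$time_weight * abs(dt - mid) / halfwidth +
    params$mass_weight * ds / params$mass_tolerance
  cost[dt < win[1L] | dt > win[2L]] <- Inf
  cost
}

#' Match events between two adjacent sensors
#'
#' Finds the globally minimum-cost assignment between detection events at
#' one sensor and the next, under the gating and cost model of
#' [match_params()]. Unequal list sizes (and events better left unlinked)
#' are handled by augmenting the cost matrix with dummy partners at
#' `unmatched_cost` per event, so the solver always works on a square
#' matrix. Cost ties are broken deterministically by earlier event time,
#' then lexicographic event id (events are sorted on these keys before the
#' matrix is built).
#'
#' @param events_a,events_b Event data.frames (`event_id, sensor_index,
#'   time_s, signal`) for the upstream and downstream sensor.
#' @param params A [match_params()].
#' @return A list with `pairs` (data.frame `a_id, b_id, cost`), and
#'   character vectors `unmatched_a`, `unmatched_b`.
#' @export
match_adjacent <- function(events_a, events_b, params) {
  if (!inherits(params, "ssmr_match_params"))
    stop_config("'params' must be created by match_params()")
  na <- nrow(events_a)
  nb <- nrow(events_b)
  empty <- list(pairs = data.frame(a_id = character(0), b_id = character(0),
                                   cost = numeric(0), stringsAsFactors = FALSE),
                unmatched_a = if (na) sort(events_a$event_id) else character(0),
                unmatched_b = if (nb) sort(events_b$event_id) else character(0))
  if (na == 0L || nb == 0L) return(empty)
  events_a <- sort_events(events_a)
  events_b <- sort_events(events_b)

  cost <- pair_costs(events_a, events_b, params)
  u <- params$unmatched_cost
  finite_max <- suppressWarnings(max(cost[is.finite(cost)], u, 0))
  n <- na + nb
  big <- (n + 1) * (finite_max + u + 1)
  cost[!is.finite(cost)] <- big

  m <- matrix(big, n, n)
  m[seq_len(na), seq_len(nb)] <- cost
  m[cbind(seq_len(na), nb + seq_len(na))] <- u           # a_i unmatched
  m[cbind(na + seq_len(nb), seq_len(nb))] <- u           # b_j unmatched
  m[na + seq_len(nb), nb + seq_len(na)] <- 0             # dummy-dummy

  sol <- solve_assignment(m)
  ai <- seq_len(na)
  bj <- sol[ai]
  keep <- bj <= nb
  keep[keep] <- cost[cbind(ai[keep], bj[keep])] < big
  pairs <- data.frame(a_id = events_a$event_id[ai[keep]],
                      b_id = events_b$event_id[bj[keep]],
                      cost = cost[cbind(ai[keep], bj[keep])],
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       unmatched_a = sort(setdiff(events_a$event_id, pairs$a_id)),
       unmatched_b = sort(setdiff(events_b$event_id, pairs$b_id)))
}

#' Build single-object traces from per-sensor events
#'
#' Runs [match_adjacent()] between every pair of consecutive sensors present
#' in the event table and chains the resulting links transitively into
#' mass-vs-time traces. A broken link (an event with no downstream partner)
#' terminates its trace; chains are never re-joined across a missed sensor,
#' trading shorter traces for protection against spurious long-gap links.
#' Chains with a single event are reported as unlinked, not as traces.
#'
#' @param events Event data.frame covering at least two sensors.
#' @param params A [match_params()].
#' @return A data.frame `trace_id, sensor_index, time_s, signal, event_id`
#'   sorted by trace then time, with attributes `match_summary` (per
#'   sensor-pair matched/unmatched counts) and `unlinked_events` (ids of
#'   events in no trace).
#' @export
build_traces <- function(events, params) {
  need <- c("event_id", "sensor_index", "time_s", "signal")
  if (!is.data.frame(events) || !all(need %in% names(events)))
    stop_config("'events' must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(events$event_id))
    stop_config("duplicate event ids in input")
  sensors <- sort(unique(events$sensor_index))
  if (length(sensors) < 2L)
    stop_config("at least two sensors are required to build traces")

  by_sensor <- split(events, factor(events$sensor_index, levels = sensors))
  succ <- character(0)
  summary_rows <- vector("list", length(sensors) - 1L)
  for (k in seq_len(length(sensors) - 1L)) {
    mres <- match_adjacent(by_sensor[[k]], by_sensor[[k + 1L]], params)
    if (nrow(mres$pairs))
      succ[mres$pairs$a_id] <- mres$pairs$b_id
    summary_rows[[k]] <- data.frame(
      sensor_a = sensors[k], sensor_b = sensors[k + 1L],
      n_matched = nrow(mres$pairs),
      n_unmatched_a = length(mres$unmatched_a),
      n_unmatched_b = length(mres$unmatched_b))
  }

  is_successor <- events$event_id %in% unname(succ)
  starts <- events$event_id[!is_successor]
  # deterministic trace ids: order chain starts by event time, then id
  ord <- order(events$time_s[match(starts, events$event_id)], starts)
  starts <- starts[ord]

  chains <- lapply(starts, function(s) {
    ids <- s
    nxt <- succ[s]
    while (!is.na(nxt)) {
      ids <- c(ids, nxt)
      nxt <- succ[nxt]
    }
    unname(ids)
  })
  lens <- lengths(chains)
  traces <- chains[lens >= 2L]
  unlinked <- unlist(chains[lens < 2L], use.names = FALSE) %||% character(0)

  if (length(traces) == 0L) {
    out <- events[0L, need]
    out$trace_id <- character(0)
  } else {
    trace_id <- sprintf("tr%05d", seq_along(traces))
    idx <- match(unlist(traces, use.names = FALSE), events$event_id)
    out <- events[idx, need]
    out$trace_id <- rep(trace_id, lengths(traces))
  }
  out <- out[, c("trace_id", "sensor_index", "time_s", "signal", "event_id")]
  rownames(out) <- NULL
  attr(out, "match_summary") <- do.call(rbind, summary_rows)
  attr(out, "unlinked_events") <- unlinked
  out
}

#' Drop traces with too few points
#'
#' @param traces Long trace data.frame from [build_traces()].
#' @param min_points Minimum number of linked points a trace must have
#'   (>= 2).
#' @return The filtered trace data.frame with attribute `retention` listing
#'   the number of traces kept and dropped. Warns (does not error) when
#'   nothing survives.
#' @export
filter_traces <- function(traces, min_points = 2L) {
  min_points <- check_count(min_points, "min_points", lower = 2L)
  counts <- table(traces$trace_id)
  keep_ids <- names(counts)[counts >= min_points]
  out <- traces[traces$trace_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retention") <- c(kept = length(keep_ids),
                              dropped = length(counts) - length(keep_ids))
  if (length(counts) > 0L && length(keep_ids) == 0L)
    warning("no traces satisfy min_points = ", min_points)
  out
}

#' Read and write trace tables
#'
#' Traces are stored as delimited text with header
#' `trace_id,sensor_index,time_s,signal`. A `# calibrated=true` comment line
#' marks traces already converted to picograms.
#'
#' @param traces Long trace data.frame.
#' @param path File path.
#' @name trace_io
#' @export
write_traces <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  calibrated <- isTRUE(attr(traces, "calibrated"))
  writeLines(sprintf("# calibrated=%s", tolower(calibrated)), con)
  utils::write.csv(traces[, c("trace_id", "sensor_index", "time_s", "signal")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1L)
  calibrated <- identical(first, "# calibrated=true")
  tr <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(trace_id = "character"))
  attr(tr, "calibrated") <- calibrated
  tr
}
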