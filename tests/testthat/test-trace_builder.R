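mk_events <- function(times, signals, sensor, ids = NULL) {
  data.frame(event_id = ids %||% sprintf("s%d_%02d", sensor, seq_along(times)),
             sensor_index = rep(sensor, length(times)),
             time_s = times, signal = signals,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("single feasible pairs match and gated-out pairs stay unmatched", {
  p <- match_params(transit_window = c(80, 130))
  a <- mk_events(0, 50, 0L)
  b <- mk_events(105, 50.02, 1L)
  m <- match_adjacent(a, b, p)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$a_id, a$event_id)
  expect_equal(m$pairs$b_id, b$event_id)

  far <- match_adjacent(mk_events(0, 50, 0L), mk_events(300, 50, 1L), p)
  expect_equal(nrow(far$pairs), 0L)
  expect_length(far$unmatched_a, 1L)
  expect_length(far$unmatched_b, 1L)
})

test_that("mass term resolves crossing candidates (2x2 brute-force case)", {
  p <- match_params(transit_window = c(80, 130))
  a <- mk_events(c(0, 0), c(50, 70), 0L)
  b <- mk_events(c(105, 105), c(70.1, 50.2), 1L)
  m <- match_adjacent(a, b, p)
  got <- setNames(m$pairs$b_id, m$pairs$a_id)
  expect_equal(unname(got["s0_01"]), "s1_02")  # 50 <-> 50.2
  expect_equal(unname(got["s0_02"]), "s1_01")  # 70 <-> 70.1
  expect_equal(achieved_match_cost(m, p),
               brute_force_match_cost(a, b, p), tolerance = 1e-10)
})

test_that("empty inputs give empty matchings, not errors", {
  p <- match_params()
  e <- mk_events(numeric(0), numeric(0), 0L)
  m <- match_adjacent(e, mk_events(105, 50, 1L), p)
  expect_equal(nrow(m$pairs), 0L)
  expect_length(m$unmatched_b, 1L)
})

test_that("matcher attains the exhaustive-search minimum on random instances", {
  p <- match_params(transit_window = c(73, 137), mass_tolerance = 0.25)
  set.seed(1234)
  for (i in 1:60) {
    inst <- random_match_instance(sample(0:6, 1), sample(0:6, 1), p)
    if (nrow(inst$a) == 0 || nrow(inst$b) == 0) next
    m <- match_adjacent(inst$a, inst$b, p)
    expect_equal(achieved_match_cost(m, p),
                 brute_force_match_cost(inst$a, inst$b, p),
                 tolerance = 1e-9)
  }
})

test_that("zero-noise well-spaced runs are recovered exactly from events", {
  dev <- device_config(mass_noise_sd = 0, seed = 404)
  pop <- population_config(n_cells = 10, n_beads = 3)
  run <- simulate_run(dev, pop)
  tr <- build_traces(run$events, default_match_params(dev))
  expect_identical(grouping_signature(tr),
                   grouping_signature(truth_traces(run)))
})

test_that("a dropped detection truncates the trace instead of bridging", {
  dev <- device_config(mass_noise_sd = 0, seed = 21)
  pop <- population_config(n_cells = 1, n_beads = 0)
  run <- simulate_run(dev, pop)
  ev <- run$events[run$events$sensor_index != 5L, ]
  tr <- build_traces(ev, default_match_params(dev))
  expect_equal(length(unique(tr$trace_id)), 2L)  # sensors 0-4, then 6-9
  lens <- table(tr$trace_id)
  expect_setequal(as.integer(lens), c(5L, 4L))
  first <- tr[tr$sensor_index <= 4, ]
  expect_equal(sort(unique(first$sensor_index)), 0:4)
})

test_that("no event is duplicated across traces and unlinked events", {
  dev <- device_config(detection_dropout_rate = 0.15, seed = 55)
  pop <- population_config(n_cells = 30, n_beads = 5)
  run <- simulate_run(dev, pop)
  tr <- build_traces(run$events, default_match_params(dev))
  all_ids <- c(tr$event_id, attr(tr, "unlinked_events"))
  expect_equal(sort(all_ids), sort(run$events$event_id))
  expect_false(anyDuplicated(tr$event_id) > 0)
})

test_that("input event order does not change the recovered traces", {
  dev <- device_config(seed = 66)
  pop <- population_config(n_cells = 15, n_beads = 3)
  run <- simulate_run(dev, pop)
  p <- default_match_params(dev)
  t1 <- build_traces(run$events, p)
  set.seed(9)
  shuffled <- run$events[sample(nrow(run$events)), ]
  t2 <- build_traces(shuffled, p)
  expect_identical(grouping_signature(t1), grouping_signature(t2))
})

test_that("a single sensor is rejected", {
  dev <- device_config(seed = 3)
  run <- simulate_run(dev, population_config(n_cells = 3, n_beads = 0))
  one <- run$events[run$events$sensor_index == 0L, ]
  expect_error(build_traces(one, default_match_params(dev)),
               "at least two sensors")
})

test_that("filter_traces keeps only traces with enough points", {
  tr <- data.frame(
    trace_id = rep(c("a", "b", "c"), c(10, 3, 7)),
    sensor_index = c(0:9, 0:2, 0:6),
    time_s = 1:20, signal = 1, event_id = sprintf("e%02d", 1:20),
    stringsAsFactors = FALSE)
  f5 <- filter_traces(tr, 5)
  expect_setequal(unique(f5$trace_id), c("a", "c"))
  expect_equal(unname(attr(f5, "retention")), c(2L, 1L))
  expect_equal(nrow(filter_traces(tr, 2)), nrow(tr))
  expect_warning(out <- filter_traces(tr, 11), "no traces")
  expect_equal(nrow(out), 0L)
})

test_that("trace files round-trip with the calibrated flag", {
  dev <- device_config(seed = 12)
  run <- simulate_run(dev, population_config(n_cells = 4, n_beads = 2))
  tr <- build_traces(run$events, default_match_params(dev))
  attr(tr, "calibrated") <- TRUE
  path <- tempfile(fileext = ".csv")
  write_traces(tr, path)
  back <- read_traces(path)
  expect_true(attr(back, "calibrated"))
  expect_equal(back$trace_id, tr$trace_id)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  unlink(path)
})
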