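#' Serial SMR device configuration
#'
#' Describes the sensor array of a serial suspended microchannel resonator
#' (sSMR): a chain of mass sensors separated by delay channels, so that each
#' flowing object is weighed once per sensor, roughly every 1.5--2 minutes.
#'
#' @param n_sensors Number of sensors in series (>= 2).
#' @param transit_time_mean Mean transit time through one delay channel,
#'   seconds. The default of 105 s gives 10 weighings in under 20 minutes.
#' @param transit_time_sd Standard deviation of a single channel transit,
#'   seconds. Transit draws are truncated at 3 SD to keep transits physical
#'   and event ordering stable.
#' @param mass_noise_sd Single-measurement mass noise, femtograms. sSMR
#'   devices resolve buoyant mass to roughly 50 fg.
#' @param detection_dropout_rate Probability that any single detection event
#'   is missed (0 disables dropout).
#' @param calibration_scale Raw-signal units per picogram. 1 means the raw
#'   signal is already in pg; a non-unit value exercises bead calibration.
#' @param seed Integer seed for the simulation, or NULL to use the current
#'   RNG state.
#'
#' @return An object of class `ssmr_device` (a validated list).
#' @seealso [population_config()], [simulate_run()]
#' @export
device_config <- function(n_sensors = 10L,
                          transit_time_mean = 105,
                          transit_time_sd = 8,
                          mass_noise_sd = 50,
                          detection_dropout_rate = 0,
                          calibration_scale = 1,
                          seed = NULL) {
  n_sensors <- check_count(n_sensors, "n_sensors", lower = 2L)
  check_scalar(transit_time_mean, "transit_time_mean", lower = 0, allow_lower = FALSE)
  check_scalar(transit_time_sd, "transit_time_sd", lower = 0)
  check_scalar(mass_noise_sd, "mass_noise_sd", lower = 0)
  check_scalar(detection_dropout_rate, "detection_dropout_rate",
               lower = 0, upper = 1, allow_upper = FALSE)
  check_scalar(calibration_scale, "calibration_scale", lower = 0, allow_lower = FALSE)
  if (!is.null(seed)) seed <- check_count(seed, "seed", lower = 0L)
  structure(list(n_sensors = n_sensors,
                 transit_time_mean = transit_time_mean,
                 transit_time_sd = transit_time_sd,
                 mass_noise_sd = mass_noise_sd,
                 detection_dropout_rate = detection_dropout_rate,
                 calibration_scale = calibration_scale,
                 seed = seed),
            class = "ssmr_device")
}

#' Cell/bead population configuration
#'
#' Describes one sample loaded on the device: a population of cells with
#' normally distributed buoyant mass and mass accumulation rate (MAR), spiked
#' with polystyrene calibration beads of fixed mass and zero MAR. Growth is
#' modelled as linear over the short (~20 min) observation window, which is
#' small relative to a cell doubling time.
#'
#' @param n_cells Number of cells.
#' @param mass_mean,mass_sd Buoyant mass distribution at entry, picograms.
#'   Negative draws are resampled, not clamped, so the distribution shape is
#'   preserved.
#' @param mar_mean,mar_sd MAR distribution, pg/h.
#' @param drug_effect Additive downward shift applied to every cell's true
#'   MAR before events are synthesised, pg/h. 0 models a resistant (or
#'   no-target) population; large positive values push the population to
#'   negative MAR, modelling a sensitive population under treatment.
#' @param n_beads Number of spiked calibration beads.
#' @param bead_mass Nominal bead buoyant mass, pg. See [bead_buoyant_mass()]
#'   for a physical default for 8 um polystyrene beads.
#' @param bead_mass_cv Bead-to-bead coefficient of variation of buoyant
#'   mass (manufacturing tolerance, ~1% for monodisperse polystyrene).
#'   Individual bead masses are drawn once per bead; each bead still has
#'   exactly zero MAR.
#' @param arrival_rate Objects entering the device per minute.
#'
#' @return An object of class `ssmr_population`.
#' @export
population_config <- function(n_cells = 60L,
                              mass_mean = 50,
                              mass_sd = 10,
                              mar_mean = 5,
                              mar_sd = 2,
                              drug_effect = 0,
                              n_beads = 10L,
                              bead_mass = bead_buoyant_mass(),
                              bead_mass_cv = 0.01,
                              arrival_rate = 0.5) {
  n_cells <- check_count(n_cells, "n_cells", lower = 0L)
  n_beads <- check_count(n_beads, "n_beads", lower = 0L)
  check_scalar(mass_mean, "mass_mean", lower = 0, allow_lower = FALSE)
  check_scalar(mass_sd, "mass_sd", lower = 0)
  check_scalar(mar_mean, "mar_mean")
  check_scalar(mar_sd, "mar_sd", lower = 0)
  check_scalar(drug_effect, "drug_effect")
  check_scalar(bead_mass, "bead_mass", lower = 0, allow_lower = FALSE)
  check_scalar(bead_mass_cv, "bead_mass_cv", lower = 0, upper = 0.5)
  check_scalar(arrival_rate, "arrival_rate", lower = 0, allow_lower = FALSE)
  structure(list(n_cells = n_cells, mass_mean = mass_mean, mass_sd = mass_sd,
                 mar_mean = mar_mean, mar_sd = mar_sd,
                 drug_effect = drug_effect, n_beads = n_beads,
                 bead_mass = bead_mass, bead_mass_cv = bead_mass_cv,
                 arrival_rate = arrival_rate),
            class = "ssmr_population")
}

#' Nominal buoyant mass of a spherical calibration bead
#'
#' Buoyant mass is the particle mass minus the mass of displaced fluid:
#' volume times the density difference between bead and medium. For the
#' default 8 um polystyrene bead in culture-medium-like fluid this is about
#' 12.6 pg.
#'
#' @param diameter_um Bead diameter, micrometres.
#' @param bead_density Bead material density, g/cm^3 (polystyrene ~1.05).
#' @param fluid_density Medium density, g/cm^3.
#' @return Buoyant mass in picograms.
#' @export
bead_buoyant_mass <- function(diameter_um = 8,
                              bead_density = 1.05,
                              fluid_density = 1.003) {
  check_scalar(diameter_um, "diameter_um", lower = 0, allow_lower = FALSE)
  volume_um3 <- (4 / 3) * pi * (diameter_um / 2)^3
  # 1 um^3 * 1 g/cm^3 = 1 pg
  volume_um3 * (bead_density - fluid_density)
}

#' Shift true MARs by a drug effect
#'
#' Applies the condition-level treatment model: every true MAR is decreased
#' by `drug_effect` pg/h before sensor events are synthesised. An effect of 0
#' leaves the distribution unchanged (the resistant model).
#'
#' @param mars Numeric vector of MARs, pg/h.
#' @param drug_effect Additive downward shift, pg/h (finite).
#' @return Shifted MARs.
#' @export
apply_drug_effect <- function(mars, drug_effect) {
  check_scalar(drug_effect, "drug_effect")
  if (!is.numeric(mars)) stop_config("'mars' must be numeric")
  mars - drug_effect
}

rnorm_positive <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
    if (guard > 1000L)
      stop_config("mass distribution places almost all probability below zero")
  }
  x
}

rnorm_truncated <- function(n, mean, sd, k = 3) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  lo <- max(mean - k * sd, 0)
  hi <- mean + k * sd
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate one sSMR run with ground truth
#'
#' Generates per-sensor detection events for a mixture of growing cells and
#' zero-MAR calibration beads flowing through the sensor array, together with
#' the ground-truth table needed to validate event linking and MAR recovery.
#'
#' Each object enters at a Poisson-like arrival time, transits every delay
#' channel with an independent (truncated) Gaussian transit time, and is
#' weighed at each sensor. The measured signal at sensor \eqn{k} is
#' \deqn{(m_0 + \mathrm{MAR} \cdot \Delta t_k / 3600) \cdot s + \epsilon,}
#' with \eqn{m_0} the entry mass (pg), \eqn{\Delta t_k} seconds since the
#' first weighing, \eqn{s} the calibration scale and \eqn{\epsilon} Gaussian
#' noise with SD `mass_noise_sd` fg. Bead signals therefore have zero slope
#' in expectation.
#'
#' With `enforce_spacing = TRUE` (the default) successive arrivals are kept
#' at least `min_spacing_factor` transit-time SDs apart by adding that floor
#' to the exponential inter-arrival gap. Together with the 3-SD truncation of
#' transit times this makes adjacent-sensor event linking provably
#' unambiguous in the noise-free case, which the matching oracle tests rely
#' on. Disable it only for stress testing the matcher.
#'
#' @param device A [device_config()].
#' @param population A [population_config()].
#' @param enforce_spacing Keep arrivals well separated (default TRUE).
#' @param min_spacing_factor Minimum arrival spacing in units of
#'   `transit_time_sd` when `enforce_spacing` is TRUE.
#'
#' @return A list of class `ssmr_run` with elements
#'   \describe{
#'     \item{events}{data.frame `event_id, sensor_index, time_s, signal`,
#'       sorted by sensor then time. `sensor_index` is 0-based.}
#'     \item{truth}{data.frame `object_id, kind, true_mass_at_entry,
#'       true_mar` (one row per object; MARs are post-drug-effect).}
#'     \item{truth_events}{data.frame `object_id, sensor_index, event_id`
#'       linking every emitted event to the object that caused it.}
#'     \item{device, population}{the configurations used.}
#'   }
#' @export
simulate_run <- function(device, population,
                         enforce_spacing = TRUE,
                         min_spacing_factor = 6) {
  if (!inherits(device, "ssmr_device"))
    stop_config("'device' must be created by device_config()")
  if (!inherits(population, "ssmr_population"))
    stop_config("'population' must be created by population_config()")
  n_obj <- population$n_cells + population$n_beads
  if (n_obj == 0L)
    stop_config("simulation requires at least one cell or bead")
  if (!is.null(device$seed)) set.seed(device$seed)

  kind <- sample(rep(c("cell", "bead"),
                     c(population$n_cells, population$n_beads)))
  object_id <- sprintf("obj%04d", seq_len(n_obj))

  mass0 <- numeric(n_obj)
  mar <- numeric(n_obj)
  is_cell <- kind == "cell"
  mass0[is_cell] <- rnorm_positive(sum(is_cell),
                                   population$mass_mean, population$mass_sd)
  mass0[!is_cell] <- if (population$bead_mass_cv > 0)
    rnorm_positive(sum(!is_cell), population$bead_mass,
                   population$bead_mass_cv * population$bead_mass)
  else population$bead_mass
  mar[is_cell] <- apply_drug_effect(
    stats::rnorm(sum(is_cell), population$mar_mean, population$mar_sd),
    population$drug_effect)
  mar[!is_cell] <- 0

  rate_s <- population$arrival_rate / 60
  gaps <- stats::rexp(n_obj, rate = rate_s)
  if (enforce_spacing)
    gaps <- gaps + min_spacing_factor * device$transit_time_sd
  arrivals <- cumsum(gaps)

  n_ch <- device$n_sensors - 1L
  transits <- matrix(rnorm_truncated(n_obj * n_ch,
                                     device$transit_time_mean,
                                     device$transit_time_sd),
                     nrow = n_obj, ncol = n_ch)
  # time at sensor k (0-based): arrival + sum of the first k channel transits
  cum_transit <- if (n_ch == 1L) transits else t(apply(transits, 1L, cumsum))
  times <- cbind(0, cum_transit) + arrivals

  elapsed_h <- hours_from_seconds(times - times[, 1L])
  true_mass <- mass0 + mar * elapsed_h
  noise_pg <- matrix(stats::rnorm(n_obj * device$n_sensors,
                                  sd = device$mass_noise_sd / 1000),
                     nrow = n_obj)
  signal <- true_mass * device$calibration_scale + noise_pg

  events <- data.frame(
    object_id = rep(object_id, times = device$n_sensors),
    sensor_index = rep(seq_len(device$n_sensors) - 1L, each = n_obj),
    time_s = as.vector(times),
    signal = as.vector(signal),
    stringsAsFactors = FALSE)
  if (device$detection_dropout_rate > 0) {
    keep <- stats::runif(nrow(events)) >= device$detection_dropout_rate
    events <- events[keep, , drop = FALSE]
  }
  events <- events[order(events$time_s, events$object_id), , drop = FALSE]
  events$event_id <- sprintf("e%06d", seq_len(nrow(events)))
  truth_events <- events[, c("object_id", "sensor_index", "event_id")]
  rownames(truth_events) <- NULL
  events <- events[order(events$sensor_index, events$time_s),
                   c("event_id", "sensor_index", "time_s", "signal")]
  rownames(events) <- NULL

  truth <- data.frame(object_id = object_id, kind = kind,
                      true_mass_at_entry = mass0, true_mar = mar,
                      stringsAsFactors = FALSE)
  structure(list(events = events, truth = truth,
                 truth_events = truth_events,
                 device = device, population = population),
            class = "ssmr_run")
}

#' Group simulated events by their true object
#'
#' Uses the simulator's ground-truth event map to assemble the ideal traces
#' that a perfect event linker would recover -- the oracle against which
#' [build_traces()] and MAR recovery are validated.
#'
#' @param run An `ssmr_run` from [simulate_run()].
#' @return A long trace data.frame `trace_id, sensor_index, time_s, signal,
#'   event_id` where `trace_id` is the true `object_id`.
#' @export
truth_traces <- function(run) {
  if (!inherits(run, "ssmr_run"))
    stop_config("'run' must come from simulate_run()")
  ev <- merge(run$truth_events, run$events,
              by = c("event_id", "sensor_index"))
  ev <- ev[order(ev$object_id, ev$sensor_index), ]
  out <- data.frame(trace_id = ev$object_id,
                    sensor_index = ev$sensor_index,
                    time_s = ev$time_s, signal = ev$signal,
                    event_id = ev$event_id, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read and write sSMR event and ground-truth tables
#'
#' Events are stored as delimited text with header
#' `event_id,sensor_index,time_s,signal`; ground truth as a second file keyed
#' by `object_id` in which the per-sensor event ids are packed as
#' `sensor:event_id` pairs separated by `;`. Both round-trip losslessly.
#'
#' @param events,run Event data.frame / `ssmr_run` to write.
#' @param path File path.
#' @return The data read, or (for writers) `path` invisibly.
#' @name event_io
NULL

#' @rdname event_io
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname event_io
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(event_id = "character"))
  need <- c("event_id", "sensor_index", "time_s", "signal")
  if (!all(need %in% names(ev)))
    stop_config("event file must have columns %s", paste(need, collapse = ", "))
  ev[, need]
}

#' @rdname event_io
#' @export
write_truth <- function(run, path) {
  te <- run$truth_events
  packed <- vapply(split(te, te$object_id), function(d) {
    d <- d[order(d$sensor_index), ]
    paste(sprintf("%d:%s", d$sensor_index, d$event_id), collapse = ";")
  }, character(1))
  out <- run$truth
  out$event_ids <- unname(packed[out$object_id])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname event_io
#' @export
read_truth <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  pieces <- strsplit(tr$event_ids, ";", fixed = TRUE)
  truth_events <- do.call(rbind, lapply(seq_along(pieces), function(i) {
    kv <- strsplit(pieces[[i]], ":", fixed = TRUE)
    data.frame(object_id = tr$object_id[i],
               sensor_index = as.integer(vapply(kv, `[`, "", 1L)),
               event_id = vapply(kv, `[`, "", 2L),
               stringsAsFactors = FALSE)
  }))
  tr$event_ids <- NULL
  list(truth = tr, truth_events = truth_events)
}
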