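#' Assemble a full run configuration
#'
#' Bundles every stage's parameters plus a condition manifest into one
#' validated object. Each manifest entry describes one measured population:
#' the control arm (exactly one, flagged `is_control = TRUE`) and any number
#' of treatment arms whose drug response is modelled as an additive downward
#' MAR shift (`drug_effect`, pg/h; 0 = resistant model).
#'
#' @param device A [device_config()].
#' @param population A [population_config()] giving the untreated population
#'   (its `drug_effect` is overridden per condition).
#' @param conditions A list of lists, each with `sample_id`,
#'   `condition_label`, `drug_effect`, and optionally `is_control`.
#' @param match A [match_params()], or NULL for [default_match_params()].
#' @param bead_window Raw-signal gate for bead traces, `(lo, hi)`. NULL
#'   derives a window of nominal bead signal +/- 10 measurement SDs.
#' @param min_points Minimum trace length kept before MAR fitting.
#' @param alpha Family-wise significance level.
#' @param family_size Bonferroni family size m; NULL uses the number of
#'   treatment comparisons in the manifest.
#' @param seed Base seed; condition i is simulated with seed + i.
#' @return An object of class `ssmr_run_config`.
#' @export
run_config <- function(device = device_config(),
                       population = population_config(),
                       conditions = list(
                         list(sample_id = "S1", condition_label = "control",
                              drug_effect = 0, is_control = TRUE),
                         list(sample_id = "S1", condition_label = "treated",
                              drug_effect = 8)),
                       match = NULL,
                       bead_window = NULL,
                       min_points = 4L,
                       alpha = 0.05,
                       family_size = NULL,
                       seed = 1L) {
  if (!inherits(device, "ssmr_device"))
    stop_config("'device' must be created by device_config()")
  if (!inherits(population, "ssmr_population"))
    stop_config("'population' must be created by population_config()")
  if (!length(conditions))
    stop_config("at least one condition is required")
  is_ctl <- vapply(conditions, function(cc) isTRUE(cc$is_control), logical(1))
  if (sum(is_ctl) != 1L)
    stop_config("exactly one condition must have is_control = TRUE")
  for (cc in conditions)
    if (is.null(cc$sample_id) || is.null(cc$condition_label) ||
        is.null(cc$drug_effect))
      stop_config("every condition needs sample_id, condition_label, drug_effect")
  match <- match %||% default_match_params(device)
  if (is.null(bead_window)) {
    # wide enough for measurement noise plus bead-to-bead mass spread
    bead_sig <- population$bead_mass * device$calibration_scale
    half <- (10 * device$mass_noise_sd / 1000 +
             4 * population$bead_mass_cv * population$bead_mass + 0.05) *
      device$calibration_scale
    bead_window <- c(bead_sig - half, bead_sig + half)
  }
  seed <- check_count(seed, "seed", lower = 0L)
  n_cmp <- sum(!is_ctl)
  structure(list(device = device, population = population,
                 conditions = conditions, match = match,
                 bead_window = bead_window,
                 min_points = check_count(min_points, "min_points", 2L),
                 alpha = alpha,
                 family_size = family_size %||% max(n_cmp, 1L),
                 seed = seed),
            class = "ssmr_run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file mirrors [run_config()]: top-level sections `device`,
#' `population`, `match` (optional), `statistics` (optional: `alpha`,
#' `family_size`, `min_points`, `bead_window`), `seed`, and a `conditions`
#' list.
#'
#' @param path YAML file path.
#' @return An `ssmr_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  stats_cfg <- y$statistics %||% list()
  run_config(
    device = do.call(device_config, y$device %||% list()),
    population = do.call(population_config, y$population %||% list()),
    conditions = y$conditions,
    match = if (!is.null(y$match)) do.call(match_params, y$match) else NULL,
    bead_window = stats_cfg$bead_window %||% NULL,
    min_points = stats_cfg$min_points %||% 4L,
    alpha = stats_cfg$alpha %||% 0.05,
    family_size = stats_cfg$family_size %||% NULL,
    seed = y$seed %||% 1L)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run one condition through simulation, linking, calibration and MAR
#'
#' Convenience wrapper used by [run_pipeline()] and available directly:
#' simulates a run, builds and filters traces, gates beads, fits and applies
#' the calibration, and fits MAR records.
#'
#' @param config An `ssmr_run_config`.
#' @param drug_effect Additive MAR shift for this condition, pg/h.
#' @param seed Seed for this condition's simulation.
#' @return A list with `run`, `traces`, `calibration`, `records`, and stage
#'   `counts`.
#' @export
run_condition <- function(config, drug_effect = 0, seed = config$seed) {
  pop <- config$population
  pop$drug_effect <- drug_effect
  dev <- config$device
  dev$seed <- seed
  run <- stage("simulate", simulate_run(dev, pop))
  traces <- stage("build_traces", build_traces(run$events, config$match))
  traces <- stage("filter_traces", filter_traces(traces, config$min_points))
  gated <- stage("gate_beads", gate_beads(traces, config$bead_window))
  calib <- stage("calibrate",
                 fit_calibration(gated$beads, pop$bead_mass))
  cells <- stage("apply_calibration", apply_calibration(gated$cells, calib))
  records <- stage("fit_mar", fit_mars(cells))
  counts <- c(events = nrow(run$events),
              traces = length(unique(traces$trace_id)),
              beads = calib$n_beads_used,
              cells = length(unique(cells$trace_id)),
              records = nrow(records))
  list(run = run, traces = traces, calibration = calib,
       records = records, counts = counts)
}

#' Run the full drug-sensitivity pipeline
#'
#' Simulates every condition in the manifest, reconstructs traces,
#' calibrates, fits MAR records, summarizes each condition, and classifies
#' every treatment arm against the control arm (LDA/ROC/AUC plus
#' Welch/Bonferroni sensitivity call). All intermediate tables and results
#' are written under `out_dir` together with a machine-readable manifest
#' linking outputs to inputs and seeds; rerunning with the same config is
#' bit-identical.
#'
#' @param config An `ssmr_run_config` (or path to a YAML file for
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @return Invisibly, a list with per-condition `records` and `summaries`,
#'   per-comparison `results` (AUC, Welch, call), and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "ssmr_run_config"))
    stop_config("'config' must be created by run_config()")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  is_ctl <- vapply(config$conditions, function(cc) isTRUE(cc$is_control),
                   logical(1))
  labels <- vapply(config$conditions, `[[`, "", "condition_label")

  cond_out <- vector("list", length(config$conditions))
  names(cond_out) <- labels
  for (i in seq_along(config$conditions)) {
    cc <- config$conditions[[i]]
    res <- run_condition(config, drug_effect = cc$drug_effect,
                         seed = config$seed + i)
    res$summary <- stage("summarize",
                         summarize_condition(res$records, cc$condition_label))
    cond_out[[i]] <- res
    if (!is.null(out_dir)) {
      pre <- file.path(out_dir, sprintf("%s_%s", cc$sample_id,
                                        cc$condition_label))
      write_events(res$run$events, paste0(pre, "_events.csv"))
      write_truth(res$run, paste0(pre, "_truth.csv"))
      write_traces(res$traces, paste0(pre, "_traces.csv"))
      write_records(res$records, paste0(pre, "_records.csv"))
      write_calibration(res$calibration, paste0(pre, "_calibration.json"))
    }
  }

  control <- cond_out[[which(is_ctl)]]
  m <- config$family_size
  results <- list()
  for (i in which(!is_ctl)) {
    cc <- config$conditions[[i]]
    call <- stage("classify",
                  call_sensitivity(control$records, cond_out[[i]]$records,
                                   alpha = config$alpha, m = m,
                                   sample_id = cc$sample_id,
                                   condition = cc$condition_label))
    cls <- classify_pair(control$records, cond_out[[i]]$records)
    results[[cc$condition_label]] <- list(
      sample_id = cc$sample_id, condition = cc$condition_label,
      auc = call$auc,
      roc_points = cls$roc$roc[, c("fpr", "tpr")],
      t = call$t_statistic, df = call$welch_df,
      p_raw = call$p_raw, p_corrected = call$p_corrected,
      call = call$call)
  }

  manifest <- list(
    seed = config$seed,
    alpha = config$alpha,
    family_size = m,
    conditions = lapply(seq_along(config$conditions), function(i) {
      cc <- config$conditions[[i]]
      list(sample_id = cc$sample_id, condition_label = cc$condition_label,
           drug_effect = cc$drug_effect, is_control = isTRUE(cc$is_control),
           seed = config$seed + i,
           counts = as.list(cond_out[[i]]$counts))
    }))
  if (!is.null(out_dir)) {
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(conditions = cond_out,
                 summaries = lapply(cond_out, `[[`, "summary"),
                 results = results, manifest = manifest))
}
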