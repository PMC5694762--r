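#' Fit the mass accumulation rate of one trace
#'
#' The MAR of a cell is the slope of the ordinary least squares line through
#' its buoyant mass versus time points, with time converted to hours so MAR
#' is in pg/h:
#' \deqn{\mathrm{MAR} = \frac{\sum_i (t_i - \bar t)(m_i - \bar m)}
#'                           {\sum_i (t_i - \bar t)^2}.}
#' MAR per mass divides by the mean of the measured masses of that same
#' cell, normalizing out size and cell-cycle effects (units 1/h).
#'
#' @param trace Data.frame with columns `time_s` and `signal` (calibrated,
#'   pg) for a single trace; at least 2 points with distinct times.
#' @return A one-row data.frame (an MAR record): `trace_id, mean_mass_pg,
#'   mar_pg_per_h, mar_per_mass_per_h, n_points, residual_sd_pg,
#'   is_negative, valid`. `residual_sd_pg` is the OLS residual SD (0 when
#'   n = 2); records with non-positive mean mass are flagged `valid = FALSE`
#'   and excluded downstream.
#' @export
fit_mar <- function(trace) {
  if (!is.data.frame(trace) || !all(c("time_s", "signal") %in% names(trace)))
    stop_config("'trace' must have columns time_s and signal")
  n <- nrow(trace)
  if (n < 2L)
    stop_config("MAR fit requires at least 2 points")
  t_h <- hours_from_seconds(trace$time_s)
  if (length(unique(t_h)) == 1L)
    stop_config("degenerate trace: all times identical")
  m <- trace$signal
  tc <- t_h - mean(t_h)
  mar <- sum(tc * (m - mean(m))) / sum(tc^2)
  fitted <- mean(m) + mar * tc
  residual_sd <- if (n > 2L) sqrt(sum((m - fitted)^2) / (n - 2L)) else 0
  mean_mass <- mean(m)
  valid <- mean_mass > 0
  data.frame(trace_id = if ("trace_id" %in% names(trace))
               trace$trace_id[1L] else NA_character_,
             mean_mass_pg = mean_mass,
             mar_pg_per_h = mar,
             mar_per_mass_per_h = if (valid) mar / mean_mass else NA_real_,
             n_points = n,
             residual_sd_pg = residual_sd,
             is_negative = mar < 0,
             valid = valid,
             stringsAsFactors = FALSE)
}

#' Fit MAR records for every trace in a table
#'
#' @param traces Long calibrated trace data.frame (see [apply_calibration()]).
#' @return A data.frame of MAR records, one row per trace (see [fit_mar()]).
#' @export
fit_mars <- function(traces) {
  if (!is.data.frame(traces) || nrow(traces) == 0L)
    stop_config("no traces to fit")
  per_trace <- split(traces, traces$trace_id)
  out <- do.call(rbind, lapply(per_trace, fit_mar))
  out <- out[order(out$trace_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the MAR distribution of one condition
#'
#' @param records MAR record data.frame from [fit_mars()]; invalid records
#'   are dropped first.
#' @param label Condition label.
#' @return An object of class `ssmr_condition_summary`: `label`, `n_cells`,
#'   `mean_mar_per_mass` (1/h), `negative_fraction` (share of cells losing
#'   mass, an indicator of growth arrest or death), and `mass_quantiles`
#'   (pg, at 0/25/50/75/100%).
#' @export
summarize_condition <- function(records, label = "condition") {
  records <- records[records$valid, , drop = FALSE]
  if (nrow(records) == 0L)
    stop_config("no valid MAR records to summarize")
  structure(list(
    label = label,
    n_cells = nrow(records),
    mean_mar_per_mass = mean(records$mar_per_mass_per_h),
    negative_fraction = mean(records$is_negative),
    mass_quantiles = stats::quantile(records$mean_mass_pg,
                                     probs = c(0, 0.25, 0.5, 0.75, 1))),
    class = "ssmr_condition_summary")
}

#' @export
print.ssmr_condition_summary <- function(x, ...) {
  cat(sprintf(paste0("Condition '%s': %d cells\n",
                     "  mean MAR/mass %.4g 1/h; negative-MAR fraction %.3f\n",
                     "  mass median %.3g pg (IQR %.3g-%.3g)\n"),
              x$label, x$n_cells, x$mean_mar_per_mass, x$negative_fraction,
              x$mass_quantiles[["50%"]], x$mass_quantiles[["25%"]],
              x$mass_quantiles[["75%"]]))
  invisible(x)
}

#' Read and write MAR record tables
#'
#' Delimited text with header `trace_id,mean_mass_pg,mar_pg_per_h,
#' mar_per_mass_per_h,n_points,residual_sd_pg`.
#'
#' @param records MAR record data.frame.
#' @param path File path.
#' @name record_io
#' @export
write_records <- function(records, path) {
  cols <- c("trace_id", "mean_mass_pg", "mar_pg_per_h", "mar_per_mass_per_h",
            "n_points", "residual_sd_pg")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname record_io
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(trace_id = "character"))
  rec$is_negative <- rec$mar_pg_per_h < 0
  rec$valid <- rec$mean_mass_pg > 0
  rec
}
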