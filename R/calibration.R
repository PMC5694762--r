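#' Separate bead traces from cell traces
#'
#' Spiked polystyrene beads are tight in mass while cells are broad, so a
#' simple gate on the mean raw signal of each trace separates the two. The
#' gate is a closed interval: a trace whose mean lies exactly on a boundary
#' counts as a bead.
#'
#' @param traces Long trace data.frame from [build_traces()].
#' @param bead_window Length-2 numeric `(lo, hi)` in raw signal units.
#' @return A list with `beads` and `cells`, each a long trace data.frame;
#'   the partition is exhaustive and disjoint.
#' @export
gate_beads <- function(traces, bead_window) {
  if (!is.numeric(bead_window) || length(bead_window) != 2L ||
      bead_window[1L] >= bead_window[2L])
    stop_config("'bead_window' must be (lo, hi) with lo < hi")
  means <- tapply(traces$signal, traces$trace_id, mean)
  bead_ids <- names(means)[means >= bead_window[1L] & means <= bead_window[2L]]
  is_bead <- traces$trace_id %in% bead_ids
  beads <- traces[is_bead, , drop = FALSE]
  cells <- traces[!is_bead, , drop = FALSE]
  rownames(beads) <- rownames(cells) <- NULL
  list(beads = beads, cells = cells)
}

ols_slope <- function(t_h, y) {
  tc <- t_h - mean(t_h)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Fit the bead calibration model
#'
#' The beads provide both the absolute-mass scale and the zero-MAR baseline:
#' `scale` converts raw signal to picograms so that the grand mean of all
#' bead signals maps exactly onto the nominal bead buoyant mass;
#' `bead_slope_mean` (pg/h, expected 0) checks the baseline; and the pooled
#' SD of calibrated bead signals about each bead's own mean estimates the
#' single-measurement noise in femtograms.
#'
#' @param bead_traces Long trace data.frame of bead traces.
#' @param bead_mass_nominal Nominal bead buoyant mass, pg (see
#'   [bead_buoyant_mass()]).
#' @return An object of class `ssmr_calibration` with fields `scale`,
#'   `bead_mass_nominal`, `bead_signal_mean`, `bead_slope_mean`,
#'   `noise_sd_estimate` (fg), `n_beads_used`.
#' @export
fit_calibration <- function(bead_traces, bead_mass_nominal) {
  check_scalar(bead_mass_nominal, "bead_mass_nominal",
               lower = 0, allow_lower = FALSE)
  if (!is.data.frame(bead_traces) || nrow(bead_traces) == 0L)
    stop_config("calibration requires beads: no bead traces supplied")
  bead_signal_mean <- mean(bead_traces$signal)
  if (bead_signal_mean <= 0)
    stop_config("mean bead signal must be positive")
  scale <- bead_mass_nominal / bead_signal_mean

  per_bead <- split(bead_traces, bead_traces$trace_id)
  slopes <- vapply(per_bead, function(d) {
    if (nrow(d) < 2L) return(NA_real_)
    ols_slope(hours_from_seconds(d$time_s), d$signal * scale)
  }, numeric(1))
  resid_ss <- vapply(per_bead, function(d) {
    m <- d$signal * scale
    sum((m - mean(m))^2)
  }, numeric(1))
  dof <- vapply(per_bead, nrow, integer(1)) - 1L
  noise_sd <- if (sum(dof) > 0L) sqrt(sum(resid_ss) / sum(dof)) * 1000 else 0

  structure(list(scale = scale,
                 bead_mass_nominal = bead_mass_nominal,
                 bead_signal_mean = bead_signal_mean,
                 bead_slope_mean = mean(slopes, na.rm = TRUE),
                 noise_sd_estimate = noise_sd,
                 n_beads_used = length(per_bead)),
            class = "ssmr_calibration")
}

#' @export
print.ssmr_calibration <- function(x, ...) {
  cat(sprintf(paste0("sSMR bead calibration: scale %.6g pg/unit from %d beads\n",
                     "  bead slope %.4g pg/h (expect ~0); ",
                     "noise SD %.3g fg\n"),
              x$scale, x$n_beads_used, x$bead_slope_mean, x$noise_sd_estimate))
  invisible(x)
}

#' Convert raw trace signals to buoyant mass
#'
#' Multiplies every signal by the calibration scale, after which signals are
#' absolute buoyant masses in picograms. Applying a model with scale 1 is
#' the identity.
#'
#' @param traces Long trace data.frame.
#' @param model An `ssmr_calibration` from [fit_calibration()].
#' @return The traces with `signal` in pg and attribute `calibrated = TRUE`.
#' @export
apply_calibration <- function(traces, model) {
  if (!inherits(model, "ssmr_calibration"))
    stop_config("'model' must be created by fit_calibration()")
  traces$signal <- traces$signal * model$scale
  attr(traces, "calibrated") <- TRUE
  traces
}

#' Serialize a calibration model to/from JSON
#'
#' @param model An `ssmr_calibration`.
#' @param path File path.
#' @name calibration_io
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_calibration <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "ssmr_calibration")
}
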