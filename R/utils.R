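# Internal validation helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'%s' must be a single finite number", name)
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop_config("'%s' = %g is outside its allowed range", name, x)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_config("'%s' must be a single non-negative integer", name)
  if (x < lower)
    stop_config("'%s' must be >= %d", name, lower)
  invisible(as.integer(x))
}

hours_from_seconds <- function(t_s) t_s / 3600
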