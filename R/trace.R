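#' Time-temperature trace
#'
#' The experimental observable of a calorimetric hyperthermia run: sampled
#' suspension temperature versus time, with a per-sample flag saying whether
#' the alternating magnetic field was on. The standard protocol is a single
#' on-then-off switch (e.g. 600 s heating, 600 s cooling), so `field_on` must
#' be a prefix of `TRUE`s followed by a suffix of `FALSE`s.
#'
#' @param time_s Strictly increasing sample times (s), starting at or after 0.
#' @param temperature_K Temperatures (K), finite and positive.
#' @param field_on Logical vector (same length), or a single switch-off time
#'   via `t_off` instead.
#' @param t_off Alternative to `field_on`: the field is on for
#'   `time_s < t_off`.
#' @return A data frame of class `temperature_trace` with columns `time_s`,
#'   `temperature_K`, `field_on`.
#' @export
temperature_trace <- function(time_s, temperature_K, field_on = NULL,
                              t_off = NULL) {
  time_s <- as.numeric(time_s)
  temperature_K <- as.numeric(temperature_K)
  if (length(time_s) != length(temperature_K))
    stop("time and temperature must have equal length", call. = FALSE)
  if (length(time_s) == 0)
    stop("empty trace", call. = FALSE)
  if (any(!is.finite(time_s)) || any(!is.finite(temperature_K)))
    stop("non-finite values in trace", call. = FALSE)
  if (any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1] + 1L
    stop(sprintf("time not strictly increasing at sample %d", bad),
         call. = FALSE)
  }
  if (any(temperature_K <= 0))
    stop("temperatures must be positive (Kelvin)", call. = FALSE)
  if (is.null(field_on)) {
    if (is.null(t_off)) t_off <- Inf
    field_on <- time_s < t_off
  }
  field_on <- as.logical(field_on)
  if (length(field_on) != length(time_s))
    stop("field_on must match the trace length", call. = FALSE)
  if (is.unsorted(rev(field_on)))
    stop("field_on must be an on-then-off pattern (prefix TRUE)", call. = FALSE)
  structure(data.frame(time_s = time_s, temperature_K = temperature_K,
                       field_on = field_on),
            class = c("temperature_trace", "data.frame"))
}

#' @export
print.temperature_trace <- function(x, ...) {
  n_on <- sum(x$field_on)
  cat(sprintf(
    "Temperature trace: %d samples over %g s (%d field-on), T in [%.2f, %.2f] K\n",
    nrow(x), x$time_s[nrow(x)] - x$time_s[1], n_on,
    min(x$temperature_K), max(x$temperature_K)))
  invisible(x)
}

#' Field switch-off time of a trace
#'
#' First time at which the field is off, or `Inf` if it never switches off.
#'
#' @param trace A [temperature_trace()].
#' @return Switch-off time (s).
#' @export
switch_off_time <- function(trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  off <- which(!trace$field_on)
  if (length(off) == 0) Inf else trace$time_s[off[1]]
}

#' Heating / cooling segments of a trace
#'
#' @param trace A [temperature_trace()].
#' @return The field-on (`heating_segment`) or field-off (`cooling_segment`)
#'   rows as a `temperature_trace`.
#' @export
heating_segment <- function(trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  seg <- trace[trace$field_on, , drop = FALSE]
  if (nrow(seg) == 0) stop("insufficient data: no field-on samples",
                           call. = FALSE)
  temperature_trace(seg$time_s, seg$temperature_K, seg$field_on)
}

#' @rdname heating_segment
#' @export
cooling_segment <- function(trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  seg <- trace[!trace$field_on, , drop = FALSE]
  if (nrow(seg) == 0) stop("insufficient data: no cooling samples",
                           call. = FALSE)
  temperature_trace(seg$time_s, seg$temperature_K, seg$field_on)
}
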