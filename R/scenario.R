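#' Piecewise-constant storage temperature scenario
#'
#' A storage scenario is an ordered sequence of constant-temperature
#' periods, e.g. 2.8 d at 17.8 degC followed by 3.2 d at 13.5 degC.
#' Within each segment the model has an exact analytical solution, so
#' scenarios built from segments are evaluated without ODE integration.
#'
#' @param durations Segment durations in days (all > 0).
#' @param temps_c Segment temperatures in degrees Celsius, same length.
#'   Temperatures outside `[0, 45]` degC are rejected as implausible for
#'   mango storage.
#' @return An object of class `temp_scenario` (type `"segments"`).
#' @seealso [temp_trace()] for logged temperatures, [mean_storage_temp()].
#' @export
#' @examples
#' sc <- temp_scenario(c(2.8, 3.2), c(17.8, 13.5))
#' mean_storage_temp(sc)
temp_scenario <- function(durations, temps_c) {
  if (length(durations) == 0L) stop("empty scenario", call. = FALSE)
  if (length(durations) != length(temps_c))
    stop("'durations' and 'temps_c' must have equal length", call. = FALSE)
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("segment durations must be strictly positive", call. = FALSE)
  check_temp_range(temps_c)
  structure(list(durations = as.numeric(durations),
                 temps_c = as.numeric(temps_c)),
            class = "temp_scenario", type = "segments")
}

#' Logged temperature trace
#'
#' A temperature record from a data logger: ordered (time, temperature)
#' pairs, interpolated piecewise-linearly between log points. Model
#' evaluation under a trace uses ODE integration ([firmness_ode()]).
#'
#' @param times_d Logging times in days, strictly increasing, starting
#'   at 0.
#' @param temps_c Logged temperatures in degrees Celsius.
#' @return An object of class `temp_scenario` (type `"trace"`).
#' @export
temp_trace <- function(times_d, temps_c) {
  if (length(times_d) < 2L)
    stop("a trace needs at least two log points", call. = FALSE)
  if (length(times_d) != length(temps_c))
    stop("'times_d' and 'temps_c' must have equal length", call. = FALSE)
  if (any(diff(times_d) <= 0))
    stop("trace times must be strictly increasing", call. = FALSE)
  if (times_d[1] < 0) stop("trace times must be >= 0", call. = FALSE)
  check_temp_range(temps_c)
  structure(list(times_d = as.numeric(times_d),
                 temps_c = as.numeric(temps_c)),
            class = "temp_scenario", type = "trace")
}

check_temp_range <- function(temps_c) {
  if (any(!is.finite(temps_c)) || any(temps_c < 0) || any(temps_c > 45))
    stop("temperatures must lie within [0, 45] degC", call. = FALSE)
  invisible(TRUE)
}

scenario_type <- function(scenario) attr(scenario, "type")

#' @export
print.temp_scenario <- function(x, ...) {
  if (scenario_type(x) == "segments") {
    cat("Temperature scenario:",
        paste(sprintf("%g d at %g degC", x$durations, x$temps_c),
              collapse = ", "), "\n")
  } else {
    cat(sprintf("Logged temperature trace: %d points over %g d (%g-%g degC)\n",
                length(x$times_d), diff(range(x$times_d)),
                min(x$temps_c), max(x$temps_c)))
  }
  invisible(x)
}

#' Total duration of a scenario (days)
#' @param scenario A [temp_scenario()] or [temp_trace()].
#' @return Duration in days.
#' @export
scenario_duration <- function(scenario) {
  stopifnot(inherits(scenario, "temp_scenario"))
  if (scenario_type(scenario) == "segments") sum(scenario$durations)
  else max(scenario$times_d)
}

#' Temperature at a given time
#' @inheritParams scenario_duration
#' @param t Time(s) in days within the scenario duration.
#' @return Temperature(s) in degC. Piecewise-constant for segment
#'   scenarios (right-continuous at switches), piecewise-linear for traces.
#' @export
temperature_at <- function(scenario, t) {
  stopifnot(inherits(scenario, "temp_scenario"))
  if (any(t < 0) || any(t > scenario_duration(scenario) + 1e-9))
    stop("time outside scenario duration", call. = FALSE)
  if (scenario_type(scenario) == "segments") {
    ends <- cumsum(scenario$durations)
    idx <- pmin(findInterval(t, c(0, ends[-length(ends)]),
                             rightmost.closed = FALSE), length(ends))
    scenario$temps_c[pmax(idx, 1L)]
  } else {
    approxfun(scenario$times_d, scenario$temps_c, rule = 2)(t)
  }
}

#' Time-weighted mean storage temperature
#'
#' Duration-weighted mean temperature of a scenario, in degrees Celsius.
#' This is the "average temperature during the storage period(s)" at
#' which the ethylene factor is evaluated: for a two-period scenario the
#' mean is weighted by the period durations; for a logged trace it is the
#' trapezoidal time average.
#'
#' @inheritParams scenario_duration
#' @return Mean temperature (degC).
#' @export
#' @examples
#' mean_storage_temp(temp_scenario(c(2.8, 3.2), c(17.8, 13.5)))  # 15.507
mean_storage_temp <- function(scenario) {
  stopifnot(inherits(scenario, "temp_scenario"))
  if (scenario_type(scenario) == "segments") {
    sum(scenario$durations * scenario$temps_c) / sum(scenario$durations)
  } else {
    tt <- scenario$times_d; tc <- scenario$temps_c
    sum(diff(tt) * (tc[-1] + tc[-length(tc)]) / 2) / diff(range(tt))
  }
}

#' Parse a compact scenario string
#'
#' Parses the command-line syntax `"dur1:temp1,dur2:temp2"` (days:degC)
#' into a [temp_scenario()], e.g. `"2.8:17.8,3.2:13.5"`.
#'
#' @param x A scenario string.
#' @return A `temp_scenario`.
#' @export
parse_scenario <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(trimws(strsplit(x, ",", fixed = TRUE)[[1]]), ":",
                    fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("scenario string must be 'dur:temp[,dur:temp...]'", call. = FALSE)
  m <- suppressWarnings(vapply(parts, as.numeric, numeric(2)))
  if (any(is.na(m)))
    stop("non-numeric duration or temperature in scenario string",
         call. = FALSE)
  temp_scenario(m[1, ], m[2, ])
}
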