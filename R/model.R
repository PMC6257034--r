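# Analytical building blocks.
#
# Within a constant-temperature segment, with A = kfenz(T) * Eth and
# kd = kd(T), the lumped enzyme level e(t) = k_f * Enz(t) obeys
#   e(tau)  = e0 * exp(-kd tau) + A * phi1(kd, tau)
# and the log "survival" factor of the softenable firmness fraction,
# log S = log((F - F_fix) / (F0 - F_fix)) = -integral of e, obeys
#   logS(tau) = logS0 - e0 * phi1(kd, tau) - A * phi2(kd, tau)
# with phi1 = (1 - exp(-kd tau)) / kd and phi2 = (tau - phi1) / kd.
# For kd * tau < 1e-4 both are evaluated by 3-term Taylor expansions to
# avoid catastrophic cancellation (this also covers kd = 0 exactly, where
# phi2 -> tau^2 / 2 and the exponent tends to -A t^2 / 2).

phi1 <- function(kd, tau) {
  x <- kd * tau
  small <- x < 1e-4
  out <- numeric(length(x))
  if (any(small)) {
    xs <- x[small]
    out[small] <- (tau * rep_len(1, length(x)))[small] *
      (1 - xs / 2 + xs * xs / 6)
  }
  if (any(!small)) {
    kdv <- rep_len(kd, length(x))
    out[!small] <- (1 - exp(-x[!small])) / kdv[!small]
  }
  out
}

phi2 <- function(kd, tau) {
  x <- kd * tau
  small <- x < 1e-4
  out <- numeric(length(x))
  if (any(small)) {
    xs <- x[small]
    tv <- rep_len(tau, length(x))[small]
    out[small] <- tv * tv * (1 / 2 - xs / 6 + xs * xs / 24)
  }
  if (any(!small)) {
    kdv <- rep_len(kd, length(x))[!small]
    out[!small] <- (x[!small] - 1 + exp(-x[!small])) / (kdv * kdv)
  }
  out
}

# Exact propagation of (log S, enzyme) across piecewise-constant segments.
# times are absolute (days from scenario start); returns logS and enz at
# those times. eth, enz0 scalar.
soften_propagate <- function(kp, eth, enz0, durations, temps_c, times) {
  n_seg <- length(durations)
  bounds <- cumsum(c(0, durations))
  tk <- celsius_to_kelvin(temps_c)
  A <- arrhenius_rate(kp$kfenz_ref, kp$E_fenz, tk, kp$t_ref) * eth
  kd <- arrhenius_rate(kp$kd_ref, kp$E_d, tk, kp$t_ref)

  e_start <- numeric(n_seg)
  logS_start <- numeric(n_seg)
  e_start[1] <- enz0
  if (n_seg > 1) {
    for (j in seq_len(n_seg - 1)) {
      tau <- durations[j]
      logS_start[j + 1] <- logS_start[j] -
        e_start[j] * phi1(kd[j], tau) - A[j] * phi2(kd[j], tau)
      e_start[j + 1] <- e_start[j] * exp(-kd[j] * tau) + A[j] * phi1(kd[j], tau)
    }
  }

  idx <- findInterval(times, bounds, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_seg] <- n_seg
  tau <- times - bounds[idx]
  p1 <- phi1(kd[idx], tau)
  list(logS = logS_start[idx] - e_start[idx] * p1 - A[idx] * phi2(kd[idx], tau),
       enz = e_start[idx] * exp(-kd[idx] * tau) + A[idx] * p1)
}

#' Enzyme level under constant temperature
#'
#' Level of the softening-enzyme pool at time `t` for a fruit held at a
#' constant temperature. Enzyme is produced at the constant rate
#' `k_enz * Eth` and degrades first-order with rate `k_d`, so with zero
#' initial enzyme the level rises as
#' `(k_fenz * Eth / k_d) * (1 - exp(-k_d t))` towards the plateau
#' `k_fenz * Eth / k_d`. Levels are reported in lumped units `k_f * Enz`
#' (arbitrary), absorbing the unidentifiable factor `k_f`.
#'
#' @param t Time(s) in days, >= 0.
#' @param kp A [kinetic_params()] object.
#' @param fs A [fruit_state()] object (uses `eth` and `enz0`).
#' @param temp_c Storage temperature (degC).
#' @return Enzyme level(s) at `t` (arbitrary units).
#' @export
enzyme_level <- function(t, kp, fs, temp_c) {
  stopifnot(inherits(kp, "kinetic_params"), inherits(fs, "fruit_state"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  check_temp_range(temp_c)
  soften_propagate(kp, fs$eth, fs$enz0, durations = max(t, 1),
                   temps_c = temp_c, times = t)$enz
}

#' Closed-form firmness under constant temperature
#'
#' Analytical solution of the softening model at constant temperature:
#' with zero initial enzyme,
#' `F(t) = F_fix + (F0 - F_fix) * exp(k_fenz * Eth * ((1 - exp(-k_d t)) / k_d^2 - t / k_d))`,
#' with `k_fenz` and `k_d` evaluated at `temp_c` by [arrhenius_rate()].
#' A non-zero initial enzyme level (`fs$enz0 > 0`) uses the full
#' analytical solution. Near-zero `k_d` is handled by a series expansion
#' of the exponent (limit `-k_fenz * Eth * t^2 / 2`), not by division.
#'
#' @inheritParams enzyme_level
#' @return Firmness value(s) in FI units; always in `(F_fix, F0]` and
#'   non-increasing in `t`.
#' @export
#' @examples
#' kp <- cultivar_params("Keitt")
#' fs <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7)
#' firmness_closed_form(0:8, kp, fs, temp_c = 24)
firmness_closed_form <- function(t, kp, fs, temp_c) {
  stopifnot(inherits(kp, "kinetic_params"), inherits(fs, "fruit_state"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  check_temp_range(temp_c)
  pr <- soften_propagate(kp, fs$eth, fs$enz0, durations = max(t, 1),
                         temps_c = temp_c, times = t)
  fs$ffix + (fs$F0 - fs$ffix) * exp(pr$logS)
}

#' Firmness trajectory under a piecewise-constant scenario (analytic)
#'
#' Evaluates the model exactly under a segment scenario by chaining the
#' per-segment analytical solution: the enzyme level and the log of the
#' softenable firmness fraction are propagated across each temperature
#' switch. Agrees with [firmness_ode()] to solver tolerance and is much
#' faster; used internally by the fitting routines.
#'
#' @param scenario A [temp_scenario()] built from segments.
#' @param kp A [kinetic_params()] object.
#' @param fs A [fruit_state()] object.
#' @param times Evaluation times (days) within the scenario duration.
#' @return A `firmness_trajectory` data frame with columns `time_d`,
#'   `firmness_fi`, `enzyme`.
#' @export
firmness_analytic <- function(scenario, kp, fs, times) {
  stopifnot(inherits(scenario, "temp_scenario"))
  if (scenario_type(scenario) != "segments")
    stop("analytic evaluation needs a segment scenario; use firmness_ode() ",
         "for logged traces", call. = FALSE)
  check_times(times, scenario)
  pr <- soften_propagate(kp, fs$eth, fs$enz0, scenario$durations,
                         scenario$temps_c, times)
  new_trajectory(times, fs$ffix + (fs$F0 - fs$ffix) * exp(pr$logS), pr$enz)
}

check_times <- function(times, scenario) {
  if (any(times < 0)) stop("evaluation times must be >= 0", call. = FALSE)
  if (any(times > scenario_duration(scenario) + 1e-9))
    stop("evaluation time beyond scenario duration", call. = FALSE)
  invisible(TRUE)
}

new_trajectory <- function(times, firmness, enzyme) {
  structure(data.frame(time_d = times, firmness_fi = firmness,
                       enzyme = enzyme),
            class = c("firmness_trajectory", "data.frame"))
}

#' Firmness trajectory by ODE integration
#'
#' Integrates the coupled system `d(Enz)/dt = k_enz * Eth - k_d * Enz`,
#' `dF/dt = -k_f * (F - F_fix) * Enz` (in the lumped `k_fenz`
#' parameterisation) with rate constants re-evaluated from the
#' instantaneous temperature. Segment scenarios are integrated segment by
#' segment so that temperature discontinuities coincide with integrator
#' restarts; logged traces use piecewise-linear interpolation of the
#' temperature. Relative tolerance 1e-8, so the analytical solution acts
#' as a strict cross-check on constant-temperature scenarios.
#'
#' @inheritParams firmness_analytic
#' @param scenario A [temp_scenario()] or [temp_trace()].
#' @param rtol,atol Solver tolerances passed to [deSolve::lsoda()].
#' @return A `firmness_trajectory` data frame (`time_d`, `firmness_fi`,
#'   `enzyme`).
#' @export
#' @examples
#' kp <- cultivar_params("Keitt")
#' fs <- fruit_state(F0 = 60, eth = 1.52, ffix = 12.7)
#' sc <- temp_scenario(c(3, 10), c(18, 22))
#' firmness_ode(sc, kp, fs, times = seq(0, 13, by = 1))
firmness_ode <- function(scenario, kp, fs, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(scenario, "temp_scenario"),
            inherits(kp, "kinetic_params"), inherits(fs, "fruit_state"))
  check_times(times, scenario)
  ord <- order(times)
  ts <- times[ord]

  rates_at <- function(temp_c) {
    tk <- celsius_to_kelvin(temp_c)
    c(A = arrhenius_rate(kp$kfenz_ref, kp$E_fenz, tk, kp$t_ref) * fs$eth,
      kd = arrhenius_rate(kp$kd_ref, kp$E_d, tk, kp$t_ref))
  }

  if (scenario_type(scenario) == "segments") {
    bounds <- cumsum(c(0, scenario$durations))
    state <- c(enz = fs$enz0, F = fs$F0)
    out_f <- numeric(length(ts)); out_e <- numeric(length(ts))
    deriv <- function(t, y, parms) {
      list(c(parms[["A"]] - parms[["kd"]] * y[1],
             -(y[2] - fs$ffix) * y[1]))
    }
    for (j in seq_along(scenario$durations)) {
      lo <- bounds[j]; hi <- bounds[j + 1]
      sel <- ts >= lo - 1e-12 & ts <= hi + 1e-12
      tt <- sort(unique(c(lo, pmin(pmax(ts[sel], lo), hi), hi)))
      sol <- deSolve::lsoda(state, tt, deriv, parms = rates_at(scenario$temps_c[j]),
                            rtol = rtol, atol = atol)
      if (any(sel)) {
        ii <- match(round(pmin(pmax(ts[sel], lo), hi), 12), round(sol[, 1], 12))
        out_e[sel] <- sol[ii, 2]
        out_f[sel] <- sol[ii, 3]
      }
      state <- c(enz = unname(sol[nrow(sol), 2]), F = unname(sol[nrow(sol), 3]))
    }
  } else {
    temp_fun <- approxfun(scenario$times_d, scenario$temps_c, rule = 2)
    deriv <- function(t, y, parms) {
      r <- rates_at(temp_fun(t))
      list(c(r[["A"]] - r[["kd"]] * y[1], -(y[2] - fs$ffix) * y[1]))
    }
    tt <- sort(unique(c(0, ts, scenario$times_d)))
    sol <- deSolve::lsoda(c(enz = fs$enz0, F = fs$F0), tt, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    ii <- match(round(ts, 12), round(sol[, 1], 12))
    out_e <- sol[ii, 2]; out_f <- sol[ii, 3]
  }

  inv <- order(ord)
  new_trajectory(times, out_f[inv], out_e[inv])
}

#' Ethylene factor (EF)
#'
#' EF = k_fenz x Eth evaluated at the time-weighted mean storage
#' temperature: the effective rate at which the enzyme system responds to
#' the ethylene driver. `k_fenz` is scaled from its reference value to
#' the mean storage temperature by [arrhenius_rate()].
#'
#' @param kp A [kinetic_params()] object.
#' @param eth Ethylene driver estimate (arbitrary units, >= 0).
#' @param scenario A [temp_scenario()] describing the storage period(s).
#' @return The ethylene factor (d^-1-scaled product).
#' @export
#' @examples
#' # untreated 'Keitt' sub-batch stored 16 d at 20 degC, Eth = 2.23
#' ethylene_factor(cultivar_params("Keitt"), 2.23, temp_scenario(16, 20))
ethylene_factor <- function(kp, eth, scenario) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (any(eth < 0)) stop("'eth' must be >= 0", call. = FALSE)
  tk <- celsius_to_kelvin(mean_storage_temp(scenario))
  arrhenius_rate(kp$kfenz_ref, kp$E_fenz, tk, kp$t_ref) * eth
}
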