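#' Breath-by-breath simulation to the intrinsic-PEEP steady state
#'
#' An independent, brute-force realization of the residual-volume series
#' behind the closed-form intrinsic PEEP: constant-flow inspiration adds the
#' tidal volume; passive expiration empties the compartment exponentially
#' (time constant tau = R/E) towards the external-PEEP equilibrium volume.
#' The expiratory decay is advanced with the exact exponential update, not
#' an Euler step, so the only truncation error is the finite number of
#' breaths. Breaths are iterated from the equilibrium volume (zero volume
#' above the external-PEEP baseline) until the end-expiratory volume changes
#' by less than `tol` relatively.
#'
#' This function never evaluates the geometric-series formula; it exists to
#' cross-validate [intrinsic_peep()] and [mechanical_power()].
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param pattern A [ventilation_pattern()] object.
#' @param dt Time step, s, used for the inspiratory work integral; default
#'   `min(t_in, tau)/1000` (or `t_in/1000` when tau = 0).
#' @param tol Relative convergence tolerance on end-expiratory volume.
#' @param max_breaths Breath cap before a convergence error is raised.
#' @return An object of class `steady_state_report`: `ipeep_sim` (mbar),
#'   `work_per_breath_J` (numeric airway pressure-volume integral over one
#'   steady-state inspiration, J), `n_breaths_to_converge`, `residual`
#'   (relative change at the last breath) and `end_expiratory_volume_L`
#'   (above the external-PEEP equilibrium).
#' @examples
#' mech <- respiratory_mechanics(10, 1, 7, 0.2)
#' pat  <- ventilation_pattern(0.5, 15, 1)
#' sim  <- simulate_to_steady_state(mech, pat)
#' c(sim$ipeep_sim, intrinsic_peep(mech, pat))
#' @export
simulate_to_steady_state <- function(mech, pattern, dt = NULL, tol = 1e-10,
                                     max_breaths = 10000L) {
  stopifnot(inherits(mech, "respiratory_mechanics"),
            inherits(pattern, "ventilation_pattern"))
  check_scalar(tol, "tol", positive = TRUE)
  tau <- time_constant(mech)
  decay <- if (tau == 0) 0 else exp(-pattern$t_ex / tau)
  v_ee <- 0   # volume above the external-PEEP equilibrium
  n <- 0L
  residual <- Inf
  repeat {
    n <- n + 1L
    v_new <- (v_ee + pattern$tidal_volume) * decay
    residual <- abs(v_new - v_ee) / max(v_new, .Machine$double.xmin)
    v_ee <- v_new
    if (residual < tol) break
    if (n >= max_breaths)
      stop_convergence(sprintf(
        "end-expiratory volume did not converge within %d breaths (residual %.3g)",
        max_breaths, residual))
  }
  ipeep_sim <- pattern$external_peep + mech$elastance * v_ee
  work <- work_per_breath(mech, pattern, ipeep_state = ipeep_sim, dt = dt)
  structure(
    list(ipeep_sim = ipeep_sim,
         work_per_breath_J = work,
         n_breaths_to_converge = n,
         residual = residual,
         end_expiratory_volume_L = v_ee),
    class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat("Steady-state breath simulation\n")
  cat(sprintf("  iPEEP: %.8g mbar   work/breath: %.8g J\n",
              x$ipeep_sim, x$work_per_breath_J))
  cat(sprintf("  converged after %d breaths (residual %.3g)\n",
              x$n_breaths_to_converge, x$residual))
  invisible(x)
}

#' End-expiratory volume after a finite number of breaths
#'
#' Runs the breath iteration for exactly `n_breaths` breaths starting from
#' the external-PEEP equilibrium volume and returns the end-expiratory
#' volume above that equilibrium — the partial sum of the residual-volume
#' series. Exposed for validation against the closed-form geometric partial
#' sum.
#'
#' @inheritParams simulate_to_steady_state
#' @param n_breaths Number of breaths to simulate, >= 1.
#' @return End-expiratory volume above equilibrium, L.
#' @export
end_expiratory_volume <- function(mech, pattern, n_breaths) {
  stopifnot(inherits(mech, "respiratory_mechanics"),
            inherits(pattern, "ventilation_pattern"))
  check_scalar(n_breaths, "n_breaths", positive = TRUE)
  tau <- time_constant(mech)
  decay <- if (tau == 0) 0 else exp(-pattern$t_ex / tau)
  v_ee <- 0
  for (k in seq_len(n_breaths)) v_ee <- (v_ee + pattern$tidal_volume) * decay
  v_ee
}

#' Numeric inspiratory work of one breath
#'
#' Integrates airway pressure times flow over the inspiration of one breath
#' at a given end-expiratory pressure state. During constant-flow
#' inspiration the airway-opening pressure is
#' `ipeep_state + E * delivered volume + R * flow`; the integral is formed
#' numerically (trapezoidal rule by default) on a uniform time grid, with no
#' recourse to the closed-form work expressions.
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param pattern A [ventilation_pattern()] object.
#' @param ipeep_state End-expiratory baseline pressure, mbar (e.g. the
#'   steady-state intrinsic PEEP; atmospheric baseline = 0).
#' @param dt Time step, s; default `min(t_in, tau)/1000` (or `t_in/1000`
#'   when tau = 0). Steps coarser than `t_in/100` raise a precision error.
#' @param method `"trapezoid"` or `"midpoint"` quadrature.
#' @return Work in J (1 mbar L = 0.1 J).
#' @examples
#' mech <- respiratory_mechanics(10, 0, 0, 0.2)
#' pat  <- ventilation_pattern(0.5, 12, 1)
#' work_per_breath(mech, pat, ipeep_state = 0)  # 0.125 J, pure elastic
#' @export
work_per_breath <- function(mech, pattern, ipeep_state, dt = NULL,
                            method = c("trapezoid", "midpoint")) {
  stopifnot(inherits(mech, "respiratory_mechanics"),
            inherits(pattern, "ventilation_pattern"))
  check_scalar(ipeep_state, "ipeep_state", nonneg = TRUE)
  method <- match.arg(method)
  tau <- time_constant(mech)
  if (is.null(dt)) {
    dt <- if (tau > 0) min(pattern$t_in, tau) / 1000 else pattern$t_in / 1000
  }
  check_scalar(dt, "dt", positive = TRUE)
  if (dt > pattern$t_in / 100)
    stop_invalid_parameter(sprintf(
      "dt = %g s is too coarse for the inspiration time %g s (need dt <= t_in/100)",
      dt, pattern$t_in))
  flow <- pattern$flow
  n <- ceiling(pattern$t_in / dt)
  pressure_at <- function(t) {
    ipeep_state + mech$elastance * flow * t + mech$resistance * flow
  }
  grid <- seq(0, pattern$t_in, length.out = n + 1L)
  h <- pattern$t_in / n
  work_mbar_l <- if (method == "trapezoid") {
    p <- pressure_at(grid) * flow
    h * (sum(p) - (p[1L] + p[n + 1L]) / 2)
  } else {
    mid <- grid[-(n + 1L)] + h / 2
    h * sum(pressure_at(mid) * flow)
  }
  0.1 * work_mbar_l
}

#' Time-stamped pressure/volume/flow trace of consecutive breaths
#'
#' Generates the sampled waveform of the single-compartment simulation for
#' a given number of breaths, starting from the external-PEEP equilibrium:
#' constant-flow inflation, then exact-exponential passive deflation while
#' the airway opening is held at the external PEEP.
#'
#' @inheritParams simulate_to_steady_state
#' @param n_breaths Number of breaths to trace.
#' @param dt Sampling interval, s; default `min(t_in, t_ex)/200`.
#' @return A data frame with columns `time_s`, `volume_L` (above the
#'   external-PEEP equilibrium volume), `flow_L_per_s` (positive
#'   inspiratory), `pressure_mbar` (airway opening) and `breath_index`.
#' @export
breath_trace <- function(mech, pattern, n_breaths = 10L, dt = NULL) {
  stopifnot(inherits(mech, "respiratory_mechanics"),
            inherits(pattern, "ventilation_pattern"))
  check_scalar(n_breaths, "n_breaths", positive = TRUE)
  tau <- time_constant(mech)
  if (is.null(dt)) dt <- min(pattern$t_in, pattern$t_ex) / 200
  check_scalar(dt, "dt", positive = TRUE)
  peep <- pattern$external_peep
  flow_in <- pattern$flow
  # half-open per-breath grid [0, cycle): the next breath's first sample
  # continues the time axis without duplication
  t_local <- seq(0, pattern$cycle_time - dt / 2, by = dt)
  insp <- t_local <= pattern$t_in
  v_ee <- 0
  out <- vector("list", n_breaths)
  for (b in seq_len(n_breaths)) {
    v_end_insp <- v_ee + pattern$tidal_volume
    volume <- ifelse(insp, v_ee + flow_in * t_local,
                     if (tau > 0)
                       v_end_insp * exp(-(t_local - pattern$t_in) / tau)
                     else 0)
    flow <- ifelse(insp, flow_in, if (tau > 0) -volume / tau else 0)
    pressure <- ifelse(insp,
                       peep + mech$elastance * volume +
                         mech$resistance * flow_in,
                       peep)
    out[[b]] <- data.frame(
      time_s = (b - 1) * pattern$cycle_time + t_local,
      volume_L = volume,
      flow_L_per_s = flow,
      pressure_mbar = pressure,
      breath_index = b)
    v_ee <- if (tau > 0) v_end_insp * exp(-pattern$t_ex / tau) else 0
  }
  do.call(rbind, out)
}
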