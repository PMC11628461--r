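#' Respiratory-system mechanics of a linear single-compartment model
#'
#' Bundles the passive patient-side parameters of the linear
#' single-compartment ("elastic balloon plus tube") model of the relaxed
#' respiratory system: a constant elastance (lung plus chest wall) and a
#' constant resistance split into its airway and artificial-airway (tube)
#' components, together with the anatomic dead space.
#'
#' Unit conventions are fixed package-wide: volumes in L, pressures in mbar,
#' elastance in mbar/L, resistances in mbar/L/s, times in s, rates in 1/min,
#' power in J/min. No implicit conversions are performed anywhere.
#'
#' @param elastance Respiratory-system elastance E, mbar/L. Must be > 0.
#' @param airway_resistance Airway component of resistance, mbar/L/s, >= 0.
#' @param tube_resistance Endotracheal/tracheostomy-tube component of
#'   resistance, mbar/L/s, >= 0.
#' @param dead_space Anatomic dead space V_D, L. Must be > 0.
#'
#' @return An object of class `respiratory_mechanics`: a list with the four
#'   fields above plus `resistance` (their sum R, mbar/L/s).
#'
#' @examples
#' mech <- respiratory_mechanics(elastance = 10, airway_resistance = 1,
#'                               tube_resistance = 7, dead_space = 0.2)
#' time_constant(mech)  # R/E = 0.8 s
#' @export
respiratory_mechanics <- function(elastance, airway_resistance = 0,
                                  tube_resistance = 0, dead_space) {
  elastance <- check_scalar(elastance, "elastance", positive = TRUE)
  airway_resistance <- check_scalar(airway_resistance, "airway_resistance",
                                    nonneg = TRUE)
  tube_resistance <- check_scalar(tube_resistance, "tube_resistance",
                                  nonneg = TRUE)
  dead_space <- check_scalar(dead_space, "dead_space", positive = TRUE)
  structure(
    list(elastance = elastance,
         airway_resistance = airway_resistance,
         tube_resistance = tube_resistance,
         dead_space = dead_space,
         resistance = airway_resistance + tube_resistance),
    class = "respiratory_mechanics")
}

#' @export
print.respiratory_mechanics <- function(x, ...) {
  cat("Respiratory mechanics (linear single-compartment)\n")
  cat(sprintf("  elastance E:        %g mbar/L\n", x$elastance))
  cat(sprintf("  resistance R:       %g mbar/L/s (airway %g + tube %g)\n",
              x$resistance, x$airway_resistance, x$tube_resistance))
  cat(sprintf("  dead space V_D:     %g L\n", x$dead_space))
  cat(sprintf("  time constant tau:  %g s\n", time_constant(x)))
  invisible(x)
}

#' Expiratory time constant of passive lung emptying
#'
#' The exponential time scale tau = R/E with which the relaxed respiratory
#' system empties passively towards its end-expiratory equilibrium volume.
#' R = 0 is allowed and gives tau = 0 (instantaneous emptying).
#'
#' @param mech A [respiratory_mechanics()] object.
#' @return Time constant in seconds.
#' @examples
#' time_constant(respiratory_mechanics(10, 1, 7, 0.2))  # 0.8 s
#' @export
time_constant <- function(mech) {
  stopifnot(inherits(mech, "respiratory_mechanics"))
  mech$resistance / mech$elastance
}

#' Ventilator-side breathing pattern
#'
#' The ventilator settings of a volume-controlled, constant-inspiratory-flow
#' breath cycle: tidal volume, respiratory rate, I:E ratio and external PEEP.
#' Derived timing quantities (`t_in`, `t_ex`, cycle time, constant
#' inspiratory flow) are computed at construction.
#'
#' @param tidal_volume Tidal volume V_T, L, > 0.
#' @param respiratory_rate Breaths per minute, > 0.
#' @param ie_ratio Inspiration-to-expiration time ratio t_in/t_ex,
#'   dimensionless, > 0.
#' @param external_peep Externally applied PEEP, mbar, >= 0.
#'
#' @return An object of class `ventilation_pattern` with fields
#'   `tidal_volume`, `respiratory_rate`, `ie_ratio`, `external_peep`,
#'   `cycle_time` (s), `t_in` (s), `t_ex` (s) and `flow`
#'   (inspiratory flow V_T/t_in, L/s).
#' @examples
#' ventilation_pattern(0.5, 15, ie_ratio = 1, external_peep = 0)
#' @export
ventilation_pattern <- function(tidal_volume, respiratory_rate, ie_ratio = 1,
                                external_peep = 0) {
  tidal_volume <- check_scalar(tidal_volume, "tidal_volume", positive = TRUE)
  respiratory_rate <- check_scalar(respiratory_rate, "respiratory_rate",
                                   positive = TRUE)
  ie_ratio <- check_scalar(ie_ratio, "ie_ratio", positive = TRUE)
  external_peep <- check_scalar(external_peep, "external_peep", nonneg = TRUE)
  timing <- breath_timing(respiratory_rate, ie_ratio)
  structure(
    list(tidal_volume = tidal_volume,
         respiratory_rate = respiratory_rate,
         ie_ratio = ie_ratio,
         external_peep = external_peep,
         cycle_time = 60 / respiratory_rate,
         t_in = timing[["t_in"]],
         t_ex = timing[["t_ex"]],
         flow = tidal_volume / timing[["t_in"]]),
    class = "ventilation_pattern")
}

#' @export
print.ventilation_pattern <- function(x, ...) {
  cat("Ventilation pattern (VCV, constant inspiratory flow)\n")
  cat(sprintf("  V_T: %g L (%g mL)   rr: %g /min   I:E: %g\n",
              x$tidal_volume, 1000 * x$tidal_volume, x$respiratory_rate,
              x$ie_ratio))
  cat(sprintf("  t_in: %g s   t_ex: %g s   flow: %g L/s   PEEP: %g mbar\n",
              x$t_in, x$t_ex, x$flow, x$external_peep))
  invisible(x)
}

#' Split the breath cycle into inspiratory and expiratory time
#'
#' Decomposes the cycle time 60/rr into `t_in` and `t_ex` such that
#' `t_in/t_ex` equals the I:E ratio and `t_in + t_ex = 60/rr` exactly.
#'
#' @param respiratory_rate Breaths per minute, > 0.
#' @param ie_ratio t_in/t_ex, dimensionless, > 0.
#' @return Named numeric vector `c(t_in = , t_ex = )`, seconds.
#' @examples
#' breath_timing(10, 1)    # 3 s / 3 s
#' breath_timing(20, 0.5)  # 1 s / 2 s
#' @export
breath_timing <- function(respiratory_rate, ie_ratio) {
  check_scalar(respiratory_rate, "respiratory_rate", positive = TRUE)
  check_scalar(ie_ratio, "ie_ratio", positive = TRUE)
  cycle <- 60 / respiratory_rate
  t_ex <- cycle / (1 + ie_ratio)
  c(t_in = cycle - t_ex, t_ex = t_ex)
}

#' Steady-state intrinsic PEEP from incomplete exhalation
#'
#' When the expiratory time is not long relative to the time constant tau,
#' part of each tidal volume remains in the lung at end-expiration. The
#' residual volumes of successive breaths form a geometric series whose sum
#' yields the steady-state intrinsic PEEP
#' \deqn{iPEEP = PEEP + E V_T \frac{x}{1-x}, \quad x = e^{-t_{ex}/\tau}.}
#'
#' The complement `1 - x` is evaluated via `expm1()` for accuracy at small
#' `t_ex/tau`. If `t_ex/tau` is so small that `1 - x` falls below 1e-15 the
#' steady state is numerically (and physiologically) degenerate and a
#' `ventpower_degenerate_expiration` error is raised instead of returning a
#' non-physical huge pressure. R = 0 (tau = 0) is handled as the analytic
#' limit: emptying is instantaneous and iPEEP equals the external PEEP.
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param pattern A [ventilation_pattern()] object.
#' @return Intrinsic PEEP, mbar (always >= external PEEP).
#' @examples
#' mech <- respiratory_mechanics(10, 1, 7, 0.2)
#' pat  <- ventilation_pattern(0.5, 15, 1)
#' intrinsic_peep(mech, pat)
#' @export
intrinsic_peep <- function(mech, pattern) {
  stopifnot(inherits(mech, "respiratory_mechanics"),
            inherits(pattern, "ventilation_pattern"))
  tau <- time_constant(mech)
  if (tau == 0) return(pattern$external_peep)
  ratio <- pattern$t_ex / tau
  one_minus_x <- -expm1(-ratio)           # 1 - exp(-t_ex/tau), accurately
  if (one_minus_x < 1e-15)
    stop_degenerate_expiration(sprintf(
      "expiratory time (%.3g s) is degenerately short relative to tau (%.3g s); steady-state iPEEP would overflow",
      pattern$t_ex, tau))
  x <- exp(-ratio)
  pattern$external_peep +
    mech$elastance * pattern$tidal_volume * x / one_minus_x
}

#' Respiratory rate required for a target alveolar minute ventilation
#'
#' Only the fraction of each breath exceeding the anatomic dead space takes
#' part in gas exchange, so rr = V_alv / (V_T - V_D). The rate diverges as
#' the tidal volume approaches the dead space from above; V_T <= V_D is a
#' `ventpower_dead_space_violation` error.
#'
#' @param v_alv Alveolar minute ventilation, L/min, > 0.
#' @param v_t Tidal volume, L.
#' @param v_d Anatomic dead space, L, > 0.
#' @return Respiratory rate, breaths per minute.
#' @examples
#' rate_from_alveolar_ventilation(10, 0.4, 0.2)  # 50 /min
#' @export
rate_from_alveolar_ventilation <- function(v_alv, v_t, v_d) {
  check_scalar(v_alv, "v_alv", positive = TRUE)
  check_scalar(v_t, "v_t", positive = TRUE)
  check_scalar(v_d, "v_d", positive = TRUE)
  if (v_t <= v_d)
    stop_dead_space_violation(sprintf(
      "tidal volume (%g L) must exceed the anatomic dead space (%g L)",
      v_t, v_d))
  v_alv / (v_t - v_d)
}

#' Mechanical power delivered to the respiratory system, by component
#'
#' Computes the power transferred from ventilator to respiratory system per
#' minute under volume-controlled constant-flow ventilation, as respiratory
#' rate times per-breath work, split into:
#' \describe{
#'   \item{elastic}{0.1 rr V_T^2 E/2 — work against elastic recoil.}
#'   \item{resistive}{0.1 rr R Vdot V_T with constant inspiratory flow
#'     Vdot = V_T/t_in — work against airway plus tube resistance.}
#'   \item{ipeep}{0.1 rr iPEEP V_T — work to move air against the
#'     end-expiratory pressure baseline, with iPEEP from
#'     [intrinsic_peep()].}
#' }
#' The factor 0.1 converts mbar L/min into J/min and is applied exactly
#' once, here. By default the iPEEP term uses the full intrinsic PEEP
#' including the external PEEP, i.e. the total power delivered at the airway
#' above atmospheric pressure; set `above_peep = TRUE` to report power above
#' the external PEEP baseline instead (the two coincide when PEEP = 0).
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param pattern A [ventilation_pattern()] object.
#' @param above_peep Logical; subtract the external PEEP from the baseline
#'   term so that the reported power is relative to the PEEP level.
#' @return An object of class `power_breakdown`: a list with numeric fields
#'   `elastic`, `resistive`, `ipeep` and `total` (their sum), all in J/min.
#' @examples
#' mech <- respiratory_mechanics(10, 1, 7, 0.2)
#' mechanical_power(mech, ventilation_pattern(0.5, 15, 1))
#' @export
mechanical_power <- function(mech, pattern, above_peep = FALSE) {
  stopifnot(inherits(mech, "respiratory_mechanics"),
            inherits(pattern, "ventilation_pattern"))
  rr <- pattern$respiratory_rate
  vt <- pattern$tidal_volume
  elastic <- elastic_power(mech$elastance, vt, rr)
  resistive <- 0.1 * rr * mech$resistance * pattern$flow * vt
  ip <- intrinsic_peep(mech, pattern)
  if (above_peep) ip <- ip - pattern$external_peep
  ipeep_comp <- 0.1 * rr * ip * vt
  power_breakdown(elastic, resistive, ipeep_comp)
}

power_breakdown <- function(elastic, resistive, ipeep) {
  structure(
    list(elastic = elastic, resistive = resistive, ipeep = ipeep,
         total = elastic + resistive + ipeep),
    class = "power_breakdown")
}

#' @export
print.power_breakdown <- function(x, ...) {
  cat("Mechanical power breakdown (J/min)\n")
  cat(sprintf("  elastic:   %.6g\n", x$elastic))
  cat(sprintf("  resistive: %.6g\n", x$resistive))
  cat(sprintf("  iPEEP:     %.6g\n", x$ipeep))
  cat(sprintf("  total:     %.6g\n", x$total))
  invisible(x)
}

#' Elastic component of mechanical power
#'
#' The power spent against elastic recoil, 0.1 rr V_T^2 E/2 (J/min). It is
#' independent of resistance, I:E ratio and flow waveform, so it applies
#' equally to volume-controlled and pressure-controlled modes.
#'
#' @param elastance Respiratory-system elastance E, mbar/L, >= 0.
#' @param v_t Tidal volume, L, > 0.
#' @param rr Respiratory rate, breaths/min, > 0.
#' @return Elastic power, J/min.
#' @examples
#' elastic_power(10, 0.4, 50)  # 4 J/min
#' @export
elastic_power <- function(elastance, v_t, rr) {
  check_scalar(elastance, "elastance", nonneg = TRUE)
  check_scalar(v_t, "v_t", positive = TRUE)
  check_scalar(rr, "rr", positive = TRUE)
  0.1 * rr * v_t^2 * elastance / 2
}

#' End-inspiratory plateau pressure
#'
#' In the linear model the plateau pressure during an end-inspiratory hold
#' is E V_T above the end-expiratory baseline; the absolute value is
#' E V_T + iPEEP. With iPEEP = 0 this reduces to E V_T.
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param v_t Tidal volume, L, >= 0.
#' @param ipeep End-expiratory baseline pressure (intrinsic PEEP), mbar,
#'   >= 0. Default 0.
#' @return Plateau pressure, mbar.
#' @examples
#' plateau_pressure(respiratory_mechanics(10, 1, 7, 0.2), 0.5)  # 5 mbar
#' @export
plateau_pressure <- function(mech, v_t, ipeep = 0) {
  stopifnot(inherits(mech, "respiratory_mechanics"))
  check_scalar(v_t, "v_t", nonneg = TRUE)
  check_scalar(ipeep, "ipeep", nonneg = TRUE)
  mech$elastance * v_t + ipeep
}
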