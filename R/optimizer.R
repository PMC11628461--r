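# Vectorized total-power evaluator used inside the grid/scalar searches.
# Mirrors the expression order of mechanical_power()/ventilation_pattern()
# exactly so that a re-evaluation through the public API is bit-identical.
mp_total_fast <- function(E, R, peep, vt, rr, ie, tau) {
  cycle <- 60 / rr
  t_ex <- cycle / (1 + ie)
  t_in <- cycle - t_ex
  flow <- vt / t_in
  elastic <- 0.1 * rr * vt^2 * E / 2
  resistive <- 0.1 * rr * R * flow * vt
  if (tau == 0) {
    ip <- peep
  } else {
    one_minus_x <- -expm1(-t_ex / tau)
    ip <- ifelse(one_minus_x < 1e-15, NA_real_,
                 peep + E * vt * exp(-t_ex / tau) / one_minus_x)
  }
  elastic + resistive + 0.1 * rr * ip * vt
}

#' Tidal-volume and I:E search space
#'
#' Bounds and resolution for the constrained minimization of mechanical
#' power at fixed alveolar minute ventilation. Defaults cover the clinically
#' plausible range and resolve the tidal-volume optimum to 1 mL.
#'
#' @param vt_min,vt_max Tidal-volume bounds, L. `vt_min` must exceed the
#'   dead space of the mechanics it is used with (checked at solve time).
#' @param vt_step Grid step for tidal volume, L. Default 0.001 (1 mL).
#' @param ie_min,ie_max I:E ratio bounds, dimensionless.
#' @return An object of class `search_space`.
#' @examples
#' search_space(vt_min = 0.21, vt_max = 2)
#' @export
search_space <- function(vt_min, vt_max = 2, vt_step = 0.001,
                         ie_min = 0.1, ie_max = 4) {
  vt_min <- check_scalar(vt_min, "vt_min", positive = TRUE)
  vt_max <- check_scalar(vt_max, "vt_max", positive = TRUE)
  vt_step <- check_scalar(vt_step, "vt_step", positive = TRUE)
  ie_min <- check_scalar(ie_min, "ie_min", positive = TRUE)
  ie_max <- check_scalar(ie_max, "ie_max", positive = TRUE)
  if (vt_max < vt_min)
    stop_invalid_parameter("'vt_max' must be >= 'vt_min'")
  if (ie_max <= ie_min)
    stop_invalid_parameter("'ie_max' must be > 'ie_min'")
  structure(list(vt_min = vt_min, vt_max = vt_max, vt_step = vt_step,
                 ie_min = ie_min, ie_max = ie_max),
            class = "search_space")
}

default_search_space <- function(dead_space) {
  search_space(vt_min = dead_space + 0.01, vt_max = 2, vt_step = 0.001,
               ie_min = 0.1, ie_max = 4)
}

#' Tidal volume minimizing elastic power (closed form)
#'
#' Under the alveolar-ventilation constraint rr = V_alv/(V_T - V_D), the
#' elastic power 0.1 rr V_T^2 E/2 is proportional to V_T^2/(V_T - V_D).
#' Its stationary point is at V_T = 2 V_D: the elastic optimum is always
#' exactly twice the anatomic dead space, independent of elastance and of
#' the level of alveolar minute ventilation.
#'
#' @param v_d Anatomic dead space, L, > 0.
#' @return Optimal tidal volume, L.
#' @examples
#' optimal_vt_elastic(0.2)  # 0.4 L
#' @export
optimal_vt_elastic <- function(v_d) {
  check_scalar(v_d, "v_d", positive = TRUE)
  2 * v_d
}

#' Body-weight-normalized elastic-power optimum
#'
#' In adults the anatomic dead space scales approximately as 2.2 mL per kg
#' of body weight, so the elastic optimum of twice the dead space becomes
#' 4.4 mL/kg.
#'
#' @param body_weight Body weight, kg, > 0.
#' @param dead_space_per_kg Dead space per kg, mL/kg. Default 2.2.
#' @return A list with `vt_per_kg_ml` (mL/kg), `dead_space_l` and
#'   `tidal_volume_l` (absolute volumes, L).
#' @examples
#' optimal_vt_per_kg(70)  # 4.4 mL/kg -> 308 mL
#' @export
optimal_vt_per_kg <- function(body_weight, dead_space_per_kg = 2.2) {
  check_scalar(body_weight, "body_weight", positive = TRUE)
  check_scalar(dead_space_per_kg, "dead_space_per_kg", nonneg = TRUE)
  per_kg <- 2 * dead_space_per_kg
  list(vt_per_kg_ml = per_kg,
       dead_space_l = dead_space_per_kg * body_weight / 1000,
       tidal_volume_l = per_kg * body_weight / 1000)
}

#' Best I:E ratio at a fixed tidal volume
#'
#' At fixed tidal volume (respiratory rate tied to the target alveolar
#' minute ventilation) only the resistive and iPEEP components depend on
#' the cycle timing: lengthening inspiration lowers the constant flow and
#' hence resistive power, but shortens expiration and raises iPEEP. The
#' interior optimum is found by a 64-point log-spaced bracketing scan over
#' the I:E bounds followed by bounded scalar minimization
#' ([stats::optimize()]) in the bracketing interval.
#'
#' When the total resistance is zero the objective is independent of I:E
#' (iPEEP equals the external PEEP regardless of timing); the documented
#' tie-break returns I:E = 1 with `status = "indifferent"`. A minimum at a
#' search bound is flagged `status = "bound-limited"`; an interior minimum
#' has `status = "interior"`.
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param v_t Tidal volume, L; must exceed the dead space.
#' @param v_alv Target alveolar minute ventilation, L/min.
#' @param ie_bounds Length-2 numeric, lower and upper I:E bound.
#' @param external_peep External PEEP, mbar.
#' @return A list with `ie`, `power` (a `power_breakdown` re-evaluated
#'   through [mechanical_power()]) and `status`.
#' @examples
#' mech <- respiratory_mechanics(10, 1, 7, 0.2)
#' best_ie_for_vt(mech, v_t = 0.5, v_alv = 10)
#' @export
best_ie_for_vt <- function(mech, v_t, v_alv, ie_bounds = c(0.1, 4),
                           external_peep = 0) {
  stopifnot(inherits(mech, "respiratory_mechanics"))
  check_scalar(external_peep, "external_peep", nonneg = TRUE)
  if (!is.numeric(ie_bounds) || length(ie_bounds) != 2L ||
      ie_bounds[1] <= 0 || ie_bounds[2] <= ie_bounds[1])
    stop_invalid_parameter("'ie_bounds' must be 0 < lower < upper")
  rr <- rate_from_alveolar_ventilation(v_alv, v_t, mech$dead_space)
  tau <- time_constant(mech)
  eval_at <- function(ie) {
    mechanical_power(mech, ventilation_pattern(v_t, rr, ie, external_peep))
  }
  if (mech$resistance == 0) {
    return(list(ie = 1, power = eval_at(1), status = "indifferent"))
  }
  ies <- exp(seq(log(ie_bounds[1]), log(ie_bounds[2]), length.out = 64L))
  vals <- mp_total_fast(mech$elastance, mech$resistance, external_peep,
                        v_t, rr, ies, tau)
  if (all(is.na(vals)))
    stop_degenerate_expiration(
      "no I:E ratio in the bounds yields a finite steady-state iPEEP")
  i <- which.min(vals)
  lo <- ies[max(1L, i - 1L)]
  hi <- ies[min(length(ies), i + 1L)]
  opt <- stats::optimize(function(ie) {
    mp_total_fast(mech$elastance, mech$resistance, external_peep,
                  v_t, rr, ie, tau)
  }, lower = lo, upper = hi, tol = 1e-9)
  ie_star <- opt$minimum
  # scan endpoints may beat the local refinement at a bound
  if (vals[i] < opt$objective) ie_star <- ies[i]
  at_bound <- ie_star <= ie_bounds[1] * (1 + 1e-6) ||
    ie_star >= ie_bounds[2] * (1 - 1e-6)
  if (at_bound) ie_star <- ies[i]  # snap to the scanned bound point
  list(ie = ie_star, power = eval_at(ie_star),
       status = if (at_bound) "bound-limited" else "interior")
}

#' Minimize mechanical power over tidal volume (and I:E ratio)
#'
#' Performs the constrained minimization of mechanical power at a fixed
#' alveolar minute ventilation: for every tidal volume on the search grid
#' the respiratory rate is set by rr = V_alv/(V_T - V_D) and — for the
#' total-power objective — the I:E ratio is optimized per tidal volume
#' (or held fixed with `ie_mode = "fixed"`). The elastic objective is
#' independent of timing by construction.
#'
#' Ties within 1e-9 relative power are broken towards the smallest tidal
#' volume, making the result deterministic and clinically conservative.
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param v_alv Target alveolar minute ventilation, L/min, > 0.
#' @param space A [search_space()]; default spans dead space + 10 mL to
#'   2 L at 1-mL resolution with I:E in [0.1, 4].
#' @param objective `"total"` (elastic + resistive + iPEEP) or `"elastic"`.
#' @param external_peep External PEEP, mbar.
#' @param ie_mode `"optimize"` (per-tidal-volume best I:E) or `"fixed"`.
#' @param ie_fixed I:E ratio used when `ie_mode = "fixed"`, and recorded for
#'   the timing-independent elastic objective.
#' @return An object of class `optimization_result`: a list with `vt_star`
#'   (L), `rr_star`, `ie_star`, `power_star` (a `power_breakdown`),
#'   `objective`, and `curve`, a data frame with columns `v_t_L`,
#'   `rr_per_min`, `ie`, `mp_elastic`, `mp_resistive`, `mp_ipeep`,
#'   `mp_total`, `is_minimum`.
#' @examples
#' mech <- respiratory_mechanics(10, 1, 7, 0.2)
#' res <- minimize_total_power(mech, v_alv = 10,
#'                             space = search_space(0.21, 1.5, 0.005))
#' res$vt_star
#' @export
minimize_total_power <- function(mech, v_alv, space = NULL,
                                 objective = c("total", "elastic"),
                                 external_peep = 0,
                                 ie_mode = c("optimize", "fixed"),
                                 ie_fixed = 1) {
  stopifnot(inherits(mech, "respiratory_mechanics"))
  objective <- match.arg(objective)
  ie_mode <- match.arg(ie_mode)
  check_scalar(v_alv, "v_alv", positive = TRUE)
  check_scalar(ie_fixed, "ie_fixed", positive = TRUE)
  check_scalar(external_peep, "external_peep", nonneg = TRUE)
  if (is.null(space)) space <- default_search_space(mech$dead_space)
  stopifnot(inherits(space, "search_space"))
  if (space$vt_min <= mech$dead_space)
    stop_invalid_parameter(
      "'vt_min' must exceed the anatomic dead space of the mechanics")
  vts <- seq(space$vt_min, space$vt_max, by = space$vt_step)
  if (length(vts) == 0L)
    stop_no_feasible_point("empty tidal-volume search space")

  rows <- vector("list", length(vts))
  n_ok <- 0L
  for (k in seq_along(vts)) {
    vt <- vts[k]
    rr <- rate_from_alveolar_ventilation(v_alv, vt, mech$dead_space)
    row <- tryCatch({
      if (objective == "elastic") {
        pb <- mechanical_power(
          mech, ventilation_pattern(vt, rr, ie_fixed, external_peep))
        list(ie = ie_fixed, pb = pb, obj = pb$elastic)
      } else if (ie_mode == "fixed") {
        pb <- mechanical_power(
          mech, ventilation_pattern(vt, rr, ie_fixed, external_peep))
        list(ie = ie_fixed, pb = pb, obj = pb$total)
      } else {
        b <- best_ie_for_vt(mech, vt, v_alv,
                            ie_bounds = c(space$ie_min, space$ie_max),
                            external_peep = external_peep)
        list(ie = b$ie, pb = b$power, obj = b$power$total)
      }
    }, ventpower_degenerate_expiration = function(e) NULL)
    if (!is.null(row)) n_ok <- n_ok + 1L
    rows[[k]] <- row
  }
  if (n_ok == 0L)
    stop_no_feasible_point(
      "every point of the search space has a degenerate expiration phase")

  ok <- !vapply(rows, is.null, logical(1))
  obj <- vapply(rows[ok], function(r) r$obj, numeric(1))
  vt_ok <- vts[ok]
  best_val <- min(obj)
  # smallest tidal volume among near-ties (1e-9 relative)
  i_best <- which(obj <= best_val * (1 + 1e-9))[1L]
  best <- rows[ok][[i_best]]

  curve <- data.frame(
    v_t_L = vt_ok,
    rr_per_min = v_alv / (vt_ok - mech$dead_space),
    ie = vapply(rows[ok], function(r) r$ie, numeric(1)),
    mp_elastic = vapply(rows[ok], function(r) r$pb$elastic, numeric(1)),
    mp_resistive = vapply(rows[ok], function(r) r$pb$resistive, numeric(1)),
    mp_ipeep = vapply(rows[ok], function(r) r$pb$ipeep, numeric(1)),
    mp_total = vapply(rows[ok], function(r) r$pb$total, numeric(1)))
  curve$is_minimum <- seq_len(nrow(curve)) == i_best

  structure(
    list(vt_star = vt_ok[i_best],
         rr_star = v_alv / (vt_ok[i_best] - mech$dead_space),
         ie_star = best$ie,
         power_star = best$pb,
         objective = objective,
         v_alv = v_alv,
         external_peep = external_peep,
         curve = curve),
    class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Mechanical-power minimization (objective: %s)\n", x$objective))
  cat(sprintf("  V_T*: %.6g L (%.4g mL)   rr*: %.6g /min   I:E*: %.6g\n",
              x$vt_star, 1000 * x$vt_star, x$rr_star, x$ie_star))
  cat(sprintf("  minimized %s power: %.6g J/min (total %.6g J/min)\n",
              x$objective,
              if (x$objective == "elastic") x$power_star$elastic
              else x$power_star$total,
              x$power_star$total))
  cat(sprintf("  curve: %d tidal-volume points\n", nrow(x$curve)))
  invisible(x)
}

#' Flatness of the total-power curve around its minimum
#'
#' Evaluates the total-power objective at 0.8 and 1.2 times the optimal
#' tidal volume (with the I:E ratio re-optimized at each point) and reports
#' the larger relative excess over the minimum. Small values mean the curve
#' is flat around its minimum, i.e. total power discriminates poorly
#' between neighbouring tidal volumes.
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param result An `optimization_result` from [minimize_total_power()].
#' @return Largest relative excess (dimensionless) of total power at
#'   0.8 and 1.2 times the optimal tidal volume.
#' @export
power_flatness <- function(mech, result) {
  stopifnot(inherits(result, "optimization_result"))
  ref <- result$power_star$total
  excess <- vapply(c(0.8, 1.2), function(f) {
    b <- best_ie_for_vt(mech, result$vt_star * f, result$v_alv,
                        external_peep = result$external_peep)
    b$power$total / ref - 1
  }, numeric(1))
  max(excess)
}

#' Power-versus-tidal-volume curves for several minute ventilations
#'
#' Recomputes the total-power curve (with per-point best I:E) for each
#' requested alveolar minute ventilation, stacking the results into one
#' table with the per-curve minimum flagged — the tabular equivalent of a
#' family of power-versus-volume curves.
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param v_alv_list Numeric vector of alveolar minute ventilations, L/min.
#' @param space A [search_space()] or NULL for the default.
#' @param external_peep External PEEP, mbar.
#' @param ie_mode,ie_fixed See [minimize_total_power()].
#' @return A data frame: column `v_alv_L_per_min` plus the curve columns of
#'   [minimize_total_power()].
#' @export
power_curve <- function(mech, v_alv_list, space = NULL, external_peep = 0,
                        ie_mode = c("optimize", "fixed"), ie_fixed = 1) {
  ie_mode <- match.arg(ie_mode)
  if (!is.numeric(v_alv_list) || length(v_alv_list) == 0L ||
      any(!is.finite(v_alv_list)) || any(v_alv_list <= 0))
    stop_invalid_parameter(
      "'v_alv_list' must be a non-empty vector of positive ventilations")
  out <- lapply(v_alv_list, function(va) {
    res <- minimize_total_power(mech, va, space = space,
                                objective = "total",
                                external_peep = external_peep,
                                ie_mode = ie_mode, ie_fixed = ie_fixed)
    cbind(v_alv_L_per_min = va, res$curve)
  })
  do.call(rbind, out)
}

#' Ventilator-settings recommendation minimizing elastic power
#'
#' Applies the four-step recipe for elastic-power-minimal settings:
#' tidal volume of twice the anatomic dead space; respiratory rate from the
#' alveolar-ventilation constraint; the clinically targeted PEEP; and a
#' reduction of the external PEEP by the predicted intrinsic-PEEP build-up
#' at these settings, clamped at zero (negative external PEEP is never
#' emitted).
#'
#' @param mech A [respiratory_mechanics()] object.
#' @param v_alv Target alveolar minute ventilation, L/min.
#' @param target_peep Clinically desired end-expiratory pressure, mbar.
#' @param ie I:E ratio to assume for the build-up computation; elastic power
#'   itself is timing-independent, and a ratio near unity balances peak
#'   inspiratory and expiratory flow. Default 1.
#' @return An object of class `settings_recommendation` with fields `vt`
#'   (L), `rr` (/min), `ie`, `ipeep_buildup` (mbar), `external_peep`
#'   (mbar, after reduction) and `notes`.
#' @examples
#' mech <- respiratory_mechanics(10, 1, 7, 0.2)
#' recommend_settings(mech, v_alv = 10, target_peep = 5)
#' @export
recommend_settings <- function(mech, v_alv, target_peep = 0, ie = 1) {
  stopifnot(inherits(mech, "respiratory_mechanics"))
  check_scalar(v_alv, "v_alv", positive = TRUE)
  check_scalar(target_peep, "target_peep", nonneg = TRUE)
  check_scalar(ie, "ie", positive = TRUE)
  vt <- optimal_vt_elastic(mech$dead_space)
  rr <- rate_from_alveolar_ventilation(v_alv, vt, mech$dead_space)
  pat <- ventilation_pattern(vt, rr, ie, external_peep = target_peep)
  buildup <- intrinsic_peep(mech, pat) - target_peep
  ext <- max(0, target_peep - buildup)
  notes <- if (target_peep - buildup < 0)
    "intrinsic-PEEP build-up exceeds the target PEEP; external PEEP clamped at 0 and end-expiratory pressure will exceed the target"
  else
    "external PEEP reduced by the predicted intrinsic-PEEP build-up"
  structure(
    list(vt = vt, rr = rr, ie = ie, target_peep = target_peep,
         ipeep_buildup = buildup, external_peep = ext, notes = notes),
    class = "settings_recommendation")
}

#' @export
print.settings_recommendation <- function(x, ...) {
  cat("Ventilator settings recommendation (elastic-power minimal)\n")
  cat(sprintf("  V_T: %g L (%g mL) = 2 x dead space\n", x$vt, 1000 * x$vt))
  cat(sprintf("  rr: %.6g /min   I:E: %g\n", x$rr, x$ie))
  cat(sprintf("  iPEEP build-up: %.6g mbar\n", x$ipeep_buildup))
  cat(sprintf("  external PEEP: %.6g mbar (target %.6g mbar)\n",
              x$external_peep, x$target_peep))
  cat(sprintf("  note: %s\n", x$notes))
  invisible(x)
}
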