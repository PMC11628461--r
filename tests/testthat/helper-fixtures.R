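# Shared parameter sets: a normal lung on an 8-mm endotracheal tube, and the
# four elastance x tube-resistance combinations used for curve panels.

normal_lung <- function() {
  respiratory_mechanics(elastance = 10, airway_resistance = 1,
                        tube_resistance = 7, dead_space = 0.2)
}

panel_grid <- function() {
  expand.grid(elastance = c(10, 20), tube_resistance = c(7, 12))
}

# Brute-force elastic-power minimizer on a tidal-volume grid, written
# without reference to the closed form.
grid_elastic_argmin <- function(E, v_alv, v_d, step = 0.001) {
  vts <- seq(v_d + step, 10 * v_d, by = step)
  rr <- v_alv / (vts - v_d)
  mp <- 0.1 * rr * vts^2 * E / 2
  vts[which.min(mp)]
}
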