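---
title: "Minimizing the mechanical power of controlled mechanical ventilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizing the mechanical power of controlled mechanical ventilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventpower)
```

## The model and its assumptions

ventpower models the passive respiratory system during volume-controlled
mechanical ventilation as a linear single compartment: an elastic balloon
with constant elastance $E$ (lung plus chest wall, mbar/L) filled through a
constant resistance $R$ (airway plus endotracheal or tracheostomy tube,
mbar/L/s). Inspiration delivers the tidal volume $V_T$ at constant flow
$\dot V = V_T/t_{in}$; during expiration the airway is held at the external
PEEP and the compartment empties passively with time constant
$\tau = R/E$. The model is linear throughout: no volume-dependent
elastance, no flow-dependent (Rohrer) tube resistance, no spontaneous
effort, no two-compartment or viscoelastic behaviour. These are deliberate
non-goals; they keep every quantity closed-form and make the optimization
landscape transparent.

The work of one inspiration decomposes into an elastic part
$\tfrac{1}{2} E V_T^2$, a resistive part $R \dot V V_T$, and the work done
against the end-expiratory pressure baseline, $iPEEP \cdot V_T$. Multiplied
by the respiratory rate $rr$ and by 0.1 (the mbar·L $\to$ J conversion,
applied exactly once, in the power functions only), this gives the total
mechanical power in J/min implemented by `mechanical_power()`:

$$MP = 0.1\, rr \left\{ V_T^2 \left[ \tfrac{1}{2}E
  + rr \frac{1 + r}{60\, r} R \right] + iPEEP\, V_T \right\},
  \qquad r = t_{in}/t_{ex}.$$

The two algebraic forms of the resistive term — the bracketed one above and
$0.1\, rr\, R \dot V V_T$ — are kept consistent to better than $10^{-12}$
relative (tested), and the implementation evaluates the flow form so that
per-component and total reporting share one code path.

### Intrinsic PEEP as a geometric series

When $t_{ex}$ is not long against $\tau$, each breath leaves a residual
volume $V_T e^{-t_{ex}/\tau}$ at end-expiration, the breath before
contributes $V_T e^{-2 t_{ex}/\tau}$, and so on; the series sums to the
steady state implemented in `intrinsic_peep()`:

$$iPEEP = PEEP + E V_T \frac{x}{1-x}, \qquad x = e^{-t_{ex}/\tau}.$$

Two degenerate regimes are handled explicitly. $R = 0$ is the analytic
limit $\tau = 0$: emptying is instantaneous and $iPEEP = PEEP$ — a branch,
not a division. At the other extreme, $1 - x$ is evaluated as
`-expm1(-t_ex/tau)`; if it falls below $10^{-15}$ the steady state would be
a non-physical, numerically meaningless pressure, so the function raises a
classed `degenerate expiration` error instead of returning a huge number.

### The constraint coupling rate and volume

Gas exchange uses only the fraction of each breath beyond the anatomic dead
space $V_D$, so maintaining an alveolar minute ventilation $\dot V_{alv}$
forces $rr = \dot V_{alv}/(V_T - V_D)$ (`rate_from_alveolar_ventilation()`).
Every power component inherits the $1/(V_T - V_D)$ divergence as
$V_T \to V_D^+$; $V_T \le V_D$ is rejected as a dead-space violation.

## The optimization

`minimize_total_power()` scans tidal volume on a uniform grid — by default
from $V_D + 10$ mL to 2 L in 1-mL steps, covering the clinically plausible
axis and resolving the optimum to the millilitre. At each $V_T$ the rate is
fixed by the constraint, and for the total-power objective the I:E ratio is
optimized per tidal volume: lengthening inspiration lowers the constant
flow (resistive power), but shortens expiration and raises iPEEP, so an
interior optimum exists. The I:E search uses a 64-point log-spaced
bracketing scan on the default bounds $[0.1, 4]$ followed by bounded scalar
minimization (`stats::optimize()`, tolerance $10^{-9}$) in the bracketing
interval; a minimum at a bound is flagged `bound-limited`. With $R = 0$ the
objective is timing-independent and the documented tie-break returns
I:E = 1 (`indifferent`) — a ratio near unity also balances peak inspiratory
and expiratory flows, which is why it is the default in
`recommend_settings()`.

Ties on the tidal-volume grid (within $10^{-9}$ relative power) are broken
towards the smallest tidal volume: deterministic and clinically
conservative. There is no randomness anywhere in the package; identical
inputs give bit-identical results, and the optimum reported is re-evaluated
through `mechanical_power()` so it is bit-identical to what a user would
recompute at the returned settings.

Whether published power-versus-volume curves use a per-tidal-volume optimal
I:E or one fixed ratio is generally not stated alongside such figures; the
package defaults to per-point optimization (which is what per-point
colour-coded I:E annotations imply) and exposes `ie_mode = "fixed"` as the
alternative. Under the reference parameter set (E = 10 mbar/L, R = 1 + 7
mbar/L/s, $V_D$ = 200 mL, $\dot V_{alv}$ = 10 L/min, PEEP 0) the
per-point-optimal policy puts the total-power minimum at 994 mL; a fixed
I:E shifts it by a few millilitres. This residual policy ambiguity is why
the total-power optimum should be quoted with a few-mL uncertainty.

### The closed-form elastic optimum

Restricting the objective to the elastic component gives
$MP_{el} = 0.1\, \dot V_{alv}\, \tfrac{E}{2}\, V_T^2/(V_T - V_D)$, whose
stationary point is $V_T^\ast = 2 V_D$ — twice the anatomic dead space,
independent of $E$, of $\dot V_{alv}$, of the I:E ratio, and of the flow
waveform (so it applies to pressure-controlled ventilation as well). With
the adult scaling of 2.2 mL dead space per kg body weight this is 4.4 mL/kg
(`optimal_vt_elastic()`, `optimal_vt_per_kg()`). The test suite confirms
the closed form against a brute-force grid search over 100 random
$(E, \dot V_{alv}, V_D)$ draws.

`recommend_settings()` chains the four resulting steps: $V_T = 2 V_D$; rate
from the constraint; the clinically chosen PEEP target; and a reduction of
the *set* external PEEP by the predicted intrinsic-PEEP build-up at these
settings, clamped at zero — the build-up at $V_T = 2V_D$ can exceed a low
PEEP target, in which case the recommendation notes that the end-expiratory
pressure will overshoot the target.

### PEEP conventions

Two conventions were genuinely open and are both exposed. First, the iPEEP
term of the total power uses the full intrinsic PEEP including the external
PEEP — the power delivered at the airway above atmospheric;
`mechanical_power(..., above_peep = TRUE)` reports power above the PEEP
baseline instead. With the default PEEP = 0 the two coincide. Second, the
plateau pressure is generalized to $E V_T + iPEEP$ so that the zero-PEEP
case reduces to the familiar $p_{plateau} = E V_T$.

## The simulator: an independent oracle

`simulate_to_steady_state()` never evaluates the geometric-series formula.
It iterates breaths from the external-PEEP equilibrium volume — constant
flow in, exact exponential decay out — until the end-expiratory volume
changes by less than $10^{-10}$ relative (cap: 10,000 breaths). Using the
exact exponential update rather than an Euler step removes any stiffness
concern at small $\tau$ and leaves breath-count truncation as the only
error source. `work_per_breath()` then integrates airway pressure times
flow over inspiration on a uniform grid (default step
$\min(t_{in}, \tau)/1000$; steps coarser than $t_{in}/100$ are rejected)
with trapezoidal or midpoint quadrature — the integrand is linear in time,
so the two agree to rounding.

The test suite uses the simulator to cross-validate the closed forms: the
simulated steady-state iPEEP matches the series sum to better than
$10^{-6}$ relative over a $5 \times 5 \times 5$ sweep of
$E \in [5, 30]$ mbar/L, $R \in [2, 20]$ mbar/L/s, $rr \in [8, 40]$/min, and
numeric per-breath work times rate matches the power equation to better
than $10^{-3}$.

What this dual route does — and does not — show: agreement demonstrates
that the closed forms and the simulation implement the *same linear model*
correctly, not that the linear model describes a real patient. Real
respiratory systems have volume-dependent elastance, flow-dependent tube
resistance, inhomogeneous emptying and (outside deep sedation or paralysis)
muscular effort; none of these are emulated, and passing tests make no
claim about them.

## Problem sizes and runtime choices

The default tidal-volume grid (1 mL over roughly 0.21–2 L, ≈1790 points,
each with a 64-point I:E scan plus a bounded refinement) solves in well
under a second. The curve-panel tests use 4–5 mL grids, which move the
located minima by at most one step; the simulator sweep integrates ~125
steady states. These sizes were chosen so the full validation remains quick
to run while every reported optimum stays at its stated resolution.

## Known limitations

- The model is strictly linear and passive; COPD-like flow limitation,
  recruitment/derecruitment and patient effort are out of scope.
- The total-power optimum location inherits a few-mL sensitivity to the I:E
  policy (see above); the elastic optimum does not.
- The recommendation step treats the dead space as known; in practice the
  body-weight estimate should be corrected for apparatus dead space and
  intubation, or measured capnographically.
- Power curves are reported per breath cycle at steady state; transients
  after a settings change (which the simulator shows take a handful of time
  constants) are not part of the power accounting.
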