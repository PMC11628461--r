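test_that("time constant is R/E and construction validates parameters", {
  expect_equal(time_constant(normal_lung()), 0.8)
  expect_equal(time_constant(respiratory_mechanics(1, 1, 0, 0.2)), 1)
  expect_equal(time_constant(respiratory_mechanics(20, 1, 12, 0.2)), 0.65)
  expect_error(respiratory_mechanics(-10, 1, 7, 0.2),
               class = "ventpower_invalid_parameter")
  expect_error(respiratory_mechanics(10, -1, 7, 0.2),
               class = "ventpower_invalid_parameter")
  expect_error(respiratory_mechanics(10, 1, 7, 0),
               class = "ventpower_invalid_parameter")
})

test_that("breath timing splits the cycle per the I:E ratio", {
  cases <- list(list(rr = 10, ie = 1, t_in = 3, t_ex = 3),
                list(rr = 20, ie = 0.5, t_in = 1, t_ex = 2),
                list(rr = 15, ie = 2, t_in = 8 / 3, t_ex = 4 / 3))
  for (cs in cases) {
    tm <- breath_timing(cs$rr, cs$ie)
    expect_equal(tm[["t_in"]], cs$t_in)
    expect_equal(tm[["t_ex"]], cs$t_ex)
    expect_identical(tm[["t_in"]] + tm[["t_ex"]], 60 / cs$rr)
  }
  expect_error(breath_timing(0, 1), class = "ventpower_invalid_parameter")
  expect_error(breath_timing(10, -1), class = "ventpower_invalid_parameter")
})

test_that("intrinsic PEEP follows the residual-volume geometric series", {
  mech <- respiratory_mechanics(10, 8, 0, 0.2)
  tau <- time_constant(mech)
  # x/(1-x) = 1 when t_ex = tau * ln 2
  rr <- 60 / (2 * tau * log(2))  # ie = 1 -> t_ex = tau ln 2
  pat <- ventilation_pattern(0.5, rr, 1)
  expect_equal(intrinsic_peep(mech, pat), 5)
  # complete emptying: t_ex = 100 tau
  rr_slow <- 60 / (2 * 100 * tau)
  pat_slow <- ventilation_pattern(0.5, rr_slow, 1, external_peep = 3)
  expect_lt(abs(intrinsic_peep(mech, pat_slow) - 3), 1e-10)
  # R = 0: analytic limit, iPEEP = PEEP
  mech0 <- respiratory_mechanics(10, 0, 0, 0.2)
  expect_identical(intrinsic_peep(mech0, ventilation_pattern(0.5, 15, 1,
                                                             external_peep = 2)),
                   2)
})

test_that("intrinsic PEEP exceeds external PEEP and is monotone", {
  mech <- normal_lung()
  pat <- ventilation_pattern(0.5, 15, 1, external_peep = 4)
  expect_gt(intrinsic_peep(mech, pat), 4)
  # decreasing in t_ex (here: lower rate at fixed I:E lengthens t_ex)
  rates <- c(30, 25, 20, 15, 10)
  ip_rr <- vapply(rates, function(rr) {
    intrinsic_peep(mech, ventilation_pattern(0.5, rr, 1))
  }, numeric(1))
  expect_true(all(diff(ip_rr) < 0))
  # increasing in R and in E*V_T
  ip_R <- vapply(c(2, 5, 10, 15), function(rt) {
    intrinsic_peep(respiratory_mechanics(10, 1, rt, 0.2),
                   ventilation_pattern(0.5, 15, 1))
  }, numeric(1))
  expect_true(all(diff(ip_R) > 0))
  ip_vt <- vapply(c(0.3, 0.45, 0.6, 0.9), function(vt) {
    intrinsic_peep(mech, ventilation_pattern(vt, 15, 1))
  }, numeric(1))
  expect_true(all(diff(ip_vt) > 0))
})

test_that("degenerately short expiration raises instead of overflowing", {
  # t_ex/tau ~ 5e-16 -> 1 - exp(-t_ex/tau) underflows below 1e-15
  mech <- respiratory_mechanics(1e-6, 1e9, 0, 0.2)  # tau = 1e15 s
  pat <- ventilation_pattern(0.5, 60, 1)            # t_ex = 0.5 s
  expect_error(intrinsic_peep(mech, pat),
               class = "ventpower_degenerate_expiration")
  expect_error(mechanical_power(mech, pat),
               class = "ventpower_degenerate_expiration")
})

test_that("rate follows from the alveolar-ventilation constraint", {
  expect_equal(rate_from_alveolar_ventilation(10, 0.4, 0.2), 50)
  expect_equal(rate_from_alveolar_ventilation(10, 1.2, 0.2), 10)
  expect_error(rate_from_alveolar_ventilation(10, 0.2, 0.2),
               class = "ventpower_dead_space_violation")
  expect_error(rate_from_alveolar_ventilation(10, 0.1, 0.2),
               class = "ventpower_dead_space_violation")
})

test_that("power reduces to the elastic term when R = 0 and PEEP = 0", {
  mech <- respiratory_mechanics(10, 0, 0, 0.2)
  pb <- mechanical_power(mech, ventilation_pattern(0.5, 12, 1))
  expect_equal(pb$total, 1.5)
  expect_identical(pb$resistive, 0)
  expect_identical(pb$ipeep, 0)
  expect_identical(pb$total, pb$elastic)
})

test_that("the two algebraic forms of the resistive term agree", {
  mech <- normal_lung()
  for (ie in c(0.3, 1, 2.5)) {
    for (rr in c(10, 18, 30)) {
      pat <- ventilation_pattern(0.55, rr, ie)
      pb <- mechanical_power(mech, pat)
      closed <- 0.1 * rr * 0.55^2 * rr * (1 + ie) / (60 * ie) *
        mech$resistance
      expect_lt(abs(pb$resistive - closed) / closed, 1e-12)
    }
  }
})

test_that("the breakdown sums to the total and components are non-negative", {
  mech <- normal_lung()
  for (peep in c(0, 5)) {
    for (vt in c(0.3, 0.6, 1.1)) {
      pat <- ventilation_pattern(vt, 14, 0.8, external_peep = peep)
      pb <- mechanical_power(mech, pat)
      expect_lt(abs(pb$total - (pb$elastic + pb$resistive + pb$ipeep)),
                1e-12 * pb$total)
      expect_true(all(c(pb$elastic, pb$resistive, pb$ipeep) >= 0))
    }
  }
})

test_that("power-above-PEEP reporting removes the external-PEEP term", {
  mech <- normal_lung()
  pat <- ventilation_pattern(0.5, 15, 1, external_peep = 5)
  abs_pb <- mechanical_power(mech, pat)
  rel_pb <- mechanical_power(mech, pat, above_peep = TRUE)
  expect_equal(abs_pb$ipeep - rel_pb$ipeep,
               0.1 * 15 * 5 * 0.5)
  expect_identical(abs_pb$elastic, rel_pb$elastic)
  expect_identical(abs_pb$resistive, rel_pb$resistive)
  # with PEEP = 0 the two conventions coincide
  pat0 <- ventilation_pattern(0.5, 15, 1)
  expect_identical(mechanical_power(mech, pat0)$total,
                   mechanical_power(mech, pat0, above_peep = TRUE)$total)
})

test_that("elastic power is quadratic in tidal volume and waveform-free", {
  expect_equal(elastic_power(10, 0.4, 50), 4)
  expect_identical(elastic_power(0, 0.4, 50), 0)
  expect_equal(elastic_power(12, 0.8, 20), 4 * elastic_power(12, 0.4, 20))
  # bit-identical across I:E ratios at fixed (E, V_T, rr)
  mech <- normal_lung()
  ref <- mechanical_power(mech, ventilation_pattern(0.5, 15, 1))$elastic
  for (ie in c(0.1, 0.37, 2, 4)) {
    expect_identical(
      mechanical_power(mech, ventilation_pattern(0.5, 15, ie))$elastic, ref)
  }
})

test_that("total power increases with elastance, resistance and ventilation", {
  vt <- 0.5
  total_at <- function(E, rt, v_alv) {
    mech <- respiratory_mechanics(E, 1, rt, 0.2)
    rr <- rate_from_alveolar_ventilation(v_alv, vt, 0.2)
    mechanical_power(mech, ventilation_pattern(vt, rr, 1))$total
  }
  expect_true(all(diff(vapply(c(5, 10, 20, 30), total_at, numeric(1),
                              rt = 7, v_alv = 10)) > 0))
  expect_true(all(diff(vapply(c(2, 7, 12, 20), function(rt) {
    total_at(10, rt, 10)
  }, numeric(1))) > 0))
  expect_true(all(diff(vapply(c(6, 8, 10, 14), function(va) {
    total_at(10, 7, va)
  }, numeric(1))) > 0))
})

test_that("plateau pressure is E V_T above the end-expiratory baseline", {
  mech <- normal_lung()
  expect_equal(plateau_pressure(mech, 0.5), 5)
  expect_equal(plateau_pressure(mech, 0, ipeep = 3), 3)
  expect_equal(plateau_pressure(respiratory_mechanics(20, 1, 7, 0.2),
                                0.3, ipeep = 2), 8)
})
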