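# Boltzmann gating, ohmic / partial / GHK current laws, calcium pools

test_that("Boltzmann steady state: midpoint, saturation, direct evaluation", {
  g <- simple_act_gate()
  expect_equal(steady_state_gate(-40, g), 0.5)
  expect_equal(steady_state_gate(-40 + g$slope, g), 1 / (1 + exp(1)))
  expect_lt(steady_state_gate(-120, g), 1e-5)          # negative slope: closes
  expect_gt(steady_state_gate(40, g), 1 - 1e-5)
  h <- simple_inact_gate()
  expect_gt(steady_state_gate(-120, h), 1 - 1e-4)      # positive slope: opens
  # strict monotonicity over the physiological range
  v <- seq(-120, 60, by = 1)
  expect_true(all(diff(steady_state_gate(v, g)) > 0))
  expect_true(all(diff(steady_state_gate(v, h)) < 0))
  expect_error(gate_spec(1, -40, 0, 2), "slope")
  expect_error(gate_spec(-1, -40, -6, 2), "power")
})

test_that("gate relaxation follows the closed-form exponential", {
  g <- simple_act_gate(tau = 2)
  v <- -40                                 # m_inf = 0.5, tau = 2 ms
  expect_equal(gate_derivative(0.5, v, g), 0)          # fixed point
  # m = 0, m_inf = 1 (very depolarised), tau = 2 -> dm/dt = 0.5 / ms
  expect_equal(gate_derivative(0, 60, g), steady_state_gate(60, g) / 2,
               tolerance = 1e-6)
  # integrate with the package's RK step under voltage clamp and compare
  # with m_inf (1 - exp(-t/tau))
  minf <- steady_state_gate(v, g)
  dt <- 0.02
  m <- 0
  f <- function(t, y) gate_derivative(y, v, g)
  for (i in 1:500) m <- as.numeric(rk_step(m, f, dt))
  t_end <- 500 * dt
  expect_equal(m, minf * (1 - exp(-t_end / 2)), tolerance = 1e-8)
})

test_that("tabulated tau interpolates and clamps", {
  g <- gate_spec(1, -40, -6, tau = cbind(c(-80, -40, 0), c(4, 2, 1)))
  expect_equal(gate_tau(-60, g), 3)
  expect_equal(gate_tau(-200, g), 4)   # clamped below
  expect_equal(gate_tau(50, g), 1)     # clamped above
  expect_error(gate_spec(1, -40, -6, tau = cbind(c(-80, 0), c(1, -1))),
               "positive")
})

test_that("ohmic current law and its limiting cases", {
  ch <- simple_ohmic(g = 1, e = -90, x = 2)
  expect_equal(ohmic_current(ch, m = 0.7, h = 1, v = -90), 0)  # reversal
  expect_equal(ohmic_current(ch, m = 0, h = 1, v = 0), 0)      # closed gate
  expect_equal(ohmic_current(ch, m = 0.5, h = 1, v = -80), 2.5)
  # g m^2 (v - e) with g=1, m=0.5, v-e=10 -> 2.5
  # linear in driving force; sign flips at e_rev
  i1 <- ohmic_current(ch, 0.5, 1, -80)
  i2 <- ohmic_current(ch, 0.5, 1, -70)
  expect_equal(i2 / i1, 2)
  expect_lt(ohmic_current(ch, 0.5, 1, -100), 0)
  expect_error(ohmic_current(simple_ampa(), 1, 1, 0), "channel_spec")
})

test_that("partial inactivation reduces to ohmic at a = 1 and flips at a = 0", {
  act <- gate_spec(2, -40, -6, 2)
  inact <- gate_spec(1, -60, 6, 10, role = "inactivation")
  mk <- function(a) channel_spec("KAs", g_max = 2, e_rev = -90,
                                 activation = act, inactivation = inact,
                                 partial_fraction = a, mode = "partial")
  ref <- channel_spec("K", g_max = 2, e_rev = -90, activation = act,
                      inactivation = inact, mode = "ohmic")
  for (h in c(0.2, 0.7, 1)) {
    expect_equal(partial_inactivation_current(mk(1), 0.6, h, -50),
                 ohmic_current(ref, 0.6, h, -50))
  }
  # the partial-inactivation factor (a h - (1 - a)) evaluated by hand:
  # a = 0.5, h = 1 -> 0 (fully open inactivation cancels the offset)
  expect_equal(partial_inactivation_current(mk(0.5), 0.6, 1, -50), 0)
  # a = 0.75, h = 0.8 -> 0.75*0.8 - 0.25 = 0.35
  expect_equal(partial_inactivation_current(mk(0.75), 0.6, 0.8, -50),
               2 * 0.6^2 * 0.35 * (-50 + 90))
  # a = 0: -g m^x (v - e) regardless of h
  expect_equal(partial_inactivation_current(mk(0), 0.6, 0.3, -50),
               -2 * 0.6^2 * (-50 + 90))
  expect_error(mk(1.5), "partial_fraction")
})

test_that("GHK flux: zero at symmetric concentrations, L'Hopital limit,
           continuity at the series switch", {
  prm <- ghk_params()
  expect_equal(ghk_current(1e-6, 0, ca_in = 5, prm), 0)
  # v -> 0 limit: p z F (ca_in - ca_out), concentrations in mol/cm^3,
  # current in uA/cm^2
  lim <- ghk_current(1e-6, 0, ca_in = 0.001, prm)
  expect_equal(lim, 1e-6 * 2 * 96489 * 1e6 * (0.001 - 5) * 1e-6)
  expect_lt(lim, 0)                                    # inward
  # series branch value lies between direct evaluations at +/- 0.1 mV
  lo <- ghk_current(1e-6, -0.1, 0.001, prm)
  hi <- ghk_current(1e-6, 0.1, 0.001, prm)
  expect_true(lim > min(lo, hi) && lim < max(lo, hi))
  # relative agreement at the switch point |xi| = 1e-4
  v_switch <- 1e-4 * prm$gas_const * prm$temperature_k /
    (prm$z * prm$faraday) * 1000
  direct <- ghk_current(1e-6, v_switch * 1.0000001, 0.001, prm)
  series <- ghk_current(1e-6, v_switch * 0.9999999, 0.001, prm)
  expect_equal(series, direct, tolerance = 1e-6)
  expect_error(ghk_current(1e-6, 0, -1, prm), "invalid state")
})

test_that("calcium permeability is bounded by p_max", {
  expect_equal(ca_permeability(2, 1, 2, 1, 1), 2)
  expect_equal(ca_permeability(2, 0, 2), 0)
  expect_equal(ca_permeability(2, 0.5, 2, 1, 0), 0.5)
  for (m in seq(0, 1, 0.25)) for (x in 0:3)
    expect_lte(ca_permeability(3, m, x), 3)
})

test_that("calcium pool: pump-only rest, sign convention, bisection oracle", {
  pool <- calcium_pool()
  # at rest with no current only the pump term survives
  expect_equal(ca_pool_derivative(pool, 0),
               -pool$pump_p * pool$k_t * 0.001 / (0.001 + pool$k_d))
  # inward (negative) current raises calcium
  expect_gt(ca_pool_derivative(pool, -1e-3),
            ca_pool_derivative(pool, 0))
  # steady state under constant current matches a 1-D root found by uniroot
  # on the same closed form (independent bracketing search)
  i_ca <- -5e-4
  f <- function(ca) ca_pool_derivative(pool, i_ca, ca_in = ca)
  root <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  expect_equal(f(root), 0, tolerance = 1e-10)
  expect_gt(root, pool$ca_rest)   # inward current elevates the steady state
})
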