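test_that("Boltzmann steady state has the textbook anchor points", {
  m <- gating_spec(-1.2, 18)
  expect_equal(x_inf(-1.2, m), 0.5)
  expect_equal(x_inf(1e4, m), 1)
  expect_equal(x_inf(-1e4, m), 0)
  # half-activation at beta for any slope, including inactivation gates
  for (spec in list(gating_spec(-13, 10), gating_spec(-30, -5),
                    gating_spec(0, 4))) {
    expect_equal(x_inf(spec$beta, spec), 0.5)
  }
})

test_that("Boltzmann curves are strictly monotone with the sign of gamma", {
  V <- seq(-100, 60, 0.5)
  act <- x_inf(V, gating_spec(-13, 10))
  inact <- x_inf(V, gating_spec(-30, -5))
  expect_true(all(diff(act) > 0))
  expect_true(all(diff(inact) < 0))
  expect_true(all(act > 0 & act < 1))
  expect_true(all(inact > 0 & inact < 1))
})

test_that("voltage-dependent time constant peaks at beta and is even", {
  w <- gating_spec(-13, 10, phi = 0.15)
  expect_equal(tau_gate(-13, w), 1 / 0.15)
  for (d in c(0.5, 3, 11, 40))
    expect_equal(tau_gate(-13 + d, w), tau_gate(-13 - d, w))
  # frozen value from direct evaluation of 1/(phi*cosh((V-beta)/(2*gamma)))
  # at V = -40, beta_w = -13, gamma_w = 10, phi_w = 0.15
  expect_equal(tau_gate(-40, w), 1 / (0.15 * cosh(-27 / 20)))
  expect_equal(tau_gate(-40, w), 3.2388671, tolerance = 1e-6)
  expect_true(all(tau_gate(seq(-100, 50, 1), w) > 0))
})

test_that("invalid gating parameters are rejected", {
  expect_error(gating_spec(-13, 0), "gamma")
  expect_error(gating_spec(-13, 10, phi = -1), "phi")
  expect_error(gating_spec(-13, 10, tau_fixed = 0), "tau_fixed")
  expect_error(gating_spec(-13, 10, phi = 0.15, tau_fixed = 300),
               "not both")
  expect_error(tau_gate(-40, gating_spec(-30, -5, tau_fixed = 2000)),
               "fixed time constant")
})
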