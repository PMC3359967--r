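presets_all <- c("normal", "neuropathic", "supercritical", "nainact-slow",
                 "ahp", "s2-normal", "s2-neuropathic", "ungrouped-inward",
                 "ungrouped-outward", "suprathreshold")

test_that("zero driving force zeroes the corresponding current", {
  p <- ml_preset("neuropathic")
  cur <- ionic_currents(model_state(p, V = -100, w = 0.4), p)
  expect_equal(unname(cur["I_slow"]), 0)
  cur <- ionic_currents(model_state(p, V = -70, w = 0.1), p)
  expect_equal(unname(cur["I_leak"]), 0)
  pa <- ml_preset("ahp")
  cur <- ionic_currents(model_state(pa, V = -100, w = 0.2, z = 0.3), pa)
  expect_equal(unname(cur[c("I_slow", "I_AHP")]), c(0, 0))
})

test_that("currents at the settled resting state sum to zero", {
  for (nm in c("normal", "neuropathic", "ahp", "s2-normal")) {
    p <- ml_preset(nm)
    st <- settle(p, 0)
    expect_lt(abs(sum(ionic_currents(st, p))), 1e-7)
  }
})

test_that("the voltage equation matches a hand-evaluated oracle", {
  # C dV/dt = (I - g_fast*m_inf(V)*(V-E_Na) - g_slow*w*(V-E_K)
  #              - g_leak*(V-E_leak)) / C, frozen by direct arithmetic at
  # V = -20, w = 0.1, beta_w = -13, I_stim = 40
  p <- ml_preset("neuropathic")
  minf <- 0.5 * (1 + tanh((-20 + 1.2) / 18))
  dV_hand <- (40 - 20 * minf * (-20 - 50) - 20 * 0.1 * (-20 + 100) -
                2 * (-20 + 70)) / 2
  d <- model_rhs(model_state(p, V = -20, w = 0.1), p, I_stim = 40)
  expect_equal(unname(d["V"]), dV_hand, tolerance = 1e-12)
  # and the recovery equation: phi * cosh((V-beta)/(2*gamma)) * (w_inf - w)
  winf <- 0.5 * (1 + tanh((-20 + 13) / 10))
  dw_hand <- 0.15 * cosh((-20 + 13) / 20) * (winf - 0.1)
  expect_equal(unname(d["w"]), dw_hand, tolerance = 1e-12)
})

test_that("R and compiled right-hand sides agree on random states", {
  set.seed(42)
  for (nm in presets_all) {
    p <- ml_preset(nm)
    for (k in 1:5) {
      st <- random_state(p)
      I <- stats::runif(1, -20, 80)
      d_r <- model_rhs(st, p, I)
      d_c <- drgexcite:::.rhs_core(drgexcite:::.variant_code(p),
                                   drgexcite:::.par_vec(p), unname(st), I)
      expect_equal(unname(d_r), as.numeric(d_c), tolerance = 1e-12,
                   info = nm)
    }
  }
})

test_that("rhs vanishes at fixed points found by the root finder", {
  for (nm in c("normal", "neuropathic", "ahp", "ungrouped-inward")) {
    p <- ml_preset(nm)
    for (fp in find_fixed_points(p, 20))
      expect_lt(max(abs(model_rhs(fp$state, p, 20))), 1e-9)
  }
})

test_that("gate at steady state implies zero gate derivative", {
  p <- ml_preset("normal")
  st <- steady_state(p, -70)
  d <- model_rhs(st, p, 0)
  expect_equal(unname(d["w"]), 0)
  expect_equal(unname(d["V"]),
               -sum(ionic_currents(st, p)) / p$C)
})

test_that("steady-state I-V curves reflect the slow-current shift", {
  V <- seq(-70, -20, 0.5)
  iv21 <- steady_state_iv(ml_preset("normal"), V, "I_slow")
  iv13 <- steady_state_iv(ml_preset("neuropathic"), V, "I_slow")
  # depolarizing beta_w shifts activation rightward: less outward current
  # at every voltage
  expect_true(all(iv13$I_slow <= iv21$I_slow + 1e-12))
  expect_equal(steady_state_iv(ml_preset("normal"), -100, "I_slow")$I_slow, 0)
  expect_equal(steady_state_iv(ml_preset("neuropathic"), -100,
                               "I_slow")$I_slow, 0)
  expect_error(steady_state_iv(ml_preset("normal"), V, "I_bogus"),
               "unknown current")
})

test_that("suprathreshold current leaves the perithreshold I-V untouched", {
  V <- seq(-70, -30, 1)
  iv <- steady_state_iv(ml_preset("suprathreshold"), V, c("I_Kdr", "I_sub"))
  expect_lt(max(abs(iv$I_sub / iv$I_Kdr)), 0.01)
})

test_that("calibration reproduces the packaged ungrouped defaults", {
  fin <- calibrate_isub("inward")
  fout <- calibrate_isub("outward")
  pin <- ml_preset("ungrouped-inward")
  pout <- ml_preset("ungrouped-outward")
  expect_equal(fin$g_sub, pin$g_sub, tolerance = 1e-3)
  expect_equal(fin$beta_y, pin$gating$y$beta, tolerance = 1e-3)
  expect_equal(fin$gamma_y, pin$gating$y$gamma, tolerance = 1e-3)
  expect_equal(fout$g_sub, pout$g_sub, tolerance = 1e-3)
  expect_lt(fin$rms, 1)
  expect_lt(fout$rms, 2)
})

test_that("ungrouped variants behave like their 2-D counterparts", {
  # inward subthreshold current: neuropathic phenotype at matched I_stim
  expect_identical(step_class(ml_preset("ungrouped-inward"), 45),
                   "repetitive")
  expect_identical(step_class(ml_preset("neuropathic"), 45), "repetitive")
  # outward subthreshold current: normal phenotype at matched I_stim
  expect_identical(step_class(ml_preset("ungrouped-outward"), 60),
                   "onset_only")
  expect_identical(step_class(ml_preset("normal"), 60), "onset_only")
})

test_that("parameter sets survive JSON and YAML round trips", {
  for (nm in c("neuropathic", "ahp", "s2-neuropathic", "ungrouped-inward")) {
    p <- ml_preset(nm)
    for (ext in c("json", "yaml")) {
      path <- withr::local_tempfile(fileext = paste0(".", ext))
      write_params(p, path)
      q <- read_params(path)
      expect_equal(drgexcite:::.par_vec(q), drgexcite:::.par_vec(p),
                   tolerance = 1e-12, info = paste(nm, ext))
      expect_identical(q$variant, p$variant)
    }
  }
})

test_that("set_param and get_param address gating fields by name", {
  p <- ml_preset("normal")
  expect_equal(get_param(p, "beta_w"), -21)
  p2 <- set_param(p, "beta_w", -13)
  expect_equal(get_param(p2, "beta_w"), -13)
  expect_equal(get_param(set_param(p, "g_fast", 25), "g_fast"), 25)
  expect_error(set_param(p, "beta_q", 1), "unknown parameter")
  # tau of a fixed-tau gate
  pa <- ml_preset("ahp")
  expect_equal(get_param(pa, "tau_z"), 300)
})

test_that("variant construction enforces its requirements", {
  expect_error(ml_params("ml2d"), "beta_w")
  expect_error(ml_params("ml2d", beta_w = -21, g_fast = -1), ">= 0")
  expect_error(model_state(ml_preset("normal"), V = -50, h = 0.5),
               "needs gates")
  expect_error(model_state(ml_preset("normal"), V = -50, w = 1.2),
               "\\[0,1\\]")
  expect_error(
    ionic_currents(c(V = -50, q = 0.1), ml_preset("normal")),
    "invalid state")
})
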