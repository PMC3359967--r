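test_that("the resting state is a unique stable fixed point", {
  p <- ml_preset("normal")
  fps <- find_fixed_points(p, 0)
  expect_length(fps, 1)
  expect_identical(fps[[1]]$stability, "stable")
  expect_lt(abs(fps[[1]]$state[["V"]] - settle(p, 0)[["V"]]), 1e-6)
})

test_that("above the Hopf the neuropathic fixed point is an unstable focus", {
  p <- ml_preset("neuropathic")
  fps <- find_fixed_points(p, 47)
  expect_length(fps, 1)
  expect_identical(fps[[1]]$stability, "unstable")
  expect_identical(fps[[1]]$geometry, "focus")
  eig <- fps[[1]]$eigenvalues
  expect_equal(eig[1], Conj(eig[2]))   # conjugate pair at a focus
})

test_that("the analytic Jacobian matches finite differences", {
  set.seed(11)
  for (nm in c("neuropathic", "s2-neuropathic")) {
    p <- ml_preset(nm)
    for (k in 1:4) {
      st <- random_state(p)
      J <- model_jacobian(p, st, I_stim = 30)
      eps <- 1e-6
      n <- length(st)
      J_fd <- matrix(0, n, n)
      for (j in seq_len(n)) {
        up <- st; up[j] <- up[j] + eps
        dn <- st; dn[j] <- dn[j] - eps
        J_fd[, j] <- (model_rhs(up, p, 30) - model_rhs(dn, p, 30)) /
          (2 * eps)
      }
      expect_equal(unname(J), J_fd, tolerance = 1e-5, info = nm)
    }
  }
})

test_that("root-finder fixed points match long noiseless settling", {
  # 20 random parameter draws near the defaults; only draws with a stable
  # resting point are settled (the others have no equilibrium to compare)
  set.seed(2024)
  n_checked <- 0
  while (n_checked < 20) {
    p <- random_params_near_default()
    fps <- Filter(function(f) f$stability == "stable",
                  find_fixed_points(p, 0))
    if (!length(fps)) next
    st <- settle(p, 0)
    d <- min(abs(vapply(fps, function(f) f$state[["V"]], numeric(1)) -
                   st[["V"]]))
    expect_lt(d, 1e-4)
    n_checked <- n_checked + 1
  }
})

test_that("nullcline intersections coincide with fixed points", {
  p <- ml_preset("neuropathic")
  nc <- nullclines(p, I_stim = 30, V_grid = seq(-80, 20, 0.01))
  dw <- nc$v_nullcline$w - x_inf(nc$v_nullcline$V, p$gating$w)
  cross <- which(dw[-1] * dw[-length(dw)] < 0)
  fps <- find_fixed_points(p, 30)
  expect_length(cross, length(fps))
  for (fp in fps)
    expect_lt(min(abs(nc$v_nullcline$V[cross] - fp$state[["V"]])), 0.02)
})

test_that("stimulation moves only the V-nullcline", {
  p <- ml_preset("normal")
  a <- nullclines(p, 0)
  b <- nullclines(p, 10)
  expect_identical(a$w_nullcline, b$w_nullcline)
  expect_false(identical(a$v_nullcline, b$v_nullcline))
  expect_equal(a$w_nullcline$w[a$w_nullcline$V == -21], 0.5)
})

test_that("Hopf refinement drives the eigenvalue real part to zero", {
  for (nm in c("neuropathic", "supercritical")) {
    hp <- hopf_point(ml_preset(nm), c(0, 100))
    expect_false(is.na(hp$I_hopf))
    fp <- find_fixed_points(ml_preset(nm), hp$I_hopf)[[1]]
    expect_lt(abs(fp$re_osc), 1e-6)
    expect_gt(fp$im_osc, 0.01)
  }
})

test_that("bifurcation diagrams find the Hopf and its type", {
  pp <- ml_preset("neuropathic")
  dg <- bifurcation_diagram(pp, range = c(38, 48), n = 41,
                            limit_cycle = TRUE)
  ev <- Filter(function(e) e$type == "hopf", dg$events)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$param, 42.8015, tolerance = 1e-3)
  expect_equal(unname(ev[[1]]$state[["V"]]), -38.5352, tolerance = 1e-3)
  expect_identical(as.character(classify_hopf(dg, ev[[1]])),
                   "hopf_subcritical")
  # hysteresis: the down-sweep sustains spiking below the up-sweep onset
  lc <- dg$limit_cycle
  on_up <- min(lc$param[lc$direction == "up" & lc$oscillating &
                          lc$amplitude > 40])
  on_dn <- min(lc$param[lc$direction == "down" & lc$oscillating &
                          lc$amplitude > 40])
  expect_lt(on_dn, on_up)
})

test_that("the beta_w = -19 Hopf is supercritical with a small stable cycle", {
  ps <- ml_preset("supercritical")
  dg <- bifurcation_diagram(ps, range = c(61, 66), n = 21, lc_dt = 0.01)
  ev <- Filter(function(e) e$type == "hopf", dg$events)
  expect_length(ev, 1)
  cls <- classify_hopf(dg, ev[[1]])
  expect_identical(as.character(cls), "hopf_supercritical")
  # squared amplitude grows linearly just past the Hopf
  d <- attr(cls, "diagnostics")
  amp <- d$creep_amplitudes
  fit <- stats::lm(I(amp^2) ~ d$probe_params)
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("the normal model has no Hopf below 80 uA/cm2 but one above", {
  pn <- ml_preset("normal")
  expect_true(is.na(hopf_point(pn, c(0, 80))$I_hopf))
  hp <- hopf_point(pn, c(80, 100))
  expect_equal(hp$I_hopf, 87.2544, tolerance = 1e-3)
})

test_that("quasi-separatrix separates spiking from non-spiking states", {
  p <- ml_preset("normal")
  qs <- quasi_separatrix(p, 60)
  w0 <- qs$fixed_point$state[["w"]]
  cls <- function(V0) {
    tr <- simulate_model(p, stim_protocol(baseline = 60), dt = 0.01,
                         duration = 100, init = c(V = V0, w = w0),
                         thin = 5L)
    max(tr$V) > 5
  }
  expect_false(cls(qs$boundary_V - 0.01))
  expect_true(cls(qs$boundary_V + 0.01))
  # the pre-stimulus rest state lies below the stimulated QS, so the step
  # must produce a spike on the way to the new fixed point
  rest <- find_fixed_points(p, 0)[[1]]$state
  expect_lt(rest[["w"]], qs_gate_at(qs, rest[["V"]]))
  expect_identical(step_class(p, 60), "onset_only")
  # at rest (no stimulation) the QS lies above/right of the fixed point:
  # no spontaneous spiking
  qs0 <- quasi_separatrix(p, 0)
  expect_gt(qs0$boundary_V, rest[["V"]])
  tr0 <- simulate_model(p, stim_protocol(baseline = 0), dt = 0.01,
                        duration = 500, thin = 10L)
  expect_lt(max(tr0$V), 0)
})

test_that("no QS regime exists past the Hopf bifurcation", {
  expect_error(quasi_separatrix(ml_preset("neuropathic"), 50),
               "no stable fixed point")
})

test_that("fast-slow analysis predicts bursting vs tonic and hysteresis", {
  pa <- ml_preset("ahp")
  fs43 <- fast_slow_analysis(pa, 43, n = 81)
  fs46 <- fast_slow_analysis(pa, 46, n = 81)
  expect_identical(fs43$regime, "bursting")
  expect_identical(fs46$regime, "tonic")
  expect_gt(abs(fs43$z_burst_on - fs43$z_burst_off), 1e-3)
  # the full model's z excursion during noiseless bursting stays close to
  # the window predicted from the frozen-z fast subsystem
  tr <- simulate_model(pa, stim_protocol(amp = 43), dt = 0.01,
                       duration = 8000, thin = 10L)
  z <- tr$gates[tr$time > 1000, "z"]
  expect_lt(abs(min(z) - fs43$z_burst_on), 0.01)
  expect_lt(abs(max(z) - fs43$z_burst_off), 0.01)
})

test_that("diagram branches and events serialize to CSV/JSON", {
  dg <- bifurcation_diagram(ml_preset("neuropathic"), range = c(40, 45),
                            n = 11, limit_cycle = FALSE)
  dir <- withr::local_tempdir()
  write_diagram(dg, dir)
  fp <- utils::read.csv(file.path(dir, "fixed_points.csv"))
  expect_true(all(c("param", "V", "stability") %in% names(fp)))
  ev <- jsonlite::read_json(file.path(dir, "events.json"),
                            simplifyVector = TRUE)
  expect_identical(ev$param, "I_stim")
})
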