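test_that("a settled state stays at rest without noise", {
  for (nm in c("normal", "neuropathic", "ahp")) {
    p <- ml_preset(nm)
    tr <- simulate_model(p, stim_protocol(baseline = 0), dt = 0.01,
                         duration = 500, thin = 10L)
    expect_lt(diff(range(tr$V)), 1e-6)
  }
})

test_that("identical seeds give bit-identical trajectories", {
  p <- ml_preset("neuropathic")
  prot <- stim_protocol(baseline = 35, noise_variance = 20, seed = 7)
  t1 <- simulate_model(p, prot, dt = 0.05, duration = 500, thin = 4L)
  t2 <- simulate_model(p, prot, dt = 0.05, duration = 500, thin = 4L)
  expect_identical(t1$V, t2$V)
  expect_identical(t1$gates, t2$gates)
  t3 <- simulate_model(p, stim_protocol(baseline = 35, noise_variance = 20,
                                        seed = 8),
                       dt = 0.05, duration = 500, thin = 4L)
  expect_false(identical(t1$V, t3$V))
})

test_that("noiseless runs are independent of the seed", {
  p <- ml_preset("normal")
  t1 <- simulate_model(p, stim_protocol(amp = 60, seed = 1), dt = 0.01,
                       duration = 200, thin = 10L)
  t2 <- simulate_model(p, stim_protocol(amp = 60, seed = 99), dt = 0.01,
                       duration = 200, thin = 10L)
  expect_identical(t1$V, t2$V)
})

test_that("halving dt leaves early spike times within 0.5 ms", {
  # cumulative phase drift over a full second of ~80 cycles grows linearly
  # with the first-order Euler error, so convergence is asserted on the
  # first ten spikes and on the spike count
  p <- ml_preset("neuropathic")
  st <- function(dt) {
    tr <- simulate_model(p, stim_protocol(amp = 45, offset = 1000),
                         dt = dt, duration = 1000,
                         thin = max(1L, as.integer(0.005 / dt)))
    detect_spikes(tr)$times
  }
  a <- st(0.01); b <- st(0.005)
  expect_identical(length(a), length(b))
  expect_lt(max(abs(a[1:10] - b[1:10])), 0.5)
})

test_that("ensemble-mean noisy voltage tracks the noiseless trace", {
  p <- ml_preset("neuropathic")
  init <- settle(p, 30)
  nl <- simulate_model(p, stim_protocol(baseline = 30), dt = 0.05,
                       duration = 400, init = init, thin = 20L)
  ens <- vapply(1:100, function(s)
    simulate_model(p, stim_protocol(baseline = 30, noise_variance = 20,
                                    seed = s),
                   dt = 0.05, duration = 400, init = init, thin = 20L)$V,
    numeric(length(nl$V)))
  m <- rowMeans(ens)
  # Monte-Carlo error plus the small rectification offset the noise
  # induces around the curved I-V relation (~0.3 mV at this holding level)
  expect_lt(max(abs(m - nl$V)), 0.6)
})

test_that("the noise discretization is dt-invariant", {
  p <- ml_preset("neuropathic")
  init <- settle(p, 30)
  v_of <- function(dt) {
    tr <- simulate_model(p, stim_protocol(baseline = 30,
                                          noise_variance = 20, seed = 3),
                         dt = dt, duration = 8000, init = init,
                         thin = as.integer(1 / dt))
    stats::var(tr$V[tr$time > 500])
  }
  v1 <- v_of(0.05); v2 <- v_of(0.01)
  expect_lt(abs(v1 - v2) / v1, 0.35)   # different sample paths, same law
})

test_that("settle agrees with the fixed-point finder and errors past it", {
  p <- ml_preset("neuropathic")
  st <- settle(p, 0)
  fps <- find_fixed_points(p, 0)
  expect_length(fps, 1)
  expect_lt(abs(st[["V"]] - fps[[1]]$state[["V"]]), 1e-6)
  expect_lt(max(abs(model_rhs(st, p, 0))), 1e-9)
  # above the Hopf current there is no stable point to settle to
  expect_error(settle(p, 50, t_max = 4000), "oscillatory")
})

test_that("dt outside the stated forward range is rejected", {
  p <- ml_preset("normal")
  expect_error(simulate_model(p, dt = 0.1, duration = 10), "dt must lie")
  expect_error(simulate_model(p, dt = 0.001, duration = 10), "dt must lie")
})

test_that("non-finite states produce a diagnostic error", {
  p <- ml_preset("normal")
  expect_error(
    simulate_model(p, stim_protocol(baseline = 1e7), dt = 0.05,
                   duration = 10, init = steady_state(p, -70)),
    "non-finite state at step")
})

test_that("strict gate mode raises where clamping would engage", {
  # far below rest the recovery time constant shrinks well under dt, so a
  # single Euler step overshoots the gate out of [0, 1]
  p <- ml_preset("neuropathic")
  init <- c(V = -150, w = 0.5)
  expect_error(
    simulate_model(p, stim_protocol(baseline = 0), dt = 0.05,
                   duration = 1, init = init, strict_gates = TRUE),
    "gate")
  tr <- simulate_model(p, stim_protocol(baseline = 0), dt = 0.05,
                       duration = 50, init = init)
  expect_true(all(tr$gates >= 0 & tr$gates <= 1))
})

test_that("backward integration from the fixed point is near-constant", {
  p <- ml_preset("normal")
  fp <- find_fixed_points(p, 60)[[1]]
  cur <- integrate_backward(p, 60, fp$state, duration = 5)
  expect_lt(diff(range(cur[, "V"])), 1e-6)
})

test_that("forward flow returns to the backward-traced curve", {
  # time-reversal consistency: a forward trajectory started on the QS
  # curve stays near it while it remains in the traced window
  p <- ml_preset("normal")
  qs <- quasi_separatrix(p, 60)
  cur <- qs$curve
  k <- which(cur[, "V"] > -60 & cur[, "V"] < -45)[1]
  expect_false(is.na(k))
  start <- c(V = unname(cur[k, "V"]), w = unname(cur[k, "w"]))
  tr <- simulate_model(p, stim_protocol(baseline = 60), dt = 0.005,
                       duration = 1.5, init = start, thin = 1L)
  d <- vapply(seq(1, length(tr$V), by = 30), function(i) {
    min(sqrt((cur[, "V"] - tr$V[i])^2 +
               (100 * (cur[, "w"] - tr$gates[i, 1]))^2))
  }, numeric(1))
  expect_lt(stats::median(d), 2)
})

test_that("trajectories round-trip through CSV with metadata", {
  p <- ml_preset("ahp")
  tr <- simulate_model(p, stim_protocol(amp = 44, noise_variance = 20,
                                        seed = 5),
                       dt = 0.05, duration = 300, thin = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  rt <- read_trajectory(path)
  expect_equal(rt$V, tr$V)
  expect_equal(rt$gates, tr$gates, ignore_attr = TRUE)
  expect_equal(rt$dt, tr$dt)
  expect_equal(rt$seed, 5)
  expect_identical(rt$variant, "ml3d_ahp")
})
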