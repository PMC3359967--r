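test_that("spike detection recovers a constructed spike train exactly", {
  tr <- synthetic_spike_traj(n_spikes = 7, peak = 40)
  sp <- detect_spikes(tr)
  expect_length(sp$times, 7)
  expect_equal(sp$peaks, rep(40, 7), tolerance = 1e-9)
  expect_true(all(diff(sp$times) >= 2))
  # a subthreshold trace yields an empty train
  quiet <- synthetic_spike_traj(n_spikes = 0)
  expect_length(detect_spikes(quiet)$times, 0)
})

test_that("response classification follows the step-timing rules", {
  prot <- stim_protocol(amp = 50, onset = 0, offset = 900)
  mk <- function(times) list(times = times)
  expect_identical(classify_response(mk(numeric(0)), prot, 900),
                   "quiescent")
  expect_identical(classify_response(mk(c(4, 30, 80)), prot, 900),
                   "onset_only")
  expect_identical(classify_response(mk(seq(5, 880, by = 15)), prot, 900),
                   "repetitive")
  # an adapting train that dies mid-step is neither class
  expect_identical(classify_response(mk(seq(5, 400, by = 15)), prot, 900),
                   "other")
  expect_error(classify_response(mk(1), stim_protocol(amp = 1, onset = 0,
                                                      offset = 300), 300),
               "500 ms")
})

test_that("rheobase bisection brackets the known model thresholds", {
  thr_n <- threshold_current(ml_preset("normal"), "spike", c(0, 100))
  expect_true(thr_n$attained)
  expect_lte(thr_n$value, 60)          # spikes at the stated 60 uA/cm2
  expect_gt(thr_n$value, 40)
  thr_p <- threshold_current(ml_preset("neuropathic"), "repetitive",
                             c(0, 100))
  expect_true(thr_p$attained)
  expect_lte(thr_p$value, 45)          # repetitive at the stated 45
  # two independent routes to the repetitive threshold agree
  hp <- hopf_point(ml_preset("neuropathic"), c(0, 100))
  expect_lt(abs(thr_p$value - hp$I_hopf), 1)
  # the normal model cannot spike repetitively below its distant Hopf
  thr_nr <- threshold_current(ml_preset("normal"), "repetitive", c(0, 80))
  expect_false(thr_nr$attained)
  expect_true(is.na(thr_nr$value))
})

test_that("spike threshold voltage reads a constructed inflection", {
  # piecewise trace: exponential approach to a knee at -35 mV followed by
  # a fast linear upstroke; the curvature maximum sits at the knee
  dt <- 0.05
  t1 <- seq(0, 20, dt)
  foot <- -60 + 10 * (1 - exp(-t1 / 8))          # slow depolarization
  knee <- max(foot)
  up <- seq(knee, 40, by = 40 * dt)              # 40 mV/ms upstroke
  down <- seq(40, -60, by = -40 * dt)
  V <- c(foot, up[-1], down[-1], rep(-60, 100))
  tr <- structure(list(time = (seq_along(V) - 1) * dt, V = V,
                       gates = matrix(0, length(V), 1,
                                      dimnames = list(NULL, "w")),
                       istim = rep(0, length(V)), dt = dt, dt_sample = dt,
                       seed = NULL, variant = "synthetic",
                       fingerprint = "syn", y_end = NULL,
                       step_failed = -1L),
                  class = "trajectory")
  sp <- detect_spikes(tr)
  expect_length(sp$times, 1)
  thr <- spike_threshold_voltage(tr, sp)
  expect_lt(abs(thr - knee), 1.5)
})

test_that("per-spike threshold rises as sodium channels inactivate", {
  pd <- ml_preset("nainact-slow")
  tr <- simulate_model(pd, stim_protocol(amp = 80, offset = 4000),
                       dt = 0.01, duration = 4000, thin = 5L)
  sp <- detect_spikes(tr)
  expect_gt(length(sp$times), 20)
  # the train terminates well before the step ends
  expect_lt(max(sp$times), 3000)
  thr <- spike_threshold_voltage(tr, sp)
  n <- length(thr)
  expect_gt(mean(thr[seq(n - 4, n)], na.rm = TRUE),
            mean(thr[2:6], na.rm = TRUE) + 2)
  # h declines along the train
  h <- tr$gates[sp$idx, "h"]
  expect_lt(h[n], h[2] - 0.05)
})

test_that("the Welch estimator recovers variance and a known peak", {
  # 60 Hz sine in white noise, 20-s trace at 1-ms sampling
  set.seed(99)
  dt <- 1
  t <- seq(0, 20000 - dt, dt)
  V <- 3 * sin(2 * pi * 60 * t / 1000) + rnorm(length(t), 0, 1)
  tr <- structure(list(time = t, V = V, dt_sample = dt), class = "trajectory")
  sp <- mpo_spectrum(tr)
  expect_equal(sp$peak_freq, 60, tolerance = 0.02)
  # estimator consistency: integrated density recovers the variance
  v_est <- sum(sp$density) * diff(sp$freq[1:2])
  expect_lt(abs(v_est - stats::var(V)) / stats::var(V), 0.05)
  expect_true(has_discernible_peak(sp))
  # pure white noise shows no discernible peak on a long trace
  V2 <- rnorm(length(t), 0, 1)
  tr2 <- structure(list(time = t, V = V2, dt_sample = dt),
                   class = "trajectory")
  expect_false(has_discernible_peak(mpo_spectrum(tr2)))
  expect_error(mpo_spectrum(tr, window = c(0, 500)), "Welch segment")
})

test_that("burst grouping recovers a constructed three-burst train", {
  times <- c(100 + c(0, 10, 20, 30), 600 + c(0, 10, 20),
             1100 + c(0, 10, 20, 30, 40))
  bs <- detect_bursts(list(times = times))
  expect_false(bs$tonic)
  expect_identical(nrow(bs$bursts), 3L)
  expect_equal(bs$bursts$n_spikes, c(4, 3, 5))
  expect_equal(bs$interburst, c(470, 480))
  # a perfectly regular train is tonic
  reg <- detect_bursts(list(times = seq(0, 1000, by = 12.5)))
  expect_true(reg$tonic)
  expect_identical(nrow(reg$bursts), 0L)
})

test_that("feature summaries serialize cleanly", {
  p <- ml_preset("neuropathic")
  prot <- stim_protocol(amp = 45, onset = 0, offset = 800)
  tr <- simulate_model(p, prot, dt = 0.01, duration = 800, thin = 10L)
  path <- withr::local_tempfile(fileext = ".json")
  fs <- feature_summary(tr, prot, path = path)
  expect_identical(fs$response_class, "repetitive")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(j$response_class, "repetitive")
  expect_gt(j$n_spikes, 10)
})

test_that("covariation grid agrees with single-parameter analysis", {
  cg <- covariation_grid(c(-21, -13), c(14.2867, 18), i_range = c(0, 100))
  norm_cell <- cg[cg$beta_w == -21 & cg$gamma_m == 18, ]
  expect_equal(norm_cell$I_repetitive,
               hopf_point(ml_preset("normal"), c(0, 100))$I_hopf,
               tolerance = 1e-6)
  # the offsetting pair restores the normal threshold
  off_cell <- cg[cg$beta_w == -13 & cg$gamma_m == 14.2867, ]
  expect_equal(off_cell$I_repetitive, norm_cell$I_repetitive,
               tolerance = 1e-3)
  # cells without a Hopf in range are flagged absent, not zero
  low <- cg[cg$beta_w == -21 & cg$gamma_m == 14.2867, ]
  expect_false(low$attained)
  expect_true(is.na(low$I_repetitive))
})

test_that("scenario registry runs end to end and self-checks", {
  res <- run_scenario("figS1", out = withr::local_tempdir(), quick = TRUE)
  expect_true(res$pass)
  expect_true(all(c("check", "pass") %in% names(res$self_check)))
})
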