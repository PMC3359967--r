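# shared helpers for the test suite

step_class <- function(params, I, duration = 1000, dt = 0.01) {
  prot <- stim_protocol(amp = I, onset = 0, offset = duration)
  tr <- simulate_model(params, prot, dt = dt, duration = duration,
                       thin = as.integer(0.1 / dt))
  classify_response(detect_spikes(tr), prot, duration)
}

# random state within physiological bounds, reproducible
random_state <- function(params) {
  g <- model_gates(params)
  st <- c(V = stats::runif(1, -85, 20),
          stats::setNames(stats::runif(length(g), 0.02, 0.95), g))
  st
}

# random parameter draw near the defaults (multiplicative jitter on
# conductances, additive on gating voltages)
random_params_near_default <- function() {
  ml_params("ml2d",
            beta_w = -21 + stats::runif(1, -1, 9),
            g_fast = 20 * stats::runif(1, 0.9, 1.1),
            g_slow = 20 * stats::runif(1, 0.9, 1.1),
            g_leak = 2 * stats::runif(1, 0.9, 1.1),
            beta_m = -1.2 + stats::runif(1, -1, 1),
            gamma_m = 18 + stats::runif(1, -1.5, 1.5))
}

# synthetic trace with triangular spikes riding on a flat baseline
synthetic_spike_traj <- function(n_spikes = 7, baseline = -60, peak = 40,
                                 dt = 0.1, gap_ms = 100) {
  width <- 40                         # samples per spike flank
  one <- c(seq(baseline, peak, length.out = width),
           seq(peak, baseline, length.out = width))
  quiet <- rep(baseline, round(gap_ms / dt))
  V <- quiet
  for (k in seq_len(n_spikes)) V <- c(V, one, quiet)
  structure(list(time = (seq_along(V) - 1) * dt, V = V,
                 gates = matrix(0, length(V), 1,
                                dimnames = list(NULL, "w")),
                 istim = rep(0, length(V)), dt = dt, dt_sample = dt,
                 seed = NULL, variant = "synthetic", fingerprint = "syn",
                 y_end = NULL, step_failed = -1L),
            class = "trajectory")
}
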