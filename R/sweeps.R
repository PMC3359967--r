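#' Minimum sustainable firing rate (down-sweep)
#'
#' Starts from the spiking attractor above threshold and lowers the
#' current stepwise, carrying the state along; the minimum sustainable
#' rate is the firing rate at the lowest current that still sustains
#' spiking for the full probe duration. With Hopf-mediated (type 2) spike
#' initiation this rate is bounded away from zero.
#'
#' @param params an `ml_params` object
#' @param I_start suprathreshold starting current (uA/cm2)
#' @param step current decrement (uA/cm2)
#' @param duration probe duration per current (ms)
#' @param dt integration step (ms)
#' @return list with `rate` (Hz), `I_min` (lowest sustaining current)
#' @export
min_sustainable_rate <- function(params, I_start, step = 0.25,
                                 duration = 2000, dt = 0.05) {
  state <- steady_state(params, -20)        # kick onto the spiking attractor
  I <- I_start
  last_rate <- NA_real_; last_I <- NA_real_
  repeat {
    tr <- simulate_model(params, stim_protocol(baseline = I), dt = dt,
                         duration = duration, init = state,
                         thin = max(1L, as.integer(0.1 / dt)))
    state <- tr$y_end
    names(state) <- c("V", model_gates(params))
    sp <- detect_spikes(tr)
    late <- sum(sp$times > duration / 2)
    if (late < 2) break
    last_rate <- 1000 * late / (duration / 2)
    last_I <- I
    I <- I - step
    if (I < 0) break
  }
  list(rate = last_rate, I_min = last_I)
}

.noisy_mpo <- function(params, I, seeds, duration, dt = 0.05,
                       noise_variance = 20, transient = 500) {
  # start at the stable fixed point: settling by simulation can fail inside
  # the bistable window where a step from rest lands on the spiking cycle
  fps <- Filter(function(f) f$stability == "stable",
                find_fixed_points(params, I))
  init <- if (length(fps)) fps[[1]]$state else "settled"
  res <- lapply(seeds, function(s) {
    tr <- simulate_model(
      params, stim_protocol(baseline = I, noise_variance = noise_variance,
                            seed = s),
      dt = dt, duration = duration + transient, init = init,
      thin = max(1L, as.integer(1 / dt)))
    sp <- tryCatch(
      mpo_spectrum(tr, window = c(transient, max(tr$time)),
                   exclude_spikes = TRUE),
      error = function(e) NULL)
    if (is.null(sp)) return(c(NA_real_, NA_real_, NA))
    c(sp$peak_power, sp$peak_freq, has_discernible_peak(sp))
  })
  m <- do.call(rbind, res)
  c(peak_power = stats::median(m[, 1], na.rm = TRUE),
    peak_freq = stats::median(m[, 2], na.rm = TRUE),
    discernible = mean(m[, 3], na.rm = TRUE) > 0.5)
}

#' Sweep the slow-current activation voltage (the pathology continuum)
#'
#' For each `beta_w` between the normal (-21 mV) and neuropathic (-13 mV)
#' values, computes the repetitive-spiking threshold (the Hopf current,
#' cross-validated against simulation elsewhere), the single/onset-spike
#' threshold, noise-driven MPO peak power and frequency at currents fixed
#' offsets below the repetitive threshold, and the minimum sustainable
#' firing rate.
#'
#' @param beta_w_grid beta_w values (mV), within \[-21, -13\]
#' @param noise_variance MPO simulation noise (mV^2)
#' @param istim_offsets currents below the repetitive threshold at which
#'   MPOs are probed (uA/cm2); the defaults bracket the window in which
#'   noise-independent oscillations can contaminate the measurement (the
#'   nearer offset) or not (the farther one)
#' @param seeds RNG seeds per grid point
#' @param mpo_duration analyzed MPO trace length (ms)
#' @return data.frame, one row per `beta_w`: thresholds, MPO summaries at
#'   the `"high"` (nearer) and `"low"` (farther) offsets, minimum
#'   sustainable rate
#' @export
sweep_beta_w <- function(beta_w_grid = seq(-21, -13, by = 1),
                         noise_variance = 20, istim_offsets = c(1.3, 4),
                         seeds = 1:3, mpo_duration = 5000) {
  stopifnot(all(beta_w_grid >= -21 & beta_w_grid <= -13))
  rows <- lapply(beta_w_grid, function(bw) {
    p <- ml_params("ml2d", beta_w = bw)
    hp <- hopf_point(p, c(0, 200))
    thr_rep <- hp$I_hopf
    thr_spike <- threshold_current(p, "spike",
                                   c(0, if (is.na(thr_rep)) 200
                                     else thr_rep + 10))$value
    hi <- .noisy_mpo(p, thr_rep - istim_offsets[1], seeds, mpo_duration,
                     noise_variance = noise_variance)
    lo <- .noisy_mpo(p, thr_rep - istim_offsets[2], seeds, mpo_duration,
                     noise_variance = noise_variance)
    msr <- min_sustainable_rate(p, thr_rep + 5)
    data.frame(beta_w = bw, I_repetitive = thr_rep, I_onset = thr_spike,
               V_hopf = hp$V_hopf,
               mpo_power_high = hi[["peak_power"]],
               mpo_freq_high = hi[["peak_freq"]],
               mpo_power_low = lo[["peak_power"]],
               mpo_freq_low = lo[["peak_freq"]],
               min_rate = msr$rate)
  })
  do.call(rbind, rows)
}

#' Repetitive-spiking threshold over a (beta_w, gamma_m) grid
#'
#' Co-variation analysis: the Hopf (repetitive-spiking threshold) current
#' for every combination of the slow-current activation voltage `beta_w`
#' and the fast-activation slope `gamma_m`. Cells where no Hopf exists in
#' `i_range` (no repetitive spiking attainable) are flagged `attained =
#' FALSE` with `I_repetitive = NA` -- absent, not zero.
#'
#' @param beta_w_grid,gamma_m_grid rectangular grid axes (mV)
#' @param i_range current range searched (uA/cm2)
#' @return data.frame with columns `beta_w`, `gamma_m`, `I_repetitive`,
#'   `attained`
#' @export
covariation_grid <- function(beta_w_grid = seq(-21, -13, by = 2),
                             gamma_m_grid = seq(13, 19, by = 1),
                             i_range = c(0, 200)) {
  cells <- expand.grid(beta_w = beta_w_grid, gamma_m = gamma_m_grid)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    p <- ml_params("ml2d", beta_w = cells$beta_w[i],
                   gamma_m = cells$gamma_m[i])
    hp <- hopf_point(p, i_range)
    data.frame(beta_w = cells$beta_w[i], gamma_m = cells$gamma_m[i],
               I_repetitive = hp$I_hopf, attained = !is.na(hp$I_hopf))
  })
  do.call(rbind, res)
}
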