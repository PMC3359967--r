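#' Stimulus protocol
#'
#' A baseline current, a step of amplitude `amp` between `onset` and
#' `offset`, and optional additive Gaussian white membrane noise of
#' variance `noise_variance` (mV^2, referenced to a 1-ms step; see
#' [simulate_model()] for the discretization convention).
#'
#' @param baseline holding current (uA/cm2)
#' @param amp step amplitude (uA/cm2)
#' @param onset,offset step timing (ms); `onset < offset`
#' @param noise_variance white-noise variance (mV^2), >= 0
#' @param seed integer RNG seed or `NULL`
#' @return an object of class `stim_protocol`
#' @export
stim_protocol <- function(baseline = 0, amp = 0, onset = 0, offset = Inf,
                          noise_variance = 0, seed = NULL) {
  stopifnot(onset < offset, noise_variance >= 0)
  structure(list(baseline = baseline, amp = amp, onset = onset,
                 offset = offset, noise_variance = noise_variance,
                 seed = seed),
            class = "stim_protocol")
}

.as_trajectory <- function(res, params, dt, thin, seed, t0 = 0) {
  n <- res$n_recorded
  states <- res$states[seq_len(n), , drop = FALSE]
  colnames(states) <- c("V", model_gates(params))
  structure(list(
    time = t0 + (seq_len(n) - 1) * dt * thin,
    V = states[, "V"],
    gates = states[, -1, drop = FALSE],
    istim = res$istim[seq_len(n)],
    dt = dt, dt_sample = dt * thin, seed = seed,
    variant = params$variant, fingerprint = .fingerprint(params),
    y_end = res$y_end, step_failed = res$step_failed),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %s, %.6g ms at dt = %g ms (sampled every %g ms), %d points\n",
    x$variant, max(x$time), x$dt, x$dt_sample, length(x$time)))
  cat(sprintf("  V in [%.2f, %.2f] mV; seed: %s\n", min(x$V), max(x$V),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_ms = x$time, V_mV = x$V, x$gates,
             I_stim = x$istim, check.names = FALSE)
}

#' Simulate a model variant under a stimulus protocol
#'
#' Forward Euler integration (Euler-Maruyama when the protocol carries
#' noise). Noise convention: the white-noise term `n(t)` with variance
#' `noise_variance` (mV^2) enters the voltage equation as a per-step draw
#' referenced to a step of `noise_ref_dt` ms, i.e. a Wiener increment of
#' intensity `noise_variance * noise_ref_dt` mV^2/ms (per-step voltage
#' kick of standard deviation `sqrt(noise_variance * noise_ref_dt * dt)`).
#' The realized trace statistics are therefore independent of `dt`, and at
#' `dt = noise_ref_dt` the discretization coincides with drawing
#' `N(0, noise_variance)` directly in the voltage update each step (the
#' fixed-step idiom this convention is calibrated to; the default
#' `noise_ref_dt = 0.05` ms reproduces weak channel-noise-like
#' fluctuations that leave subthreshold oscillation and bursting structure
#' intact). `noise_scaling = "per_step"` instead adds the raw
#' `N(0, noise_variance)` term to dV/dt scaled only by `dt`
#' (dt-dependent; for cross-checking the convention).
#'
#' @param params an `ml_params` object
#' @param protocol a [stim_protocol()]
#' @param dt Euler time step (ms), in \[0.005, 0.05\]
#' @param duration total simulated time (ms)
#' @param init named state vector, or `"settled"` (default) for the
#'   noiseless equilibrium at the baseline current via [settle()]
#' @param thin record every `thin`-th step
#' @param strict_gates error (instead of clamping) if a gate leaves \[0, 1\]
#' @param noise_scaling `"wiener"` (dt-invariant, default) or `"per_step"`
#' @param noise_ref_dt reference step (ms) fixing the Wiener intensity
#' @return a `trajectory` object
#' @examples
#' p <- ml_preset("neuropathic")
#' tr <- simulate_model(p, stim_protocol(amp = 45), dt = 0.01, duration = 200)
#' @export
simulate_model <- function(params, protocol = stim_protocol(), dt = 0.01,
                           duration = 1000, init = "settled", thin = 1L,
                           strict_gates = FALSE,
                           noise_scaling = c("wiener", "per_step"),
                           noise_ref_dt = 0.05) {
  stopifnot(inherits(params, "ml_params"), inherits(protocol, "stim_protocol"),
            duration > 0)
  if (dt < 0.005 || dt > 0.05)
    stop("dt must lie in [0.005, 0.05] ms for forward runs")
  noise_scaling <- match.arg(noise_scaling)
  if (identical(init, "settled")) {
    init <- settle(params, I_stim = protocol$baseline)
  } else {
    init <- .check_state(init, params)
  }
  sd_step <- if (protocol$noise_variance > 0) {
    if (noise_scaling == "wiener")
      sqrt(protocol$noise_variance * noise_ref_dt * dt)
    else dt * sqrt(protocol$noise_variance)   # raw N(0, s2) term in dV/dt
  } else 0
  if (sd_step > 0 && !is.null(protocol$seed)) set.seed(protocol$seed)
  n_steps <- ceiling(duration / dt)
  res <- .euler_core(.variant_code(params), .par_vec(params),
                     unname(init), dt, as.integer(n_steps),
                     protocol$baseline, protocol$amp, protocol$onset,
                     protocol$offset, sd_step, as.integer(thin),
                     strict_gates)
  if (res$step_failed > 0)
    stop(sprintf(
      "non-finite state at step %d (t = %.4f ms); last recorded V = %.3f",
      res$step_failed, res$step_failed * dt,
      res$states[res$n_recorded, 1]))
  .as_trajectory(res, params, dt, thin, protocol$seed)
}

#' Noiseless equilibrium state at a holding current
#'
#' Integrates the noiseless model forward until the right-hand side norm
#' drops below `tol`; errors if no stable fixed point is approached within
#' `t_max` (e.g. when the holding current puts the model past its Hopf
#' bifurcation and the steady behavior is oscillatory).
#'
#' @param params an `ml_params` object
#' @param I_stim holding current (uA/cm2)
#' @param tol convergence tolerance on `max(abs(rhs))`
#' @param t_max giving-up time (ms)
#' @return named state vector at equilibrium
#' @export
settle <- function(params, I_stim = 0, tol = 1e-9, t_max = 60000) {
  y <- steady_state(params, params$E_leak)
  dt <- 0.05
  t <- 0
  chunk <- 2000
  repeat {
    res <- .euler_core(.variant_code(params), .par_vec(params), unname(y),
                       dt, as.integer(chunk / dt), I_stim, 0, 0, Inf,
                       0, as.integer(chunk / dt), FALSE)
    if (res$step_failed > 0) stop("state diverged while settling")
    y_new <- res$y_end
    names(y_new) <- names(y)
    t <- t + chunk
    d <- model_rhs(y_new, params, I_stim)
    if (max(abs(d)) < tol) return(y_new)
    # no progress toward a fixed point and time is up -> oscillatory regime
    if (t >= t_max)
      stop("settle() did not converge within ", t_max, " ms (max|rhs| = ",
           signif(max(abs(d)), 3),
           "); the regime at this current is likely oscillatory ",
           "(no stable fixed point)")
    y <- y_new
  }
}

#' Backward-time integration (quasi-separatrix tracing)
#'
#' Integrates a 2-D variant backward in time from `start`. Trajectories
#' that diverge to the edge of the stated voltage window terminate cleanly,
#' returning the partial curve.
#'
#' @param params a 2-D `ml_params` object (`ml2d` or `ml2d_nainact_fast`)
#' @param I_stim stimulus current held constant (uA/cm2)
#' @param start named state vector to start from
#' @param duration backward time span (ms)
#' @param dt step (ms)
#' @param v_window voltage window outside which the trace stops (mV)
#' @param thin record every `thin`-th step
#' @return matrix with columns `V` and the gate name
#' @export
integrate_backward <- function(params, I_stim, start, duration, dt = 0.01,
                               v_window = c(-120, 60), thin = 1L) {
  if (!params$variant %in% c("ml2d", "ml2d_nainact_fast"))
    stop("backward integration is for 2-D (phase-plane) variants only")
  start <- .check_state(start, params)
  res <- .euler_backward_core(.variant_code(params), .par_vec(params),
                              unname(start), dt,
                              as.integer(ceiling(duration / dt)), I_stim,
                              v_window, as.integer(thin))
  out <- res$states[seq_len(res$n_recorded), , drop = FALSE]
  colnames(out) <- c("V", model_gates(params))
  out
}

#' Write / read a trajectory as CSV (+ JSON metadata sidecar)
#'
#' Columns: `time_ms`, `V_mV`, one per gate, `I_stim`. Metadata (dt, seed,
#' variant, parameter fingerprint) goes to `<path>.json`.
#'
#' @param traj a `trajectory`
#' @param path CSV file path
#' @return `read_trajectory` returns a `trajectory`; `write_trajectory`
#'   returns `path` invisibly
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- traj[c("dt", "dt_sample", "seed", "variant", "fingerprint")]
  meta$seed <- if (is.null(meta$seed)) NA else meta$seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else list(dt = NA, dt_sample = diff(d$time_ms[1:2]), seed = NA,
                    variant = NA, fingerprint = NA)
  gates <- setdiff(names(d), c("time_ms", "V_mV", "I_stim"))
  structure(list(time = d$time_ms, V = d$V_mV,
                 gates = as.matrix(d[gates]), istim = d$I_stim,
                 dt = meta$dt, dt_sample = meta$dt_sample,
                 seed = if (is.na(meta$seed[1])) NULL else meta$seed,
                 variant = meta$variant, fingerprint = meta$fingerprint,
                 y_end = NULL, step_failed = -1L),
            class = "trajectory")
}
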