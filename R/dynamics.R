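#' Jacobian of the model at a state
#'
#' Analytic partial derivatives for the 2-D variants (`ml2d`,
#' `ml2d_nainact_fast`); central finite differences (step 1e-6) on
#' [model_rhs()] for the 3-D variants.
#'
#' @param params an `ml_params` object
#' @param state named state vector
#' @param I_stim stimulus current (uA/cm2)
#' @return square Jacobian matrix (d(dstate/dt) / dstate)
#' @export
model_jacobian <- function(params, state, I_stim = 0) {
  state <- .check_state(state, params)
  p <- params
  V <- state[["V"]]
  dxinf <- function(V, s) 0.5 / (s$gamma * cosh((V - s$beta) / s$gamma)^2)
  if (p$variant == "ml2d") {
    m <- p$gating$m; w <- p$gating$w
    wv <- state[["w"]]
    fV <- -(p$g_fast * p$h_clamp *
              (dxinf(V, m) * (V - p$E_Na) + x_inf(V, m)) +
            p$g_slow * wv + p$g_adapt * p$z_clamp + p$g_leak) / p$C
    fw <- -p$g_slow * (V - p$E_K) / p$C
    ch <- cosh((V - w$beta) / (2 * w$gamma))
    sh <- sinh((V - w$beta) / (2 * w$gamma))
    gV <- w$phi * (sh / (2 * w$gamma) * (x_inf(V, w) - wv) +
                   ch * dxinf(V, w))
    gw <- -w$phi * ch
    return(matrix(c(fV, gV, fw, gw), 2, 2,
                  dimnames = list(c("V", "w"), c("V", "w"))))
  }
  if (p$variant == "ml2d_nainact_fast") {
    m <- p$gating$m; h <- p$gating$h
    hv <- state[["h"]]
    fV <- -(p$g_fast * hv * (dxinf(V, m) * (V - p$E_Na) + x_inf(V, m)) +
            p$g_leak) / p$C
    fh <- -p$g_fast * x_inf(V, m) * (V - p$E_Na) / p$C
    ch <- cosh((V - h$beta) / (2 * h$gamma))
    sh <- sinh((V - h$beta) / (2 * h$gamma))
    gV <- h$phi * (sh / (2 * h$gamma) * (x_inf(V, h) - hv) +
                   ch * dxinf(V, h))
    gh <- -h$phi * ch
    return(matrix(c(fV, gV, fh, gh), 2, 2,
                  dimnames = list(c("V", "h"), c("V", "h"))))
  }
  # central finite differences for 3-D variants
  n <- length(state)
  J <- matrix(0, n, n, dimnames = list(names(state), names(state)))
  eps <- 1e-6
  for (j in seq_len(n)) {
    up <- state; up[j] <- up[j] + eps
    dn <- state; dn[j] <- dn[j] - eps
    J[, j] <- (model_rhs(up, params, I_stim) -
               model_rhs(dn, params, I_stim)) / (2 * eps)
  }
  J
}

.classify_fp <- function(eig) {
  re <- Re(eig); im <- Im(eig)
  focus <- any(abs(im) > 1e-9)
  stability <- if (all(re < 0)) "stable" else "unstable"
  geometry <- if (focus) "focus"
              else if (any(re > 0) && any(re < 0)) "saddle" else "node"
  list(stability = stability, geometry = geometry)
}

.make_fp <- function(params, V, I_stim) {
  state <- steady_state(params, V)
  eig <- eigen(model_jacobian(params, state, I_stim),
               only.values = TRUE)$values
  cls <- .classify_fp(eig)
  im <- Im(eig)
  osc <- which(abs(im) > 1e-9)
  structure(list(state = state, I_stim = I_stim, eigenvalues = eig,
                 stability = cls$stability, geometry = cls$geometry,
                 re_osc = if (length(osc)) max(Re(eig[osc])) else NA_real_,
                 im_osc = if (length(osc)) max(abs(im[osc])) else NA_real_),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point> V = %.4f mV (%s %s), I_stim = %g\n",
              x$state[["V"]], x$stability, x$geometry, x$I_stim))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Find all fixed points at a stimulus current
#'
#' Fixed points have every gate at steady state, so the problem reduces to
#' the scalar equation `I_stim = iv_total(V)`, solved by bracketing sign
#' changes on a multi-start grid over `v_range` and polishing each with
#' [stats::uniroot()]. Eigenvalues come from [model_jacobian()].
#'
#' @param params an `ml_params` object
#' @param I_stim stimulus current (uA/cm2)
#' @param v_range voltage bracket searched (mV)
#' @param n_seeds number of multi-start grid intervals
#' @return list of `fixed_point` objects (possibly empty), ordered by V
#' @export
find_fixed_points <- function(params, I_stim = 0, v_range = c(-90, 40),
                              n_seeds = 27) {
  f <- function(V) I_stim - iv_total(params, V)
  Vg <- seq(v_range[1], v_range[2], length.out = n_seeds + 1)
  fg <- f(Vg)
  roots <- numeric(0)
  for (i in seq_len(n_seeds)) {
    if (!is.finite(fg[i]) || !is.finite(fg[i + 1])) next
    if (fg[i] == 0) roots <- c(roots, Vg[i])
    else if (sign(fg[i]) * sign(fg[i + 1]) < 0)
      roots <- c(roots, stats::uniroot(f, c(Vg[i], Vg[i + 1]),
                                       tol = 1e-12)$root)
  }
  if (length(fg) && fg[length(fg)] == 0) roots <- c(roots, Vg[length(fg)])
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-6)]  # dedupe to 1e-6 mV
  lapply(roots, function(V) .make_fp(params, V, I_stim))
}

#' Nullclines of a 2-D model on the (V, w) phase plane
#'
#' The V-nullcline is solved analytically for the recovery variable at each
#' grid voltage; the w-nullcline is the gate's steady-state curve.
#' Stimulation enters only the V-nullcline. Grid voltages at which the
#' algebraic solve degenerates (zero driving force on the slow current) are
#' skipped and reported in the `"skipped"` attribute.
#'
#' @param params an `ml2d` (or `ml2d_nainact_fast`) parameter set
#' @param I_stim stimulus current (uA/cm2)
#' @param V_grid voltage grid (mV)
#' @return list of two data.frames `v_nullcline` and `w_nullcline`, each
#'   with columns `V` and the gate value
#' @export
nullclines <- function(params, I_stim = 0, V_grid = seq(-80, 40, 0.25)) {
  p <- params
  gate <- model_gates(p)
  if (length(gate) != 1L)
    stop("nullclines() supports the 2-D variants only")
  minf <- x_inf(V_grid, p$gating$m)
  if (p$variant == "ml2d") {
    denom <- p$g_slow * (V_grid - p$E_K)
    num <- I_stim - p$g_fast * p$h_clamp * minf * (V_grid - p$E_Na) -
      p$g_adapt * p$z_clamp * (V_grid - p$E_K) -
      p$g_leak * (V_grid - p$E_leak)
  } else { # ml2d_nainact_fast: "w" axis is h multiplying I_fast
    denom <- p$g_fast * minf * (V_grid - p$E_Na)
    num <- I_stim - p$g_leak * (V_grid - p$E_leak)
  }
  ok <- abs(denom) > 1e-12
  vnull <- data.frame(V = V_grid[ok], gate = (num / denom)[ok])
  names(vnull)[2] <- gate
  wnull <- data.frame(V = V_grid, gate = x_inf(V_grid, p$gating[[gate]]))
  names(wnull)[2] <- gate
  out <- list(v_nullcline = vnull, w_nullcline = wnull)
  attr(out, "skipped") <- V_grid[!ok]
  out
}

# Apply a swept parameter value: "I_stim" is special (not a model field).
.sweep_apply <- function(params, param, value, I_stim) {
  if (param == "I_stim") list(params = params, I_stim = value)
  else list(params = set_param(params, param, value), I_stim = I_stim)
}

# Real part of the oscillatory eigenvalue pair, tracked by V-continuity;
# falls back to the largest real part if the pair collides and turns real
# (the sign still encodes the stability change being bisected).
.re_osc_at <- function(params, param, value, I_stim, v_near = NULL) {
  s <- .sweep_apply(params, param, value, I_stim)
  fps <- find_fixed_points(s$params, s$I_stim)
  if (!length(fps)) return(NA_real_)
  vs <- vapply(fps, function(f) f$state[["V"]], numeric(1))
  fp <- if (is.null(v_near)) {
    osc <- Filter(function(f) !is.na(f$re_osc), fps)
    if (!length(osc)) return(NA_real_)
    osc[[1]]
  } else fps[[which.min(abs(vs - v_near))]]
  if (is.na(fp$re_osc)) max(Re(fp$eigenvalues)) else fp$re_osc
}

# Bisection on .re_osc_at() (sign-robust: tolerates the pair turning real
# near the bracket edges, unlike a blind uniroot).
.bisect_re <- function(params, param, lo, hi, I_stim, v_near,
                       tol = 1e-10, max_iter = 80) {
  flo <- .re_osc_at(params, param, lo, I_stim, v_near)
  fhi <- .re_osc_at(params, param, hi, I_stim, v_near)
  if (is.na(flo) || is.na(fhi) || sign(flo) == sign(fhi))
    return((lo + hi) / 2)
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- .re_osc_at(params, param, mid, I_stim, v_near)
    if (is.na(fm)) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Limit-cycle branch by parameter continuation of forward simulations:
# inherit the end state between grid points, nudge V to leave unstable
# fixed points, discard a transient, then measure per-cycle extrema.
.lc_sweep <- function(params, param, grid, I_stim, dt = 0.05,
                      transient = 400, measure = 400, init = NULL,
                      amp_min = 0.5) {
  state <- init
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    s <- .sweep_apply(params, param, grid[i], I_stim)
    if (is.null(state)) {
      state <- tryCatch(settle(s$params, s$I_stim, t_max = 5000),
                        error = function(e) steady_state(s$params, -20))
    }
    state[["V"]] <- state[["V"]] + 0.5  # escape exact unstable equilibria
    tr <- simulate_model(s$params, stim_protocol(baseline = s$I_stim),
                         dt = dt, duration = transient + measure,
                         init = state, thin = 1L)
    state <- tr$y_end
    names(state) <- c("V", model_gates(s$params))
    keep <- tr$time >= transient
    V <- tr$V[keep]; tt <- tr$time[keep]
    amp <- diff(range(V))
    per <- NA_real_
    if (amp > amp_min) {
      mid <- (max(V) + min(V)) / 2
      up <- which(V[-length(V)] < mid & V[-1] >= mid)
      if (length(up) >= 3) per <- mean(diff(tt[up]))
    }
    rows[[i]] <- data.frame(param = grid[i], V_min = min(V), V_max = max(V),
                            amplitude = amp, period = per,
                            oscillating = amp > amp_min)
  }
  do.call(rbind, rows)
}

#' Bifurcation diagram along one swept parameter
#'
#' Fixed-point branches come from [find_fixed_points()] continuation along
#' the sweep grid; Hopf bifurcations are located where the real part of a
#' fixed point's complex eigenvalue pair changes sign between adjacent grid
#' points, then refined by root bisection in the swept parameter. The
#' limit-cycle branch is tracked by slow bidirectional parameter
#' continuation of forward simulations (up- and down-sweep, so that
#' hysteresis/bistability is visible); unstable limit cycles are not
#' traced. Saddle-node (fold) bifurcations of limit cycles are flagged
#' where a stable oscillation terminates or jumps discontinuously away
#' from a Hopf point.
#'
#' The grid must be fine enough that the tracked eigenvalue real part
#' changes sign at most once per interval.
#'
#' @param params an `ml_params` object
#' @param param swept parameter name (`"I_stim"`, or any [set_param()]
#'   name such as `"beta_w"`, `"z_clamp"`, `"h_clamp"`, `"g_fast"`)
#' @param range length-2 sweep range
#' @param n number of grid points
#' @param I_stim holding current used when `param != "I_stim"`
#' @param limit_cycle track the limit-cycle branch by simulation
#' @param lc_dt,lc_transient,lc_measure integration step and per-point
#'   transient/measurement windows (ms) for the limit-cycle sweeps
#' @return object of class `bifurcation_diagram`: `fixed_points`
#'   (data.frame), `limit_cycle` (data.frame with a `direction` column),
#'   `events` (list of detected bifurcations), plus the sweep metadata
#' @export
bifurcation_diagram <- function(params, param = "I_stim", range, n = 201,
                                I_stim = 0, limit_cycle = TRUE,
                                lc_dt = 0.05, lc_transient = 400,
                                lc_measure = 400) {
  grid <- seq(range[1], range[2], length.out = n)
  fp_rows <- list()
  fp_per_point <- vector("list", n)
  for (i in seq_along(grid)) {
    s <- .sweep_apply(params, param, grid[i], I_stim)
    fps <- find_fixed_points(s$params, s$I_stim)
    fp_per_point[[i]] <- fps
    if (length(fps))
      fp_rows[[i]] <- data.frame(
        param = grid[i],
        V = vapply(fps, function(f) f$state[["V"]], numeric(1)),
        stability = vapply(fps, function(f) f$stability, character(1)),
        geometry = vapply(fps, function(f) f$geometry, character(1)),
        re_osc = vapply(fps, function(f) f$re_osc, numeric(1)),
        im_osc = vapply(fps, function(f) f$im_osc, numeric(1)))
  }
  fp_df <- do.call(rbind, fp_rows)

  # Hopf events: sign change of re_osc along V-continuous branch pieces
  events <- list()
  for (i in seq_len(n - 1)) {
    a <- fp_per_point[[i]]; b <- fp_per_point[[i + 1]]
    for (fa in a) {
      if (is.na(fa$re_osc)) next
      vb <- vapply(b, function(f) f$state[["V"]], numeric(1))
      if (!length(vb)) next
      j <- which.min(abs(vb - fa$state[["V"]]))
      fb <- b[[j]]
      if (is.na(fb$re_osc) || abs(fb$state[["V"]] - fa$state[["V"]]) > 10)
        next
      if (sign(fa$re_osc) * sign(fb$re_osc) < 0) {
        root <- .bisect_re(params, param, grid[i], grid[i + 1], I_stim,
                           v_near = fa$state[["V"]])
        s <- .sweep_apply(params, param, root, I_stim)
        fps <- find_fixed_points(s$params, s$I_stim)
        vs <- vapply(fps, function(f) f$state[["V"]], numeric(1))
        fp <- fps[[which.min(abs(vs - fa$state[["V"]]))]]
        if (is.na(fp$im_osc) || fp$im_osc < 1e-6) next  # not oscillatory
        events[[length(events) + 1]] <-
          list(type = "hopf", param = root, state = fp$state,
               eigenvalues = fp$eigenvalues, im_osc = fp$im_osc)
      }
    }
  }

  lc <- NULL
  if (limit_cycle) {
    up <- .lc_sweep(params, param, grid, I_stim, dt = lc_dt,
                    transient = lc_transient, measure = lc_measure)
    dn <- .lc_sweep(params, param, rev(grid), I_stim, dt = lc_dt,
                    transient = lc_transient, measure = lc_measure)
    lc <- rbind(cbind(direction = "up", up), cbind(direction = "down", dn))
    hopf_params <- vapply(events, function(e) e$param, numeric(1))
    step <- if (n > 1) abs(diff(range)) / (n - 1) else 0
    for (dir in c("up", "down")) {
      br <- lc[lc$direction == dir, ]
      br <- br[order(br$param), ]
      osc <- br$oscillating
      # oscillation boundaries away from any Hopf -> fold of limit cycles
      tr_idx <- which(osc[-1] != osc[-length(osc)])
      for (k in tr_idx) {
        pmid <- (br$param[k] + br$param[k + 1]) / 2
        amp <- max(br$amplitude[k:(k + 1)])
        near_hopf <- length(hopf_params) &&
          any(abs(hopf_params - pmid) <= 1.5 * step)
        if (!near_hopf && amp > 20)
          events[[length(events) + 1]] <-
            list(type = "fold_of_limit_cycles", param = pmid,
                 direction = dir)
      }
      # discontinuous amplitude jump between oscillating neighbors
      both <- which(osc[-1] & osc[-length(osc)])
      for (k in both) {
        if (abs(br$amplitude[k + 1] - br$amplitude[k]) > 30)
          events[[length(events) + 1]] <-
            list(type = "fold_of_limit_cycles",
                 param = (br$param[k] + br$param[k + 1]) / 2,
                 direction = dir)
      }
    }
  }

  structure(list(param = param, grid = grid, I_stim = I_stim,
                 params = params, fixed_points = fp_df, limit_cycle = lc,
                 events = events),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("<bifurcation_diagram> sweep of %s over [%g, %g] (%d points)\n",
              x$param, min(x$grid), max(x$grid), length(x$grid)))
  if (!length(x$events)) cat("  no bifurcation events detected\n")
  for (e in x$events)
    cat(sprintf("  %s at %s = %.6g\n", e$type, x$param, e$param))
  invisible(x)
}

#' Classify a Hopf bifurcation as sub- or supercritical
#'
#' Uses simulation-based evidence from fine local parameter sweeps around
#' the event:
#'
#' 1. *Supercritical* if, departing from the (newly unstable) fixed point
#'    just past the Hopf, the limit-cycle amplitude grows continuously from
#'    zero -- operationally, the amplitude at the nearest probed point is
#'    small and squared amplitude is locally linear in the parameter with
#'    positive slope.
#' 2. Otherwise *subcritical* if the departure lands directly on a
#'    large-amplitude cycle and that cycle coexists with the stable fixed
#'    point on the pre-Hopf side (up/down-sweep disagreement, the bistable
#'    window).
#'
#' The order matters: a large spiking cycle can coexist with the stable
#' fixed point below a *super*critical Hopf as well (the fold of the large
#' cycle may lie below the Hopf), so bistability alone is not diagnostic.
#' If neither signature is found the result is `"indeterminate"` and the
#' collected diagnostics are attached.
#'
#' @param diagram a [bifurcation_diagram()]
#' @param event one element of `diagram$events` (type `"hopf"`)
#' @param delta local probe spacing in the swept parameter (default: half
#'   the diagram grid step, at most 0.1)
#' @param n_probe number of probe points past the Hopf
#' @return `"hopf_subcritical"`, `"hopf_supercritical"`, or
#'   `"indeterminate"` (with attribute `"diagnostics"`)
#' @export
classify_hopf <- function(diagram, event, delta = NULL, n_probe = 6) {
  stopifnot(inherits(diagram, "bifurcation_diagram"),
            identical(event$type, "hopf"))
  params <- diagram$params; param <- diagram$param
  I_stim <- diagram$I_stim; p0 <- event$param
  step <- abs(diff(diagram$grid[1:2]))
  if (is.null(delta)) delta <- min(step / 2, 0.1)
  v_fp <- event$state[["V"]]
  # which side of the Hopf is unstable?
  re_up <- .re_osc_at(params, param, p0 + 2 * delta, I_stim, v_near = v_fp)
  s_unst <- if (!is.na(re_up) && re_up > 0) 1 else -1

  # (1) creep from the fixed point into the unstable side
  probes <- p0 + s_unst * delta * seq_len(n_probe)
  start_p <- p0 - s_unst * 2 * delta
  s0 <- .sweep_apply(params, param, start_p, I_stim)
  fps0 <- find_fixed_points(s0$params, s0$I_stim)
  init <- NULL
  if (length(fps0)) {
    vs0 <- vapply(fps0, function(f) f$state[["V"]], numeric(1))
    init <- fps0[[which.min(abs(vs0 - v_fp))]]$state
  }
  up <- .lc_sweep(params, param, probes, I_stim, dt = 0.01,
                  transient = 800, measure = 400, init = init)
  amp <- up$amplitude
  diag <- list(probe_params = probes, creep_amplitudes = amp)
  grows_from_zero <- amp[1] < 30 && all(diff(amp) > -1)
  lin <- stats::lm(I(amp^2) ~ probes)
  slope_ok <- unname(stats::coef(lin)[2]) * s_unst > 0 &&
    summary(lin)$r.squared > 0.8
  if (grows_from_zero && slope_ok && max(amp) > 1) {
    out <- "hopf_supercritical"
    attr(out, "diagnostics") <- diag
    return(out)
  }

  # (2) bistability: carry the large cycle from the unstable side back
  #     across the Hopf into the stable side
  back <- p0 - s_unst * delta * seq_len(n_probe)
  kicked <- steady_state(params, -20)
  dn <- .lc_sweep(params, param, c(probes[2], back), I_stim, dt = 0.01,
                  transient = 800, measure = 400, init = kicked)
  diag$downsweep_amplitudes <- dn$amplitude[-1]
  if (amp[1] >= 30 && any(dn$amplitude[-1] > 40)) {
    out <- "hopf_subcritical"
    attr(out, "diagnostics") <- diag
    return(out)
  }
  out <- "indeterminate"
  attr(out, "diagnostics") <- diag
  out
}

#' Hopf bifurcation current of a model
#'
#' Convenience wrapper: locates the lowest-current Hopf bifurcation in
#' `i_range` from the fixed-point eigenvalues, refined by root bisection.
#' Returns `NA` if the tracked eigenvalue pair never destabilizes in range.
#'
#' @param params an `ml_params` object
#' @param i_range current range searched (uA/cm2)
#' @param n coarse grid size
#' @return list with `I_hopf`, fixed-point voltage `V_hopf`, and the
#'   eigenvalue pair's `im_osc` (rad/ms) at the event, or `NA`s
#' @export
hopf_point <- function(params, i_range = c(0, 200), n = 401) {
  grid <- seq(i_range[1], i_range[2], length.out = n)
  prev <- NULL; prev_v <- NULL; prev_i <- NULL
  for (i in seq_along(grid)) {
    fps <- find_fixed_points(params, grid[i])
    if (!length(fps)) next
    # track the lowest-V branch (the resting branch)
    fp <- fps[[1]]
    re <- if (is.na(fp$re_osc)) max(Re(fp$eigenvalues)) else fp$re_osc
    if (!is.null(prev) && sign(prev) * sign(re) < 0) {
      root <- .bisect_re(params, "I_stim", prev_i, grid[i], 0,
                         v_near = prev_v)
      fps2 <- find_fixed_points(params, root)
      vs <- vapply(fps2, function(f) f$state[["V"]], numeric(1))
      fp2 <- fps2[[which.min(abs(vs - prev_v))]]
      # only report oscillatory (Hopf) destabilizations, not saddle-nodes
      if (!is.na(fp2$im_osc) && fp2$im_osc > 1e-6)
        return(list(I_hopf = root, V_hopf = fp2$state[["V"]],
                    im_osc = fp2$im_osc, eigenvalues = fp2$eigenvalues))
    }
    prev <- re; prev_v <- fp$state[["V"]]; prev_i <- grid[i]
  }
  list(I_hopf = NA_real_, V_hopf = NA_real_, im_osc = NA_real_,
       eigenvalues = NULL)
}

#' Quasi-separatrix of a 2-D model
#'
#' Auto-seeds the quasi-separatrix (QS): bisects between spiking and
#' non-spiking initial conditions along a vertical transect through the
#' stable fixed point, follows the two near-boundary trajectories forward
#' until they diverge after clinging to the QS, and integrates backward in
#' time from the divergence locus. Requires a regime with a stable fixed
#' point and a spiking/non-spiking dichotomy (no Hopf at this current).
#'
#' @param params a 2-D `ml_params` object
#' @param I_stim stimulus current (uA/cm2)
#' @param v_span how far below the fixed point the transect reaches (mV)
#' @param back_duration backward integration time (ms)
#' @param eps transect bisection tolerance (mV)
#' @return list with `curve` (matrix V, gate), `seed` (divergence-locus
#'   state), `boundary_V` (transect crossing), and `gate` name
#' @export
quasi_separatrix <- function(params, I_stim = 0, v_span = 60,
                             back_duration = 60, eps = 1e-4) {
  gate <- model_gates(params)
  if (length(gate) != 1L) stop("quasi-separatrix is a phase-plane analysis ",
                               "(2-D variants only)")
  fps <- find_fixed_points(params, I_stim)
  stab <- Filter(function(f) f$stability == "stable", fps)
  if (!length(stab))
    stop("no stable fixed point at I_stim = ", I_stim,
         " (past the Hopf bifurcation?); no QS regime here")
  fp <- stab[[1]]
  w0 <- fp$state[[gate]]
  v0 <- fp$state[["V"]]
  spikes_from <- function(V0) {
    st <- c(V = V0, g = w0); names(st) <- c("V", gate)
    tr <- simulate_model(params, stim_protocol(baseline = I_stim),
                         dt = 0.01, duration = 100, init = st, thin = 5L)
    max(tr$V) > 5
  }
  # transect: depolarize along V from the fixed point at fixed gate value
  v_top <- min(v0 + v_span, -10)
  while (v_top < -5 && !spikes_from(v_top)) v_top <- v_top + 5
  if (!spikes_from(v_top) || spikes_from(v0 + eps))
    stop("no spiking/non-spiking dichotomy along the transect at I_stim = ",
         I_stim, "; no quasi-separatrix found at these settings")
  lo <- v0; hi <- v_top           # lo: no spike, hi: spike
  while (hi - lo > eps) {
    mid <- (lo + hi) / 2
    if (spikes_from(mid)) hi <- mid else lo <- mid
  }
  vb <- (lo + hi) / 2
  # forward pair straddling the QS: both cling to it, then diverge; the
  # divergence locus marks the end of the QS and seeds the backward trace
  run <- function(V0) {
    st <- c(V = V0, g = w0); names(st) <- c("V", gate)
    simulate_model(params, stim_protocol(baseline = I_stim), dt = 0.01,
                   duration = 100, init = st, thin = 1L)
  }
  ta <- run(lo); tb <- run(hi)
  dv <- abs(ta$V - tb$V)
  idx <- which(dv > min(10, max(dv) / 2))   # graded responses: adapt
  i_div <- if (length(idx)) idx[1] else which.max(dv)
  # seed on the spiking member just as it pulls away: backward flow first
  # contracts onto the (backward-attracting) QS, then slides along it
  sp_traj <- if (max(ta$V) > max(tb$V)) ta else tb
  seed <- c(V = sp_traj$V[i_div], g = sp_traj$gates[i_div, 1])
  names(seed) <- c("V", gate)
  curve <- integrate_backward(params, I_stim, seed, back_duration,
                              dt = 0.005, thin = 4L)
  list(curve = curve, seed = seed, boundary_V = vb, gate = gate,
       fixed_point = fp)
}

#' Gate value of the quasi-separatrix at given voltages
#'
#' Linear interpolation of the QS curve, for testing which side of the QS
#' a phase-plane point lies on.
#'
#' @param qs result of [quasi_separatrix()]
#' @param V voltages (mV)
#' @return interpolated gate values (NA outside the traced range)
#' @export
qs_gate_at <- function(qs, V) {
  cur <- qs$curve
  stats::approx(cur[, "V"], cur[, 2], xout = V, ties = mean)$y
}

#' Write bifurcation-diagram branches to CSV (+ JSON event list)
#'
#' @param diagram a [bifurcation_diagram()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_diagram <- function(diagram, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(diagram$fixed_points,
                   file.path(dir, "fixed_points.csv"), row.names = FALSE)
  if (!is.null(diagram$limit_cycle))
    utils::write.csv(diagram$limit_cycle,
                     file.path(dir, "limit_cycle.csv"), row.names = FALSE)
  ev <- lapply(diagram$events, function(e) {
    e$state <- if (!is.null(e$state)) as.list(e$state)
    e$eigenvalues <- if (!is.null(e$eigenvalues))
      list(re = Re(e$eigenvalues), im = Im(e$eigenvalues))
    e
  })
  jsonlite::write_json(list(param = diagram$param, events = ev),
                       file.path(dir, "events.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
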