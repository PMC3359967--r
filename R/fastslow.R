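#' Fast subsystem of the adaptation model
#'
#' Freezes the slow AHP activation `z` as a clamped parameter, turning the
#' 3-D adaptation model into a 2-D model whose bifurcation structure in
#' `z` underlies elliptic bursting.
#'
#' @param params an `ml3d_ahp` parameter set
#' @param z clamped adaptation level in \[0, 1\]
#' @return an `ml2d` parameter set with `z_clamp = z`
#' @export
fast_subsystem <- function(params, z = 0) {
  stopifnot(params$variant == "ml3d_ahp")
  w <- params$gating$w
  ml_params("ml2d", beta_w = w$beta, C = params$C,
            g_fast = params$g_fast, g_slow = params$g_slow,
            g_leak = params$g_leak, g_adapt = params$g_adapt,
            E_Na = params$E_Na, E_K = params$E_K, E_leak = params$E_leak,
            beta_m = params$gating$m$beta, gamma_m = params$gating$m$gamma,
            gamma_w = w$gamma, phi_w = w$phi, z_clamp = z)
}

#' Fast-slow dissection of the adaptation (elliptic bursting) model
#'
#' Treats the AHP activation `z` as the bifurcation parameter of the fast
#' `(V, w)` subsystem at a fixed stimulus current and predicts the response
#' regime:
#'
#' * The z-swept [bifurcation_diagram()] gives the fast subsystem's
#'   fixed-point branch and its Hopf point, plus the stable limit-cycle
#'   branch tracked by continuation (the up-in-z sweep starting from the
#'   spiking state at `z = 0`).
#' * The z-nullcline is the locus `z = z_inf(V)`, drawn as
#'   `V = z_inf^{-1}(z)`.
#' * `V_equivalent(z)`: simulate the fast subsystem on its limit cycle at
#'   clamped `z`, average `z_inf(V(t))` over complete cycles, and map the
#'   average back through `z_inf^{-1}` -- the constant voltage that would
#'   drive the same mean adaptation.
#'
#' Prediction: *quiescent* if the z-nullcline intersects the stable
#' fixed-point branch (`z_inf(V_fp(z)) = z` for some stable z); otherwise
#' the slow flow on the spiking branch is `dz/dt sign = zbar(z) - z` where
#' `zbar = z_inf^{-1}(V_equivalent)` average: *tonic* if that flow has a
#' stable zero inside the stable limit-cycle branch (the z-nullcline
#' intersects the stable part of V_equivalent); *bursting* if the flow is
#' still positive when the branch ends (the would-be equilibrium lies on
#' the unattainable part of V_equivalent past the fold, so `z` repeatedly
#' overshoots the branch end and falls back -- hysteresis).
#'
#' @param params an `ml3d_ahp` parameter set
#' @param I_stim stimulus current (uA/cm2)
#' @param z_range swept range of the adaptation variable
#' @param n grid resolution in z
#' @return object of class `fast_slow_result`: the z-swept `diagram`,
#'   `z_nullcline` and `v_equivalent` data.frames, `regime`
#'   (`"bursting"`, `"tonic"` or `"quiescent"`), `z_burst_on` (fast
#'   subsystem Hopf z), `z_burst_off` (end of the stable limit-cycle
#'   branch), and `z_tonic` (stable zero of the slow flow, if any)
#' @export
fast_slow_analysis <- function(params, I_stim, z_range = c(0, 0.3),
                               n = 121) {
  stopifnot(params$variant == "ml3d_ahp")
  fast <- fast_subsystem(params, 0)
  zspec <- params$gating$z
  grid <- seq(z_range[1], z_range[2], length.out = n)

  dg <- bifurcation_diagram(fast, param = "z_clamp", range = z_range,
                            n = n, I_stim = I_stim, limit_cycle = FALSE)
  hopf <- Filter(function(e) e$type == "hopf", dg$events)
  z_hopf <- if (length(hopf)) hopf[[1]]$param else NA_real_

  # stable limit-cycle branch: ride the spiking cycle up in z from z = 0
  kick <- steady_state(fast, -20)
  lc <- .lc_sweep(fast, "z_clamp", grid, I_stim, dt = 0.01,
                  transient = 300, measure = 300, init = kick,
                  amp_min = 40)
  dg$limit_cycle <- cbind(direction = "up", lc)
  osc <- lc$oscillating
  if (!any(osc))
    stop("fast subsystem never spikes over this z range at I_stim = ",
         I_stim, "; nothing for the z-nullcline to intersect")
  z_off <- max(lc$param[osc])

  # z-nullcline as V(z) through the analytic Boltzmann inverse
  zinv <- function(z) zspec$beta + zspec$gamma * atanh(pmin(pmax(
    2 * z - 1, -1 + 1e-12), 1 - 1e-12))
  z_null <- data.frame(z = grid, V = zinv(grid))

  # V_equivalent on the stable limit-cycle branch
  zg <- grid[osc]
  veq_rows <- lapply(zg, function(z) {
    f <- fast_subsystem(params, z)
    tr <- simulate_model(f, stim_protocol(baseline = I_stim), dt = 0.01,
                         duration = 700, init = steady_state(f, -20),
                         thin = 1L)
    keep <- tr$time >= 300
    V <- tr$V[keep]
    mid <- (max(V) + min(V)) / 2
    up <- which(V[-length(V)] < mid & V[-1] >= mid)
    if (length(up) < 2) return(NULL)           # not on a cycle here
    V <- V[up[1]:up[length(up)]]               # whole cycles only
    zbar <- mean(x_inf(V, zspec))
    data.frame(z = z, zbar = zbar, V_equivalent = zinv(zbar))
  })
  veq <- do.call(rbind, veq_rows)
  if (is.null(veq) || nrow(veq) < 2)
    stop("could not measure the limit cycle of the fast subsystem")
  # slow flow on the spiking branch: dz/dt has the sign of zbar - z
  flow <- veq$zbar - veq$z

  # quiescent? z-nullcline meeting the stable fixed-point branch
  fp <- dg$fixed_points
  fp_stable <- fp[fp$stability == "stable", ]
  quiescent <- FALSE
  if (nrow(fp_stable) > 1) {
    gap <- x_inf(fp_stable$V, zspec) - fp_stable$param
    quiescent <- any(gap[-1] * gap[-length(gap)] <= 0)
  }

  z_tonic <- NA_real_
  regime <- if (quiescent) "quiescent" else {
    cross <- which(flow[-1] <= 0 & flow[-length(flow)] > 0)
    if (length(cross)) {
      k <- cross[1]
      z_tonic <- stats::approx(flow[k:(k + 1)], veq$z[k:(k + 1)],
                               xout = 0)$y
      "tonic"
    } else if (all(flow > 0)) "bursting" else "tonic"
  }

  structure(list(diagram = dg, z_nullcline = z_null, v_equivalent = veq,
                 regime = regime, z_burst_on = z_hopf, z_burst_off = z_off,
                 z_tonic = z_tonic, I_stim = I_stim, flow = flow),
            class = "fast_slow_result")
}

#' @export
print.fast_slow_result <- function(x, ...) {
  cat(sprintf("<fast_slow_result> I_stim = %g: predicted regime '%s'\n",
              x$I_stim, x$regime))
  cat(sprintf("  fast-subsystem Hopf (burst onset) z = %.4f; ", x$z_burst_on))
  cat(sprintf("stable cycle ends (burst offset) z = %.4f\n", x$z_burst_off))
  if (!is.na(x$z_tonic))
    cat(sprintf("  slow flow stabilizes at z = %.4f (tonic)\n", x$z_tonic))
  invisible(x)
}
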