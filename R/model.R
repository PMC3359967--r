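#' Construct a state vector
#'
#' @param params an `ml_params` object
#' @param V membrane potential (mV)
#' @param ... gate values by name (all gates of the variant required)
#' @return named numeric state vector `c(V, <gates>)`
#' @export
model_state <- function(params, V, ...) {
  gates <- c(...)
  need <- model_gates(params)
  if (!setequal(names(gates), need))
    stop("invalid state: variant ", params$variant, " needs gates ",
         paste(need, collapse = ", "))
  if (any(gates < 0 | gates > 1)) stop("invalid state: gates must be in [0,1]")
  c(V = unname(V), gates[need])
}

#' State with all gates at steady state for a given voltage
#'
#' @param params an `ml_params` object
#' @param V membrane potential (mV)
#' @return named state vector
#' @export
steady_state <- function(params, V) {
  gates <- vapply(model_gates(params),
                  function(g) x_inf(V, params$gating[[g]]), numeric(1))
  c(V = unname(V), gates)
}

.check_state <- function(state, params) {
  need <- c("V", model_gates(params))
  if (!all(need %in% names(state)))
    stop("invalid state for variant ", params$variant, ": need ",
         paste(need, collapse = ", "))
  state[need]
}

#' Ionic membrane currents at a given state
#'
#' Decomposes the total ionic current (uA/cm2) into its named components.
#' Sign convention: positive = outward; the voltage equation is
#' `C dV/dt = I_stim - sum(ionic_currents)`.
#'
#' @param state named state vector (see [model_state()])
#' @param params an `ml_params` object
#' @return named numeric vector of currents (uA/cm2)
#' @export
ionic_currents <- function(state, params) {
  state <- .check_state(state, params)
  V <- state[["V"]]
  p <- params
  minf <- x_inf(V, p$gating$m)
  out <- switch(p$variant,
    ml2d = {
      cur <- c(I_fast = p$g_fast * p$h_clamp * minf * (V - p$E_Na),
               I_slow = p$g_slow * state[["w"]] * (V - p$E_K),
               I_leak = p$g_leak * (V - p$E_leak))
      if (p$g_adapt > 0)
        cur <- c(cur, I_AHP = p$g_adapt * p$z_clamp * (V - p$E_K))
      cur
    },
    ml2d_nainact_fast = c(
      I_fast = p$g_fast * minf * state[["h"]] * (V - p$E_Na),
      I_leak = p$g_leak * (V - p$E_leak)),
    ml3d_nainact_slow = c(
      I_fast = p$g_fast * minf * state[["h"]] * (V - p$E_Na),
      I_slow = p$g_slow * state[["w"]] * (V - p$E_K),
      I_leak = p$g_leak * (V - p$E_leak)),
    ml3d_ahp = c(
      I_fast = p$g_fast * minf * (V - p$E_Na),
      I_slow = p$g_slow * state[["w"]] * (V - p$E_K),
      I_AHP = p$g_adapt * state[["z"]] * (V - p$E_K),
      I_leak = p$g_leak * (V - p$E_leak)),
    ml3d_ungrouped = c(
      I_fast = p$g_fast * minf * (V - p$E_Na),
      I_Kdr = p$g_kdr * state[["ws"]] * (V - p$E_K),
      I_sub = p$g_sub * state[["y"]] * (V - p$E_sub),
      I_leak = p$g_leak * (V - p$E_leak)))
  out
}

#' Right-hand side of the model ODEs
#'
#' `dV/dt = (I_stim - sum(ionic currents)) / C`; each dynamic gate follows
#' `dx/dt = (x_inf(V) - x) / tau(V)` with `tau` either the voltage-dependent
#' [tau_gate()] form or the gate's fixed time constant. Pure R reference
#' implementation; the compiled integrator evaluates the identical
#' expressions (cross-checked in the test suite).
#'
#' @param state named state vector
#' @param params an `ml_params` object
#' @param I_stim injected current (uA/cm2)
#' @return named vector of time derivatives (mV/ms and 1/ms)
#' @export
model_rhs <- function(state, params, I_stim = 0) {
  state <- .check_state(state, params)
  V <- state[["V"]]
  dV <- (I_stim - sum(ionic_currents(state, params))) / params$C
  d <- c(V = dV)
  for (g in model_gates(params)) {
    spec <- params$gating[[g]]
    tau <- if (!is.null(spec$tau_fixed)) spec$tau_fixed else tau_gate(V, spec)
    d[g] <- (x_inf(V, spec) - state[[g]]) / tau
  }
  d
}

#' Steady-state current-voltage curves
#'
#' Evaluates selected ionic currents with every gate at its steady state
#' (`w = w_inf(V)`, etc.) on a voltage grid, as used for the steady-state
#' I-V analysis of the slow/subthreshold currents.
#'
#' @param params an `ml_params` object
#' @param V_grid sorted voltage grid (mV)
#' @param components current names to keep (default: all, plus their sum as
#'   `I_total`)
#' @return data.frame with column `V` and one column per current
#' @export
steady_state_iv <- function(params, V_grid, components = NULL) {
  stopifnot(!is.unsorted(V_grid))
  rows <- t(vapply(V_grid, function(V)
    ionic_currents(steady_state(params, V), params),
    ionic_currents(steady_state(params, V_grid[1]), params)))
  avail <- colnames(rows)
  if (is.null(components)) components <- avail
  if (!all(components %in% avail))
    stop("unknown current component(s): ",
         paste(setdiff(components, avail), collapse = ", "),
         " (available: ", paste(avail, collapse = ", "), ")")
  out <- data.frame(V = V_grid, rows[, components, drop = FALSE])
  out$I_total <- rowSums(rows)
  out
}

#' Total steady-state ionic current (the fixed-point equation)
#'
#' Fixed points satisfy `I_stim = iv_total(V)`.
#'
#' @param params an `ml_params` object
#' @param V voltage (mV), vectorized
#' @return total ionic current at steady state (uA/cm2)
#' @export
iv_total <- function(params, V) {
  vapply(V, function(v) sum(ionic_currents(steady_state(params, v), params)),
         numeric(1))
}

#' Calibrate the ungrouped model's subthreshold current
#'
#' Fits `(g_sub, beta_y, gamma_y)` by least squares so that the steady-state
#' `(I_Kdr + I_sub)-V` curve of the ungrouped model reproduces the shift of
#' the 2-D model's `I_slow`-V curve when `beta_w` moves from -21 mV
#' (normal) to -13 mV (neuropathic):
#'
#' * `direction = "inward"`: I_Kdr keeps the normal position
#'   (`beta_ws = -21`) and an inward current (`E_sub = E_Na`) is added until
#'   the summed curve matches the neuropathic `I_slow`-V curve.
#' * `direction = "outward"`: I_Kdr takes the neuropathic position
#'   (`beta_ws = -13`) and an outward current (`E_sub = E_K`) is added until
#'   the summed curve matches the normal `I_slow`-V curve (so that removing
#'   it recovers the neuropathic state).
#'
#' The fitted values are shipped as the packaged defaults of the
#' `"ungrouped-inward"` / `"ungrouped-outward"` presets.
#'
#' @param direction `"inward"` or `"outward"`
#' @param V_range fitting window (mV)
#' @param n number of grid points
#' @return list with `g_sub`, `beta_y`, `gamma_y`, the achieved root mean
#'   squared residual (`rms`, uA/cm2) and the fitting grid
#' @export
calibrate_isub <- function(direction = c("inward", "outward"),
                           V_range = c(-70, -20), n = 101) {
  direction <- match.arg(direction)
  V <- seq(V_range[1], V_range[2], length.out = n)
  w21 <- 0.5 * (1 + tanh((V + 21) / 10))
  w13 <- 0.5 * (1 + tanh((V + 13) / 10))
  if (direction == "inward") {
    target <- 20 * w13 * (V + 100)   # neuropathic I_slow
    base <- 20 * w21 * (V + 100)     # I_Kdr at the normal position
    E_sub <- 50
  } else {
    target <- 20 * w21 * (V + 100)   # normal I_slow
    base <- 20 * w13 * (V + 100)     # I_Kdr at the neuropathic position
    E_sub <- -100
  }
  resid <- function(th) {
    y <- 0.5 * (1 + tanh((V - th[2]) / th[3]))
    base + exp(th[1]) * y * (V - E_sub) - target
  }
  obj <- function(th) sum(resid(th)^2)
  fit <- stats::optim(c(log(1), -35, 10), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(g_sub = exp(fit$par[1]), beta_y = fit$par[2], gamma_y = fit$par[3],
       rms = sqrt(fit$value / n), V_grid = V)
}
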