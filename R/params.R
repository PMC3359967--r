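#' Gating-variable specification
#'
#' Describes one Boltzmann-gated variable: its half-activation voltage
#' `beta`, slope factor `gamma` (positive for activation, negative for
#' inactivation), and either a dimensionless rate scale `phi` (for gates
#' whose time constant is the voltage-dependent `1 / (phi * cosh(...))`
#' form) or a fixed time constant `tau_fixed` in ms. Exactly one of
#' `phi` / `tau_fixed` must be given for a dynamic gate; both may be absent
#' for an instantaneous gate (`m`).
#'
#' @param beta half-activation voltage (mV)
#' @param gamma slope factor (mV), nonzero
#' @param phi rate scale (dimensionless, > 0) or `NULL`
#' @param tau_fixed constant time constant (ms, > 0) or `NULL`
#' @return an object of class `gating_spec`
#' @examples
#' gating_spec(beta = -1.2, gamma = 18)             # instantaneous m
#' gating_spec(beta = -13, gamma = 10, phi = 0.15)  # recovery gate w
#' @export
gating_spec <- function(beta, gamma, phi = NULL, tau_fixed = NULL) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma == 0) stop("invalid gating parameters: gamma must be nonzero")
  if (!is.null(phi) && !is.null(tau_fixed))
    stop("a gate is governed by either phi or tau_fixed, not both")
  if (!is.null(phi) && (!is.finite(phi) || phi <= 0))
    stop("invalid gating parameters: phi must be > 0")
  if (!is.null(tau_fixed) && (!is.finite(tau_fixed) || tau_fixed <= 0))
    stop("invalid gating parameters: tau_fixed must be > 0")
  structure(list(beta = beta, gamma = gamma, phi = phi,
                 tau_fixed = tau_fixed),
            class = "gating_spec")
}

#' @export
print.gating_spec <- function(x, ...) {
  tau <- if (!is.null(x$tau_fixed)) sprintf("tau = %g ms", x$tau_fixed)
         else if (!is.null(x$phi)) sprintf("phi = %g", x$phi)
         else "instantaneous"
  cat(sprintf("<gating_spec> beta = %g mV, gamma = %g mV, %s\n",
              x$beta, x$gamma, tau))
  invisible(x)
}

.VARIANTS <- c("ml2d", "ml2d_nainact_fast", "ml3d_nainact_slow",
               "ml3d_ahp", "ml3d_ungrouped")

#' Gate names carried as state variables by a model variant
#'
#' The instantaneous activation `m` is never part of the state.
#'
#' @param params an `ml_params` object (or variant string)
#' @return character vector of gate names
#' @export
model_gates <- function(params) {
  variant <- if (is.character(params)) params else params$variant
  switch(variant,
         ml2d = "w",
         ml2d_nainact_fast = "h",
         ml3d_nainact_slow = c("w", "h"),
         ml3d_ahp = c("w", "z"),
         ml3d_ungrouped = c("ws", "y"),
         stop("unknown variant: ", variant))
}

#' Construct a model parameter set
#'
#' Builds the full parameter set for one of the five model variants. All
#' defaults are the standard values of the 2-D model (C = 2 uF/cm2,
#' E_Na = 50, E_K = -100, E_leak = -70 mV, g_fast = g_slow = 20,
#' g_leak = 2 mS/cm2, beta_m = -1.2, gamma_m = 18, gamma_w = 10 mV,
#' phi_w = 0.15); `beta_w` has no default because it is the parameter the
#' normal/neuropathic distinction rests on. Variant-specific gates:
#'
#' * `ml2d`: recovery gate `w`; optionally a clamped sodium-inactivation
#'   factor `h_clamp` multiplying the fast current and a clamped adaptation
#'   level `z_clamp` (with `g_adapt`) adding a constant-activation AHP
#'   current -- used for bifurcation analysis with a frozen slow variable.
#' * `ml2d_nainact_fast`: fast positive feedback plus sodium-channel
#'   inactivation `h` as the slow negative feedback (no recovery gate).
#' * `ml3d_nainact_slow`: 2-D model plus slow cumulative sodium
#'   inactivation `h` with a fixed 2000-ms time constant.
#' * `ml3d_ahp`: 2-D model plus AHP-current activation `z` with a fixed
#'   300-ms time constant.
#' * `ml3d_ungrouped`: the slow current split into a delayed-rectifier
#'   K+ current (gate `ws`) and a subthreshold current `I_sub` (gate `y`)
#'   with reversal `E_sub`.
#'
#' @param variant one of `"ml2d"`, `"ml2d_nainact_fast"`,
#'   `"ml3d_nainact_slow"`, `"ml3d_ahp"`, `"ml3d_ungrouped"`
#' @param beta_w half-activation of the recovery gate (mV); required by
#'   variants that carry `w`
#' @param C membrane capacitance (uF/cm2)
#' @param g_fast,g_slow,g_leak,g_adapt,g_kdr,g_sub maximal conductances
#'   (mS/cm2); only those the variant uses are kept
#' @param E_Na,E_K,E_leak,E_sub reversal potentials (mV)
#' @param beta_m,gamma_m instantaneous activation gate parameters (mV)
#' @param gamma_w,phi_w recovery gate slope (mV) and rate scale
#' @param beta_h,gamma_h,tau_h,phi_h sodium-inactivation gate parameters;
#'   `tau_h` (ms) for the slow-inactivation variant, `phi_h` for the fast
#'   one
#' @param beta_z,gamma_z,tau_z adaptation gate parameters
#' @param beta_ws,gamma_ws,phi_ws delayed-rectifier gate parameters
#' @param beta_y,gamma_y,phi_y subthreshold-current gate parameters
#' @param h_clamp,z_clamp clamped values treated as parameters (`ml2d`
#'   only); `h_clamp = 1` means no inactivation
#' @return an object of class `ml_params`
#' @examples
#' ml_params("ml2d", beta_w = -21)   # the "normal" model
#' ml_preset("neuropathic")          # same as ml_params("ml2d", beta_w = -13)
#' @export
ml_params <- function(variant = "ml2d", beta_w = NULL,
                      C = 2, g_fast = 20, g_slow = 20, g_leak = 2,
                      g_adapt = 0, g_kdr = 20, g_sub = 0,
                      E_Na = 50, E_K = -100, E_leak = -70, E_sub = 50,
                      beta_m = -1.2, gamma_m = 18,
                      gamma_w = 10, phi_w = 0.15,
                      beta_h = -30, gamma_h = -5, tau_h = 2000, phi_h = 0.15,
                      beta_z = 0, gamma_z = 4, tau_z = 300,
                      beta_ws = -21, gamma_ws = 10, phi_ws = 0.15,
                      beta_y = 0, gamma_y = 4, phi_y = 0.3,
                      h_clamp = 1, z_clamp = 0) {
  variant <- match.arg(variant, .VARIANTS)
  for (g in c(C, g_fast, g_slow, g_leak, g_adapt, g_kdr, g_sub))
    if (!is.finite(g) || g < 0) stop("capacitance and conductances must be >= 0")
  if (C <= 0) stop("capacitance must be > 0")
  gating <- list(m = gating_spec(beta_m, gamma_m))
  needs_w <- variant %in% c("ml2d", "ml3d_nainact_slow", "ml3d_ahp")
  if (needs_w) {
    if (is.null(beta_w)) stop("beta_w is required for variant ", variant)
    gating$w <- gating_spec(beta_w, gamma_w, phi = phi_w)
  }
  if (variant == "ml2d_nainact_fast")
    gating$h <- gating_spec(beta_h, gamma_h, phi = phi_h)
  if (variant == "ml3d_nainact_slow")
    gating$h <- gating_spec(beta_h, gamma_h, tau_fixed = tau_h)
  if (variant == "ml3d_ahp") {
    gating$z <- gating_spec(beta_z, gamma_z, tau_fixed = tau_z)
    if (g_adapt <= 0) g_adapt <- 0.5
  }
  if (variant == "ml3d_ungrouped") {
    gating$ws <- gating_spec(beta_ws, gamma_ws, phi = phi_ws)
    gating$y <- gating_spec(beta_y, gamma_y, phi = phi_y)
  }
  p <- list(variant = variant, C = C,
            g_fast = g_fast, g_slow = g_slow, g_leak = g_leak,
            g_adapt = g_adapt, g_kdr = g_kdr, g_sub = g_sub,
            E_Na = E_Na, E_K = E_K, E_leak = E_leak, E_sub = E_sub,
            gating = gating,
            h_clamp = h_clamp, z_clamp = z_clamp)
  if (variant != "ml2d") { p$h_clamp <- NULL; p$z_clamp <- NULL }
  structure(p, class = "ml_params")
}

#' @export
print.ml_params <- function(x, ...) {
  cat(sprintf("<ml_params> variant %s; gates: %s\n", x$variant,
              paste(model_gates(x), collapse = ", ")))
  gs <- vapply(c("g_fast", "g_slow", "g_leak", "g_adapt", "g_kdr", "g_sub"),
               function(n) x[[n]], numeric(1))
  cat("  conductances (mS/cm2): ",
      paste(sprintf("%s=%g", names(gs), gs), collapse = " "), "\n", sep = "")
  for (g in names(x$gating)) {
    s <- x$gating[[g]]
    tau <- if (!is.null(s$tau_fixed)) sprintf("tau=%g ms", s$tau_fixed)
           else if (!is.null(s$phi)) sprintf("phi=%g", s$phi) else "instant"
    cat(sprintf("  %-2s: beta=%g gamma=%g (%s)\n", g, s$beta, s$gamma, tau))
  }
  invisible(x)
}

# Fitted subthreshold-current parameters for the ungrouped variant (see
# calibrate_isub(); values reproduce the 2-D beta_w -21 -> -13 shift of the
# steady-state I-V curve over V in [-70, -20] mV).
.UNGROUPED_DEFAULTS <- list(
  inward  = list(g_sub = 12.8028, beta_y = -22.3616, gamma_y = 8.80769),
  outward = list(g_sub = 10.1737, beta_y = -23.9656, gamma_y = 9.42099)
)

#' Named model presets
#'
#' Registry of the parameter sets used throughout the package:
#'
#' * `"normal"`: 2-D model, `beta_w = -21` mV (onset-only spiking).
#' * `"neuropathic"`: 2-D model, `beta_w = -13` mV (repetitive spiking via a
#'   subcritical Hopf bifurcation).
#' * `"supercritical"`: 2-D model, `beta_w = -19` mV (supercritical Hopf
#'   with a stable subthreshold limit cycle).
#' * `"nainact-slow"`: neuropathic model plus slow cumulative sodium
#'   inactivation (`gamma_m = 15`, `beta_h = -30`, `gamma_h = -5`,
#'   `tau_h = 2000` ms; half-inactivation at perithreshold voltage, so
#'   sustained depolarization accumulates inactivation).
#' * `"ahp"`: neuropathic model plus adaptation (`g_adapt = 0.5`,
#'   `beta_z = 0`, `gamma_z = 4`, `tau_z = 300` ms) -- the elliptic burster.
#' * `"s2-normal"` / `"s2-neuropathic"`: the 2-D variant whose slow negative
#'   feedback is fast sodium inactivation rather than potassium activation
#'   (`beta_m = -5`, `gamma_m = 15`, `gamma_h = -8`; `beta_h = -30` normal,
#'   `-27` neuropathic).
#' * `"ungrouped-inward"`: slow current split into I_Kdr (`beta_ws = -21`)
#'   plus a calibrated *inward* subthreshold current -- behaves like the
#'   neuropathic 2-D model.
#' * `"ungrouped-outward"`: I_Kdr at `beta_ws = -13` plus a calibrated
#'   *outward* subthreshold current -- behaves like the normal 2-D model
#'   (reducing `g_sub` to 0 recovers the neuropathic state).
#' * `"suprathreshold"`: I_Kdr at `beta_ws = -13` plus a current activating
#'   only at suprathreshold voltages (`beta_y = 0` mV); spike shape changes
#'   but spike initiation does not.
#'
#' @param name preset name
#' @param ... overrides passed on to [ml_params()]
#' @return an `ml_params` object
#' @export
ml_preset <- function(name, ...) {
  name <- match.arg(name, c("normal", "neuropathic", "supercritical",
                            "nainact-slow", "ahp", "s2-normal",
                            "s2-neuropathic", "ungrouped-inward",
                            "ungrouped-outward", "suprathreshold"))
  over <- list(...)
  base <- switch(name,
    "normal"        = list(variant = "ml2d", beta_w = -21),
    "neuropathic"   = list(variant = "ml2d", beta_w = -13),
    "supercritical" = list(variant = "ml2d", beta_w = -19),
    "nainact-slow"  = list(variant = "ml3d_nainact_slow", beta_w = -13,
                           gamma_m = 15, beta_h = -30, gamma_h = -5,
                           tau_h = 2000),
    "ahp"           = list(variant = "ml3d_ahp", beta_w = -13,
                           g_adapt = 0.5, beta_z = 0, gamma_z = 4,
                           tau_z = 300),
    "s2-normal"     = list(variant = "ml2d_nainact_fast", beta_m = -5,
                           gamma_m = 15, beta_h = -30, gamma_h = -8,
                           phi_h = 0.8),
    "s2-neuropathic" = list(variant = "ml2d_nainact_fast", beta_m = -5,
                           gamma_m = 15, beta_h = -27, gamma_h = -8,
                           phi_h = 0.8),
    "ungrouped-inward" = c(list(variant = "ml3d_ungrouped", beta_ws = -21,
                                E_sub = 50, phi_y = 0.3),
                           .UNGROUPED_DEFAULTS$inward),
    "ungrouped-outward" = c(list(variant = "ml3d_ungrouped", beta_ws = -13,
                                 E_sub = -100, phi_y = 0.15),
                            .UNGROUPED_DEFAULTS$outward),
    "suprathreshold" = list(variant = "ml3d_ungrouped", beta_ws = -13,
                            E_sub = 50, phi_y = 0.3, g_sub = 2,
                            beta_y = 0, gamma_y = 4))
  base[names(over)] <- over
  do.call(ml_params, base)
}

# Flatten parameters to the fixed-layout vector the C++ core indexes.
.par_vec <- function(p) {
  g <- function(name, field, default = 0)
    if (!is.null(p$gating[[name]]) && !is.null(p$gating[[name]][[field]]))
      p$gating[[name]][[field]] else default
  c(p$C, p$g_fast, p$g_slow, p$g_leak, p$E_Na, p$E_K, p$E_leak,
    g("m", "beta"), g("m", "gamma", 1),
    g("w", "beta"), g("w", "gamma", 1), g("w", "phi", 1),
    g("h", "beta"), g("h", "gamma", 1), g("h", "tau_fixed", 1),
    g("h", "phi", 1),
    as.numeric(!is.null(p$gating$h) && !is.null(p$gating$h$tau_fixed)),
    g("z", "beta"), g("z", "gamma", 1), g("z", "tau_fixed", 1), p$g_adapt,
    p$g_kdr, g("ws", "beta"), g("ws", "gamma", 1), g("ws", "phi", 1),
    p$g_sub, p$E_sub, g("y", "beta"), g("y", "gamma", 1), g("y", "phi", 1),
    if (is.null(p$h_clamp)) 1 else p$h_clamp,
    if (is.null(p$z_clamp)) 0 else p$z_clamp)
}

.variant_code <- function(p) match(p$variant, .VARIANTS)

# Stable short fingerprint of a parameter set (trajectory metadata).
.fingerprint <- function(p) {
  v <- signif(.par_vec(p), 10)
  paste0(p$variant, "-", format(sum(v * seq_along(v)^2) %% 1e8, digits = 12))
}

#' Set a named parameter, including gating fields, by name
#'
#' Accepts plain fields (`"g_fast"`, `"C"`, `"h_clamp"`, ...) and gating
#' shorthands (`"beta_w"`, `"gamma_m"`, `"phi_y"`, `"tau_h"`, ...).
#'
#' @param params an `ml_params` object
#' @param name parameter name
#' @param value new numeric value
#' @return the modified `ml_params` object
#' @export
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "ml_params"), is.numeric(value),
            length(value) == 1L)
  m <- regmatches(name, regexec("^(beta|gamma|phi|tau)_([a-z]+s?)$", name))[[1]]
  if (length(m) == 3L && m[3] %in% names(params$gating)) {
    field <- c(beta = "beta", gamma = "gamma", phi = "phi",
               tau = "tau_fixed")[m[2]]
    spec <- params$gating[[m[3]]]
    spec[[field]] <- value
    params$gating[[m[3]]] <-
      gating_spec(spec$beta, spec$gamma, spec$phi, spec$tau_fixed)
  } else if (name %in% names(params) && is.numeric(params[[name]])) {
    params[[name]] <- value
  } else stop("unknown parameter: ", name)
  params
}

#' Retrieve a named parameter (complement of [set_param()])
#' @inheritParams set_param
#' @return numeric value
#' @export
get_param <- function(params, name) {
  m <- regmatches(name, regexec("^(beta|gamma|phi|tau)_([a-z]+s?)$", name))[[1]]
  if (length(m) == 3L && m[3] %in% names(params$gating)) {
    field <- c(beta = "beta", gamma = "gamma", phi = "phi",
               tau = "tau_fixed")[m[2]]
    return(params$gating[[m[3]]][[field]])
  }
  if (name %in% names(params)) return(params[[name]])
  stop("unknown parameter: ", name)
}

#' Write / read model parameters (JSON or YAML)
#'
#' The file format follows the extension: `.json` or `.yaml`/`.yml`.
#'
#' @param params an `ml_params` object
#' @param path file path
#' @return `read_params` returns an `ml_params` object; `write_params`
#'   returns `path` invisibly
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ml_params"))
  x <- unclass(params)
  x$gating <- lapply(x$gating, function(s)
    Filter(Negate(is.null), unclass(s)))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list(variant = x$variant)
  for (n in c("C", "g_fast", "g_slow", "g_leak", "g_adapt", "g_kdr", "g_sub",
              "E_Na", "E_K", "E_leak", "E_sub", "h_clamp", "z_clamp"))
    if (!is.null(x[[n]])) args[[n]] <- x[[n]]
  for (g in names(x$gating)) {
    s <- x$gating[[g]]
    args[[paste0("beta_", g)]] <- s$beta
    args[[paste0("gamma_", g)]] <- s$gamma
    if (!is.null(s$phi)) args[[paste0("phi_", g)]] <- s$phi
    if (!is.null(s$tau_fixed)) args[[paste0("tau_", g)]] <- s$tau_fixed
  }
  # beta_w is mandatory for w-carrying variants; gating loop supplies it
  do.call(ml_params, args)
}
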