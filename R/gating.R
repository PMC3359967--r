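#' Boltzmann steady-state activation
#'
#' `x_inf(V) = 0.5 * (1 + tanh((V - beta) / gamma))`: the steady-state value
#' of a gate at membrane potential `V`. Monotonically increasing in `V` for
#' `gamma > 0` (activation), decreasing for `gamma < 0` (inactivation).
#'
#' @param V membrane potential (mV), vectorized
#' @param spec a [gating_spec()]
#' @return gate steady state in (0, 1)
#' @examples
#' x_inf(-1.2, gating_spec(-1.2, 18))  # 0.5 at V = beta
#' @export
x_inf <- function(V, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  0.5 * (1 + tanh((V - spec$beta) / spec$gamma))
}

#' Voltage-dependent gate time constant
#'
#' `tau(V) = 1 / (phi * cosh((V - beta) / (2 * gamma)))` in ms: maximal
#' (`1 / phi`) at `V = beta` and symmetric about it. Only defined for gates
#' governed by a rate scale `phi`; calling it for a fixed-tau gate is an
#' error (use the gate's `tau_fixed` directly).
#'
#' @inheritParams x_inf
#' @return time constant (ms), vectorized over `V`
#' @examples
#' tau_gate(-13, gating_spec(-13, 10, phi = 0.15))  # = 1/0.15
#' @export
tau_gate <- function(V, spec) {
  stopifnot(inherits(spec, "gating_spec"))
  if (is.null(spec$phi))
    stop("tau_gate() called for a gate without a rate scale phi; ",
         "this gate has a fixed time constant")
  1 / (spec$phi * cosh((V - spec$beta) / (2 * spec$gamma)))
}
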