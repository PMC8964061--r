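#' Leaky integrate-and-fire neuron parameters
#'
#' Bundles the constants of the discrete-time LIF neuron shared by the hidden
#' (liquid) and readout populations: resting, reset and threshold potentials,
#' membrane time constant, simulation resolution, and an input gain that
#' scales synaptic current into membrane potential units.
#'
#' The membrane decays geometrically with factor `d = exp(-dt/tau_m)` per
#' step. The defaults give `d = 0.9` at `dt = 1` ms (`tau_m = 9.4912` ms)
#' with a normalized threshold of 0.3 above rest.
#'
#' @param u_rest resting potential (mV). Default 0.
#' @param u_reset post-spike reset potential (mV). Default 0.
#' @param u_th firing threshold (mV); must exceed `u_rest`. Default 0.3.
#' @param tau_m membrane time constant (ms), positive. Default 9.4912.
#' @param dt simulation resolution (ms), positive. Default 1.
#' @param gain dimensionless scale applied to the synaptic current before it
#'   is added to the membrane (absorbs a `dt / c_m` factor when working in
#'   physical units). Default 1.
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params()
#' decay_factor(p$tau_m, p$dt) # ~0.9
#' @export
neuron_params <- function(u_rest = 0, u_reset = 0, u_th = 0.3,
                          tau_m = 9.4912, dt = 1.0, gain = 1.0) {
  stopifnot(is.numeric(u_rest), is.numeric(u_reset), is.numeric(u_th),
            is.numeric(tau_m), is.numeric(dt), is.numeric(gain))
  if (tau_m <= 0) stop("tau_m must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (u_th <= u_rest) stop("u_th must exceed u_rest", call. = FALSE)
  p <- list(u_rest = u_rest, u_reset = u_reset, u_th = u_th,
            tau_m = tau_m, dt = dt, gain = gain)
  class(p) <- "neuron_params"
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron parameters\n")
  cat(sprintf("  u_rest = %g mV, u_reset = %g mV, u_th = %g mV\n",
              x$u_rest, x$u_reset, x$u_th))
  cat(sprintf("  tau_m = %g ms, dt = %g ms (decay d = %.6f), gain = %g\n",
              x$tau_m, x$dt, decay_factor(x$tau_m, x$dt), x$gain))
  invisible(x)
}

#' Per-step membrane decay factor
#'
#' `d = exp(-dt / tau_m)`: the fraction of membrane potential (relative to
#' rest) surviving one simulation step of length `dt`.
#'
#' @param tau_m membrane time constant (ms), positive.
#' @param dt step length (ms), nonnegative.
#' @return decay factor in (0, 1] (equals 1 only when `dt = 0`).
#' @seealso [tau_from_decay()] for the inverse mapping.
#' @export
decay_factor <- function(tau_m, dt) {
  if (!is.numeric(tau_m) || any(tau_m <= 0))
    stop("tau_m must be positive", call. = FALSE)
  if (!is.numeric(dt) || any(dt < 0))
    stop("dt must be nonnegative", call. = FALSE)
  exp(-dt / tau_m)
}

#' Membrane time constant from a per-step decay factor
#'
#' Inverts [decay_factor()]: `tau_m = -dt / log(d)`. A decay of 0.9 per 1 ms
#' step corresponds to `tau_m = 9.4912` ms.
#'
#' @param d decay factor, strictly inside (0, 1).
#' @param dt step length (ms), positive.
#' @return membrane time constant (ms).
#' @export
tau_from_decay <- function(d, dt) {
  if (!is.numeric(d) || any(d <= 0) || any(d >= 1))
    stop("decay factor must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(dt) || any(dt <= 0))
    stop("dt must be positive", call. = FALSE)
  -dt / log(d)
}

#' Threshold spike indicator
#'
#' A neuron emits a spike at the current step iff its membrane potential at
#' the end of the previous step reached threshold (inclusive comparison).
#'
#' @param u_prev membrane potentials at the previous step (vector or matrix).
#' @param u_th firing threshold.
#' @return binary 0/1 object of the same shape as `u_prev`.
#' @export
spike_indicator <- function(u_prev, u_th) {
  out <- (u_prev >= u_th) + 0
  out
}

#' One membrane update step with embedded reset
#'
#' Advances the membrane one step: `u = u_prev * d * (1 - theta) + gain * I`,
#' where `theta` is the spike indicator computed from `u_prev`. The
#' `(1 - theta)` factor implements the reset: the decayed contribution of a
#' spiking neuron's potential is zeroed, so after a spike the membrane
#' restarts from `u_reset = 0` plus the incoming current. With the one-step
#' synaptic delay convention, `I` is the current computed from spikes of the
#' previous step.
#'
#' @param u_prev membrane potentials at the previous step.
#' @param I synaptic current for this step (same shape as `u_prev`).
#' @param theta binary spike indicator for this step, normally
#'   `spike_indicator(u_prev, params$u_th)`.
#' @param params a [neuron_params()] object.
#' @return updated membrane potentials.
#' @export
membrane_step <- function(u_prev, I, theta, params) {
  if (length(u_prev) != length(I) || length(u_prev) != length(theta))
    stop("u_prev, I and theta must be conformable", call. = FALSE)
  d <- decay_factor(params$tau_m, params$dt)
  u_prev * d * (1 - theta) + params$gain * I
}

#' Free membrane decay trace
#'
#' Closed-form trajectory `u0 * d^k`, k = 0..n_steps, of a neuron receiving
#' no input and emitting no spike (requires `u0 < u_th` for consistency with
#' the simulator). Useful for plotting single-neuron responses.
#'
#' @param u0 initial membrane potential.
#' @param n_steps number of steps to trace (the result has `n_steps + 1`
#'   entries including the initial value).
#' @param params a [neuron_params()] object.
#' @return numeric vector of length `n_steps + 1`.
#' @export
free_decay_trace <- function(u0, n_steps, params) {
  stopifnot(n_steps >= 0)
  d <- decay_factor(params$tau_m, params$dt)
  out <- numeric(n_steps + 1)
  out[1] <- u0
  if (n_steps > 0) {
    # iterate in the simulator's arithmetic order so traces agree bit-for-bit
    # with repeated membrane_step() calls under zero input
    for (k in seq_len(n_steps)) out[k + 1] <- out[k] * d
  }
  out
}
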