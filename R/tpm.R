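#' Tsodyks-Pawelzik-Markram synapse parameters
#'
#' The five-constant phenomenological model of a unitary synaptic signal
#' with short-term facilitation and depression: conductance `g`, decay
#' time `tau_d`, recovery time `tau_r`, facilitation time `tau_f`, and
#' utilization ratio `U`; plus the reversal potential `E_rev` that turns
#' conductance into current.
#'
#' @param g Unitary synaptic conductance (nS), positive.
#' @param tau_d Conductance decay time constant (ms), positive.
#' @param tau_r Resource recovery time constant (ms), positive.
#' @param tau_f Facilitation time constant (ms), positive.
#' @param U Utilization ratio, in (0, 1].
#' @param E_rev Reversal potential (mV); defaults 0 (excitatory
#'   convention) — use -70 for inhibitory synapses.
#' @param annotations Named list of opaque condition metadata (species,
#'   sex, age, temperature, recording mode, ...), carried along unchanged.
#' @return A `tpm_params` object.
#' @export
tpm_params <- function(g, tau_d, tau_r, tau_f, U, E_rev = 0,
                       annotations = list()) {
  if (g <= 0) stop("g must be positive", call. = FALSE)
  if (any(c(tau_d, tau_r, tau_f) <= 0)) {
    stop("all time constants must be positive", call. = FALSE)
  }
  if (U <= 0 || U > 1) stop("U must lie in (0, 1]", call. = FALSE)
  structure(
    list(g = g, tau_d = tau_d, tau_r = tau_r, tau_f = tau_f, U = U,
         E_rev = E_rev, annotations = annotations),
    class = "tpm_params"
  )
}

#' @export
print.tpm_params <- function(x, ...) {
  cat(sprintf(
    "<tpm_params> g=%g nS tau_d=%g tau_r=%g tau_f=%g ms U=%g E_rev=%g mV\n",
    x$g, x$tau_d, x$tau_r, x$tau_f, x$U, x$E_rev))
  invisible(x)
}

#' Initial (rested) TPM state
#'
#' @return A `tpm_state`: `u = 0` (no running facilitation), `R = 1` (full
#'   resources), `g_t = 0` (no open conductance).
#' @export
tpm_state <- function() {
  structure(list(u = 0, R = 1, g_t = 0), class = "tpm_state")
}

#' Evolve a TPM state between events
#'
#' Analytic inter-event decay: `u <- u e^(-dt/tau_f)`,
#' `R <- 1 - (1 - R) e^(-dt/tau_r)`, `g_t <- g_t e^(-dt/tau_d)`. Exact for
#' any step size, so two half-steps equal one full step.
#'
#' @param state A `tpm_state`.
#' @param dt Elapsed time (ms), nonnegative.
#' @param params A [tpm_params()] object.
#' @return The decayed `tpm_state`.
#' @export
tpm_evolve <- function(state, dt, params) {
  if (dt < 0) stop("dt must be nonnegative", call. = FALSE)
  state$u <- state$u * exp(-dt / params$tau_f)
  state$R <- 1 - (1 - state$R) * exp(-dt / params$tau_r)
  state$g_t <- state$g_t * exp(-dt / params$tau_d)
  state
}

#' Apply a presynaptic spike to a TPM state
#'
#' Canonical update order: facilitation first
#' (`u+ = u + U (1 - u)`), then release (`release = u+ R`), then resource
#' consumption (`R <- R - release`); the conductance jumps by
#' `g * release` and that amplitude is returned.
#'
#' @param state A `tpm_state` (already decayed to the event time).
#' @param params A [tpm_params()] object.
#' @return List with `state` (updated) and `amplitude` (nS conductance
#'   increment, `g * release`).
#' @examples
#' tpm_on_spike(tpm_state(), tpm_params(1, 10, 500, 50, 0.3))$amplitude
#' # first release from rest = g * U = 0.3
#' @export
tpm_on_spike <- function(state, params) {
  u_plus <- state$u + params$U * (1 - state$u)
  release <- u_plus * state$R
  state$u <- u_plus
  state$R <- state$R - release
  amp <- params$g * release
  state$g_t <- state$g_t + amp
  list(state = state, amplitude = amp)
}

#' Steady-state facilitation under a periodic train
#'
#' Closed-form fixed point of the facilitation variable immediately after
#' each spike of an infinitely long periodic train with interval `dt`:
#' `u* = U / (1 - (1 - U) e^(-dt/tau_f))`.
#'
#' @param params A [tpm_params()] object.
#' @param dt Inter-spike interval (ms).
#' @return The post-spike fixed point `u*`.
#' @export
tpm_steady_u <- function(params, dt) {
  decay <- exp(-dt / params$tau_f)
  params$U / (1 - (1 - params$U) * decay)
}

#' Simulate a train of postsynaptic conductances and currents
#'
#' Drives a TPM synapse with a presynaptic spike train and returns the
#' per-spike released amplitudes plus the conductance and current traces
#' sampled on a regular grid: `I(t) = g_t(t) (E_rev - V_hold)`.
#'
#' @param params A [tpm_params()] object.
#' @param spike_times Increasing presynaptic spike times (ms).
#' @param V_hold Holding potential (mV).
#' @param T Trace span (ms); defaults to last spike + 5 decay constants.
#' @param dt Trace sampling step (ms).
#' @return List with `amplitudes` (nS conductance increment per spike),
#'   `t`, `g` (nS), `I` (pA; positive inward for excitatory conventions),
#'   and `state` (final `tpm_state`).
#' @export
tpm_psc_train <- function(params, spike_times, V_hold = -70,
                          T = NULL, dt = 0.1) {
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (is.null(T)) {
    T <- if (length(spike_times) > 0L)
      max(spike_times) + 5 * params$tau_d else 5 * params$tau_d
  }
  st <- tpm_state()
  amps <- numeric(length(spike_times))
  t_last <- 0
  events <- list()
  for (i in seq_along(spike_times)) {
    st <- tpm_evolve(st, spike_times[i] - t_last, params)
    hit <- tpm_on_spike(st, params)
    st <- hit$state
    amps[i] <- hit$amplitude
    t_last <- spike_times[i]
  }
  # reconstruct the conductance trace from the event amplitudes
  t <- seq(0, T, by = dt)
  g <- numeric(length(t))
  for (i in seq_along(spike_times)) {
    after <- t >= spike_times[i]
    g[after] <- g[after] + amps[i] * exp(-(t[after] - spike_times[i]) / params$tau_d)
  }
  list(amplitudes = amps, t = t, g = g,
       I = g * (params$E_rev - V_hold), state = st)
}

#' Synaptic transfer strength
#'
#' The time-integral of a unit-release conductance transient:
#' `g * integral e^(-t/tau_d) dt = g * tau_d` (nS ms). Used to rank
#' connections by their charge-transfer capacity.
#'
#' @param params A [tpm_params()] object.
#' @return `g * tau_d` (nS ms).
#' @export
transfer_strength <- function(params) {
  params$g * params$tau_d
}
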