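#' Single-compartment Izhikevich model parameters
#'
#' The nine-parameter quadratic integrate-and-fire model used to represent
#' a neuron type's input-output function:
#' `C dv/dt = k (v - v_r)(v - v_t) - u + I`,
#' `du/dt = a (b (v - v_r) - u)`, with reset `v <- v_min`, `u <- u + d`
#' whenever `v >= v_peak`.
#'
#' @param C Membrane capacitance (pF), positive.
#' @param k Quadratic rate constant (nS/mV).
#' @param v_r Resting potential (mV).
#' @param v_t Threshold potential (mV); must exceed `v_r`.
#' @param v_peak Spike cutoff potential (mV); must exceed `v_t`.
#' @param v_min Post-spike reset potential (mV).
#' @param a Recovery time scale (1/ms), positive.
#' @param b Recovery sensitivity (nS).
#' @param d Post-spike recovery increment (pA).
#' @return An `izhikevich_params` object.
#' @examples
#' izhikevich_params(C = 100, k = 0.7, v_r = -60, v_t = -40, v_peak = 35,
#'                   v_min = -50, a = 0.03, b = -2, d = 100)
#' @export
izhikevich_params <- function(C, k, v_r, v_t, v_peak, v_min, a, b, d) {
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (!(v_r < v_t && v_t < v_peak)) {
    stop("require v_r < v_t < v_peak", call. = FALSE)
  }
  if (a <= 0) stop("a must be positive", call. = FALSE)
  structure(
    list(C = C, k = k, v_r = v_r, v_t = v_t, v_peak = v_peak,
         v_min = v_min, a = a, b = b, d = d),
    class = "izhikevich_params"
  )
}

#' @export
print.izhikevich_params <- function(x, ...) {
  cat(sprintf(
    "<izhikevich_params> C=%g pF k=%g v_r=%g v_t=%g v_peak=%g v_min=%g a=%g b=%g d=%g\n",
    x$C, x$k, x$v_r, x$v_t, x$v_peak, x$v_min, x$a, x$b, x$d))
  invisible(x)
}

# Canonical parameter sets (Izhikevich-style cortical archetypes), used as
# seeds for fixtures and as regimes in tests.
#' Canonical Izhikevich parameter sets
#'
#' @param which `"regular_spiking"` (pyramidal-like, adapting) or
#'   `"fast_spiking"` (basket-like, non-adapting).
#' @return An [izhikevich_params()] object.
#' @export
izhikevich_preset <- function(which = c("regular_spiking", "fast_spiking")) {
  which <- match.arg(which)
  switch(which,
    regular_spiking = izhikevich_params(C = 100, k = 0.7, v_r = -60,
                                        v_t = -40, v_peak = 35, v_min = -50,
                                        a = 0.03, b = -2, d = 100),
    fast_spiking = izhikevich_params(C = 20, k = 1, v_r = -55, v_t = -40,
                                     v_peak = 25, v_min = -45, a = 0.15,
                                     b = 8, d = 200)
  )
}

#' Integrate an Izhikevich neuron
#'
#' Forward-Euler integration on a fixed grid. After each step the voltage
#' is tested against `v_peak`; on a crossing the sample is recorded at
#' `v_peak` (for plotting), a spike is logged at that step's time, and the
#' state is reset to `(v_min, u + d)`.
#'
#' @param p An [izhikevich_params()] object.
#' @param I Input current (pA): a scalar, a vector of length `T/dt`
#'   (one value per step), or a function of time (ms).
#' @param dt Time step (ms), in (0, 1].
#' @param T Total simulated time (ms).
#' @param v0 Initial voltage (mV); defaults to `v_r`.
#' @param u0 Initial recovery current (pA); default 0.
#' @param stim_window Optional c(onset, offset) ms annotation stored on the
#'   spike train (defaults to the full span).
#' @return A list with `t` (sample times, ms), `v` (voltage trace, mV),
#'   `u` (recovery trace), and `train` (a `spike_train`: `times`,
#'   `stim_window`, `dt`, `T`).
#' @examples
#' p <- izhikevich_preset("regular_spiking")
#' out <- izhikevich_integrate(p, I = 70, dt = 0.1, T = 500)
#' length(out$train$times)
#' @export
izhikevich_integrate <- function(p, I, dt = 0.1, T, v0 = p$v_r, u0 = 0,
                                 stim_window = NULL) {
  stopifnot(inherits(p, "izhikevich_params"))
  if (dt <= 0 || dt > 1) stop("dt must lie in (0, 1] ms", call. = FALSE)
  if (T <= 0) stop("T must be positive", call. = FALSE)
  n <- as.integer(round(T / dt))
  times <- seq_len(n) * dt
  Ivec <- if (is.function(I)) I(times)
          else if (length(I) == 1L) rep(I, n)
          else if (length(I) == n) I
          else stop("I must be scalar, length T/dt, or a function",
                    call. = FALSE)

  v <- numeric(n + 1L); u <- numeric(n + 1L)
  v[1L] <- v0; u[1L] <- u0
  spikes <- numeric(0)
  vi <- v0; ui <- u0
  for (s in seq_len(n)) {
    dv <- (p$k * (vi - p$v_r) * (vi - p$v_t) - ui + Ivec[s]) / p$C
    du <- p$a * (p$b * (vi - p$v_r) - ui)
    vi <- vi + dt * dv
    ui <- ui + dt * du
    if (!is.finite(vi) || !is.finite(ui)) {
      stop(sprintf("integration diverged at step %d (t = %g ms)", s, s * dt),
           call. = FALSE)
    }
    if (vi >= p$v_peak) {
      v[s + 1L] <- p$v_peak
      spikes <- c(spikes, s * dt)
      vi <- p$v_min
      ui <- ui + p$d
    } else {
      v[s + 1L] <- vi
    }
    u[s + 1L] <- ui
  }
  if (is.null(stim_window)) stim_window <- c(0, T)
  list(
    t = c(0, times), v = v, u = u,
    train = spike_train(spikes, stim_window = stim_window, dt = dt, T = T)
  )
}

#' Construct a spike train
#'
#' @param times Strictly increasing spike times (ms).
#' @param stim_window c(onset, offset) of the stimulus (ms).
#' @param dt Integration step the train was produced at (ms).
#' @param T Simulation span (ms); all times must lie within \[0, T\].
#' @return A `spike_train` object.
#' @export
spike_train <- function(times, stim_window, dt = NA_real_, T = Inf) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (length(times) > 0L && (min(times) < 0 || max(times) > T)) {
    stop("spike times must lie within the simulation span", call. = FALSE)
  }
  structure(list(times = times, stim_window = stim_window, dt = dt, T = T),
            class = "spike_train")
}

#' F-I curve of an Izhikevich model
#'
#' Simulates a family of constant current steps and reports the firing
#' rate (spikes / duration, Hz) at each level, plus the rheobase: the
#' smallest tested current that evokes at least one spike.
#'
#' @param p An [izhikevich_params()] object.
#' @param I_min,I_max Current range (pA).
#' @param step Current increment (pA), positive; 10 pA is the conventional
#'   resolution.
#' @param duration Step duration (ms); at least 500 ms recommended.
#' @param dt Integration step (ms).
#' @return A list with `curve` (data frame `I`, `n_spikes`, `rate_Hz`) and
#'   `rheobase` (pA; NA if nothing spiked).
#' @export
f_i_curve <- function(p, I_min = 0, I_max = 500, step = 10,
                      duration = 1000, dt = 0.1) {
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  I_levels <- seq(I_min, I_max, by = step)
  n_spikes <- vapply(I_levels, function(I) {
    length(izhikevich_integrate(p, I, dt = dt, T = duration)$train$times)
  }, numeric(1))
  curve <- data.frame(I = I_levels, n_spikes = as.integer(n_spikes),
                      rate_Hz = n_spikes / (duration / 1000))
  fired <- which(n_spikes > 0)
  list(curve = curve,
       rheobase = if (length(fired) > 0L) I_levels[min(fired)] else NA_real_)
}
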