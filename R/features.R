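#' Extract electrophysiological features from a simulated trace
#'
#' Summarizes a voltage trace plus spike train into the feature set used
#' for model fitting and firing-pattern labeling. Rate features are 0 for
#' silent traces; the adaptation ratio (last ISI / first ISI) is defined
#' only with at least three spikes.
#'
#' @param trace Output of [izhikevich_integrate()] (or a list with `t`,
#'   `v`, `train`).
#' @param v_thresh_slope dv/dt threshold (mV/ms) used to estimate the
#'   spike threshold voltage from the rising phase.
#' @return A named list: `V_rest` (mV, voltage mode before stimulus or
#'   trace start), `V_thresh` (mV), `AP_ampl` (mV), `mean_rate` and
#'   `max_rate` (Hz, over the stimulus window), `latency` (ms from
#'   stimulus onset to first spike), `adaptation_ratio`, `n_spikes`.
#' @export
extract_features <- function(trace, v_thresh_slope = 10) {
  train <- trace$train
  times <- train$times
  win <- train$stim_window
  dur_s <- (win[2L] - win[1L]) / 1000

  # resting V: median of samples before stimulus onset (or first 5% of trace)
  pre_idx <- if (win[1L] > 0) trace$t < win[1L] else
    trace$t <= 0.05 * max(trace$t)
  V_rest <- stats::median(trace$v[pre_idx])

  V_thresh <- NA_real_
  AP_ampl <- NA_real_
  if (length(times) > 0L && !is.na(train$dt)) {
    dvdt <- diff(trace$v) / train$dt
    cross <- which(dvdt >= v_thresh_slope)
    if (length(cross) > 0L) V_thresh <- trace$v[cross[1L]]
    AP_ampl <- max(trace$v) - V_rest
  }

  in_win <- times >= win[1L] & times <= win[2L]
  n_win <- sum(in_win)
  mean_rate <- if (dur_s > 0) n_win / dur_s else 0
  isi <- diff(times[in_win])
  max_rate <- if (length(isi) > 0L) 1000 / min(isi) else mean_rate
  latency <- if (n_win > 0L) times[in_win][1L] - win[1L] else NA_real_
  adaptation <- if (n_win >= 3L) isi[length(isi)] / isi[1L] else NA_real_

  list(V_rest = V_rest, V_thresh = V_thresh, AP_ampl = AP_ampl,
       mean_rate = mean_rate, max_rate = max_rate, latency = latency,
       adaptation_ratio = adaptation, n_spikes = length(times))
}

#' Label a spike train with a reduced firing-pattern phenotype
#'
#' Deterministic inter-spike-interval rules over a reduced taxonomy of
#' hippocampal firing-pattern phenotypes:
#'
#' * `SLN` — no spikes during the stimulus.
#' * `TSTUT.SLN` — spiking confined to the transient window (the first
#'   25% of the stimulus) followed by silence.
#' * `PSTUT` — stutter gaps (ISI > 3x median ISI) recurring beyond the
#'   transient window.
#' * `TSTUT.PSTUT` — a transient-window burst followed by persistent
#'   stuttering.
#' * `TSTUT.` — stutter gaps confined to the transient window, steady
#'   afterwards.
#' * `ASP.` — no stuttering, ISIs drifting upward (adapting): last ISI at
#'   least 30% above the first, non-decreasing trend.
#' * `NASP` — non-adapting spiking: ISIs within a +/-10% steadiness band
#'   around their median.
#'
#' Traces that stutter nowhere and fall between the ASP. and NASP bands
#' are labeled `ASP.` when the ISI trend is increasing and `NASP`
#' otherwise.
#'
#' @param train A `spike_train` with a known stimulus window.
#' @param steadiness_band Half-width of the NASP ISI band, fraction of the
#'   median ISI (default 0.10).
#' @param stutter_factor Gap threshold as a multiple of the median ISI
#'   (default 3).
#' @param transient_fraction Fraction of the stimulus counted as the
#'   transient window (default 0.25).
#' @param adaptation_min Minimum last/first ISI ratio for ASP. (default 1.3).
#' @return A single label string.
#' @export
classify_firing_pattern <- function(train, steadiness_band = 0.10,
                                    stutter_factor = 3,
                                    transient_fraction = 0.25,
                                    adaptation_min = 1.3) {
  stopifnot(inherits(train, "spike_train"))
  win <- train$stim_window
  if (is.null(win) || any(is.na(win))) {
    stop("stimulus window must be known", call. = FALSE)
  }
  t <- train$times[train$times >= win[1L] & train$times <= win[2L]]
  if (length(t) == 0L) return("SLN")

  dur <- win[2L] - win[1L]
  t_edge <- win[1L] + transient_fraction * dur
  # tail silence: no spike after the transient window and a silent gap
  # longer than the remaining stimulus' half
  if (max(t) <= t_edge) return("TSTUT.SLN")

  if (length(t) == 1L) return("NASP")  # single late spike: no ISI structure
  isi <- diff(t)
  med <- stats::median(isi)
  gaps <- which(isi > stutter_factor * med)
  gap_mid <- (t[gaps] + t[gaps + 1L]) / 2

  if (length(gaps) > 0L) {
    early <- gap_mid <= t_edge
    burst_in_transient <- sum(t <= t_edge) >= 2L
    if (all(early)) return("TSTUT.")
    if (burst_in_transient && any(!early)) return("TSTUT.PSTUT")
    return("PSTUT")
  }

  steady <- all(abs(isi - med) <= steadiness_band * med)
  if (steady) return("NASP")
  adapting <- isi[length(isi)] / isi[1L] >= adaptation_min &&
    all(diff(isi) >= -steadiness_band * med)
  if (adapting) return("ASP.")
  # in-between: label by trend
  if (isi[length(isi)] > isi[1L]) "ASP." else "NASP"
}
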