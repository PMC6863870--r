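# EPSP feature extraction from averaged membrane-potential sweeps.

#' Sampled membrane-potential sweeps
#'
#' @param time_ms strictly increasing, uniformly spaced time base (ms).
#' @param sweeps numeric matrix, one sweep per row, `length(time_ms)`
#'   samples per sweep (a single vector is accepted and treated as one
#'   sweep).
#' @param stim_onset_ms stimulus onset, inside the trace span.
#' @param presyn_ap_time_ms presynaptic action-potential time, or `NA`.
#' @param meta free-form provenance list.
#' @return An object of class `TraceSet`.
#' @export
trace_set <- function(time_ms, sweeps, stim_onset_ms,
                      presyn_ap_time_ms = NA_real_, meta = list()) {
  if (is.null(dim(sweeps))) sweeps <- matrix(sweeps, nrow = 1)
  if (!is.matrix(sweeps)) stop("sweeps must be a matrix (ragged input?)")
  if (ncol(sweeps) != length(time_ms))
    stop("each sweep must have length(time_ms) samples")
  dt <- diff(time_ms)
  if (any(dt <= 0)) stop("time_ms must be strictly increasing")
  if (diff(range(dt)) > 1e-9 * mean(dt))
    stop("time_ms must be uniformly sampled")
  if (stim_onset_ms < time_ms[1] || stim_onset_ms > time_ms[length(time_ms)])
    stop("stim_onset_ms outside trace span")
  structure(list(time_ms = time_ms, sweeps = sweeps,
                 stim_onset_ms = stim_onset_ms,
                 presyn_ap_time_ms = presyn_ap_time_ms, meta = meta),
            class = "TraceSet")
}

#' @export
print.TraceSet <- function(x, ...) {
  cat(sprintf("TraceSet: %d sweep(s) x %d samples, %.3f-%.3f ms, stim at %g ms\n",
              nrow(x$sweeps), ncol(x$sweeps), x$time_ms[1],
              x$time_ms[length(x$time_ms)], x$stim_onset_ms))
  invisible(x)
}

#' Pointwise mean across sweeps
#'
#' @param t a [trace_set()] with at least one sweep.
#' @return Numeric vector, the averaged trace.
#' @export
average_sweeps <- function(t) {
  stopifnot(inherits(t, "TraceSet"))
  if (nrow(t$sweeps) < 1) stop("need at least one sweep")
  colMeans(t$sweeps)
}

# centered boxcar smoother (edges use the available window)
.boxcar <- function(v, half) {
  if (half < 1) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect an EPSP in an averaged trace
#'
#' The baseline mean and SD come from a window of `baseline_window_ms`
#' ending `pre_gap_ms` before the stimulus. The amplitude is the peak of
#' a boxcar-smoothed copy of the trace (width `smooth_ms`) over the
#' response window, minus the baseline mean; smoothing keeps the peak
#' estimate from riding on the maximum of the noise. An EPSP is detected
#' when the amplitude exceeds twice the raw baseline SD. If the baseline
#' SD is zero (noiseless input) any positive amplitude is detected, with
#' a warning.
#'
#' @param time_ms time base (ms).
#' @param v averaged voltage trace (mV).
#' @param stim_onset_ms stimulus onset.
#' @param baseline_window_ms baseline window length.
#' @param response_window_ms response window length after the stimulus.
#' @param pre_gap_ms gap between baseline window and stimulus.
#' @param smooth_ms boxcar width for the peak estimate (0 disables).
#' @return A list (class `EpspFeature`) with `detected`, `amplitude_mV`,
#'   `baseline_mean_mV`, `baseline_sd_mV`, `peak_time_ms`.
#' @export
detect_epsp <- function(time_ms, v, stim_onset_ms,
                        baseline_window_ms = 50, response_window_ms = 50,
                        pre_gap_ms = 2, smooth_ms = 2) {
  stopifnot(length(time_ms) == length(v))
  b_hi <- stim_onset_ms - pre_gap_ms
  b_lo <- b_hi - baseline_window_ms
  bl <- time_ms >= max(b_lo, time_ms[1]) & time_ms < b_hi
  if (sum(bl) < 2) stop("baseline window has fewer than 2 samples")
  resp <- time_ms > stim_onset_ms &
    time_ms <= stim_onset_ms + response_window_ms
  if (!any(resp)) stop("response window outside trace")
  b_mean <- mean(v[bl])
  b_sd <- stats::sd(v[bl])
  dt <- time_ms[2] - time_ms[1]
  vs <- .boxcar(v, half = floor(smooth_ms / (2 * dt)))
  peak_i <- which(resp)[which.max(vs[resp])]
  amp <- vs[peak_i] - b_mean
  if (b_sd == 0) {
    warning("baseline SD is zero; detecting any positive amplitude")
    detected <- amp > 0
  } else {
    detected <- amp > 2 * b_sd
  }
  structure(list(detected = detected, amplitude_mV = amp,
                 baseline_mean_mV = b_mean, baseline_sd_mV = b_sd,
                 peak_time_ms = time_ms[peak_i]),
            class = "EpspFeature")
}

#' Synaptic delay to 20% of the EPSP maximum
#'
#' Time from the presynaptic action potential to the first point after
#' it where the (raw, unsmoothed) trace reaches 20% of the EPSP
#' amplitude above baseline, with linear interpolation between samples.
#' Baseline and amplitude default to the mean before the AP and the
#' post-AP maximum minus baseline; supply values from [detect_epsp()]
#' for windowed estimates.
#'
#' @param time_ms time base (ms).
#' @param v averaged voltage trace (mV).
#' @param presyn_ap_time_ms presynaptic AP time, inside the trace.
#' @param baseline_mean_mV,amplitude_mV optional overrides.
#' @param threshold_frac fraction of the maximum defining onset.
#' @return Delay in ms.
#' @export
synaptic_delay <- function(time_ms, v, presyn_ap_time_ms,
                           baseline_mean_mV = NULL, amplitude_mV = NULL,
                           threshold_frac = 0.2) {
  stopifnot(length(time_ms) == length(v))
  if (presyn_ap_time_ms < time_ms[1] ||
      presyn_ap_time_ms > time_ms[length(time_ms)])
    stop("presyn_ap_time_ms outside trace")
  pre <- time_ms < presyn_ap_time_ms
  post <- time_ms >= presyn_ap_time_ms
  if (is.null(baseline_mean_mV))
    baseline_mean_mV <- if (any(pre)) mean(v[pre]) else v[1]
  if (is.null(amplitude_mV))
    amplitude_mV <- max(v[post]) - baseline_mean_mV
  if (amplitude_mV <= 0) stop("no positive deflection after the AP")
  thr <- baseline_mean_mV + threshold_frac * amplitude_mV
  idx <- which(post)
  above <- v[idx] >= thr
  if (!any(above))
    stop("threshold never crossed (inconsistent with detection)")
  i2 <- idx[which(above)[1]]
  if (i2 == idx[1] || v[i2 - 1] >= thr) {
    t_cross <- time_ms[i2]
  } else {
    i1 <- i2 - 1
    t_cross <- time_ms[i1] + (thr - v[i1]) / (v[i2] - v[i1]) *
      (time_ms[i2] - time_ms[i1])
  }
  t_cross - presyn_ap_time_ms
}

#' Input resistance from a current step
#'
#' Ohm's law on the steady-state voltage deflection of a current step:
#' `R = dV / I`, reported in megaohms (mV / nA). The baseline is the
#' mean over `baseline_window_ms` before the step onset; the steady
#' state is the mean over the last `steady_frac` of the step.
#'
#' @param time_ms time base (ms).
#' @param v voltage trace (mV).
#' @param injected_current_pA step current (nonzero).
#' @param step_onset_ms,step_end_ms step window.
#' @param baseline_window_ms baseline window before the step.
#' @param steady_frac final fraction of the step treated as steady state.
#' @return Input resistance in megaohms.
#' @export
input_resistance <- function(time_ms, v, injected_current_pA = -300,
                             step_onset_ms, step_end_ms,
                             baseline_window_ms = 50, steady_frac = 0.2) {
  stopifnot(length(time_ms) == length(v))
  if (injected_current_pA == 0) stop("injected current must be nonzero")
  bl <- time_ms >= step_onset_ms - baseline_window_ms &
    time_ms < step_onset_ms
  if (!any(bl)) stop("baseline window outside trace")
  ss_lo <- step_end_ms - steady_frac * (step_end_ms - step_onset_ms)
  ss <- time_ms >= ss_lo & time_ms < step_end_ms
  if (!any(ss)) stop("steady-state window outside trace")
  dv <- mean(v[ss]) - mean(v[bl])
  dv / (injected_current_pA / 1000)
}
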