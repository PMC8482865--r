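# Paired-pulse ratio analysis of evoked synaptic currents: sweep
# averaging, amplitude measurement with optional summation correction,
# PPR computation and release-probability classification, and the
# recording-quality gate.

#' Set of evoked-current sweeps
#'
#' @param current numeric matrix, one column per sweep, pA (inward
#'   currents negative).
#' @param time time axis in seconds, one value per row.
#' @param sampling_rate Hz.
#' @param stim_times two strictly increasing stimulus times within the
#'   trace, seconds.
#' @param holding_potential mV; informational (default -70).
#' @return A `sweep_set` object.
#' @export
sweep_set <- function(current, time, sampling_rate, stim_times,
                      holding_potential = -70) {
  current <- as.matrix(current)
  stopifnot(nrow(current) == length(time), ncol(current) >= 1,
            length(stim_times) == 2)
  if (!(stim_times[1] < stim_times[2]))
    stop("stim_times must be strictly increasing")
  if (stim_times[1] < min(time) || stim_times[2] > max(time))
    stop("stim_times must lie within the trace")
  structure(list(current = current, time = as.numeric(time),
                 sampling_rate = sampling_rate,
                 stim_times = as.numeric(stim_times),
                 holding_potential = holding_potential),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("sweep_set: %d sweeps x %d samples at %g kHz; stimuli at %s s\n",
              ncol(x$current), nrow(x$current), x$sampling_rate / 1000,
              paste(x$stim_times, collapse = ", ")))
  invisible(x)
}

#' Average sweeps pointwise
#'
#' @param sweeps a [sweep_set()] (or a numeric matrix of equal-length
#'   sweeps in columns).
#' @return Numeric mean trace, one value per sample.
#' @export
average_sweeps <- function(sweeps) {
  if (inherits(sweeps, "sweep_set")) {
    m <- sweeps$current
  } else if (is.list(sweeps)) {
    len <- vapply(sweeps, length, integer(1))
    if (length(unique(len)) != 1) stop("ragged sweeps: unequal lengths")
    m <- do.call(cbind, sweeps)
  } else {
    m <- as.matrix(sweeps)
  }
  rowMeans(m)
}

#' Measure the two evoked amplitudes from an averaged trace
#'
#' The first amplitude is the peak deviation from the pre-stimulus
#' baseline inside the first peak window. For the second pulse, the decay
#' of the first response between the pulses is fit with a single
#' exponential and extrapolated under the second response; the second
#' amplitude is the peak deviation from that extrapolated decay
#' (summation correction). With `correct_summation = FALSE` both
#' amplitudes are measured from the common baseline. Amplitudes are
#' returned as positive magnitudes; response polarity (inward/outward) is
#' detected from the first response.
#'
#' @param trace averaged current trace, pA.
#' @param time time axis, seconds.
#' @param stim_times the two stimulus times, seconds.
#' @param baseline_window seconds of pre-stimulus baseline averaged
#'   before the first stimulus.
#' @param peak_window search window relative to each stimulus, seconds
#'   (default 1-15 ms, opening right after the 1 ms artifact blanking so
#'   the window contains the transient peak of fast synaptic kinetics).
#' @param correct_summation logical; see above.
#' @param fit_window decay-fit window relative to the first stimulus,
#'   seconds; its end is clipped 1 ms before the second stimulus.
#' @param noise_k amplitudes below `noise_k` times the baseline noise SD
#'   raise a "no evoked response" error.
#' @return List with `amp1`, `amp2` (pA, magnitudes), `baseline`,
#'   `noise_sd`, `polarity` (-1 inward), and `tau_decay` from the fit
#'   (NA when uncorrected).
#' @export
measure_amplitudes <- function(trace, time, stim_times,
                               baseline_window = 0.05,
                               peak_window = c(0.001, 0.015),
                               correct_summation = TRUE,
                               fit_window = c(0.008, 0.019),
                               noise_k = 3) {
  stopifnot(length(trace) == length(time), length(stim_times) == 2,
            stim_times[1] < stim_times[2])
  t1 <- stim_times[1]; t2 <- stim_times[2]
  if (t1 + peak_window[2] > max(time) || t2 + peak_window[2] > max(time))
    stop("peak windows fall outside the trace")

  bl_idx <- time >= t1 - baseline_window & time < t1
  if (!any(bl_idx)) stop("no samples in the baseline window")
  baseline <- mean(trace[bl_idx])
  noise_sd <- sd(trace[bl_idx])
  if (is.na(noise_sd)) noise_sd <- 0

  w1 <- which(time >= t1 + peak_window[1] & time <= t1 + peak_window[2])
  dev1 <- trace[w1] - baseline
  polarity <- if (abs(min(dev1)) >= abs(max(dev1))) -1 else 1
  amp1 <- max(polarity * dev1)
  floor_amp <- max(noise_k * noise_sd, sqrt(.Machine$double.eps))
  if (amp1 < floor_amp)
    stop("no evoked response: first amplitude below the noise floor")

  w2 <- which(time >= t2 + peak_window[1] & time <= t2 + peak_window[2])
  tau_decay <- NA_real_
  if (correct_summation) {
    fit_idx <- which(time >= t1 + fit_window[1] &
                       time <= min(t1 + fit_window[2], t2 - 0.001))
    ref <- polarity * (trace[fit_idx] - baseline)
    ok <- ref > 0
    extrap <- rep(0, length(w2))
    if (sum(ok) >= 3) {
      ft <- time[fit_idx][ok]
      co <- stats::coef(stats::lm(log(ref[ok]) ~ ft))
      if (is.finite(co[2]) && co[2] < 0) {
        tau_decay <- -1 / co[2]
        extrap <- exp(co[1] + co[2] * time[w2])
      }
    }
    dev2 <- polarity * (trace[w2] - baseline) - extrap
  } else {
    dev2 <- polarity * (trace[w2] - baseline)
  }
  amp2 <- max(dev2)
  if (amp2 < floor_amp)
    stop("no evoked response: second amplitude below the noise floor")

  list(amp1 = amp1, amp2 = amp2, baseline = baseline,
       noise_sd = noise_sd, polarity = polarity, tau_decay = tau_decay)
}

#' Paired-pulse ratio and release-probability class
#'
#' PPR is the second over the first response amplitude (both positive
#' magnitudes). Release probability is classified as low when the pair
#' facilitates (PPR > 1), high when it depresses (PPR < 1), and moderate
#' in a band around 1.
#'
#' @param amp1,amp2 response magnitudes, pA; `amp1` must be > 0.
#' @param moderate_band half-width of the "moderate" band:
#'   `|ppr - 1| <= moderate_band` classifies as moderate.
#' @return A `ppr_result` with `amp1`, `amp2`, `ppr`, `release_class`.
#' @export
compute_ppr <- function(amp1, amp2, moderate_band = 0.1) {
  if (!is.finite(amp1) || amp1 <= 0) stop("amp1 must be > 0")
  if (!is.finite(amp2) || amp2 < 0) stop("amp2 must be >= 0")
  ppr <- amp2 / amp1
  release_class <- if (abs(ppr - 1) <= moderate_band) "moderate"
  else if (ppr > 1) "low" else "high"
  structure(list(amp1 = amp1, amp2 = amp2, ppr = ppr,
                 release_class = release_class),
            class = "ppr_result")
}

#' @export
print.ppr_result <- function(x, ...) {
  cat(sprintf("PPR = %.3f (amp1 %.1f pA, amp2 %.1f pA): %s release probability\n",
              x$ppr, x$amp1, x$amp2, x$release_class))
  invisible(x)
}

#' Measure the PPR of a sweep set
#'
#' Convenience wrapper: average the sweeps, measure both amplitudes and
#' compute the PPR.
#'
#' @param sweeps a [sweep_set()].
#' @param ... passed to [measure_amplitudes()].
#' @param moderate_band passed to [compute_ppr()].
#' @return A `ppr_result`.
#' @export
measure_ppr <- function(sweeps, ..., moderate_band = 0.1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  tr <- average_sweeps(sweeps)
  amps <- measure_amplitudes(tr, sweeps$time, sweeps$stim_times, ...)
  compute_ppr(amps$amp1, amps$amp2, moderate_band = moderate_band)
}

#' Recording quality gate
#'
#' A recording passes unless its access resistance exceeds 40 or its
#' whole-cell capacitance is below 4 pF (the printed exclusion rule, with
#' units as reported).
#'
#' @param access_resistance access resistance values.
#' @param whole_cell_capacitance whole-cell capacitance values, pF.
#' @return Logical vector: `TRUE` = pass. Missing values are an error.
#' @export
qc_recording <- function(access_resistance, whole_cell_capacitance) {
  if (length(access_resistance) != length(whole_cell_capacitance))
    stop("inputs must have equal length")
  if (anyNA(access_resistance) || anyNA(whole_cell_capacitance))
    stop("missing QC values")
  !(access_resistance > 40 | whole_cell_capacitance < 4)
}
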