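#' Spike-detection parameters
#'
#' Band edges, threshold scaling and event-handling rules for
#' amplitude-threshold detection on a band-passed extracellular trace.
#' Defaults are standard practice for single-unit tungsten recordings:
#' 0.3-8 kHz band, negative-going threshold at 4 robust noise SDs, 1 ms
#' dead time, extremum alignment.
#'
#' @param band_low_hz,band_high_hz Pass band edges, Hz.
#' @param threshold_k Threshold in multiples of the robust noise SD.
#' @param polarity `"negative"`, `"positive"` or `"both"`.
#' @param dead_time_ms Minimum separation between detections, ms; also the
#'   search window for the waveform extremum after a crossing.
#' @param alignment `"extremum"` (spike time = waveform extremum) or
#'   `"threshold_crossing"`.
#' @return A validated list of class `detection_params`.
#' @export
detection_params <- function(band_low_hz = 300, band_high_hz = 8000,
                             threshold_k = 4,
                             polarity = c("negative", "positive", "both"),
                             dead_time_ms = 1,
                             alignment = c("extremum", "threshold_crossing")) {
  polarity <- match.arg(polarity)
  alignment <- match.arg(alignment)
  check_scalar_number(band_low_hz, "band_low_hz", lower = 1e-9)
  check_scalar_number(band_high_hz, "band_high_hz")
  if (band_high_hz <= band_low_hz) stop_field("band_high_hz", "must exceed band_low_hz")
  check_scalar_number(threshold_k, "threshold_k", lower = 1e-9)
  check_scalar_number(dead_time_ms, "dead_time_ms", lower = 0)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 threshold_k = threshold_k, polarity = polarity,
                 dead_time_ms = dead_time_ms, alignment = alignment),
            class = "detection_params")
}

#' Zero-phase band-pass filter a voltage trace
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the net filter has zero phase and spike times
#' are not shifted by group delay. Output length equals input length.
#'
#' @param trace A [voltage_trace()].
#' @param params A [detection_params()] supplying the band edges.
#' @return A filtered `voltage_trace`.
#' @export
bandpass <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "voltage_trace"))
  fs <- sampling_rate(trace)
  if (params$band_high_hz >= fs / 2) {
    stop_field("band_high_hz", "must be below the Nyquist frequency")
  }
  if (nrow(trace) == 0) return(trace)
  bf <- signal::butter(2, c(params$band_low_hz, params$band_high_hz) / (fs / 2),
                       type = "pass")
  out <- trace
  out$uv <- signal::filtfilt(bf, trace$uv)
  out
}

#' Robust noise standard deviation of a trace
#'
#' Median absolute deviation estimator `median(|x|) / 0.6745`, which is
#' nearly unbiased for Gaussian noise and insensitive to the small fraction
#' of samples occupied by spikes.
#'
#' @param trace A [voltage_trace()] (ordinarily already band-passed).
#' @return Noise SD estimate in microvolts.
#' @export
estimate_noise_sd <- function(trace) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (nrow(trace) < 1000) stop_field("trace", "need at least 1000 samples")
  median(abs(trace$uv)) / 0.6745
}

#' Detect spikes by amplitude threshold
#'
#' Band-passes the trace (unless `prefiltered = TRUE`), estimates the noise
#' SD robustly, thresholds at `threshold_k` times that SD with the chosen
#' polarity, and reports one event per threshold excursion, timed at the
#' waveform extremum within `dead_time_ms` of the crossing. No two events
#' are closer than `dead_time_ms`.
#'
#' @param trace A [voltage_trace()].
#' @param params A [detection_params()].
#' @param prefiltered Set `TRUE` when `trace` is already band-passed.
#' @return A `spike_train` with `source = "detected"`, carrying the
#'   threshold (uV) and noise SD used as attributes `threshold_uv` and
#'   `noise_sd_uv`.
#' @examples
#' ses <- generate_chr2_session(
#'   synth_config(spont_rate_hz = 0, evoked_prob = 1, doublet_prob = 0, seed = 2),
#'   stim_protocol("pulse_train", frequency_hz = 20, pulses_per_train = 10,
#'                 n_trains = 1))
#' detect_spikes(ses$trace)
#' @export
detect_spikes <- function(trace, params = detection_params(), prefiltered = FALSE) {
  stopifnot(inherits(trace, "voltage_trace"))
  fs <- sampling_rate(trace)
  filt <- if (prefiltered) trace else bandpass(trace, params)
  x <- filt$uv
  noise_sd <- if (length(x) >= 1000) estimate_noise_sd(filt) else stats::sd(x)
  thr <- params$threshold_k * noise_sd
  dur <- trace_duration_s(trace)
  # signed signal so that "crossing" always means exceeding +thr
  y <- switch(params$polarity,
              negative = -x,
              positive = x,
              both = abs(x))
  over <- y > thr
  if (!any(over)) {
    return(structure(spike_train(numeric(), dur, source = "detected"),
                     threshold_uv = thr, noise_sd_uv = noise_sd))
  }
  onset <- which(over & !c(FALSE, over[-length(over)]))
  dead_n <- max(1L, round(params$dead_time_ms / 1000 * fs))
  times <- numeric(length(onset))
  kept <- 0L
  last_i <- -Inf
  for (i in onset) {
    if (i - last_i < dead_n) next
    j <- if (params$alignment == "extremum") {
      win <- i:min(i + dead_n, length(y))
      win[which.max(y[win])]
    } else i
    times[kept <- kept + 1L] <- trace$time_s[j]
    last_i <- i
  }
  times <- times[seq_len(kept)]
  # extremum alignment can reorder/eclipse events from adjacent excursions
  if (kept > 1) {
    times <- sort(times)
    times <- times[c(TRUE, diff(times) * 1000 >= params$dead_time_ms)]
  }
  structure(spike_train(times, dur, source = "detected"),
            threshold_uv = thr, noise_sd_uv = noise_sd)
}
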