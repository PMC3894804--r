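#' Biphasic extracellular spike template
#'
#' Builds the fixed waveform inserted into synthetic traces: a sharp lobe
#' carrying the full amplitude (by convention negative, as seen on a
#' tungsten electrode near a soma) over half of `width_ms`, followed by a
#' broader opposite-polarity lobe of one third the amplitude over 1.5 times
#' `width_ms`, scaled so the two half-sine lobes cancel and the template
#' integrates to (approximately) zero. Total support is `2 * width_ms`.
#'
#' @param amplitude Peak voltage of the main lobe in microvolts; negative
#'   values give the usual negative-going extracellular spike. `0` yields an
#'   all-zero template.
#' @param width_ms Nominal spike width in milliseconds (positive).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Numeric vector of waveform samples (length
#'   `round(2 * width_ms * 1e-3 * sampling_rate_hz)`); the extremum of the
#'   main lobe equals `amplitude`.
#' @examples
#' w <- spike_waveform(-80, width_ms = 1, sampling_rate_hz = 20000)
#' min(w)      # -80
#' length(w)   # 40 samples
#' @export
spike_waveform <- function(amplitude, width_ms, sampling_rate_hz = 20000) {
  check_scalar_number(amplitude, "amplitude")
  check_scalar_number(width_ms, "width_ms")
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  if (width_ms <= 0) stop_field("width_ms", "must be positive")
  n <- round(2 * width_ms * 1e-3 * sampling_rate_hz)
  if (n < 2) return(numeric(n))
  t <- (seq_len(n) - 0.5) / n * 2        # in units of width_ms, support [0, 2)
  w <- numeric(n)
  main <- t < 0.5
  w[main] <- sin(pi * t[main] / 0.5)
  w[!main] <- -sin(pi * (t[!main] - 0.5) / 1.5) / 3
  m <- max(abs(w))
  if (m == 0) return(numeric(n))
  w <- w * (amplitude / m)    # sampled extremum hits amplitude exactly
  # exact sampled zero integral (analytic areas cancel; remove residual
  # discretisation offset on the broad lobe)
  if (any(!main) && amplitude != 0) {
    resid <- sum(w)
    w[!main] <- w[!main] - resid / sum(!main)
  }
  w
}
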