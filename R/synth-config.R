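#' Synthetic-session generator configuration
#'
#' Collects every knob of the synthetic extracellular-signal generator in a
#' validated list. Defaults describe a well-isolated prefrontal unit on a
#' tungsten electrode: 20 kHz sampling, 10 uV background noise, a -100 uV
#' (signal-to-noise 10) biphasic spike, sparse spontaneous firing, reliable
#' light-evoked spiking with a 7 ms modal onset latency, and strong but
#' imperfect continuous-light silencing.
#'
#' @param duration_s Session length in seconds. `NA` (default) lets the
#'   generator derive it from the stimulation protocol.
#' @param sampling_rate_hz Sampling rate in Hz; must exceed twice the 8 kHz
#'   upper edge of the analysis band.
#' @param noise_sd Background noise standard deviation, uV.
#' @param spike_amplitude Template peak, uV; negative-going by convention.
#' @param spike_width_ms Template nominal width, ms (support is twice this).
#' @param spont_rate_hz Mean spontaneous firing rate, Hz.
#' @param spont_mode `"poisson"` (homogeneous) or `"phasic"` (sinusoidally
#'   rate-modulated inhomogeneous Poisson).
#' @param phasic_period_s Period of the phasic rate modulation, seconds.
#' @param phasic_depth Modulation depth in `[0, 1]`; 0 reduces to Poisson.
#' @param evoked_prob Probability that a light pulse evokes at least one
#'   spike.
#' @param doublet_prob Probability that an evoked response is a doublet
#'   (a second spike 3-8 ms after the first), so mean spikes per pulse can
#'   exceed 1.
#' @param latency_mode_ms Modal first-spike latency after pulse onset, ms.
#' @param latency_jitter_ms Spread (SD before truncation) of the latency
#'   distribution, ms.
#' @param silencing_efficacy Probability that a spontaneous spike falling in
#'   a light-on interval is suppressed.
#' @param rebound_gain Multiplicative firing-rate factor immediately after
#'   light offset (1 = no rebound).
#' @param rebound_tau_s Exponential decay constant of the rebound, seconds.
#' @param refractory_ms Minimum separation enforced between any two
#'   generated spikes, ms.
#' @param seed Integer RNG seed; identical configurations and seeds give
#'   bit-identical sessions.
#'
#' @return A validated list of class `synth_config`.
#' @examples
#' cfg <- synth_config(spont_rate_hz = 2, seed = 1)
#' @export
synth_config <- function(duration_s = NA,
                         sampling_rate_hz = 20000,
                         noise_sd = 10,
                         spike_amplitude = -100,
                         spike_width_ms = 1,
                         spont_rate_hz = 1,
                         spont_mode = c("poisson", "phasic"),
                         phasic_period_s = 0.5,
                         phasic_depth = 0.8,
                         evoked_prob = 0.95,
                         doublet_prob = 0.1,
                         latency_mode_ms = 7,
                         latency_jitter_ms = 1.5,
                         silencing_efficacy = 0.98,
                         rebound_gain = 1.5,
                         rebound_tau_s = 0.1,
                         refractory_ms = 2,
                         seed = 1L) {
  spont_mode <- match.arg(spont_mode)
  check_scalar_number(duration_s, "duration_s", allow_na = TRUE)
  if (!is.na(duration_s) && duration_s <= 0) stop_field("duration_s", "must be positive")
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  if (sampling_rate_hz <= 2 * 8000) {
    stop_field("sampling_rate_hz", "must exceed twice the 8 kHz band edge")
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(spike_amplitude, "spike_amplitude")
  check_scalar_number(spike_width_ms, "spike_width_ms", lower = 1e-9)
  check_scalar_number(spont_rate_hz, "spont_rate_hz", lower = 0)
  check_scalar_number(phasic_period_s, "phasic_period_s", lower = 1e-9)
  check_prob(phasic_depth, "phasic_depth")
  check_prob(evoked_prob, "evoked_prob")
  check_prob(doublet_prob, "doublet_prob")
  check_scalar_number(latency_mode_ms, "latency_mode_ms", lower = 1e-9)
  check_scalar_number(latency_jitter_ms, "latency_jitter_ms", lower = 1e-9)
  check_prob(silencing_efficacy, "silencing_efficacy")
  check_scalar_number(rebound_gain, "rebound_gain", lower = 0)
  check_scalar_number(rebound_tau_s, "rebound_tau_s", lower = 1e-9)
  check_scalar_number(refractory_ms, "refractory_ms", lower = 0)
  check_scalar_number(seed, "seed")
  structure(
    list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
         noise_sd = noise_sd, spike_amplitude = spike_amplitude,
         spike_width_ms = spike_width_ms, spont_rate_hz = spont_rate_hz,
         spont_mode = spont_mode, phasic_period_s = phasic_period_s,
         phasic_depth = phasic_depth, evoked_prob = evoked_prob,
         doublet_prob = doublet_prob, latency_mode_ms = latency_mode_ms,
         latency_jitter_ms = latency_jitter_ms,
         silencing_efficacy = silencing_efficacy,
         rebound_gain = rebound_gain, rebound_tau_s = rebound_tau_s,
         refractory_ms = refractory_ms, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Light-stimulation protocol
#'
#' Describes how light is delivered in a synthetic session: repeated trains
#' of brief pulses (photoactivation experiments) or repeated stretches of
#' continuous light (silencing experiments). Defaults match 10 ms pulses,
#' 100 per train, trains every 2 minutes, and 10 s of continuous light with
#' a 5 s baseline before the first delivery.
#'
#' @param kind `"pulse_train"` or `"continuous"`.
#' @param pulse_width_ms Pulse width in ms (pulse-train mode); must be
#'   shorter than the inter-pulse interval `1000 / frequency_hz`.
#' @param frequency_hz Within-train pulse rate, Hz.
#' @param pulses_per_train Pulses per train.
#' @param n_trains Number of trains (or continuous-light trials).
#' @param inter_train_interval_s Onset-to-onset spacing of consecutive
#'   trains/trials, seconds.
#' @param baseline_s Light-free period before the first delivery, seconds.
#' @param light_duration_s Continuous-light duration per trial, seconds
#'   (continuous mode).
#' @return A validated list of class `stim_protocol`.
#' @examples
#' stim_protocol("pulse_train", frequency_hz = 20, n_trains = 61)
#' stim_protocol("continuous", n_trains = 5)
#' @export
stim_protocol <- function(kind = c("pulse_train", "continuous"),
                          pulse_width_ms = 10,
                          frequency_hz = 20,
                          pulses_per_train = 100,
                          n_trains = 1,
                          inter_train_interval_s = 120,
                          baseline_s = 5,
                          light_duration_s = 10) {
  kind <- match.arg(kind)
  check_scalar_number(pulse_width_ms, "pulse_width_ms", lower = 1e-9)
  check_scalar_number(frequency_hz, "frequency_hz", lower = 1e-9)
  check_scalar_number(pulses_per_train, "pulses_per_train", lower = 1)
  check_scalar_number(n_trains, "n_trains", lower = 1)
  check_scalar_number(inter_train_interval_s, "inter_train_interval_s", lower = 0)
  check_scalar_number(baseline_s, "baseline_s", lower = 0)
  check_scalar_number(light_duration_s, "light_duration_s", lower = 1e-9)
  if (kind == "pulse_train" && pulse_width_ms >= 1000 / frequency_hz) {
    stop_field("pulse_width_ms", "must be shorter than the inter-pulse interval")
  }
  if (n_trains > 1) {
    span <- if (kind == "pulse_train") {
      (pulses_per_train - 1) / frequency_hz + pulse_width_ms / 1000
    } else {
      light_duration_s
    }
    if (inter_train_interval_s <= span) {
      stop_field("inter_train_interval_s", "trains/trials would overlap")
    }
  }
  structure(
    list(kind = kind, pulse_width_ms = pulse_width_ms,
         frequency_hz = frequency_hz,
         pulses_per_train = as.integer(pulses_per_train),
         n_trains = as.integer(n_trains),
         inter_train_interval_s = inter_train_interval_s,
         baseline_s = baseline_s, light_duration_s = light_duration_s),
    class = "stim_protocol"
  )
}

#' Named stimulation presets
#'
#' Canonical protocols for the three experiments the package emulates:
#' `"chr2-freqs"` (10-pulse trains at 1, 5, 10 and 20 Hz), `"chr2-20hz-2hr"`
#' (100 pulses at 20 Hz per train, 61 trains, 2 min onset spacing) and
#' `"nphr-10s"` (five 10 s continuous-light trials).
#'
#' @param name Preset name.
#' @return For `"chr2-freqs"`, a named list of `stim_protocol`s (one per
#'   frequency); otherwise a single `stim_protocol`.
#' @export
stim_preset <- function(name = c("chr2-20hz-2hr", "chr2-freqs", "nphr-10s")) {
  name <- match.arg(name)
  switch(name,
    "chr2-20hz-2hr" = stim_protocol("pulse_train", frequency_hz = 20,
                                    pulses_per_train = 100, n_trains = 61,
                                    inter_train_interval_s = 120),
    "chr2-freqs" = lapply(
      setNames(c(1, 5, 10, 20), paste0("hz", c(1, 5, 10, 20))),
      function(f) stim_protocol("pulse_train", frequency_hz = f,
                                pulses_per_train = 10, n_trains = 1,
                                inter_train_interval_s = 30)
    ),
    "nphr-10s" = stim_protocol("continuous", n_trains = 5,
                               inter_train_interval_s = 30,
                               light_duration_s = 10)
  )
}

# Pulse/trial onset layout implied by a protocol -------------------------

protocol_pulses <- function(protocol) {
  if (protocol$kind == "pulse_train") {
    ipi <- 1 / protocol$frequency_hz
    onsets <- as.vector(outer(
      (seq_len(protocol$pulses_per_train) - 1) * ipi,
      protocol$baseline_s + (seq_len(protocol$n_trains) - 1) * protocol$inter_train_interval_s,
      "+"
    ))
    train <- rep(seq_len(protocol$n_trains), each = protocol$pulses_per_train)
    width <- protocol$pulse_width_ms / 1000
  } else {
    onsets <- protocol$baseline_s +
      (seq_len(protocol$n_trains) - 1) * protocol$inter_train_interval_s
    train <- seq_len(protocol$n_trains)
    width <- protocol$light_duration_s
  }
  tibble(on_s = onsets, off_s = onsets + width, train = train)
}

protocol_duration_s <- function(protocol) {
  p <- protocol_pulses(protocol)
  max(p$off_s) + protocol$baseline_s
}
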