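# Synthetic extracellular sessions with known ground truth.
#
# Spike times are generated first (spontaneous + light-evoked, or
# spontaneous - silenced + rebound), a 2 ms refractory floor is enforced,
# and only then is the voltage trace rendered by adding one fixed biphasic
# template per spike to Gaussian background noise. The event log therefore
# IS the ground truth for every downstream detector and statistic.

# -- elementary point-process generators ---------------------------------

sim_homog_poisson <- function(rate_hz, t0, t1) {
  if (rate_hz <= 0 || t1 <= t0) return(numeric())
  n <- rpois(1, rate_hz * (t1 - t0))
  sort(runif(n, t0, t1))
}

# thinning (Lewis & Shedler) against a known rate ceiling
sim_inhom_poisson <- function(rate_fun, rate_max, t0, t1) {
  cand <- sim_homog_poisson(rate_max, t0, t1)
  if (!length(cand)) return(cand)
  keep <- runif(length(cand)) < rate_fun(cand) / rate_max
  cand[keep]
}

spont_rate_fun <- function(config) {
  r <- config$spont_rate_hz
  if (config$spont_mode == "poisson") {
    list(f = function(t) rep(r, length(t)), max = r)
  } else {
    d <- config$phasic_depth
    p <- config$phasic_period_s
    list(f = function(t) r * (1 + d * sin(2 * pi * t / p)), max = r * (1 + d))
  }
}

enforce_refractory <- function(times_s, refractory_s) {
  if (length(times_s) < 2 || refractory_s <= 0) return(seq_along(times_s))
  keep <- logical(length(times_s))
  keep[1] <- TRUE
  last <- times_s[1]
  for (i in 2:length(times_s)) {
    if (times_s[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- times_s[i]
    }
  }
  which(keep)
}

#' Simulate a spontaneous spike train
#'
#' Homogeneous Poisson firing, or sinusoidally rate-modulated ("phasic")
#' inhomogeneous Poisson firing emulating periodic network-driven activity.
#' A 2 ms refractory floor is applied.
#'
#' @param rate_hz Mean rate, Hz.
#' @param duration_s Duration, seconds.
#' @param mode `"poisson"` or `"phasic"`.
#' @param period_s,depth Phasic modulation period (s) and depth in `[0, 1]`.
#' @param refractory_ms Minimum inter-spike separation, ms.
#' @param seed Integer RNG seed.
#' @return A `spike_train` with `source = "ground_truth"`.
#' @examples
#' simulate_spike_train(5, 10, seed = 1)
#' @export
simulate_spike_train <- function(rate_hz, duration_s,
                                 mode = c("poisson", "phasic"),
                                 period_s = 0.5, depth = 0.8,
                                 refractory_ms = 2, seed = 1L) {
  mode <- match.arg(mode)
  check_scalar_number(rate_hz, "rate_hz", lower = 0)
  check_scalar_number(duration_s, "duration_s", lower = 1e-9)
  check_prob(depth, "depth")
  times <- withr::with_seed(as.integer(seed), {
    if (mode == "poisson") {
      sim_homog_poisson(rate_hz, 0, duration_s)
    } else {
      f <- function(t) rate_hz * (1 + depth * sin(2 * pi * t / period_s))
      sim_inhom_poisson(f, rate_hz * (1 + depth), 0, duration_s)
    }
  })
  # finite RNG granularity can produce exact ties at refractory 0; a point
  # process has distinct points, so drop them silently
  times <- unique(times[enforce_refractory(times, refractory_ms / 1000)])
  spike_train(times, duration_s, source = "ground_truth")
}

# -- latency distribution ------------------------------------------------

# truncated Gaussian on (0, upper); mode at `mode_s` when inside the support
sample_latency <- function(n, mode_s, sd_s, upper_s) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- rnorm(length(todo), mode_s, sd_s)
    ok <- draw > 0 & draw <= upper_s
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# -- trace rendering -----------------------------------------------------

render_trace <- function(true_times_s, config, duration_s) {
  fs <- config$sampling_rate_hz
  n <- round(duration_s * fs)
  uv <- rnorm(n, 0, config$noise_sd)
  w <- spike_waveform(config$spike_amplitude, config$spike_width_ms, fs)
  nw <- length(w)
  # a spike's ground-truth time marks the template extremum (the feature a
  # threshold detector reports), so the template is inserted trough-aligned
  trough <- which.max(abs(w)) - 1L
  for (t in true_times_s) {
    i0 <- round(t * fs) + 1 - trough
    j0 <- max(i0, 1L)
    i1 <- min(i0 + nw - 1, n)
    if (j0 <= n && i1 >= j0) uv[j0:i1] <- uv[j0:i1] + w[(j0 - i0 + 1):(i1 - i0 + 1)]
  }
  new_voltage_trace(tibble(time_s = (seq_len(n) - 1) / fs, uv = uv), fs)
}

new_ground_truth <- function(spikes, per_pulse = NULL, per_trial = NULL) {
  structure(list(spikes = spikes, per_pulse = per_pulse, per_trial = per_trial),
            class = "ground_truth")
}

#' Generate a synthetic photoactivation (ChR2-style) session
#'
#' Emulates pulse-train photostimulation of a transduced unit: spontaneous
#' background firing plus, for each light pulse, a light-evoked spike with
#' probability `evoked_prob` at a latency drawn from a truncated Gaussian
#' whose mode is `latency_mode_ms`, optionally followed (with probability
#' `doublet_prob`) by a second evoked spike 3-8 ms later within the same
#' inter-pulse interval.
#'
#' @param config A [synth_config()].
#' @param protocol A [stim_protocol()] with `kind = "pulse_train"`.
#' @param render `"trace"` renders the full voltage trace; `"events"` skips
#'   trace synthesis (TTL and ground truth only), useful for long sessions
#'   analysed at the spike-train level.
#' @return A list of class `synth_session` with elements `trace`
#'   (`voltage_trace` or `NULL`), `ttl` (interval table), `truth`
#'   (`ground_truth`: `$spikes` tibble with `time_s`, `evoked`, `pulse`;
#'   `$per_pulse` tibble with evoked-spike counts per pulse), `config`,
#'   `protocol` and `duration_s`.
#' @examples
#' ses <- generate_chr2_session(
#'   synth_config(spont_rate_hz = 0, seed = 7),
#'   stim_protocol("pulse_train", frequency_hz = 20, pulses_per_train = 20,
#'                 n_trains = 2, inter_train_interval_s = 10),
#'   render = "events")
#' nrow(ses$ttl)
#' @export
generate_chr2_session <- function(config, protocol, render = c("trace", "events")) {
  render <- match.arg(render)
  stopifnot(inherits(config, "synth_config"), inherits(protocol, "stim_protocol"))
  if (protocol$kind != "pulse_train") {
    stop_field("protocol$kind", "photoactivation sessions need a pulse_train protocol")
  }
  pulses <- protocol_pulses(protocol)
  duration_s <- if (is.na(config$duration_s)) protocol_duration_s(protocol) else config$duration_s
  if (max(pulses$off_s) > duration_s) {
    stop_field("duration_s", "shorter than the stimulation protocol")
  }
  ipi <- 1 / protocol$frequency_hz
  res <- withr::with_seed(config$seed, {
    sp <- spont_rate_fun(config)
    spont <- if (config$spont_rate_hz > 0) {
      sim_inhom_poisson(sp$f, sp$max, 0, duration_s)
    } else numeric()
    np <- nrow(pulses)
    evoked_first <- runif(np) < config$evoked_prob
    ev_idx <- which(evoked_first)
    lat <- numeric(0)
    if (length(ev_idx)) {
      # centred mid-bin so the modal 1 ms latency-histogram bin is
      # [latency_mode_ms, latency_mode_ms + 1), the bin an onset-latency
      # mode is read from
      lat <- sample_latency(length(ev_idx), (config$latency_mode_ms + 0.5) / 1000,
                            config$latency_jitter_ms / 1000, ipi)
    }
    t_first <- pulses$on_s[ev_idx] + lat
    is_doublet <- runif(length(ev_idx)) < config$doublet_prob
    gap <- runif(sum(is_doublet), 0.003, 0.008)
    t_second <- t_first[is_doublet] + gap
    p_second <- ev_idx[is_doublet]
    in_ipi <- t_second <= pulses$on_s[p_second] + ipi
    ev <- tibble(
      time_s = c(t_first, t_second[in_ipi]),
      evoked = TRUE,
      pulse = c(ev_idx, p_second[in_ipi])
    )
    all <- bind_rows(
      tibble(time_s = spont, evoked = FALSE, pulse = NA_integer_),
      ev
    )
    all <- all[all$time_s >= 0 & all$time_s < duration_s, , drop = FALSE]
    all <- all[order(all$time_s), , drop = FALSE]
    all <- all[enforce_refractory(all$time_s, config$refractory_ms / 1000), , drop = FALSE]
    trace <- if (render == "trace") render_trace(all$time_s, config, duration_s) else NULL
    list(all = all, trace = trace)
  })
  spikes <- as_tibble(res$all)
  per_pulse <- pulses
  per_pulse$pulse <- seq_len(nrow(pulses))
  cnt <- tabulate(spikes$pulse[spikes$evoked & !is.na(spikes$pulse)], nbins = nrow(pulses))
  per_pulse$count <- cnt
  structure(
    list(trace = res$trace,
         ttl = ttl(pulses$on_s, pulses$off_s),
         truth = new_ground_truth(spikes, per_pulse = per_pulse),
         config = config, protocol = protocol, duration_s = duration_s),
    class = "synth_session"
  )
}

#' Generate a synthetic photoinhibition (NpHR-style) session
#'
#' Emulates continuous-light silencing of a spontaneously active unit: each
#' would-be spontaneous spike falling inside a light-on interval is deleted
#' with probability `silencing_efficacy` (survivors are "breakthrough"
#' spikes); when `rebound_gain > 1` the firing rate after each light offset
#' is transiently multiplied by a factor decaying exponentially with
#' `rebound_tau_s`, emulating post-inhibitory rebound excitability.
#'
#' @inheritParams generate_chr2_session
#' @param protocol A [stim_protocol()] with `kind = "continuous"`.
#' @return A `synth_session` list as in [generate_chr2_session()]; the
#'   ground truth carries `$per_trial` (columns `trial`, `on_s`, `off_s`,
#'   `breakthrough`) instead of `$per_pulse`.
#' @examples
#' ses <- generate_nphr_session(
#'   synth_config(spont_rate_hz = 2, silencing_efficacy = 1, seed = 3),
#'   stim_protocol("continuous", n_trains = 3, inter_train_interval_s = 30),
#'   render = "events")
#' ses$truth$per_trial
#' @export
generate_nphr_session <- function(config, protocol, render = c("trace", "events")) {
  render <- match.arg(render)
  stopifnot(inherits(config, "synth_config"), inherits(protocol, "stim_protocol"))
  if (protocol$kind != "continuous") {
    stop_field("protocol$kind", "silencing sessions need a continuous protocol")
  }
  if (config$spont_rate_hz <= 0) {
    warn("spont_rate_hz is 0: there is no spontaneous activity to silence")
  }
  trials <- protocol_pulses(protocol)
  duration_s <- if (is.na(config$duration_s)) protocol_duration_s(protocol) else config$duration_s
  if (max(trials$off_s) > duration_s) {
    stop_field("duration_s", "shorter than the stimulation protocol")
  }
  res <- withr::with_seed(config$seed, {
    sp <- spont_rate_fun(config)
    gain <- config$rebound_gain
    tau <- config$rebound_tau_s
    offs <- trials$off_s
    rebound_mult <- function(t) {
      m <- rep(1, length(t))
      if (gain != 1) {
        for (o in offs) {
          after <- t >= o
          m[after] <- pmax(m[after], 1 + (gain - 1) * exp(-(t[after] - o) / tau))
        }
      }
      m
    }
    rate_fun <- function(t) sp$f(t) * rebound_mult(t)
    rate_max <- sp$max * max(gain, 1)
    cand <- sim_inhom_poisson(rate_fun, rate_max, 0, duration_s)
    in_light <- rep(FALSE, length(cand))
    for (k in seq_len(nrow(trials))) {
      in_light <- in_light | (cand >= trials$on_s[k] & cand < trials$off_s[k])
    }
    silenced <- in_light & (runif(length(cand)) < config$silencing_efficacy)
    keep <- cand[!silenced]
    keep <- keep[enforce_refractory(keep, config$refractory_ms / 1000)]
    trace <- if (render == "trace") render_trace(keep, config, duration_s) else NULL
    list(times = keep, trace = trace)
  })
  spikes <- tibble(time_s = res$times, evoked = FALSE, pulse = NA_integer_)
  per_trial <- tibble(
    trial = seq_len(nrow(trials)),
    on_s = trials$on_s, off_s = trials$off_s,
    breakthrough = vapply(seq_len(nrow(trials)), function(k) {
      any(spikes$time_s >= trials$on_s[k] & spikes$time_s < trials$off_s[k])
    }, logical(1))
  )
  structure(
    list(trace = res$trace,
         ttl = ttl(trials$on_s, trials$off_s),
         truth = new_ground_truth(spikes, per_trial = per_trial),
         config = config, protocol = protocol, duration_s = duration_s),
    class = "synth_session"
  )
}

#' Ground-truth spike train of a synthetic session
#'
#' @param session A `synth_session`.
#' @return A `spike_train` with `source = "ground_truth"`.
#' @export
true_spike_train <- function(session) {
  stopifnot(inherits(session, "synth_session"))
  spike_train(session$truth$spikes$time_s, session$duration_s,
              source = "ground_truth")
}
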