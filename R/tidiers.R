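# broom-style tidiers for the result objects

#' @export
tidy.fidelity_result <- function(x, ...) x$per_position

#' @export
glance.fidelity_result <- function(x, ...) {
  tibble(mean_prob = x$mean_prob, sem_prob = x$sem_prob,
         latency_mode_ms = x$latency_mode_ms,
         n_trains = x$n_trains, n_pulses = x$n_pulses,
         n_latencies = length(x$latencies_ms))
}

#' @export
tidy.silencing_result <- function(x, ...) x$per_trial

#' @export
glance.silencing_result <- function(x, ...) {
  tibble(n_trials = x$n_trials,
         n_breakthrough_trials = x$n_breakthrough_trials,
         breakthrough_fraction = x$breakthrough_fraction,
         mean_pre_rate_hz = x$mean_pre_rate_hz,
         mean_during_rate_hz = x$mean_during_rate_hz,
         mean_post_rate_hz = x$mean_post_rate_hz,
         rebound_index = x$rebound_index)
}

#' @export
tidy.ach_result <- function(x, ...) as_tibble(x)

#' @export
glance.ach_result <- function(x, ...) {
  tibble(n_spikes = attr(x, "n_spikes"), n_pairs = attr(x, "n_pairs"),
         bin_s = attr(x, "bin_s"), max_lag_s = attr(x, "max_lag_s"),
         classification = classification(x),
         n_peaks = length(attr(x, "peak_lags_s") %||% numeric()),
         first_peak_lag_s = (attr(x, "peak_lags_s") %||% numeric())[1] %|na|% NA_real_)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf(
    "<fidelity_result> %d trains x %d pulses\n  mean spikes/pulse %.3f +/- %.3f (SEM over %s); latency mode %s ms\n",
    x$n_trains, x$n_pulses / max(x$n_trains, 1), x$mean_prob, x$sem_prob,
    x$sem_over,
    if (is.na(x$latency_mode_ms)) "absent" else format(x$latency_mode_ms)))
  invisible(x)
}

#' @export
print.silencing_result <- function(x, ...) {
  cat(sprintf(
    "<silencing_result> %d trials; breakthrough %d/%d (%.0f%%)\n  rates (Hz): pre %.2f, during %.2f, post %.2f; rebound index %.2f\n",
    x$n_trials, x$n_breakthrough_trials, x$n_trials,
    100 * x$breakthrough_fraction, x$mean_pre_rate_hz,
    x$mean_during_rate_hz, x$mean_post_rate_hz, x$rebound_index))
  invisible(x)
}
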