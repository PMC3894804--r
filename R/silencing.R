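#' Silencing and rebound metrics for continuous-light trials
#'
#' For each continuous-light trial, computes the firing rate in a pre-light
#' baseline window `[on - pre_s, on)`, the light-on window `[on, off)`, and
#' a post-light window `[off, off + post_s)`. A trial is a breakthrough
#' trial when at least one spike escapes suppression during light. The
#' rebound index is the ratio of post- to pre-light rate (per trial where
#' the baseline is non-zero, and pooled over all trials). Pre/post windows
#' that would reach into a neighbouring trial's light period are truncated
#' with a warning.
#'
#' @param spikes A `spike_train`.
#' @param schedule A `pulse_schedule` with `protocol_kind = "continuous"`.
#' @param pre_s,post_s Baseline and post-light window lengths, seconds.
#' @return A list of class `silencing_result`:
#'   * `per_trial`: tibble with `trial`, `on_s`, `off_s`, `pre_rate_hz`,
#'     `during_rate_hz`, `post_rate_hz`, `breakthrough_count`,
#'     `breakthrough`, `rebound_index`;
#'   * `n_trials`, `n_breakthrough_trials`, `breakthrough_fraction`;
#'   * `mean_pre_rate_hz`, `mean_during_rate_hz`, `mean_post_rate_hz`;
#'   * `rebound_index`: pooled post/pre rate ratio (`NA` when no baseline
#'     spikes).
#' @examples
#' ses <- generate_nphr_session(
#'   synth_config(spont_rate_hz = 3, silencing_efficacy = 1, seed = 9),
#'   stim_protocol("continuous", n_trains = 5, inter_train_interval_s = 30),
#'   render = "events")
#' silencing_metrics(true_spike_train(ses), parse_schedule(ses$ttl))$breakthrough_fraction
#' @export
silencing_metrics <- function(spikes, schedule, pre_s = 5, post_s = 5) {
  stopifnot(inherits(spikes, "spike_train"), inherits(schedule, "pulse_schedule"))
  if (protocol_kind(schedule) != "continuous") {
    abort("silencing metrics require a continuous-light schedule",
          class = "optrode_protocol_error")
  }
  check_scalar_number(pre_s, "pre_s", lower = 1e-9)
  check_scalar_number(post_s, "post_s", lower = 1e-9)
  sched <- as_tibble(schedule)
  n_tr <- nrow(sched)
  if (n_tr == 0) abort("empty schedule")
  pre_lo <- pmax(sched$on_s - pre_s, c(0, sched$off_s[-n_tr]))
  post_hi <- pmin(sched$off_s + post_s,
                  c(sched$on_s[-1], train_duration_s(spikes)))
  if (any(pre_lo > sched$on_s - pre_s + 1e-12) ||
      any(post_hi < sched$off_s + post_s - 1e-12)) {
    warn("pre/post windows truncated to avoid neighbouring trials")
  }
  rate <- function(lo, hi) {
    vapply(seq_along(lo), function(k) {
      if (hi[k] <= lo[k]) return(NA_real_)
      firing_rate(spikes, c(lo[k], hi[k]))
    }, numeric(1))
  }
  t <- spike_times(spikes)
  during_count <- vapply(seq_len(n_tr), function(k) {
    sum(t >= sched$on_s[k] & t < sched$off_s[k])
  }, numeric(1))
  per_trial <- tibble(
    trial = seq_len(n_tr),
    on_s = sched$on_s, off_s = sched$off_s,
    pre_rate_hz = rate(pre_lo, sched$on_s),
    during_rate_hz = during_count / (sched$off_s - sched$on_s),
    post_rate_hz = rate(sched$off_s, post_hi),
    breakthrough_count = as.integer(during_count),
    breakthrough = during_count > 0
  )
  per_trial$rebound_index <- ifelse(per_trial$pre_rate_hz > 0,
                                    per_trial$post_rate_hz / per_trial$pre_rate_hz,
                                    NA_real_)
  mean_pre <- mean(per_trial$pre_rate_hz, na.rm = TRUE)
  mean_post <- mean(per_trial$post_rate_hz, na.rm = TRUE)
  structure(
    list(per_trial = per_trial,
         n_trials = n_tr,
         n_breakthrough_trials = sum(per_trial$breakthrough),
         breakthrough_fraction = mean(per_trial$breakthrough),
         mean_pre_rate_hz = mean_pre,
         mean_during_rate_hz = mean(per_trial$during_rate_hz),
         mean_post_rate_hz = mean_post,
         rebound_index = if (mean_pre > 0) mean_post / mean_pre else NA_real_),
    class = "silencing_result"
  )
}

#' Post-offset rebound time course
#'
#' Average firing rate in fixed-width bins after light offset, pooled over
#' trials — a descriptive view of transient rebound excitability (the
#' default 1 s window at 100 ms resolution matches the timescale on which
#' post-inhibitory rebound is expected).
#'
#' @param spikes A `spike_train`.
#' @param schedule A continuous-light `pulse_schedule`.
#' @param window_s Length of the post-offset window, seconds.
#' @param bin_s Bin width, seconds.
#' @return A `psth` tibble aligned to light offsets.
#' @export
rebound_profile <- function(spikes, schedule, window_s = 1, bin_s = 0.1) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (protocol_kind(schedule) != "continuous") {
    abort("rebound profile requires a continuous-light schedule",
          class = "optrode_protocol_error")
  }
  psth(spikes, event_times_s = schedule$off_s, window_s = c(0, window_s),
       bin_s = bin_s)
}
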