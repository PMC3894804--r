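#' Peristimulus time histogram
#'
#' Bins spike times relative to a set of alignment events. Bin edges run
#' from `window_s[1]` to `window_s[2]` in steps of `bin_s` (half-open bins
#' `[left, right)`); the binned counts conserve the total number of spikes
#' falling inside the windows. The rate form divides the summed counts by
#' `n_events * bin_s`; the SEM is computed across events per bin.
#'
#' @param spikes A `spike_train`.
#' @param event_times_s Alignment event times (e.g. pulse or trial onsets),
#'   seconds; at least one.
#' @param window_s Length-2 window relative to each event, seconds.
#' @param bin_s Bin width, seconds; must divide the window length (within
#'   one part in 10^6).
#' @return A tibble of class `psth` with columns `bin_left_s`, `bin_mid_s`,
#'   `bin_right_s`, `count`, `rate_hz`, `sem_hz`; attribute `n_events`.
#' @examples
#' tr <- spike_train(c(0.105, 1.107, 2.109), duration_s = 3)
#' psth(tr, event_times_s = c(0.1, 1.1, 2.1), window_s = c(0, 0.05), bin_s = 0.001)
#' @export
psth <- function(spikes, event_times_s, window_s = c(-0.05, 0.25), bin_s = 0.001) {
  stopifnot(inherits(spikes, "spike_train"))
  if (!length(event_times_s)) abort("need at least one alignment event")
  if (length(window_s) != 2 || window_s[2] <= window_s[1]) {
    stop_field("window_s", "must be an increasing (start, end) pair")
  }
  check_scalar_number(bin_s, "bin_s", lower = 1e-12)
  span <- window_s[2] - window_s[1]
  n_bins <- round(span / bin_s)
  if (abs(n_bins * bin_s - span) > 1e-6 * span || n_bins < 1) {
    stop_field("bin_s", "must divide the window length")
  }
  t <- spike_times(spikes)
  n_ev <- length(event_times_s)
  counts <- matrix(0L, nrow = n_ev, ncol = n_bins)
  for (e in seq_len(n_ev)) {
    rel <- t - event_times_s[e]
    rel <- rel[rel >= window_s[1] & rel < window_s[2]]
    if (length(rel)) {
      idx <- pmin(floor((rel - window_s[1]) / bin_s + 1e-9), n_bins - 1) + 1
      tb <- tabulate(idx, nbins = n_bins)
      counts[e, ] <- tb
    }
  }
  total <- colSums(counts)
  rate_by_event <- counts / bin_s
  out <- tibble(
    bin_left_s = window_s[1] + (seq_len(n_bins) - 1) * bin_s,
    bin_mid_s = window_s[1] + (seq_len(n_bins) - 0.5) * bin_s,
    bin_right_s = window_s[1] + seq_len(n_bins) * bin_s,
    count = as.integer(total),
    rate_hz = total / (n_ev * bin_s),
    sem_hz = if (n_ev > 1) apply(rate_by_event, 2, sd) / sqrt(n_ev) else NA_real_
  )
  structure(out, n_events = n_ev, bin_s = bin_s,
            class = c("psth", class(tibble())))
}

#' Mean firing rate in a time window
#'
#' Spike count in the half-open window `[start_s, end_s)` divided by its
#' duration.
#'
#' @param spikes A `spike_train`.
#' @param window Length-2 numeric `(start_s, end_s)`, `end_s > start_s`.
#' @return Rate in Hz.
#' @examples
#' firing_rate(spike_train((1:10) / 2, 5), c(0, 5))  # 2 Hz
#' @export
firing_rate <- function(spikes, window) {
  stopifnot(inherits(spikes, "spike_train"))
  if (length(window) != 2 || window[2] <= window[1]) {
    stop_field("window", "must be an increasing (start, end) pair")
  }
  t <- spike_times(spikes)
  sum(t >= window[1] & t < window[2]) / (window[2] - window[1])
}
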