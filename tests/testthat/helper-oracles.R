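# Independent oracles used across the suite. These deliberately use naive
# O(n^2) / scan implementations, not the package's own code paths.

# all-pairs ACH count with the documented binning convention: half-open
# [k*bin, (k+1)*bin) with a 1e-9 relative guard; lags of exactly max_lag
# land in the final bin
brute_force_ach <- function(times, bin_s, max_lag_s) {
  n_bins <- ceiling(max_lag_s / bin_s - 1e-9)
  counts <- integer(n_bins)
  times <- sort(times)
  n <- length(times)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- times[j] - times[i]
        if (d <= max_lag_s) {
          k <- min(floor(d / bin_s + 1e-9), n_bins - 1) + 1
          counts[k] <- counts[k] + 1L
        }
      }
    }
  }
  counts
}

# nearest-neighbour matching of detections to ground truth
match_spikes <- function(detected_s, true_s, tol_s = 5e-4) {
  matched <- vapply(true_s, function(t) any(abs(detected_s - t) <= tol_s), logical(1))
  false_pos <- vapply(detected_s, function(t) !any(abs(true_s - t) <= tol_s), logical(1))
  list(recall = if (length(true_s)) mean(matched) else NA_real_,
       precision = if (length(detected_s)) 1 - mean(false_pos) else NA_real_,
       n_false_pos = sum(false_pos))
}

# O(n) scan grouping of pulse onsets into trains by a gap threshold
brute_force_trains <- function(onsets, gap_s) {
  if (!length(onsets)) return(integer())
  g <- 1L
  out <- integer(length(onsets))
  out[1] <- 1L
  for (i in seq_along(onsets)[-1]) {
    if (onsets[i] - onsets[i - 1] > gap_s) g <- g + 1L
    out[i] <- g
  }
  out
}

# direct interval-membership count of spikes inside light-on windows
brute_force_breakthrough <- function(times, on_s, off_s) {
  vapply(seq_along(on_s), function(k) {
    any(times >= on_s[k] & times < off_s[k])
  }, logical(1))
}

quick_chr2 <- function(..., protocol = NULL, render = "events") {
  protocol <- protocol %||% stim_protocol(
    "pulse_train", frequency_hz = 20, pulses_per_train = 50,
    n_trains = 4, inter_train_interval_s = 10)
  generate_chr2_session(synth_config(...), protocol, render = render)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
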