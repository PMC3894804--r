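#' Autocorrelation histogram of a spike train
#'
#' Counts time differences between all ordered spike pairs — consecutive
#' and non-consecutive alike — up to `max_lag_s`, in half-open bins
#' `[k * bin_s, (k+1) * bin_s)` over positive lags (the histogram is
#' symmetric, so negative lags carry no extra information; zero-lag
#' self-pairs are excluded). Periodic peaks mark phasic (rhythmically
#' firing) units.
#'
#' @param spikes A `spike_train` (or bare numeric vector of spike times).
#' @param bin_s Bin width, seconds (default 20 ms).
#' @param max_lag_s Maximum lag, seconds (default 2 s).
#' @return A tibble of class `ach_result` with columns `lag_left_s`,
#'   `lag_mid_s`, `lag_right_s`, `count`; attributes `n_spikes`, `bin_s`,
#'   `max_lag_s`, `n_pairs` (total pairs with lag at or under `max_lag_s`)
#'   and `duration_s`.
#' @examples
#' autocorrelogram(spike_train(c(0, 0.010, 0.030), 1))
#' @export
autocorrelogram <- function(spikes, bin_s = 0.020, max_lag_s = 2.0) {
  check_scalar_number(bin_s, "bin_s", lower = 1e-12)
  check_scalar_number(max_lag_s, "max_lag_s", lower = bin_s)
  t <- if (inherits(spikes, "spike_train")) spike_times(spikes) else sort(as.numeric(spikes))
  dur <- if (inherits(spikes, "spike_train")) train_duration_s(spikes) else
    (if (length(t)) max(t) else 0)
  n_bins <- ceiling(max_lag_s / bin_s - 1e-9)
  counts <- integer(n_bins)
  n <- length(t)
  if (n >= 2) {
    # accumulate order-k differences while any stay within max_lag
    for (k in seq_len(n - 1)) {
      d <- t[(k + 1):n] - t[1:(n - k)]
      d <- d[d <= max_lag_s]
      if (!length(d)) break
      # half-open bins with a one-part-in-10^9 guard against the binary
      # representation of decimal spike times (e.g. 0.03 - 0.01)
      idx <- pmin(floor(d / bin_s + 1e-9), n_bins - 1) + 1
      counts <- counts + tabulate(idx, nbins = n_bins)
    }
  }
  out <- tibble(
    lag_left_s = (seq_len(n_bins) - 1) * bin_s,
    lag_mid_s = (seq_len(n_bins) - 0.5) * bin_s,
    lag_right_s = seq_len(n_bins) * bin_s,
    count = as.integer(counts)
  )
  structure(out, n_spikes = n, bin_s = bin_s, max_lag_s = max_lag_s,
            n_pairs = sum(counts), duration_s = dur,
            class = c("ach_result", class(tibble())))
}

#' Classify a unit as phasic or non-phasic from its autocorrelogram
#'
#' A unit is called phasic when at least one histogram bin at lag of at
#' least `2 * bin_s` rises significantly above the flat baseline expected
#' of an unmodulated (Poisson-like) train. The baseline is estimated as the
#' mean count over the upper half of the lag range; the spread used for the
#' exceedance test is the Poisson counting noise `sqrt(baseline)`, so a
#' rhythmic unit whose oscillation also inflates the tail variance is not
#' penalised. The default exceedance threshold `z` applies a Bonferroni
#' correction over the tested bins at family-wise level `alpha`, keeping
#' the false-phasic rate of a homogeneous Poisson train at about `alpha`.
#' Histograms with fewer than `min_pairs` total pairs are `unclassifiable`.
#'
#' @param ach An `ach_result` from [autocorrelogram()].
#' @param z Exceedance threshold in baseline SDs; `NULL` (default) uses
#'   `qnorm(1 - alpha / n_tested_bins)`.
#' @param alpha Family-wise false-positive rate used when `z` is `NULL`.
#' @param min_pairs Minimum total pair count for classification.
#' @return The input `ach_result` with added attributes `classification`
#'   (`"phasic"`, `"non_phasic"` or `"unclassifiable"`), `peak_lags_s`
#'   (bin centers of significant peaks), `baseline`, `spread` and
#'   `z_threshold`.
#' @examples
#' tr <- simulate_spike_train(8, 300, mode = "phasic", depth = 0.9, seed = 2)
#' classification(classify_phasic(autocorrelogram(tr)))
#' @export
classify_phasic <- function(ach, z = NULL, alpha = 0.01, min_pairs = 100) {
  stopifnot(inherits(ach, "ach_result"))
  bin_s <- attr(ach, "bin_s")
  eligible <- ach$lag_left_s >= 2 * bin_s - 1e-12
  if (attr(ach, "n_pairs") < min_pairs || !any(eligible)) {
    attr(ach, "classification") <- "unclassifiable"
    attr(ach, "peak_lags_s") <- numeric()
    return(ach)
  }
  upper <- ach$lag_left_s >= attr(ach, "max_lag_s") / 2
  baseline <- mean(ach$count[upper])
  spread <- sqrt(max(baseline, 1))
  if (is.null(z)) z <- qnorm(1 - alpha / sum(eligible))
  hit <- eligible & (ach$count > baseline + z * spread)
  attr(ach, "classification") <- if (any(hit)) "phasic" else "non_phasic"
  attr(ach, "peak_lags_s") <- peak_cluster_lags(ach, hit, which(eligible)[1])
  attr(ach, "baseline") <- baseline
  attr(ach, "spread") <- spread
  attr(ach, "z_threshold") <- z
  ach
}

# Reduce significant bins to one peak lag per contiguous run (the run's
# maximal count). A run starting at the first testable bin is the shoulder
# of the central zero-lag peak, not evidence of a rhythm at that lag, and
# is not reported as a peak.
peak_cluster_lags <- function(ach, hit, first_eligible) {
  idx <- which(hit)
  if (!length(idx)) return(numeric())
  run <- cumsum(c(1L, as.integer(diff(idx) > 1)))
  peaks <- vapply(split(idx, run), function(b) b[which.max(ach$count[b])], integer(1))
  starts <- vapply(split(idx, run), min, integer(1))
  peaks <- peaks[starts != first_eligible]
  unname(ach$lag_mid_s[peaks])
}

#' Classification label of an autocorrelogram
#'
#' @param ach An `ach_result` (after [classify_phasic()]).
#' @return `"phasic"`, `"non_phasic"` or `"unclassifiable"` (`NA` if not
#'   yet classified).
#' @export
classification <- function(ach) {
  attr(ach, "classification") %||% NA_character_
}
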