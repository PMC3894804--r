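#' Construct a voltage trace
#'
#' A voltage trace is a tibble with columns `time_s` and `uv` (microvolts),
#' uniformly sampled, carrying the sampling rate and channel label as
#' attributes. All downstream filtering and detection functions take this
#' tibble as their first argument.
#'
#' @param uv Numeric vector of voltage samples, in microvolts. All values
#'   must be finite.
#' @param sampling_rate_hz Sampling rate in Hz (positive scalar).
#' @param start_time_s Time of the first sample in seconds (default 0).
#' @param channel_label Free-text channel name.
#'
#' @return A tibble of class `voltage_trace` with columns `time_s`, `uv`.
#' @examples
#' tr <- voltage_trace(rnorm(2000), sampling_rate_hz = 20000)
#' sampling_rate(tr)
#' @export
voltage_trace <- function(uv, sampling_rate_hz = 20000, start_time_s = 0,
                          channel_label = "ch1") {
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  check_scalar_number(start_time_s, "start_time_s")
  if (!is.numeric(uv)) stop_field("uv", "must be numeric")
  if (length(uv) && any(!is.finite(uv))) stop_field("uv", "must be finite")
  n <- length(uv)
  out <- tibble(
    time_s = start_time_s + (seq_len(n) - 1) / sampling_rate_hz,
    uv = as.numeric(uv)
  )
  new_voltage_trace(out, sampling_rate_hz, channel_label)
}

new_voltage_trace <- function(df, sampling_rate_hz, channel_label = "ch1") {
  structure(
    df,
    sampling_rate_hz = sampling_rate_hz,
    channel_label = channel_label,
    class = c("voltage_trace", class(tibble()))
  )
}

#' Sampling rate of a trace
#'
#' @param x A `voltage_trace` (or any object with a `sampling_rate_hz`
#'   attribute).
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(x) {
  sr <- attr(x, "sampling_rate_hz")
  if (is.null(sr)) abort("object carries no sampling rate")
  sr
}

trace_duration_s <- function(trace) nrow(trace) / sampling_rate(trace)

#' Construct a TTL event table from light on/off intervals
#'
#' The light-command (TTL) channel is represented as a tibble of
#' non-overlapping `(on_s, off_s)` intervals, sorted by onset. A sampled
#' binary stream representation is available through [ttl_to_wave()] and
#' [ttl_from_wave()]; the two representations are interconvertible.
#'
#' @param on_s,off_s Numeric vectors of light onsets and offsets in seconds;
#'   must satisfy `off_s > on_s` pairwise and must not overlap.
#' @return A tibble of class `ttl` with columns `on_s`, `off_s`.
#' @examples
#' ttl(on_s = c(1, 2), off_s = c(1.01, 2.01))
#' @export
ttl <- function(on_s = numeric(), off_s = numeric()) {
  if (length(on_s) != length(off_s)) stop_field("off_s", "length mismatch with on_s")
  ord <- order(on_s)
  on_s <- as.numeric(on_s[ord]); off_s <- as.numeric(off_s[ord])
  if (length(on_s)) {
    if (any(off_s <= on_s)) stop_field("off_s", "every interval needs off_s > on_s")
    if (any(diff(c(rbind(on_s, off_s))) < 0)) {
      stop_field("on_s", "intervals overlap")
    }
  }
  structure(tibble(on_s = on_s, off_s = off_s),
            class = c("ttl", class(tibble())))
}

#' Render a TTL interval table as a binary sample stream
#'
#' @param x A `ttl` interval table.
#' @param sampling_rate_hz Sampling rate of the stream.
#' @param n_samples Stream length in samples.
#' @return Integer vector of 0/1 values; sample `i` is high when its time
#'   `(i-1)/rate` falls inside `[on_s, off_s)` of some pulse.
#' @export
ttl_to_wave <- function(x, sampling_rate_hz, n_samples) {
  wave <- integer(n_samples)
  for (k in seq_len(nrow(x))) {
    i0 <- ceiling(x$on_s[k] * sampling_rate_hz) + 1
    i1 <- ceiling(x$off_s[k] * sampling_rate_hz)
    i0 <- max(i0, 1L); i1 <- min(i1, n_samples)
    if (i1 >= i0) wave[i0:i1] <- 1L
  }
  wave
}

#' Parse a binary sample stream into a TTL interval table
#'
#' Pulse onset is the time of the first high sample of each run of high
#' samples; offset is the time of the first low sample after the run.
#'
#' @param wave Numeric/integer vector; values > 0.5 count as high.
#' @param sampling_rate_hz Sampling rate of the stream.
#' @return A `ttl` interval table.
#' @export
ttl_from_wave <- function(wave, sampling_rate_hz) {
  hi <- wave > 0.5
  if (!any(hi)) return(ttl())
  d <- diff(c(FALSE, hi, FALSE))
  on_i <- which(d == 1)
  off_i <- which(d == -1)
  ttl(on_s = (on_i - 1) / sampling_rate_hz, off_s = (off_i - 1) / sampling_rate_hz)
}

#' Construct a spike train
#'
#' A spike train is a tibble with a single `time_s` column of strictly
#' increasing spike timestamps, carrying the recording duration and the
#' provenance of the events (`detected`, `imported` or `ground_truth`) as
#' attributes.
#'
#' @param times_s Numeric vector of spike times in seconds, within
#'   `[0, duration_s]`. Sorted on construction; exact duplicates are
#'   collapsed with a warning.
#' @param duration_s Recording duration in seconds.
#' @param source One of `"detected"`, `"imported"`, `"ground_truth"`.
#' @return A tibble of class `spike_train` with column `time_s`.
#' @examples
#' spike_train(c(0.5, 0.1, 1.2), duration_s = 2)
#' @export
spike_train <- function(times_s, duration_s, source = c("detected", "imported", "ground_truth")) {
  source <- match.arg(source)
  check_scalar_number(duration_s, "duration_s", lower = 0)
  times_s <- as.numeric(times_s)
  if (length(times_s) && any(!is.finite(times_s))) {
    stop_field("times_s", "must be finite")
  }
  if (length(times_s) && (min(times_s) < 0 || max(times_s) > duration_s)) {
    stop_field("times_s", "must lie in [0, duration_s]")
  }
  times_s <- sort(times_s)
  dup <- duplicated(times_s)
  if (any(dup)) {
    warn(sprintf("collapsed %d duplicate spike timestamp(s)", sum(dup)))
    times_s <- times_s[!dup]
  }
  structure(tibble(time_s = times_s),
            duration_s = duration_s, source = source,
            class = c("spike_train", class(tibble())))
}

spike_times <- function(train) train$time_s

train_duration_s <- function(train) attr(train, "duration_s")
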