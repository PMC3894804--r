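#' Parse a TTL record into a pulse schedule
#'
#' Groups light pulses into trains wherever the gap between consecutive
#' onsets exceeds `train_gap_s`, numbers the pulse positions within each
#' train, and computes each train's frequency from the median within-train
#' inter-onset interval. Single long light deliveries (pulse duration above
#' `continuous_min_s`) are classified as a continuous (silencing) protocol.
#'
#' @param ttl A `ttl` interval table (use [ttl_from_wave()] for sampled
#'   streams).
#' @param train_gap_s Inter-onset gap that starts a new train, seconds.
#' @param continuous_min_s Pulse durations at or above this are treated as
#'   continuous-light trials, seconds.
#' @return A tibble of class `pulse_schedule` with columns `on_s`, `off_s`,
#'   `train`, `position`, and attributes `protocol_kind`
#'   (`"pulse_train"` or `"continuous"`) and `trains` (per-train tibble with
#'   `train`, `onset_s`, `n_pulses`, `frequency_hz`).
#' @examples
#' sched <- parse_schedule(ttl(on_s = (0:9) * 0.05, off_s = (0:9) * 0.05 + 0.01))
#' attr(sched, "trains")
#' @export
parse_schedule <- function(ttl, train_gap_s = 1.0, continuous_min_s = 1.0) {
  stopifnot(inherits(ttl, "ttl"))
  check_scalar_number(train_gap_s, "train_gap_s", lower = 1e-9)
  n <- nrow(ttl)
  if (n == 0) {
    return(new_pulse_schedule(tibble(on_s = numeric(), off_s = numeric(),
                                     train = integer(), position = integer()),
                              "pulse_train",
                              tibble(train = integer(), onset_s = numeric(),
                                     n_pulses = integer(), frequency_hz = numeric())))
  }
  kind <- if (median(ttl$off_s - ttl$on_s) >= continuous_min_s) "continuous" else "pulse_train"
  gaps <- diff(ttl$on_s)
  train <- cumsum(c(1L, as.integer(gaps > train_gap_s)))
  if (kind == "continuous") train <- seq_len(n)
  sched <- tibble(on_s = ttl$on_s, off_s = ttl$off_s, train = train)
  sched <- sched |> group_by(train) |> mutate(position = dplyr::row_number()) |> ungroup()
  trains <- sched |>
    group_by(train) |>
    summarise(onset_s = first(on_s), n_pulses = n(),
              frequency_hz = if (n() > 1) 1 / median(diff(on_s)) else NA_real_,
              .groups = "drop")
  new_pulse_schedule(sched, kind, trains)
}

new_pulse_schedule <- function(df, kind, trains) {
  structure(df, protocol_kind = kind, trains = trains,
            class = c("pulse_schedule", class(tibble())))
}

#' Protocol kind of a schedule
#' @param schedule A `pulse_schedule`.
#' @return `"pulse_train"` or `"continuous"`.
#' @export
protocol_kind <- function(schedule) attr(schedule, "protocol_kind")

#' Restrict a schedule to trains starting inside a session block
#'
#' Used for first/last 10 minute comparisons of long repeated-stimulation
#' recordings: a train belongs to the block when its onset does.
#'
#' @param schedule A `pulse_schedule`.
#' @param start_s,end_s Block limits in seconds; train onsets in
#'   `[start_s, end_s)` are kept.
#' @return The filtered `pulse_schedule` (train numbering preserved).
#' @export
schedule_block <- function(schedule, start_s, end_s) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  trains <- attr(schedule, "trains")
  keep <- trains$train[trains$onset_s >= start_s & trains$onset_s < end_s]
  new_pulse_schedule(
    as_tibble(schedule)[schedule$train %in% keep, , drop = FALSE],
    protocol_kind(schedule),
    trains[trains$train %in% keep, , drop = FALSE]
  )
}
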