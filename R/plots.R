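# ggplot2 views of the result objects

#' @export
autoplot.psth <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid_s, y = .data$rate_hz)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::labs(x = "time from event (s)", y = "firing rate (Hz)")
  if (!all(is.na(df$sem_hz))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$rate_hz - .data$sem_hz,
                   ymax = .data$rate_hz + .data$sem_hz),
      alpha = 0.25)
  }
  p
}

#' @export
autoplot.fidelity_result <- function(object, ...) {
  ggplot2::ggplot(object$per_position,
                  ggplot2::aes(x = .data$position, y = .data$prob)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$prob - .data$sem, ymax = .data$prob + .data$sem)) +
    ggplot2::geom_hline(yintercept = object$mean_prob, linetype = 2) +
    ggplot2::labs(x = "pulse position in train", y = "mean spikes per pulse")
}

#' @export
autoplot.ach_result <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$lag_mid_s, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_s")) +
    ggplot2::labs(x = "lag (s)", y = "pair count",
                  subtitle = classification(object))
  b <- attr(object, "baseline")
  if (!is.null(b)) {
    p <- p + ggplot2::geom_hline(
      yintercept = b + attr(object, "z_threshold") * attr(object, "spread"),
      linetype = 3)
  }
  p
}

#' @export
autoplot.silencing_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_trial[c("trial", "pre_rate_hz", "during_rate_hz", "post_rate_hz")],
    -"trial", names_to = "period", values_to = "rate_hz")
  df$period <- factor(df$period,
                      levels = c("pre_rate_hz", "during_rate_hz", "post_rate_hz"),
                      labels = c("pre", "light", "post"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$rate_hz)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$trial), alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3) +
    ggplot2::labs(x = NULL, y = "firing rate (Hz)")
}

#' Raster plot of spikes around events
#'
#' @param spikes A `spike_train`.
#' @param event_times_s Alignment events, seconds.
#' @param window_s Length-2 window around each event, seconds.
#' @return A ggplot: one row per event, one point per spike.
#' @export
plot_raster <- function(spikes, event_times_s, window_s = c(-1, 6)) {
  stopifnot(inherits(spikes, "spike_train"))
  t <- spike_times(spikes)
  df <- purrr::map_dfr(seq_along(event_times_s), function(e) {
    rel <- t - event_times_s[e]
    tibble(event = e, rel_s = rel[rel >= window_s[1] & rel < window_s[2]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_s, y = .data$event)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "steelblue") +
    ggplot2::labs(x = "time from event (s)", y = "event")
}
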