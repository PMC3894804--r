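test_that("TTL pulses group into trains exactly as a brute-force gap scan", {
  set.seed(7)
  for (rep in 1:5) {
    gaps <- runif(60, 0.02, 3)        # gaps straddling the 1 s threshold
    onsets <- cumsum(gaps)
    sched <- parse_schedule(ttl(onsets, onsets + 0.01), train_gap_s = 1)
    expect_identical(sched$train, brute_force_trains(onsets, 1))
  }
  expect_identical(nrow(parse_schedule(ttl())), 0L)
})

test_that("schedule blocks select trains by onset", {
  ses <- generate_chr2_session(
    synth_config(spont_rate_hz = 0, evoked_prob = 0, seed = 1),
    stim_preset("chr2-20hz-2hr"), render = "events")
  sched <- parse_schedule(ses$ttl)
  first10 <- schedule_block(sched, 0, 600)
  last10 <- schedule_block(sched, ses$duration_s - 600, ses$duration_s)
  expect_identical(nrow(attr(first10, "trains")), 5L)   # onsets 5,125,...,485 s
  expect_identical(nrow(attr(last10, "trains")), 5L)
  expect_identical(nrow(first10), 500L)
})

test_that("fidelity is exact for perfectly driven trains and empty for silence", {
  ses <- quick_chr2(seed = 5, evoked_prob = 1, doublet_prob = 0, spont_rate_hz = 0)
  sched <- parse_schedule(ses$ttl)
  fid <- spike_fidelity(true_spike_train(ses), sched)
  expect_equal(fid$mean_prob, 1)
  expect_true(all(fid$per_position$prob == 1))
  expect_true(all(fid$latencies_ms > 0 & fid$latencies_ms <= 50))

  none <- spike_fidelity(spike_train(numeric(), ses$duration_s), sched)
  expect_equal(none$mean_prob, 0)
  expect_true(is.na(none$latency_mode_ms))

  expect_error(
    spike_fidelity(true_spike_train(ses),
                   parse_schedule(ttl(5, 15))),
    class = "optrode_protocol_error")
})

test_that("fidelity matches the generator event log, doublets included", {
  ses <- quick_chr2(seed = 9, evoked_prob = 0.9, doublet_prob = 0.3,
                    spont_rate_hz = 0)
  fid <- spike_fidelity(true_spike_train(ses), parse_schedule(ses$ttl))
  expect_equal(fid$mean_prob, mean(ses$truth$per_pulse$count))
  expect_gt(max(fid$per_pulse$count), 1)
  # per-pulse counts agree pulse by pulse with the ground-truth log
  expect_identical(fid$per_pulse$count, ses$truth$per_pulse$count)
})

test_that("SEM over trains is available as the alternative population", {
  ses <- quick_chr2(seed = 15, evoked_prob = 0.8, spont_rate_hz = 0)
  a <- spike_fidelity(true_spike_train(ses), parse_schedule(ses$ttl), sem = "positions")
  b <- spike_fidelity(true_spike_train(ses), parse_schedule(ses$ttl), sem = "trains")
  expect_equal(a$mean_prob, b$mean_prob)
  expect_false(identical(a$sem_prob, b$sem_prob))
})

test_that("latency mode picks the fullest 1 ms bin, ties toward shorter", {
  expect_equal(latency_mode(rep(5.2, 10)), 5.5)
  expect_equal(latency_mode(c(1.1, 1.2, 3.4)), 1.5)
  expect_equal(latency_mode(c(1.1, 2.1)), 1.5)       # tie -> smaller bin
  expect_true(is.na(latency_mode(numeric())))
  # derived: brute-force bin count over a random draw
  set.seed(3)
  lat <- runif(500, 0, 20)
  counts <- tabulate(floor(lat) + 1, nbins = 20)
  expect_equal(latency_mode(lat), which.max(counts) - 1 + 0.5)
})

test_that("PSTH conserves spike counts and peaks at the latency mode", {
  ses <- quick_chr2(seed = 19, evoked_prob = 1, doublet_prob = 0.2,
                    spont_rate_hz = 2)
  train <- true_spike_train(ses)
  h <- psth(train, ses$ttl$on_s, window_s = c(0, 0.05), bin_s = 0.001)
  # conservation against a direct interval count
  direct <- sum(vapply(ses$ttl$on_s, function(o) {
    sum(train$time_s >= o & train$time_s < o + 0.05)
  }, numeric(1)))
  expect_identical(sum(h$count), as.integer(direct))
  fid <- spike_fidelity(train, parse_schedule(ses$ttl))
  expect_equal(h$bin_mid_s[which.max(h$count)] * 1000, fid$latency_mode_ms)

  empty <- psth(spike_train(numeric(), 10), c(1, 2), c(0, 0.5), 0.01)
  expect_true(all(empty$count == 0))
  expect_error(psth(train, numeric(), c(0, 1), 0.1), "event")
  expect_error(psth(train, 1, c(0, 1), 0.3), "bin_s")
})

test_that("firing rate is count over duration", {
  expect_equal(firing_rate(spike_train((1:10) / 2 - 0.25, 5), c(0, 5)), 2)
  expect_equal(firing_rate(spike_train(numeric(), 5), c(0, 5)), 0)
  expect_error(firing_rate(spike_train(1, 5), c(3, 3)), "window")
})

test_that("baseline rates recover the generator's spontaneous rate", {
  ses <- generate_chr2_session(
    synth_config(spont_rate_hz = 2, evoked_prob = 1, seed = 33),
    stim_protocol("pulse_train", frequency_hz = 20, pulses_per_train = 100,
                  n_trains = 10, inter_train_interval_s = 30),
    render = "events")
  train <- true_spike_train(ses)
  sched <- parse_schedule(ses$ttl)
  onsets <- attr(sched, "trains")$onset_s
  rates <- vapply(onsets, function(o) firing_rate(train, c(o - 5, o)), numeric(1))
  se <- sqrt(2 / (5 * length(onsets)))          # Poisson SE of the pooled mean
  expect_lt(abs(mean(rates) - 2), 3 * se)
})

test_that("silencing metrics match the generator log and show suppression", {
  ses <- generate_nphr_session(
    synth_config(spont_rate_hz = 2, silencing_efficacy = 0.9, seed = 13),
    stim_protocol("continuous", n_trains = 30, inter_train_interval_s = 30),
    render = "events")
  sil <- silencing_metrics(true_spike_train(ses), parse_schedule(ses$ttl))
  expect_identical(sil$per_trial$breakthrough, ses$truth$per_trial$breakthrough)
  expect_equal(sil$breakthrough_fraction, mean(ses$truth$per_trial$breakthrough))
  expect_lt(sil$mean_during_rate_hz, sil$mean_pre_rate_hz)

  full <- generate_nphr_session(
    synth_config(spont_rate_hz = 2, silencing_efficacy = 1, seed = 14),
    stim_protocol("continuous", n_trains = 10, inter_train_interval_s = 30),
    render = "events")
  sf <- silencing_metrics(true_spike_train(full), parse_schedule(full$ttl))
  expect_identical(sf$n_breakthrough_trials, 0L)
  expect_equal(sf$mean_during_rate_hz, 0)

  expect_error(
    silencing_metrics(true_spike_train(ses), parse_schedule(ttl((0:9) * 0.05, (0:9) * 0.05 + 0.01))),
    class = "optrode_protocol_error")
})

test_that("pre/post windows are truncated with a warning when trials crowd", {
  ses <- generate_nphr_session(
    synth_config(spont_rate_hz = 3, silencing_efficacy = 0.9, seed = 21),
    stim_protocol("continuous", n_trains = 4, inter_train_interval_s = 16,
                  light_duration_s = 10),
    render = "events")
  expect_warning(
    sil <- silencing_metrics(true_spike_train(ses), parse_schedule(ses$ttl),
                             pre_s = 10, post_s = 10),
    "truncated")
  expect_identical(sil$n_trials, 4L)
})

test_that("alignment statistics are equivariant under a time shift", {
  ses <- quick_chr2(seed = 25, evoked_prob = 0.9, spont_rate_hz = 1)
  train <- true_spike_train(ses)
  shift <- 12.345
  sched <- parse_schedule(ses$ttl)
  train2 <- spike_train(train$time_s + shift, train_duration_s(train) + shift)
  sched2 <- parse_schedule(ttl(ses$ttl$on_s + shift, ses$ttl$off_s + shift))
  a <- spike_fidelity(train, sched)
  b <- spike_fidelity(train2, sched2)
  expect_equal(b$mean_prob, a$mean_prob)
  expect_equal(b$latencies_ms, a$latencies_ms, tolerance = 1e-9)
  h1 <- psth(train, ses$ttl$on_s, c(0, 0.05), 0.001)
  h2 <- psth(train2, ses$ttl$on_s + shift, c(0, 0.05), 0.001)
  expect_identical(h1$count, h2$count)
})
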