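test_that("identical config and seed give bit-identical sessions", {
  mk <- function() quick_chr2(seed = 17, spont_rate_hz = 3, render = "trace",
                              protocol = stim_protocol("pulse_train",
                                frequency_hz = 20, pulses_per_train = 20,
                                n_trains = 2, inter_train_interval_s = 10))
  a <- mk(); b <- mk()
  expect_identical(a$trace$uv, b$trace$uv)
  expect_identical(a$truth$spikes, b$truth$spikes)
  expect_identical(a$ttl, b$ttl)
  c <- quick_chr2(seed = 18, spont_rate_hz = 3, render = "trace",
                  protocol = a$protocol)
  expect_false(identical(a$trace$uv, c$trace$uv))
})

test_that("a silent, stimulus-free configuration emits pure noise", {
  ses <- quick_chr2(seed = 1, evoked_prob = 0, spont_rate_hz = 0, render = "trace")
  expect_identical(nrow(ses$truth$spikes), 0L)
  expect_true(all(ses$truth$per_pulse$count == 0))
  # pure Gaussian noise: robust SD matches noise_sd, nothing above 6 SD
  expect_equal(median(abs(ses$trace$uv)) / 0.6745, 10, tolerance = 0.05)
  expect_lt(max(abs(ses$trace$uv)), 6 * 10 * 1.2)
})

test_that("the repeated-stimulation protocol lays out 61 trains over 2 hours", {
  ses <- generate_chr2_session(
    synth_config(spont_rate_hz = 0, evoked_prob = 0, seed = 1),
    stim_preset("chr2-20hz-2hr"), render = "events")
  expect_identical(nrow(ses$ttl), 6100L)
  expect_gte(ses$duration_s, 120 * 60)
  sched <- parse_schedule(ses$ttl)
  trains <- attr(sched, "trains")
  expect_identical(nrow(trains), 61L)
  expect_equal(trains$frequency_hz, rep(20, 61), tolerance = 1e-9)
  expect_equal(diff(trains$onset_s), rep(120, 60))
})

test_that("every pulse evokes exactly one spike when fidelity is perfect", {
  ses <- quick_chr2(seed = 23, evoked_prob = 1, doublet_prob = 0,
                    spont_rate_hz = 0, render = "trace")
  expect_true(all(ses$truth$per_pulse$count == 1))
  # conservation: one inserted waveform per true spike, recounted
  # independently as threshold excursions at SNR 10
  x <- ses$trace$uv
  over <- x < -50          # half the template trough, 5 noise SDs
  onsets <- which(over & !c(FALSE, over[-length(over)]))
  # merge onsets within 1 ms: one excursion per waveform even if noise
  # briefly interrupts the crossing
  n_excursions <- sum(diff(c(-Inf, onsets)) > 20)
  expect_identical(n_excursions, nrow(ses$truth$spikes))
  expect_identical(nrow(ses$truth$spikes), nrow(ses$ttl))
})

test_that("evoked latencies are unimodal with the configured 7 ms mode", {
  ses <- generate_chr2_session(
    synth_config(spont_rate_hz = 0, evoked_prob = 1, doublet_prob = 0, seed = 5),
    stim_protocol("pulse_train", frequency_hz = 20, pulses_per_train = 100,
                  n_trains = 25, inter_train_interval_s = 10),
    render = "events")
  lat_ms <- (ses$truth$spikes$time_s -
               ses$ttl$on_s[ses$truth$spikes$pulse]) * 1000
  expect_gte(length(lat_ms), 2000)
  expect_true(all(lat_ms > 0 & lat_ms <= 50))
  counts <- table(floor(lat_ms))
  expect_identical(names(which.max(counts)), "7")
})

test_that("doublets produce per-pulse counts above one", {
  ses <- quick_chr2(seed = 29, evoked_prob = 1, doublet_prob = 0.5,
                    spont_rate_hz = 0, render = "events")
  counts <- ses$truth$per_pulse$count
  expect_true(any(counts == 2))
  expect_gt(mean(counts), 1)
  # doublet companion arrives 3-8 ms after the first evoked spike
  both <- which(counts == 2)
  gaps <- vapply(both, function(p) {
    diff(ses$truth$spikes$time_s[which(ses$truth$spikes$pulse == p)])
  }, numeric(1))
  expect_true(all(gaps >= 0.003 - 1e-12 & gaps <= 0.008 + 1e-12))
})

test_that("generated spike trains respect the refractory floor", {
  for (seed in 1:3) {
    ses <- quick_chr2(seed = seed, spont_rate_hz = 20, evoked_prob = 1,
                      doublet_prob = 0.3, render = "events")
    expect_true(all(diff(ses$truth$spikes$time_s) >= 0.002 - 1e-12))
  }
})

test_that("complete silencing leaves no spikes in any light interval", {
  ses <- generate_nphr_session(
    synth_config(spont_rate_hz = 5, silencing_efficacy = 1, seed = 7),
    stim_protocol("continuous", n_trains = 5, inter_train_interval_s = 30),
    render = "events")
  expect_identical(nrow(ses$ttl), 5L)
  expect_equal(ses$ttl$off_s - ses$ttl$on_s, rep(10, 5))
  expect_true(all(!ses$truth$per_trial$breakthrough))
  inside <- brute_force_breakthrough(ses$truth$spikes$time_s,
                                     ses$ttl$on_s, ses$ttl$off_s)
  expect_true(all(!inside))
})

test_that("logged breakthrough flags equal a brute-force interval scan", {
  ses <- generate_nphr_session(
    synth_config(spont_rate_hz = 2, silencing_efficacy = 0.9, seed = 13),
    stim_protocol("continuous", n_trains = 30, inter_train_interval_s = 30),
    render = "events")
  expect_identical(
    ses$truth$per_trial$breakthrough,
    brute_force_breakthrough(ses$truth$spikes$time_s, ses$ttl$on_s, ses$ttl$off_s))
  expect_gt(mean(ses$truth$per_trial$breakthrough), 0)
})

test_that("rebound transiently raises the post-offset rate", {
  cfg <- synth_config(spont_rate_hz = 5, silencing_efficacy = 1,
                      rebound_gain = 4, rebound_tau_s = 0.2, seed = 3)
  proto <- stim_protocol("continuous", n_trains = 40, inter_train_interval_s = 30,
                         light_duration_s = 5)
  ses <- generate_nphr_session(cfg, proto, render = "events")
  t <- ses$truth$spikes$time_s
  early <- sum(vapply(ses$ttl$off_s, function(o) sum(t >= o & t < o + 0.4), numeric(1)))
  ctrl <- sum(vapply(ses$ttl$off_s, function(o) sum(t >= o + 5 & t < o + 5.4), numeric(1)))
  expect_gt(early, ctrl * 1.3)
})

test_that("a silencing protocol with nothing to silence warns", {
  expect_warning(
    generate_nphr_session(
      synth_config(spont_rate_hz = 0, seed = 1),
      stim_protocol("continuous", n_trains = 1), render = "events"),
    "silence")
})

test_that("invalid configurations name the offending field", {
  expect_error(synth_config(evoked_prob = 1.2), "evoked_prob")
  expect_error(synth_config(phasic_depth = -0.1), "phasic_depth")
  expect_error(synth_config(sampling_rate_hz = 10000), "sampling_rate_hz")
  expect_error(stim_protocol("pulse_train", frequency_hz = 200), "pulse_width_ms")
  expect_error(stim_protocol("continuous", n_trains = 2,
                             inter_train_interval_s = 5), "inter_train_interval_s")
  expect_error(
    generate_chr2_session(synth_config(), stim_protocol("continuous")),
    "pulse_train")
  expect_error(
    generate_nphr_session(synth_config(), stim_protocol("pulse_train")),
    "continuous")
})
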