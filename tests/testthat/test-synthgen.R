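# Synthetic generator: exact structure without noise, statistical structure
# with it, and reproducibility.

test_that("noiseless evoked cascade places sweep and relay spikes exactly", {
  cfg <- scenario_config("evoked", n_animals = 1, n_epochs = 1,
                         rates = rep(0, 6), cascade_lag = 1, jitter_sd = 0,
                         participation = rep(1, 6), burst_rates = rep(0, 6),
                         relay_delay = 9, relay_superficial_increment = 1.6,
                         evoked_onset = 10, seed = 1)
  ev <- generate_events(cfg)
  contra <- ev[ev$hemisphere == "contra", ]
  # granular/infragranular co-activation at onset, one step per layer upward
  expect_equal(contra$time_ms[contra$layer == 4], 10)
  expect_equal(contra$time_ms[contra$layer == 3], 11)
  expect_equal(contra$time_ms[contra$layer == 2], 12)
  expect_equal(contra$time_ms[contra$layer == 1], 13)
  expect_equal(contra$time_ms[contra$layer == 5], 10)
  expect_equal(contra$time_ms[contra$layer == 6], 10)
  # relay arrives deep-first in the other hemisphere
  ipsi <- ev[ev$hemisphere == "ipsi", ]
  expect_equal(ipsi$time_ms[ipsi$layer == 6], 19)
  expect_equal(ipsi$time_ms[ipsi$layer == 1], 19 + 5 * 1.6)
  gt <- attr(ev, "ground_truth")
  expect_equal(gt$velocity_m_s, 0.28)
  expect_equal(gt$relay_delays_ms, 9 + (6:1 - 1) * 1.6)
})

test_that("generation is deterministic in (config, seed) and seed-sensitive", {
  cfg <- scenario_config("spontaneous", n_animals = 2, n_epochs = 5, seed = 42)
  a <- generate_events(cfg)
  b <- generate_events(cfg)
  expect_identical(a, b)
  cfg2 <- scenario_config("spontaneous", n_animals = 2, n_epochs = 5, seed = 43)
  expect_false(identical(generate_events(cfg2)$time_ms, a$time_ms))
})

test_that("rate-only null reproduces configured rates within 3 SE", {
  cfg <- scenario_config("spontaneous", n_animals = 1, n_epochs = 200,
                         epoch_duration_ms = 7000, rates = rep(5, 6),
                         seed = 7)
  ev <- generate_rate_only_null(cfg)
  total_s <- 200 * 7
  se <- sqrt(5 / total_s)
  for (h in c("contra", "ipsi")) {
    for (L in 1:6) {
      rate <- sum(ev$hemisphere == h & ev$layer == L) / total_s
      expect_lt(abs(rate - 5), 3 * se)
    }
  }
})

test_that("zero-rate channels stay silent and give count-0 delay cells", {
  rates <- rbind(contra = c(0, 4, 6, 10, 14, 8), ipsi = c(2, 4, 6, 10, 14, 8))
  cfg <- scenario_config("spontaneous", n_animals = 1, n_epochs = 50,
                         epoch_duration_ms = 1000, rates = rates,
                         upstate_rate = 0, seed = 3)
  ev <- generate_rate_only_null(cfg)
  expect_equal(sum(ev$hemisphere == "contra" & ev$layer == 1), 0)
  dm <- next_spike_delays(ev)
  expect_true(all(dm$contra$same$count[1, ] == 0))
  expect_true(all(dm$contra$same$count[, 1] == 0))
  expect_true(all(is.na(dm$contra$same$mean[1, ])))
})

test_that("layer-step lag round-trips through the delay module exactly", {
  cfg <- scenario_config("evoked", n_animals = 1, n_epochs = 3,
                         rates = rep(0, 6), cascade_lag = 0.3, jitter_sd = 0,
                         participation = rep(1, 6), burst_rates = rep(0, 6),
                         evoked_onset = 10, seed = 2)
  ev <- generate_events(cfg)
  dm <- next_spike_delays(ev)
  m <- dm$contra$same$mean
  for (s in 4:6) {
    for (t in 1:3) expect_equal(unname(m[s, t]), (4 - t) * 0.3)
  }
  expect_equal(unname(m[4, 3]), 0.3)
  expect_equal(unname(m[4, 1]), 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(rates = c(-1, 2, 3, 4, 5, 6)), "rates")
  expect_error(scenario_config(n_epochs = 0), "n_epochs")
  expect_error(scenario_config(cascade_lag = -0.1), "cascade_lag")
  expect_error(scenario_config(participation = rep(2, 6)), "participation")
  expect_error(scenario_config(epoch_duration_ms = -5), "epoch_duration_ms")
  expect_error(scenario_config(jitter_sd = -1), "jitter_sd")
})

test_that("scenario YAML round trip preserves the configuration", {
  cfg <- scenario_config("evoked", n_animals = 3, n_epochs = 17,
                         rates = c(1, 2, 3, 4, 5, 6), cascade_lag = 0.7,
                         seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(cfg, path)
  back <- read_scenario_yaml(path)
  expect_equal(back, cfg)
  expect_identical(generate_events(back), generate_events(cfg))
})

test_that("continuous generation injects transients at ground-truth times", {
  cfg <- scenario_config("evoked", n_animals = 1, n_epochs = 3,
                         rates = rep(2, 6), jitter_sd = 0, seed = 5)
  out <- generate_continuous(cfg, noise_sd = 1, amplitude = 10)
  expect_s3_class(out$recording, "laminar_recording")
  expect_equal(length(out$recording$stimulus_onsets_ms), 3)
  ev <- out$events
  expect_gt(nrow(ev), 0)
  # each event sits on a pronounced negative deflection
  fs <- out$recording$sampling_rate
  idx <- round(ev$time_ms / 1000 * fs) + 1
  ch <- (match(ev$hemisphere, c("contra", "ipsi")) - 1) * 6 + ev$layer
  vals <- out$recording$samples[cbind(idx, ch)]
  expect_true(mean(vals < -5) > 0.95)
  expect_error(generate_continuous(cfg, noise_sd = 0), "noise_sd")
  expect_error(generate_continuous(cfg, amplitude = -1), "amplitude")
})
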