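# Epoch extraction, next-spike delay matrices (vs brute force), collapsing,
# summaries, and spike-likelihood profiles.

test_that("evoked epoching keeps the half-open 5-60 ms window", {
  ev <- data.frame(animal_id = 1L, epoch = NA_integer_, regime = NA,
                   hemisphere = "contra", layer = 4L,
                   time_ms = 1000 + c(4, 5, 30, 59.9, 60, 75))
  out <- epoch_events(ev, epoch_spec("evoked"), stimulus_onsets_ms = 1000)
  expect_equal(out$time_ms, c(5, 30, 59.9))
  expect_equal(unique(out$epoch), 1L)
})

test_that("spontaneous epoching starts 2 s after stimulation", {
  ev <- data.frame(animal_id = 1L, epoch = NA_integer_, regime = NA,
                   hemisphere = "ipsi", layer = 2L,
                   time_ms = c(1500, 2500, 8999, 9000))
  out <- epoch_events(ev, epoch_spec("spontaneous"), stimulus_onsets_ms = 0)
  # 1.5 s after stimulus is before the 2 s offset; 9 s is past the epoch end
  expect_equal(out$time_ms, c(500, 6999))
})

test_that("overlapping epoch windows are rejected", {
  ev <- data.frame(animal_id = 1L, epoch = NA_integer_, regime = NA,
                   hemisphere = "contra", layer = 1L, time_ms = 10)
  expect_error(epoch_events(ev, epoch_spec("evoked"), c(0, 30)), "overlap")
  expect_error(epoch_events(ev, epoch_spec("evoked"), c(30, 0)), "sorted")
})

test_that("single-pair and horizon behaviour of next_spike_delays", {
  base <- data.frame(animal_id = 1L, epoch = 1L, regime = "evoked",
                     hemisphere = "contra", layer = c(5L, 4L),
                     time_ms = c(10, 12))
  dm <- next_spike_delays(base)
  expect_equal(unname(dm$contra$same$mean["L5", "L4"]), 2)
  expect_equal(unname(dm$contra$same$count["L5", "L4"]), 1)
  # a target spike 35 ms later exceeds the 30 ms horizon
  far <- base
  far$time_ms <- c(10, 45)
  dm2 <- next_spike_delays(far)
  expect_equal(unname(dm2$contra$same$count["L5", "L4"]), 0)
  expect_true(is.na(dm2$contra$same$mean["L5", "L4"]))
  # simultaneous spikes are not "next"
  tie <- base
  tie$time_ms <- c(10, 10)
  dm3 <- next_spike_delays(tie)
  expect_equal(unname(dm3$contra$same$count["L5", "L4"]), 0)
  # delays never cross epoch boundaries
  split <- base
  split$epoch <- c(1L, 2L)
  dm4 <- next_spike_delays(split)
  expect_equal(sum(dm4$contra$same$count), 0)
  # same-layer same-hemisphere diagonal is undefined
  expect_true(all(is.na(diag(dm$contra$same$mean))))
})

test_that("delay matrices equal the brute-force oracle on random data", {
  for (seed in 1:5) {
    expect_matches_brute_force(random_events(400, seed = seed))
  }
  # degenerate shapes: empty and single-channel inputs
  empty <- random_events(0)
  dm <- next_spike_delays(empty)
  expect_equal(sum(dm$contra$same$count) + sum(dm$ipsi$same$count), 0)
})

test_that("results are invariant to input record order", {
  ev <- random_events(300, seed = 9)
  dm1 <- next_spike_delays(ev)
  set.seed(1)
  ev_shuf <- ev[sample(nrow(ev)), ]
  dm2 <- next_spike_delays(ev_shuf)
  expect_equal(dm1$contra$same, dm2$contra$same)
  expect_equal(dm1$ipsi$other, dm2$ipsi$other)
})

test_that("shrinking the horizon never increases any count", {
  ev <- random_events(500, seed = 4)
  d30 <- next_spike_delays(ev, 30)
  d10 <- next_spike_delays(ev, 10)
  for (h in c("contra", "ipsi")) {
    for (r in c("same", "other")) {
      expect_true(all(d10[[h]][[r]]$count <= d30[[h]][[r]]$count))
    }
  }
})

test_that("collapse_references pools cell-wise with count weighting", {
  mk <- function(val, cnt) {
    m <- matrix(val, 6, 6); n <- matrix(cnt, 6, 6)
    m[n == 0] <- NA
    dimnames(m) <- dimnames(n) <- list(spike_layer = paste0("L", 1:6),
                                       target_layer = paste0("L", 1:6))
    list(mean = m, count = n)
  }
  expect_equal(unname(collapse_references(mk(2, 1), mk(4, 1))$mean[1, 2]), 3)
  expect_equal(unname(collapse_references(mk(2, 3), mk(6, 1))$mean[1, 2]), 3)
  # all-zero counts on one side: result equals the other matrix
  out <- collapse_references(mk(2, 5), mk(9, 0))
  expect_equal(unname(out$mean[3, 4]), 2)
  expect_equal(unname(out$count[3, 4]), 5)
})

test_that("summaries split triangles and depths as specified", {
  mk <- function(m) {
    n <- matrix(100, 6, 6)
    dimnames(m) <- dimnames(n) <- list(spike_layer = paste0("L", 1:6),
                                       target_layer = paste0("L", 1:6))
    list(mean = m, count = n)
  }
  uni <- matrix(2.5, 6, 6); diag(uni) <- NA
  s <- summarize_delays(mk(uni), mk(matrix(2.5, 6, 6)))
  expect_equal(s$upward_mean, 2.5)
  expect_equal(s$downward_mean, 2.5)
  expect_equal(unname(s$delay_ratio), c(1, 1))

  # upward delays grow with layer distance, downward flat at 1 ms
  m <- outer(1:6, 1:6, function(sp, tg) ifelse(tg < sp, (sp - tg) * 1.0, 1.0))
  diag(m) <- NA
  s2 <- summarize_delays(mk(m), mk(matrix(c(rep(5, 18), rep(3, 18)), 6, 6)))
  expect_gt(s2$upward_mean, s2$downward_mean)
  expect_gt(s2$delay_ratio[["same_S1"]], 1)
  # other-S1 targets: first three columns 5 ms (superficial), last three 3 ms
  expect_equal(s2$deep_mean, 3)
  expect_equal(s2$superficial_mean, 5)
})

test_that("delay ratio exceeds 1 iff post-deep delays exceed post-superficial", {
  mk <- function(m) {
    n <- matrix(1, 6, 6)
    dimnames(m) <- dimnames(n) <- list(spike_layer = paste0("L", 1:6),
                                       target_layer = paste0("L", 1:6))
    list(mean = m, count = n)
  }
  deep_slow <- rbind(matrix(1, 3, 6), matrix(4, 3, 6))
  s <- summarize_delays(mk(deep_slow), mk(deep_slow))
  expect_gt(s$delay_ratio[["same_S1"]], 1)
  sup_slow <- rbind(matrix(4, 3, 6), matrix(1, 3, 6))
  s2 <- summarize_delays(mk(sup_slow), mk(sup_slow))
  expect_lt(s2$delay_ratio[["same_S1"]], 1)
})

test_that("spike likelihood counts trials with at least one spike per bin", {
  ev <- data.frame(animal_id = 1L, epoch = rep(1:20, each = 2),
                   regime = "evoked", hemisphere = "contra", layer = 4L,
                   time_ms = rep(c(8.2, 8.7), 20))  # two spikes, same bin
  lp <- spike_likelihood(ev, bin_ms = 1, n_trials = 20)
  expect_equal(unname(lp$likelihood["contra_L4", 9]), 1)  # bin [8, 9)
  expect_equal(sum(lp$likelihood["contra_L4", -9]), 0)
  expect_equal(unname(lp$peak_latency_ms["contra_L4"]), 8.5)
  # no spikes anywhere: all-zero profile, undefined peak
  lp0 <- spike_likelihood(random_events(0), bin_ms = 1, n_trials = 5)
  expect_true(all(lp0$likelihood == 0))
  expect_true(all(is.na(lp0$peak_latency_ms)))
  expect_error(spike_likelihood(random_events(0), n_trials = 0), "trial")
})

test_that("evoked scenario peaks earlier in granular than supragranular layers", {
  cfg <- scenario_config("evoked", n_animals = 1, n_epochs = 100, seed = 21)
  ev <- generate_events(cfg)
  lp <- spike_likelihood(ev, bin_ms = 1, n_trials = 100, window_ms = c(0, 60))
  pk <- lp$peak_latency_ms
  expect_lte(pk[["contra_L4"]], pk[["contra_L2"]])
  expect_lte(pk[["contra_L5"]], pk[["contra_L1"]])
})
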