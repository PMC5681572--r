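# Independent oracles and fixture builders shared across tests.

# Brute-force next-spike delays: per-spike scan over every other channel
# within the same epoch.  Deliberately naive (double loop, no offsets) so it
# shares no code path with the implementation.
brute_force_delays <- function(events, max_delay_ms = 30) {
  ch <- (match(events$hemisphere, c("contra", "ipsi")) - 1L) * 6L +
    events$layer
  s <- matrix(0, 12, 12)
  n <- matrix(0, 12, 12)
  for (i in seq_len(nrow(events))) {
    for (c2 in 1:12) {
      if (c2 == ch[i]) next
      cand <- events$time_ms[events$epoch == events$epoch[i] & ch == c2 &
                               events$time_ms > events$time_ms[i]]
      if (length(cand)) {
        d <- min(cand) - events$time_ms[i]
        if (d <= max_delay_ms) {
          s[ch[i], c2] <- s[ch[i], c2] + d
          n[ch[i], c2] <- n[ch[i], c2] + 1
        }
      }
    }
  }
  list(sum = s, count = n)
}

# mean/count block of the brute-force result, dimnamed like the package's
brute_block <- function(bf, rows, cols) {
  m <- bf$sum[rows, cols] / bf$count[rows, cols]
  m[bf$count[rows, cols] == 0] <- NA_real_
  dimnames(m) <- list(spike_layer = paste0("L", 1:6),
                      target_layer = paste0("L", 1:6))
  list(mean = m, count = bf$count[rows, cols])
}

expect_matches_brute_force <- function(events, max_delay_ms = 30) {
  dm <- next_spike_delays(events, max_delay_ms)
  bf <- brute_force_delays(events, max_delay_ms)
  blocks <- list(list(dm$contra$same, 1:6, 1:6),
                 list(dm$contra$other, 1:6, 7:12),
                 list(dm$ipsi$same, 7:12, 7:12),
                 list(dm$ipsi$other, 7:12, 1:6))
  for (b in blocks) {
    ref <- brute_block(bf, b[[2]], b[[3]])
    expect_equal(b[[1]]$mean, ref$mean)
    expect_equal(unname(b[[1]]$count), unname(ref$count))
  }
  invisible(dm)
}

random_events <- function(n, n_epochs = 5, t_max = 60, seed = 1) {
  set.seed(seed)
  data.frame(animal_id = rep(1L, n),
             epoch = sample.int(n_epochs, n, replace = TRUE),
             regime = rep("evoked", n),
             hemisphere = sample(c("contra", "ipsi"), n, replace = TRUE),
             layer = sample.int(6L, n, replace = TRUE),
             time_ms = round(stats::runif(n, 0, t_max), 4))
}

# Naive sample-by-sample threshold scan with dead time; the detection oracle.
naive_threshold_scan <- function(sig, thr, dead_samples) {
  events <- integer(0)
  last <- -Inf
  below_prev <- FALSE
  for (i in seq_along(sig)) {
    below <- sig[i] < thr
    if (below && !below_prev && i - last > dead_samples) {
      events <- c(events, i)
      last <- i
    }
    below_prev <- below
  }
  events
}

# Clean layer-step cascade scenario (no background, no afterdischarge, full
# participation): the sweep structure is the only signal.
clean_cascade_config <- function(regime = "spontaneous", lag = 0.3,
                                 jitter = 0, n_epochs = 40, n_animals = 1,
                                 relay_delay = 9, seed = 1,
                                 rates = rep(0, 6), ...) {
  scenario_config(regime, n_animals = n_animals, n_epochs = n_epochs,
                  rates = rates, cascade_lag = lag,
                  participation = rep(1, 6), burst_rates = rep(0, 6),
                  relay_delay = relay_delay,
                  relay_superficial_increment = lag,
                  upstate_rate = 1.2, jitter_sd = jitter, seed = seed, ...)
}
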