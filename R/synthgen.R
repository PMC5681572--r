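# Synthetic event and continuous-signal generators with known ground truth.

.as_spike_events <- function(df) {
  df <- df[order(df$animal_id, df$epoch, df$time_ms, df$hemisphere, df$layer), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_events", "data.frame")
  df
}

.empty_events <- function() {
  .as_spike_events(data.frame(
    animal_id = integer(), epoch = integer(), regime = character(),
    hemisphere = character(), layer = integer(), time_ms = numeric()))
}

# Per-layer time offsets of an upward sweep that starts at `start_layer`.
# layer_step: constant lag per layer step; depth_linear: lag proportional to
# the distance between the actual recording depths, scaled so that one model
# layer spacing (0.28 mm) costs `lag` ms.
.sweep_offsets <- function(start_layer, lag, mode) {
  if (mode == "layer_step") {
    pmax(start_layer - .LAYERS, 0) * lag
  } else {
    d <- .RECORDING_DEPTHS
    pmax(d[.LAYERS] - d[start_layer], 0) / .LAYER_SPACING * lag
  }
}

# One cascade event at onset t0: an upward first-spike sweep plus a brief
# afterdischarge that trails each participating layer's own sweep spike (so
# the first spike per layer carries the propagation lag while later spikes
# make the deeper layers dense).  Returns a list of numeric vectors (times
# per layer).  Caller owns the RNG state.
.cascade_event <- function(cfg, t0, offsets) {
  take <- stats::runif(6L) < cfg$participation
  times <- vector("list", 6L)
  for (L in .LAYERS) {
    tt <- numeric()
    if (take[L]) {
      tt <- t0 + offsets[L]
      if (cfg$burst_rates[L] > 0) {
        w <- cfg$burst_window_ms[L]
        n <- stats::rpois(1L, cfg$burst_rates[L] * w / 1000)
        if (n > 0) tt <- c(tt, tt[1L] + stats::runif(n, 0, w))
      }
    }
    if (length(tt) && cfg$jitter_sd > 0)
      tt <- tt + stats::rnorm(length(tt), 0, cfg$jitter_sd)
    times[[L]] <- tt
  }
  times
}

.background_epoch <- function(cfg) {
  dur_s <- cfg$epoch_duration_ms / 1000
  out <- vector("list", .N_CHANNELS)
  for (h in 1:2) for (L in .LAYERS) {
    n <- stats::rpois(1L, cfg$rates[h, L] * dur_s)
    out[[(h - 1L) * 6L + L]] <-
      if (n > 0) stats::runif(n, 0, cfg$epoch_duration_ms) else numeric()
  }
  out
}

# Assemble one epoch of one animal; returns list(times, channel) plus cascade
# onsets for the ground-truth record.
.generate_epoch <- function(cfg) {
  chans <- .background_epoch(cfg)
  onsets <- data.frame(onset_ms = numeric(), source = character())
  up_off <- .sweep_offsets(4L, cfg$cascade_lag, cfg$cascade_mode)
  deep_off <- .sweep_offsets(6L, cfg$cascade_lag, cfg$cascade_mode)
  relay_off <- cfg$relay_delay + (6L - .LAYERS) * cfg$relay_superficial_increment

  add_event <- function(hemi_idx, times) {
    for (L in .LAYERS) {
      k <- (hemi_idx - 1L) * 6L + L
      chans[[k]] <<- c(chans[[k]], times[[L]])
    }
  }

  if (cfg$regime == "evoked") {
    t0 <- cfg$evoked_onset
    # contralateral volley: granular + infragranular co-activation at t0,
    # upward sweep above L4
    add_event(1L, .cascade_event(cfg, t0, up_off))
    # interhemispheric relay: deep-first upward sweep in the other hemisphere
    add_event(2L, .cascade_event(cfg, t0, relay_off))
    onsets <- data.frame(onset_ms = t0, source = "contra")
  } else {
    span <- max(deep_off, relay_off) + max(cfg$burst_window_ms) + 20
    avail <- cfg$epoch_duration_ms - span
    n_up <- if (avail > 0) stats::rpois(1L, cfg$upstate_rate *
                                          cfg$epoch_duration_ms / 1000) else 0L
    if (n_up > 0) {
      t_on <- sort(stats::runif(n_up, 0, avail))
      src <- sample(1:2, n_up, replace = TRUE)
      for (i in seq_len(n_up)) {
        add_event(src[i], .cascade_event(cfg, t_on[i], deep_off))
        add_event(3L - src[i], .cascade_event(cfg, t_on[i], relay_off))
      }
      onsets <- data.frame(onset_ms = t_on, source = .HEMIS[src])
    }
  }

  n_per <- lengths(chans)
  times <- unlist(chans, use.names = FALSE)
  keep <- !is.na(times) & times >= 0 & times < cfg$epoch_duration_ms
  list(times = times[keep],
       channel = rep.int(seq_len(.N_CHANNELS), n_per)[keep],
       onsets = onsets)
}

#' Generate synthetic laminar population-spike events
#'
#' Simulates event-level spike tables for a two-hemisphere, six-layer
#' preparation under the configured regime, together with the ground truth
#' the generator used (cascade onsets, true per-layer structural lags, and
#' the true upward propagation velocity), attached as attribute
#' `"ground_truth"`.
#'
#' Epochs are generated independently (no spike crosses an epoch boundary)
#' from one RNG stream per animal split per epoch by counter, so identical
#' `(config, seed)` reproduce the output exactly.
#'
#' @param config a [scenario_config()].
#' @param animal_ids integer vector of animals to generate (default all).
#' @return a `spike_events` data frame with columns `animal_id`, `epoch`,
#'   `regime`, `hemisphere`, `layer`, `time_ms` (epoch-relative), sorted by
#'   animal, epoch and time, with attribute `"ground_truth"`.
#' @examples
#' cfg <- scenario_config("evoked", n_animals = 1, n_epochs = 5, seed = 7)
#' ev <- generate_events(cfg)
#' attr(ev, "ground_truth")$velocity_m_s
#' @export
generate_events <- function(config, animal_ids = seq_len(config$n_animals)) {
  stopifnot(inherits(config, "scenario_config"))
  pieces <- list()
  onset_rows <- list()
  for (a in animal_ids) {
    for (e in seq_len(config$n_epochs)) {
      set.seed(.epoch_seed(config$seed, a, e))
      ep <- .generate_epoch(config)
      if (length(ep$times)) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          animal_id = a, epoch = e, regime = config$regime,
          hemisphere = .HEMIS[(ep$channel - 1L) %/% 6L + 1L],
          layer = (ep$channel - 1L) %% 6L + 1L,
          time_ms = ep$times)
      }
      if (nrow(ep$onsets)) {
        onset_rows[[length(onset_rows) + 1L]] <- data.frame(
          animal_id = a, epoch = e, ep$onsets)
      }
    }
  }
  ev <- if (length(pieces)) .as_spike_events(do.call(rbind, pieces))
        else .empty_events()
  start_layer <- if (config$regime == "evoked") 4L else 6L
  attr(ev, "ground_truth") <- list(
    regime = config$regime,
    velocity_m_s = if (config$cascade_lag > 0)
      .LAYER_SPACING / config$cascade_lag else Inf,
    cascade_offsets_ms = .sweep_offsets(start_layer, config$cascade_lag,
                                        config$cascade_mode),
    relay_delays_ms = config$relay_delay +
      (6L - .LAYERS) * config$relay_superficial_increment,
    onsets = if (length(onset_rows)) do.call(rbind, onset_rows)
             else data.frame(animal_id = integer(), epoch = integer(),
                             onset_ms = numeric(), source = character())
  )
  ev
}

#' Generate a rate-only null data set
#'
#' Twelve mutually independent stationary Poisson spike trains with the
#' configured per-channel rates and no propagation structure.  This is the
#' generative counterpart of the label-shuffle control: any delay-matrix
#' structure found in these data reflects firing rates alone, so the
#' downstream delay ratio is ~1 and shuffled and unshuffled matrices agree.
#'
#' @inheritParams generate_events
#' @return a `spike_events` data frame (no ground-truth attribute; there is
#'   no structure to recover).
#' @export
generate_rate_only_null <- function(config,
                                    animal_ids = seq_len(config$n_animals)) {
  stopifnot(inherits(config, "scenario_config"))
  pieces <- list()
  for (a in animal_ids) {
    for (e in seq_len(config$n_epochs)) {
      set.seed(.epoch_seed(config$seed, a, e, salt = 1))
      chans <- .background_epoch(config)
      n_per <- lengths(chans)
      if (sum(n_per) == 0L) next
      ch <- rep.int(seq_len(.N_CHANNELS), n_per)
      pieces[[length(pieces) + 1L]] <- data.frame(
        animal_id = a, epoch = e, regime = config$regime,
        hemisphere = .HEMIS[(ch - 1L) %/% 6L + 1L],
        layer = (ch - 1L) %% 6L + 1L,
        time_ms = unlist(chans, use.names = FALSE))
    }
  }
  if (length(pieces)) .as_spike_events(do.call(rbind, pieces))
  else .empty_events()
}

# Biphasic population-spike waveform (dominant negative phase), in samples.
# The negative peak sits at offset 0; values are multiples of `amplitude`.
.spike_kernel <- function(amplitude) {
  tt <- -4:7
  amplitude * (-exp(-(tt / 1.1)^2) + 0.45 * exp(-((tt - 3) / 1.8)^2))
}

#' Build a laminar recording container
#'
#' @param samples numeric matrix, samples x channels (12 channels, contra
#'   L1..L6 then ipsi L1..L6).
#' @param sampling_rate sampling rate, Hz.
#' @param stimulus_onsets_ms stimulus onset times, ms from recording start.
#' @param depths_mm per-layer electrode depths, mm (negative below pia).
#' @return an object of class `laminar_recording`.
#' @export
laminar_recording <- function(samples, sampling_rate = 6250,
                              stimulus_onsets_ms = numeric(),
                              depths_mm = .ELECTRODE_DEPTHS) {
  samples <- as.matrix(samples)
  if (ncol(samples) != .N_CHANNELS)
    stop("`samples` must have 12 channels (contra L1..L6, ipsi L1..L6)",
         call. = FALSE)
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0", call. = FALSE)
  if (length(depths_mm) != 6L || any(diff(depths_mm) >= 0))
    stop("`depths_mm` must be 6 strictly decreasing values", call. = FALSE)
  channels <- data.frame(hemisphere = rep(.HEMIS, each = 6L),
                         layer = rep(.LAYERS, 2L),
                         depth_mm = rep(depths_mm, 2L))
  colnames(samples) <- .chan12_labels()
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channels = channels,
                 stimulus_onsets_ms = sort(stimulus_onsets_ms)),
            class = "laminar_recording")
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat("Laminar recording: 12 channels x", nrow(x$samples), "samples @",
      x$sampling_rate, "Hz\n")
  cat("  duration:", round(nrow(x$samples) / x$sampling_rate, 3), "s;",
      length(x$stimulus_onsets_ms), "stimulus onsets\n")
  invisible(x)
}

#' Generate a continuous synthetic recording with injected spike transients
#'
#' Lays the configured epochs out along one continuous multichannel signal
#' (stimulus onsets every `inter_stimulus_ms`), fills each channel with
#' Gaussian background noise, and injects a biphasic transient (dominant
#' negative phase, amplitude in multiples of the noise SD) at each generated
#' event time.  The generated events, re-expressed in recording time, are the
#' detection ground truth and are returned alongside the recording.
#'
#' Intended as a fixture for the detection stage at short epoch lengths; a
#' full 200-epoch spontaneous scenario would be several GB of signal.
#'
#' @inheritParams generate_events
#' @param noise_sd background noise standard deviation (arbitrary units).
#' @param amplitude transient amplitude in multiples of `noise_sd`.
#' @param sampling_rate sampling rate, Hz.
#' @param inter_stimulus_ms spacing of stimulus onsets, ms (default epoch
#'   length + 100 ms).
#' @param pre_ms quiet lead-in before the first stimulus, ms.
#' @return a list with elements `recording` (a [laminar_recording()]) and
#'   `events` (`spike_events` whose `time_ms` is absolute recording time),
#'   carrying the generator's `"ground_truth"` attribute.
#' @export
generate_continuous <- function(config, animal_ids = 1L, noise_sd = 1,
                                amplitude = 8, sampling_rate = 6250,
                                inter_stimulus_ms = NULL, pre_ms = 40) {
  stopifnot(inherits(config, "scenario_config"))
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  if (length(animal_ids) != 1L)
    stop("continuous generation covers one animal per recording", call. = FALSE)
  if (is.null(inter_stimulus_ms))
    inter_stimulus_ms <- config$epoch_duration_ms + 100
  if (inter_stimulus_ms < config$epoch_duration_ms)
    stop("`inter_stimulus_ms` must cover the epoch duration", call. = FALSE)

  ev <- generate_events(config, animal_ids = animal_ids)
  gt <- attr(ev, "ground_truth")
  onsets <- pre_ms + (seq_len(config$n_epochs) - 1L) * inter_stimulus_ms
  dur_ms <- pre_ms + config$n_epochs * inter_stimulus_ms + 40
  n <- ceiling(dur_ms / 1000 * sampling_rate)

  set.seed(.epoch_seed(config$seed, animal_ids, 0L, salt = 2))
  x <- matrix(stats::rnorm(n * .N_CHANNELS, 0, noise_sd), n, .N_CHANNELS)
  kern <- .spike_kernel(amplitude * noise_sd)
  koff <- -4:7

  abs_ms <- onsets[ev$epoch] + ev$time_ms
  chan <- .chan12(ev$hemisphere, ev$layer)
  centre <- round(abs_ms / 1000 * sampling_rate) + 1L
  for (i in seq_along(centre)) {
    idx <- centre[i] + koff
    ok <- idx >= 1L & idx <= n
    x[idx[ok], chan[i]] <- x[idx[ok], chan[i]] + kern[ok]
  }
  ev$time_ms <- (centre - 1L) / sampling_rate * 1000  # sample-aligned truth
  ev <- .as_spike_events(ev)
  attr(ev, "ground_truth") <- gt

  list(recording = laminar_recording(x, sampling_rate,
                                     stimulus_onsets_ms = onsets),
       events = ev)
}

#' Simulate per-animal delay-versus-depth rows for model-selection studies
#'
#' Generates mean-delay rows (one per animal, target layers L1..L6) that are
#' exactly linear either in layer index (step-wise propagation, equally
#' spaced model depths) or in the actual recording depths (continuous
#' propagation), plus Gaussian noise.  Used to validate the Bayes-factor
#' model comparison: layer-generated rows should yield BF >> 1, depth-linear
#' rows BF << 1.
#'
#' @param n_animals number of rows.
#' @param spacing `"layer"` or `"depth"`: which predictor generates the truth.
#' @param intercept delay at L6, ms.
#' @param slope_ms_per_step delay increase per 0.28 mm model step, ms.
#' @param noise_sd Gaussian noise SD, ms.
#' @param geometry a [layer_geometry()].
#' @param seed RNG seed.
#' @return matrix `n_animals` x 6 of delays (ms), columns L1..L6.
#' @export
generate_delay_rows <- function(n_animals = 20, spacing = c("layer", "depth"),
                                intercept = 9, slope_ms_per_step = 1.6,
                                noise_sd = 0.1, geometry = layer_geometry(),
                                seed = 1L) {
  spacing <- match.arg(spacing)
  d <- if (spacing == "layer") geometry$layer_depths_model
       else geometry$recording_depths_model
  mu <- intercept + (d[6L] - d) / .LAYER_SPACING * slope_ms_per_step
  set.seed(as.integer(seed))
  rows <- matrix(rep(mu, each = n_animals), n_animals, 6L) +
    matrix(stats::rnorm(n_animals * 6L, 0, noise_sd), n_animals, 6L)
  colnames(rows) <- paste0("L", .LAYERS)
  rows
}
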