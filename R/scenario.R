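# Scenario configuration for the synthetic two-hemisphere, six-layer generator.
#
# Coordinate conventions used throughout the package:
#   * layers are numbered 1 (most superficial, just below pia) to 6 (deepest);
#   * hemispheres are "contra" (contralateral to stimulation, receives the
#     evoked volley first) and "ipsi";
#   * times are in ms, epoch-relative; depths in mm, negative below pia.

.LAYERS <- 1:6
.HEMIS <- c("contra", "ipsi")
.N_CHANNELS <- 12L
# model (equally spaced) layer depths and inter-layer spacing, mm
.LAYER_DEPTHS <- c(-0.10, -0.38, -0.66, -0.94, -1.22, -1.50)
.LAYER_SPACING <- 0.28
# unequally spaced recording depths used by the depth (continuous) model, mm
.RECORDING_DEPTHS <- c(-0.10, -0.25, -0.50, -0.75, -1.10, -1.50)
# electrode contact depths (from histology), mm below pia
.ELECTRODE_DEPTHS <- c(-0.10, -0.30, -0.50, -0.80, -1.10, -1.50)

#' Channel index for a (hemisphere, layer) pair
#'
#' Channels are ordered contra L1..L6 then ipsi L1..L6 (indices 1..12).
#'
#' @param hemisphere character vector, `"contra"` or `"ipsi"`.
#' @param layer integer vector in 1..6.
#' @return integer channel indices in 1..12.
#' @keywords internal
.chan12 <- function(hemisphere, layer) {
  (match(hemisphere, .HEMIS) - 1L) * 6L + as.integer(layer)
}

.chan12_labels <- function() {
  paste0(rep(.HEMIS, each = 6L), "_L", rep(.LAYERS, 2L))
}

# Deterministic per-epoch seed derived from the scenario seed.  One stream per
# (animal, epoch, salt) keeps epochs independently reproducible.
.epoch_seed <- function(seed, animal, epoch, salt = 0) {
  v <- (as.numeric(seed) * 48271 + animal * 1299709 +
          epoch * 15485863 + salt * 32452843) %% 2147483629
  as.integer(v) + 1L
}

#' Configure a synthetic laminar spiking scenario
#'
#' Describes one recording regime for the synthetic generator: stationary
#' Poisson background per channel plus structured cascade events.  In the
#' evoked regime a stimulus-locked volley arrives in contralateral S1 at
#' `evoked_onset` ms, co-activating the granular and infragranular layers and
#' climbing upward with `cascade_lag` ms per layer step; the other hemisphere
#' is relayed `relay_delay` ms after volley onset, arriving first in L6 and
#' climbing upward with `relay_superficial_increment` ms per step.  In the
#' spontaneous regime up-state-like cascades start at random onsets in a
#' random hemisphere, sweep upward from L6, and are relayed to the other
#' hemisphere in the same deep-first fashion.
#'
#' Defaults describe the "paper-like" study conditions: 6 animals, 200 epochs
#' per regime, 100 ms evoked / 7 s spontaneous epochs, a 7 ms evoked volley
#' onset, a 9 ms (evoked) interhemispheric relay arriving in L6, and sparser
#' participation of superficial layers.
#'
#' @param regime `"evoked"` or `"spontaneous"`.
#' @param n_animals number of animals to simulate.
#' @param n_epochs epochs per animal.
#' @param epoch_duration_ms epoch length, ms.
#' @param rates 2 x 6 matrix of background Poisson rates (Hz), rows
#'   `"contra"`/`"ipsi"`, columns layers L1..L6; or a length-6 vector applied
#'   to both hemispheres.
#' @param cascade_lag per-layer-step lag of the upward sweep, ms.
#' @param cascade_mode `"layer_step"` (constant lag per layer) or
#'   `"depth_linear"` (lag proportional to inter-electrode distance).
#' @param participation length-6 probability that each layer takes part in a
#'   cascade event; defaults decrease from L5 upward (sparser superficial
#'   activity).
#' @param burst_rates length-6 rates (Hz) of the brief afterdischarge that
#'   trails each participating layer's own first (sweep) spike; 0 disables.
#' @param burst_window_ms per-layer duration of the afterdischarge window,
#'   ms (scalar recycled); infragranular windows are long and supragranular
#'   ones short, reproducing abundant deep versus sparse superficial
#'   activity around each event.
#' @param relay_delay source-volley to other-hemisphere-L6 lag, ms.
#' @param relay_superficial_increment added lag per layer upward in the other
#'   hemisphere, ms.
#' @param evoked_onset latency of the first volley in contralateral S1, ms
#'   (evoked regime only).
#' @param upstate_rate rate of spontaneous up-state onsets, Hz (spontaneous
#'   regime only).
#' @param jitter_sd Gaussian timing jitter added to every structured spike, ms.
#' @param seed integer RNG seed; identical `(config, seed)` give bitwise
#'   identical data.
#' @return an object of class `scenario_config`.
#' @seealso [generate_events()], [generate_rate_only_null()],
#'   [generate_continuous()]
#' @examples
#' cfg <- scenario_config("evoked", n_animals = 1, n_epochs = 20, seed = 1)
#' ev <- generate_events(cfg)
#' head(ev)
#' @export
scenario_config <- function(regime = c("evoked", "spontaneous"),
                            n_animals = 6L,
                            n_epochs = 200L,
                            epoch_duration_ms = NULL,
                            rates = NULL,
                            cascade_lag = NULL,
                            cascade_mode = c("layer_step", "depth_linear"),
                            participation = c(0.45, 0.55, 0.70, 0.85, 0.95, 0.90),
                            burst_rates = NULL,
                            burst_window_ms = NULL,
                            relay_delay = NULL,
                            relay_superficial_increment = NULL,
                            evoked_onset = 7,
                            upstate_rate = 1.5,
                            jitter_sd = 0.3,
                            seed = 1L) {
  regime <- match.arg(regime)
  cascade_mode <- match.arg(cascade_mode)
  evoked <- regime == "evoked"
  if (is.null(epoch_duration_ms)) epoch_duration_ms <- if (evoked) 100 else 7000
  if (is.null(rates)) {
    rates <- if (evoked) c(2, 4, 6, 10, 14, 8) else c(0.5, 1, 2, 3, 5, 3)
  }
  if (is.null(cascade_lag)) cascade_lag <- if (evoked) 0.4 else 1.1
  if (is.null(burst_rates)) burst_rates <- c(150, 200, 250, 300, 350, 300)
  if (is.null(burst_window_ms)) {
    burst_window_ms <- if (evoked) c(2, 3, 4, 8, 12, 10)
                       else c(4, 6, 8, 15, 25, 20)
  }
  if (length(burst_window_ms) == 1L) burst_window_ms <- rep(burst_window_ms, 6L)
  if (is.null(relay_delay)) relay_delay <- if (evoked) 9 else 8
  if (is.null(relay_superficial_increment)) {
    relay_superficial_increment <- if (evoked) 1.6 else 0.8
  }
  if (is.vector(rates) && is.null(dim(rates))) {
    if (length(rates) != 6L)
      stop("`rates` must be a length-6 vector or a 2 x 6 matrix", call. = FALSE)
    rates <- rbind(contra = rates, ipsi = rates)
  }
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(2L, 6L)))
    stop("`rates` must be 2 x 6 (hemispheres x layers)", call. = FALSE)
  rownames(rates) <- .HEMIS
  colnames(rates) <- paste0("L", .LAYERS)

  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (cascade_lag < 0) stop("`cascade_lag` must be >= 0", call. = FALSE)
  if (n_epochs < 1) stop("`n_epochs` must be >= 1", call. = FALSE)
  if (n_animals < 1) stop("`n_animals` must be >= 1", call. = FALSE)
  if (epoch_duration_ms <= 0) stop("`epoch_duration_ms` must be > 0", call. = FALSE)
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  if (length(participation) != 6L || any(participation < 0 | participation > 1))
    stop("`participation` must be 6 probabilities in [0, 1]", call. = FALSE)
  if (length(burst_rates) != 6L || any(burst_rates < 0))
    stop("`burst_rates` must be 6 nonnegative rates", call. = FALSE)
  if (length(burst_window_ms) != 6L || any(burst_window_ms < 0))
    stop("`burst_window_ms` must be 6 nonnegative durations", call. = FALSE)
  if (relay_delay < 0 || relay_superficial_increment < 0)
    stop("relay parameters must be >= 0", call. = FALSE)
  if (evoked && (evoked_onset < 0 || evoked_onset >= epoch_duration_ms))
    stop("`evoked_onset` must lie inside the epoch", call. = FALSE)
  if (!evoked && upstate_rate < 0) stop("`upstate_rate` must be >= 0", call. = FALSE)

  structure(list(
    regime = regime,
    n_animals = as.integer(n_animals),
    n_epochs = as.integer(n_epochs),
    epoch_duration_ms = epoch_duration_ms,
    rates = rates,
    cascade_lag = cascade_lag,
    cascade_mode = cascade_mode,
    participation = participation,
    burst_rates = burst_rates,
    burst_window_ms = burst_window_ms,
    relay_delay = relay_delay,
    relay_superficial_increment = relay_superficial_increment,
    evoked_onset = evoked_onset,
    upstate_rate = upstate_rate,
    jitter_sd = jitter_sd,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic laminar scenario (", x$regime, ")\n", sep = "")
  cat("  animals:", x$n_animals, " epochs:", x$n_epochs,
      " duration:", x$epoch_duration_ms, "ms\n")
  cat("  cascade lag:", x$cascade_lag, "ms/step (", x$cascade_mode, ")\n", sep = "")
  cat("  relay: L6 at +", x$relay_delay, " ms, +",
      x$relay_superficial_increment, " ms per layer upward\n", sep = "")
  cat("  jitter sd:", x$jitter_sd, "ms  seed:", x$seed, "\n")
  cat("  background rates (Hz), L1..L6:\n")
  print(x$rates)
  invisible(x)
}

#' Read or write a scenario configuration as YAML
#'
#' @param config a [scenario_config()] object.
#' @param path file path.
#' @return `read_scenario_yaml()` returns a `scenario_config`;
#'   `write_scenario_yaml()` returns `path` invisibly.
#' @export
write_scenario_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  lst <- unclass(config)
  lst$rates <- list(contra = unname(lst$rates["contra", ]),
                    ipsi = unname(lst$rates["ipsi", ]))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$rates <- rbind(contra = lst$rates$contra, ipsi = lst$rates$ipsi)
  do.call(scenario_config, lst)
}

#' Electrode and model depth geometry of the six-layer probe
#'
#' Two candidate predictor sets for delay-versus-depth fits: equally spaced
#' per-layer model depths (0.28 mm spacing) for the step-wise layer model, and
#' the unequally spaced actual recording depths for the continuous depth
#' model.  Depths are in mm, negative below pia, strictly decreasing from L1
#' to L6.
#'
#' @param layer_depths_model length-6 equally spaced depths, mm.
#' @param recording_depths_model length-6 actual recording depths, mm.
#' @return an object of class `layer_geometry`.
#' @export
layer_geometry <- function(layer_depths_model = .LAYER_DEPTHS,
                           recording_depths_model = .RECORDING_DEPTHS) {
  for (d in list(layer_depths_model, recording_depths_model)) {
    if (length(d) != 6L || any(diff(d) >= 0))
      stop("depths must be 6 values strictly decreasing from L1 to L6",
           call. = FALSE)
  }
  structure(list(layer_depths_model = layer_depths_model,
                 recording_depths_model = recording_depths_model),
            class = "layer_geometry")
}

#' @export
print.layer_geometry <- function(x, ...) {
  cat("Layer geometry (mm below pia, L1..L6)\n")
  cat("  layer model:    ", paste(x$layer_depths_model, collapse = ", "), "\n")
  cat("  recording model:", paste(x$recording_depths_model, collapse = ", "), "\n")
  invisible(x)
}
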