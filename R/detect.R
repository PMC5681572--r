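# Population-spike detection: zero-phase bandpass + adaptive negative
# thresholding of the multi-unit band, with post-stimulus artifact exclusion.

#' Detection parameters
#'
#' The default band is 500-3000 Hz with a data-driven threshold of 5 noise
#' standard deviations per channel; `band_presets()` also names a narrower
#' 750-2000 Hz multi-unit band.  The noise scale defaults to the robust
#' median estimator median(|x|)/0.6745 (consistent for the SD of Gaussian
#' noise but insensitive to the spikes themselves); `"plain_sd"` is the
#' literal sample standard deviation.
#'
#' @param band_low,band_high bandpass corner frequencies, Hz.
#' @param threshold_multiplier threshold in multiples of the noise scale.
#' @param noise_estimator `"robust_median"` or `"plain_sd"`.
#' @param dead_time_ms minimum separation between events on one channel, ms;
#'   suppresses repeated counting of multi-sample crossings of one transient.
#' @param artifact_window_ms `(start, end)` ms after each stimulus onset
#'   within which events are discarded (mechanical stimulator artifacts).
#' @param filter_order Butterworth order of the bandpass.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(band_low = 500, band_high = 3000,
                             threshold_multiplier = 5,
                             noise_estimator = c("robust_median", "plain_sd"),
                             dead_time_ms = 1,
                             artifact_window_ms = c(0, 5),
                             filter_order = 4) {
  noise_estimator <- match.arg(noise_estimator)
  if (!(band_low > 0 && band_low < band_high))
    stop("need 0 < band_low < band_high", call. = FALSE)
  if (threshold_multiplier <= 0)
    stop("`threshold_multiplier` must be > 0", call. = FALSE)
  if (dead_time_ms < 0) stop("`dead_time_ms` must be >= 0", call. = FALSE)
  if (length(artifact_window_ms) != 2L ||
      artifact_window_ms[1] > artifact_window_ms[2])
    stop("`artifact_window_ms` must be (start, end) with start <= end",
         call. = FALSE)
  structure(list(band_low = band_low, band_high = band_high,
                 threshold_multiplier = threshold_multiplier,
                 noise_estimator = noise_estimator,
                 dead_time_ms = dead_time_ms,
                 artifact_window_ms = artifact_window_ms,
                 filter_order = filter_order),
            class = "detection_params")
}

#' @rdname detection_params
#' @export
band_presets <- function() {
  list(methods = c(500, 3000),   # default detection band
       mua_narrow = c(750, 2000))
}

#' Zero-phase bandpass filter
#'
#' Butterworth bandpass applied forward and backward
#' ([signal::filtfilt()]), so event timestamps are not biased by filter
#' group delay.  Works on a numeric vector, a samples-by-channels matrix, or
#' a [laminar_recording()] (filtered in place, same length and channel
#' order).
#'
#' @param x signal (vector, matrix, or `laminar_recording`).
#' @param band_low,band_high corner frequencies, Hz; must lie inside the
#'   Nyquist band.
#' @param sampling_rate Hz (taken from the recording when `x` is one).
#' @param order Butterworth order.
#' @return the filtered object, with attribute `"bandpassed"` set.
#' @export
bandpass <- function(x, band_low = 500, band_high = 3000,
                     sampling_rate = NULL, order = 4) {
  if (inherits(x, "laminar_recording")) {
    x$samples <- bandpass(x$samples, band_low, band_high,
                          x$sampling_rate, order)
    attr(x, "bandpassed") <- c(band_low, band_high)
    return(x)
  }
  if (is.null(sampling_rate))
    stop("`sampling_rate` is required for plain signals", call. = FALSE)
  nyq <- sampling_rate / 2
  if (!(band_low > 0 && band_low < band_high && band_high < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  bf <- signal::butter(order, c(band_low, band_high) / nyq, type = "pass")
  if (is.matrix(x)) {
    y <- apply(x, 2L, function(col) signal::filtfilt(bf, col))
    dimnames(y) <- dimnames(x)
  } else {
    y <- signal::filtfilt(bf, x)
  }
  attr(y, "bandpassed") <- c(band_low, band_high)
  y
}

#' Data-driven detection threshold for one channel
#'
#' Returns `-multiplier * scale` where the noise scale is either the robust
#' estimator `median(|x|) / 0.6745` (0.6745 is the 0.75 normal quantile, so
#' the estimator is consistent for the SD of Gaussian noise) or the plain
#' sample SD.
#'
#' @param x numeric signal for one channel (nonempty).
#' @param multiplier threshold multiplier (> 0).
#' @param noise_estimator `"robust_median"` or `"plain_sd"`.
#' @return negative threshold in the signal's voltage units.
#' @export
estimate_threshold <- function(x, multiplier = 5,
                               noise_estimator = c("robust_median", "plain_sd")) {
  noise_estimator <- match.arg(noise_estimator)
  if (!length(x)) stop("empty signal", call. = FALSE)
  if (multiplier <= 0) stop("`multiplier` must be > 0", call. = FALSE)
  if (max(x) == min(x))
    stop("degenerate signal: noise scale is zero (all-constant input)",
         call. = FALSE)
  scale <- switch(noise_estimator,
                  robust_median = stats::median(abs(x)) / 0.6745,
                  plain_sd = stats::sd(x))
  if (!is.finite(scale) || scale == 0)
    stop("degenerate signal: noise scale is zero (all-constant input?)",
         call. = FALSE)
  -multiplier * scale
}

# indices of samples falling in any [onset + a, onset + b] window (ms)
.artifact_mask <- function(n, sampling_rate, onsets_ms, window_ms) {
  mask <- logical(n)
  for (on in onsets_ms) {
    i0 <- max(1L, floor((on + window_ms[1]) / 1000 * sampling_rate) + 1L)
    i1 <- min(n, ceiling((on + window_ms[2]) / 1000 * sampling_rate) + 1L)
    if (i0 <= i1) mask[i0:i1] <- TRUE
  }
  mask
}

#' Detect population spikes in a laminar recording
#'
#' One event per negative threshold crossing (the first sample below the
#' per-channel data-driven threshold), with subsequent crossings within
#' `dead_time_ms` suppressed, and events inside the post-stimulus artifact
#' window removed.  The threshold is estimated over the full recording
#' excluding artifact windows.
#'
#' @param recording a [laminar_recording()].
#' @param params a [detection_params()].
#' @param apply_bandpass filter internally before thresholding?  Set `FALSE`
#'   for recordings already bandpassed (the choice is recorded in the result's
#'   `"provenance"` attribute).
#' @param animal_id value for the `animal_id` column of the output.
#' @return a `spike_events` data frame with absolute `time_ms` (`epoch` is
#'   `NA` until [epoch_events()] assigns it).
#' @seealso [epoch_events()], [next_spike_delays()]
#' @export
detect_spikes <- function(recording, params = detection_params(),
                          apply_bandpass = TRUE, animal_id = 1L) {
  stopifnot(inherits(recording, "laminar_recording"),
            inherits(params, "detection_params"))
  n <- nrow(recording$samples)
  if (n == 0L) {
    warning("empty recording: no events")
    return(.empty_events())
  }
  fs <- recording$sampling_rate
  x <- recording$samples
  if (apply_bandpass)
    x <- bandpass(x, params$band_low, params$band_high, fs,
                  params$filter_order)
  art <- .artifact_mask(n, fs, recording$stimulus_onsets_ms,
                        params$artifact_window_ms)
  dead_samp <- params$dead_time_ms / 1000 * fs

  pieces <- list()
  for (k in seq_len(ncol(x))) {
    sig <- x[, k]
    thr <- tryCatch(
      estimate_threshold(sig[!art], params$threshold_multiplier,
                         params$noise_estimator),
      error = function(e) {
        warning("channel ", k, ": ", conditionMessage(e),
                "; no events detected", call. = FALSE)
        NA_real_
      })
    if (is.na(thr)) next
    below <- sig < thr
    cross <- which(below & !c(FALSE, below[-n]))
    if (length(cross) && dead_samp > 0) {
      keep <- integer(0)
      last <- -Inf
      for (cc in cross) {
        if (cc - last > dead_samp) {
          keep <- c(keep, cc)
          last <- cc
        }
      }
      cross <- keep
    }
    cross <- cross[!art[cross]]
    if (length(cross)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        animal_id = animal_id, epoch = NA_integer_, regime = NA_character_,
        hemisphere = recording$channels$hemisphere[k],
        layer = recording$channels$layer[k],
        time_ms = (cross - 1L) / fs * 1000)
    }
  }
  ev <- if (length(pieces)) .as_spike_events(do.call(rbind, pieces))
        else .empty_events()
  attr(ev, "provenance") <- list(bandpassed_internally = apply_bandpass,
                                 params = params)
  ev
}
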