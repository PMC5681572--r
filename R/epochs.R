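# Epoch extraction: cut continuous-time event tables into stimulus-locked
# (evoked) or quiet-interval (spontaneous) epochs.

#' Epoch specification
#'
#' Evoked epochs keep events in a half-open window `[window_ms[1],
#' window_ms[2])` after each stimulus onset (default 5-60 ms; the 0-5 ms
#' artifact span is already outside it).  Spontaneous epochs keep events in
#' `[offset_s, offset_s + duration_s)` seconds after each onset (default a
#' 7 s epoch starting 2 s after stimulation).
#'
#' @param regime `"evoked"` or `"spontaneous"`.
#' @param window_ms evoked analysis window relative to stimulus onset, ms.
#' @param offset_s,duration_s spontaneous epoch placement, s.
#' @return an object of class `epoch_spec` with fields `start_ms`, `end_ms`
#'   (relative to stimulus onset) and `rezero` (the origin subtracted from
#'   epoch-relative times: onset for evoked, window start for spontaneous).
#' @export
epoch_spec <- function(regime = c("evoked", "spontaneous"),
                       window_ms = c(5, 60), offset_s = 2, duration_s = 7) {
  regime <- match.arg(regime)
  if (regime == "evoked") {
    if (window_ms[1] >= window_ms[2]) stop("window start must be < end",
                                           call. = FALSE)
    start_ms <- window_ms[1]; end_ms <- window_ms[2]; rezero <- 0
  } else {
    if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
    start_ms <- offset_s * 1000
    end_ms <- (offset_s + duration_s) * 1000
    rezero <- start_ms
  }
  structure(list(regime = regime, start_ms = start_ms, end_ms = end_ms,
                 rezero = rezero),
            class = "epoch_spec")
}

#' Assign events to epochs around stimulus onsets
#'
#' Events outside every window are dropped; kept events get an `epoch` id and
#' an epoch-relative `time_ms` (relative to stimulus onset for evoked epochs,
#' to the window start for spontaneous epochs, so spontaneous times run from
#' 0).  Windows are half-open `[start, end)`.
#'
#' @param events a `spike_events` table with absolute `time_ms` (e.g. from
#'   [detect_spikes()]).
#' @param spec an [epoch_spec()].
#' @param stimulus_onsets_ms sorted stimulus onsets, ms.
#' @return epoch-limited `spike_events`.
#' @export
epoch_events <- function(events, spec, stimulus_onsets_ms) {
  stopifnot(inherits(spec, "epoch_spec"))
  if (is.unsorted(stimulus_onsets_ms))
    stop("stimulus onsets must be sorted", call. = FALSE)
  if (length(stimulus_onsets_ms) > 1 &&
      any(diff(stimulus_onsets_ms) < spec$end_ms - spec$start_ms))
    stop("epoch windows overlap: onsets closer than the window span",
         call. = FALSE)
  if (!nrow(events)) return(.empty_events())
  k <- findInterval(events$time_ms - spec$start_ms, stimulus_onsets_ms)
  ok <- k >= 1L
  rel <- events$time_ms - ifelse(ok, stimulus_onsets_ms[pmax(k, 1L)], NA_real_)
  keep <- ok & rel >= spec$start_ms & rel < spec$end_ms
  out <- events[keep, , drop = FALSE]
  out$epoch <- k[keep]
  out$regime <- spec$regime
  out$time_ms <- rel[keep] - spec$rezero
  .as_spike_events(out)
}
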