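# Next-spike delay matrices across the 12 layer x hemisphere channels,
# their triangle / deep-superficial summaries, the delay-ratio statistic,
# and spike-likelihood profiles.

# 12x12 next-spike delay sums and counts.  For every spike and every other
# channel, the earliest spike with 0 < dt <= max_delay in the SAME epoch
# contributes.  Epochs are made non-adjacent by a large time offset so a
# single findInterval per target channel covers all epochs; ties (dt == 0)
# never count because findInterval treats equal times as "not after".
.pair_delay_stats <- function(time_ms, channel, epoch, max_delay_ms) {
  stopifnot(length(time_ms) == length(channel),
            length(time_ms) == length(epoch))
  if (!length(time_ms))
    return(list(sum = matrix(0, .N_CHANNELS, .N_CHANNELS),
                count = matrix(0, .N_CHANNELS, .N_CHANNELS)))
  o <- order(epoch, time_ms)
  t <- time_ms[o]; ch <- channel[o]; ep <- epoch[o]
  big <- max(t) - min(t) + 2 * max_delay_ms + 1
  toff <- t + match(ep, unique(ep)) * big
  .pair_delay_stats_off(toff, ch, max_delay_ms)
}

.block <- function(stats12, rows, cols) {
  s <- stats12$sum[rows, cols, drop = FALSE]
  n <- stats12$count[rows, cols, drop = FALSE]
  m <- s / n
  m[n == 0] <- NA_real_
  dimnames(m) <- dimnames(n) <- list(spike_layer = paste0("L", .LAYERS),
                                     target_layer = paste0("L", .LAYERS))
  list(mean = m, count = n)
}

#' Next-spike delay matrices
#'
#' For every detected spike at time t, finds in each of the 11 other
#' channels the next spike within the same epoch and a maximal delay of
#' `max_delay_ms`, and averages the delays per (spike layer, target layer)
#' cell.  Matrices are computed separately per spike hemisphere and split
#' into a same-hemisphere (`same`, diagonal undefined) and an
#' other-hemisphere (`other`) 6 x 6 reference; rows are the spike layer,
#' columns the target layer, both numbered 1 (superficial) to 6 (deep).
#'
#' Delays are strictly positive (simultaneous spikes do not count as "next")
#' and never cross epoch boundaries.  Cells without contributing pairs are
#' `NA` with count 0 and are excluded from all downstream summaries.
#'
#' @param events epoch-limited `spike_events` for a single animal and regime.
#' @param max_delay_ms delay horizon, ms (default 30).
#' @return an object of class `delay_matrices`: for each spike hemisphere
#'   (`contra`, `ipsi`) a list of `same` and `other` references, each with
#'   `mean` (ms) and `count` matrices; plus `max_delay_ms`, `animal_id`,
#'   `regime`.
#' @examples
#' ev <- data.frame(animal_id = 1, epoch = 1, regime = "evoked",
#'                  hemisphere = "contra", layer = c(5, 4),
#'                  time_ms = c(10, 12))
#' dm <- next_spike_delays(ev)
#' dm$contra$same$mean["L5", "L4"]  # 2 ms
#' @export
next_spike_delays <- function(events, max_delay_ms = 30) {
  if (max_delay_ms <= 0) stop("`max_delay_ms` must be > 0", call. = FALSE)
  animal <- unique(events$animal_id)
  if (length(animal) > 1L)
    stop("`events` must contain a single animal; split and loop", call. = FALSE)
  regime <- unique(events$regime)
  if (length(regime) > 1L)
    stop("`events` must contain a single regime", call. = FALSE)
  st <- .pair_delay_stats(events$time_ms,
                          .chan12(events$hemisphere, events$layer),
                          events$epoch, max_delay_ms)
  structure(list(
    contra = list(same = .block(st, 1:6, 1:6), other = .block(st, 1:6, 7:12)),
    ipsi = list(same = .block(st, 7:12, 7:12), other = .block(st, 7:12, 1:6)),
    max_delay_ms = max_delay_ms,
    animal_id = if (length(animal)) animal else NA_integer_,
    regime = if (length(regime)) regime else NA_character_,
    n_events = nrow(events)
  ), class = "delay_matrices")
}

#' @export
print.delay_matrices <- function(x, digits = 2, ...) {
  cat("Next-spike delay matrices (animal ", x$animal_id, ", ", x$regime,
      ", horizon ", x$max_delay_ms, " ms, ", x$n_events, " spikes)\n",
      sep = "")
  cl <- collapse_references(x)
  cat("Spike S1 (references collapsed; rows spike layer, cols target layer):\n")
  print(round(cl$same$mean, digits))
  cat("Other S1:\n")
  print(round(cl$other$mean, digits))
  invisible(x)
}

#' @export
plot.delay_matrices <- function(x, ...) {
  cl <- collapse_references(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (ref in c("same", "other")) {
    m <- cl[[ref]]$mean
    graphics::image(1:6, 1:6, t(m[6:1, ]), axes = FALSE,
                    xlab = "target layer", ylab = "spike layer",
                    main = if (ref == "same") "spike S1" else "other S1", ...)
    graphics::axis(1, 1:6, paste0("L", 1:6))
    graphics::axis(2, 1:6, paste0("L", 6:1))
  }
  invisible(x)
}

.pool_cells <- function(a, b) {
  wa <- a$count; wb <- b$count
  sa <- ifelse(wa > 0, a$mean * wa, 0)
  sb <- ifelse(wb > 0, b$mean * wb, 0)
  n <- wa + wb
  m <- (sa + sb) / n
  m[n == 0] <- NA_real_
  dimnames(m) <- dimnames(n) <- dimnames(a$mean)
  list(mean = m, count = n)
}

#' Collapse the two spike-hemisphere references
#'
#' Delay patterns following spikes in either hemisphere are expected to be
#' highly similar, so their matrices are pooled cell-wise with count
#' weighting (equivalent to pooling the underlying spike pairs).
#'
#' Called with a single `delay_matrices` object it pools contra- and
#' ipsi-referenced matrices within it; called with two single-reference
#' matrices (lists with `mean` and `count`) it pools those.
#'
#' @param x a `delay_matrices` object, or a list with `mean`/`count`.
#' @param y optional second `mean`/`count` list to pool with `x`.
#' @return collapsed matrices: either `list(same, other)` (class
#'   `delay_matrices_collapsed`) or a single `mean`/`count` list.
#' @export
collapse_references <- function(x, y = NULL) {
  if (inherits(x, "delay_matrices") && is.null(y)) {
    return(structure(list(same = .pool_cells(x$contra$same, x$ipsi$same),
                          other = .pool_cells(x$contra$other, x$ipsi$other),
                          animal_id = x$animal_id, regime = x$regime,
                          max_delay_ms = x$max_delay_ms),
                     class = "delay_matrices_collapsed"))
  }
  if (is.list(x) && is.list(y) && !is.null(x$mean) && !is.null(y$mean))
    return(.pool_cells(x, y))
  stop("unsupported arguments to collapse_references()", call. = FALSE)
}

.cell_mean <- function(m, rows = 1:6, cols = 1:6, part = c("all", "upper",
                                                           "lower")) {
  part <- match.arg(part)
  sel <- matrix(FALSE, 6, 6)
  sel[rows, cols] <- TRUE
  if (part == "upper") sel <- sel & outer(1:6, 1:6, function(s, t) t < s)
  if (part == "lower") sel <- sel & outer(1:6, 1:6, function(s, t) t > s)
  v <- m[sel]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Summary statistics of a pair of delay matrices
#'
#' Computes, from the same-hemisphere matrix: the mean upward delay (cells
#' whose target layer lies above the spike layer) and mean downward delay;
#' from the other-hemisphere matrix: mean delays onto deep (L4-L6) and
#' superficial (L1-L3) target layers.  The delay ratio -- mean delay over
#' all cells following deep-layer spikes (L4-L6) divided by the mean over
#' cells following superficial-layer spikes (L1-L3) -- is computed per
#' reference; it exceeds 1 when upward delays dominate downward ones.
#' Undefined cells (count 0) are excluded; a partition with no defined cells
#' yields `NA` and a warning.
#'
#' @param same,other `mean`/`count` matrix lists (e.g. from
#'   [collapse_references()]), or `same` may be a `delay_matrices_collapsed`
#'   object.
#' @return an object of class `delay_summary` with fields `upward_mean`,
#'   `downward_mean`, `deep_mean`, `superficial_mean`, `delay_ratio`
#'   (named vector, `same_S1` and `other_S1`), all in ms (ratio unitless).
#' @export
summarize_delays <- function(same, other = NULL) {
  if (inherits(same, "delay_matrices_collapsed")) {
    other <- same$other
    same <- same$same
  }
  if (inherits(same, "delay_matrices")) {
    cl <- collapse_references(same)
    other <- cl$other
    same <- cl$same
  }
  ms <- same$mean; mo <- other$mean
  out <- list(
    upward_mean = .cell_mean(ms, part = "upper"),
    downward_mean = .cell_mean(ms, part = "lower"),
    deep_mean = .cell_mean(mo, cols = 4:6),
    superficial_mean = .cell_mean(mo, cols = 1:3),
    delay_ratio = c(
      same_S1 = .cell_mean(ms, rows = 4:6) / .cell_mean(ms, rows = 1:3),
      other_S1 = .cell_mean(mo, rows = 4:6) / .cell_mean(mo, rows = 1:3))
  )
  und <- names(out)[vapply(out, function(v) any(!is.finite(v)), TRUE)]
  if (length(und))
    warning("undefined summary fields (empty cell partition): ",
            paste(und, collapse = ", "))
  structure(out, class = "delay_summary")
}

#' @export
print.delay_summary <- function(x, digits = 3, ...) {
  cat("Delay summary (ms):\n")
  cat("  spike S1   upward ", round(x$upward_mean, digits),
      "  downward ", round(x$downward_mean, digits), "\n")
  cat("  other S1   deep   ", round(x$deep_mean, digits),
      "  superficial ", round(x$superficial_mean, digits), "\n")
  cat("  delay ratio: same_S1 ", round(x$delay_ratio["same_S1"], digits),
      "  other_S1 ", round(x$delay_ratio["other_S1"], digits), "\n")
  invisible(x)
}

#' Spike likelihood across trials and peak latencies
#'
#' For each of the 12 channels and each time bin, the fraction of trials
#' (epochs) containing at least one spike in the bin; the peak latency is
#' the centre of the bin with maximal likelihood inside a per-hemisphere
#' search window (by default the first 10 ms for the contralateral
#' hemisphere, where the initial evoked volley is expected, and the full
#' range for the ipsilateral one).
#'
#' @param events epoch-limited `spike_events` (single animal and regime).
#' @param bin_ms bin width, ms.
#' @param n_trials number of trials; defaults to `max(events$epoch)` (pass
#'   explicitly when trailing trials contain no spikes).
#' @param window_ms analysis range `(start, end)`, ms; defaults to
#'   `(0, max(time))` rounded up to a bin.
#' @param peak_window_ms named list of per-hemisphere search windows for the
#'   peak, e.g. `list(contra = c(0, 10), ipsi = NULL)` (`NULL` = full range).
#' @return an object of class `likelihood_profile`: `bin_edges`,
#'   `likelihood` (12 x nbins, rows contra L1..L6 then ipsi L1..L6),
#'   `peak_latency_ms` (length 12, `NA` where no spikes), `n_trials`.
#' @export
spike_likelihood <- function(events, bin_ms = 1, n_trials = NULL,
                             window_ms = NULL,
                             peak_window_ms = list(contra = c(0, 10),
                                                   ipsi = NULL)) {
  if (is.null(n_trials)) {
    n_trials <- if (nrow(events)) max(events$epoch) else 0L
  }
  if (n_trials < 1L) stop("need at least one trial", call. = FALSE)
  if (is.null(window_ms)) {
    hi <- if (nrow(events)) ceiling(max(events$time_ms) / bin_ms) * bin_ms
          else bin_ms
    window_ms <- c(0, max(hi, bin_ms))
  }
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  nb <- length(edges) - 1L
  lik <- matrix(0, .N_CHANNELS, nb,
                dimnames = list(.chan12_labels(), NULL))
  if (nrow(events)) {
    chan <- .chan12(events$hemisphere, events$layer)
    bin <- findInterval(events$time_ms, edges, rightmost.closed = FALSE)
    ok <- bin >= 1L & bin <= nb
    key <- paste(chan[ok], events$epoch[ok], bin[ok])
    first <- !duplicated(key)
    tab <- table(factor(chan[ok][first], levels = 1:.N_CHANNELS),
                 factor(bin[ok][first], levels = 1:nb))
    lik <- unclass(tab) / n_trials
    dimnames(lik) <- list(.chan12_labels(), NULL)
  }
  centres <- edges[-length(edges)] + bin_ms / 2
  peak <- rep(NA_real_, .N_CHANNELS)
  for (k in seq_len(.N_CHANNELS)) {
    hemi <- .HEMIS[(k - 1L) %/% 6L + 1L]
    win <- peak_window_ms[[hemi]]
    sel <- if (is.null(win)) rep(TRUE, nb)
           else centres >= win[1] & centres < win[2]
    if (any(sel) && any(lik[k, sel] > 0))
      peak[k] <- centres[sel][which.max(lik[k, sel])]
  }
  names(peak) <- .chan12_labels()
  structure(list(bin_edges = edges, likelihood = lik,
                 peak_latency_ms = peak, n_trials = n_trials),
            class = "likelihood_profile")
}

#' @export
print.likelihood_profile <- function(x, ...) {
  cat("Spike likelihood profile:", nrow(x$likelihood), "channels x",
      ncol(x$likelihood), "bins,", x$n_trials, "trials\n")
  cat("Peak latencies (ms):\n")
  print(round(x$peak_latency_ms, 2))
  invisible(x)
}

#' @export
plot.likelihood_profile <- function(x, ...) {
  centres <- x$bin_edges[-length(x$bin_edges)] + diff(x$bin_edges) / 2
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (h in 1:2) {
    rows <- (h - 1L) * 6L + 1:6
    graphics::matplot(centres, t(x$likelihood[rows, , drop = FALSE]),
                      type = "l", lty = 1, col = 1:6,
                      xlab = "time (ms)", ylab = "P(spike)",
                      main = .HEMIS[h], ...)
    graphics::legend("topright", paste0("L", 1:6), col = 1:6, lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}
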