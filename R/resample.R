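# Label-shuffle rate control and animal-level nonparametric bootstrap.

# mean matrices and ratios for one 12-channel labelling; reuses the delay
# core on pre-offset times.
.shuffle_pass <- function(toff, lab, max_delay_ms) {
  st <- .pair_delay_stats_off(toff, lab, max_delay_ms)
  same <- .pool_cells(.block(st, 1:6, 1:6), .block(st, 7:12, 7:12))
  other <- .pool_cells(.block(st, 1:6, 7:12), .block(st, 7:12, 1:6))
  list(same = same, other = other,
       ratio_same = .cell_mean(same$mean, rows = 4:6) /
         .cell_mean(same$mean, rows = 1:3),
       ratio_other = .cell_mean(other$mean, rows = 4:6) /
         .cell_mean(other$mean, rows = 1:3))
}

# variant of .pair_delay_stats taking already epoch-offset times
.pair_delay_stats_off <- function(toff, channel, max_delay_ms) {
  sums <- matrix(0, .N_CHANNELS, .N_CHANNELS)
  counts <- matrix(0, .N_CHANNELS, .N_CHANNELS)
  for (c2 in seq_len(.N_CHANNELS)) {
    tt <- toff[channel == c2]
    if (!length(tt)) next
    nxt <- findInterval(toff, tt) + 1L
    ok <- nxt <= length(tt)
    d <- tt[nxt[ok]] - toff[ok]
    src <- channel[ok]
    good <- d > 0 & d <= max_delay_ms & src != c2
    if (!any(good)) next
    s <- rowsum(d[good], src[good])
    idx <- as.integer(rownames(s))
    sums[idx, c2] <- sums[idx, c2] + s[, 1L]
    counts[idx, c2] <- counts[idx, c2] + tabulate(src[good], .N_CHANNELS)[idx]
  }
  list(sum = sums, count = counts)
}

#' Label-shuffle rate control
#'
#' Randomly permutes the 12 (hemisphere, layer) labels across all observed
#' spikes of one animal (times fixed, so per-channel spike totals are
#' preserved but temporal structure between channels is destroyed),
#' recomputes the delay matrices per shuffle, and averages.  Under this null
#' the delay to each target layer reflects only its firing rate, so the
#' per-shuffle delay-ratio distribution is the rate-only reference against
#' which the observed ratio is judged.
#'
#' @param events epoch-limited `spike_events` for one animal.
#' @param n_shuffles number of label permutations (>= 1; study default 1000).
#' @param seed RNG seed (results are reproducible given `seed`).
#' @param max_delay_ms delay horizon, ms.
#' @return an object of class `shuffle_result`: `mean_same` / `mean_other`
#'   (cell-wise average over shuffles of the collapsed mean matrices, with
#'   average counts), `ratio_same` / `ratio_other` (per-shuffle delay
#'   ratios), `channel_totals`, `n_shuffles`, `seed`.
#' @seealso [next_spike_delays()], [summarize_delays()]
#' @export
shuffle_labels <- function(events, n_shuffles = 1000, seed = 1L,
                           max_delay_ms = 30) {
  if (n_shuffles < 1) stop("`n_shuffles` must be >= 1", call. = FALSE)
  if (length(unique(events$animal_id)) > 1L)
    stop("shuffle one animal at a time", call. = FALSE)
  o <- order(events$epoch, events$time_ms)
  t <- events$time_ms[o]
  lab0 <- .chan12(events$hemisphere[o], events$layer[o])
  ep <- events$epoch[o]
  big <- if (length(t)) max(t) - min(t) + 2 * max_delay_ms + 1 else 1
  toff <- t + match(ep, unique(ep)) * big

  acc_same <- matrix(0, 6, 6); acc_same_n <- matrix(0, 6, 6)
  acc_other <- matrix(0, 6, 6); acc_other_n <- matrix(0, 6, 6)
  cnt_same <- matrix(0, 6, 6); cnt_other <- matrix(0, 6, 6)
  ratio_same <- numeric(n_shuffles); ratio_other <- numeric(n_shuffles)

  set.seed(as.integer(seed))
  for (s in seq_len(n_shuffles)) {
    lab <- sample(lab0)
    p <- .shuffle_pass(toff, lab, max_delay_ms)
    ds <- !is.na(p$same$mean); do_ <- !is.na(p$other$mean)
    acc_same[ds] <- acc_same[ds] + p$same$mean[ds]
    acc_same_n <- acc_same_n + ds
    acc_other[do_] <- acc_other[do_] + p$other$mean[do_]
    acc_other_n <- acc_other_n + do_
    cnt_same <- cnt_same + p$same$count
    cnt_other <- cnt_other + p$other$count
    ratio_same[s] <- p$ratio_same
    ratio_other[s] <- p$ratio_other
  }
  mk <- function(acc, nacc, cnt) {
    m <- acc / nacc
    m[nacc == 0] <- NA_real_
    dimnames(m) <- list(spike_layer = paste0("L", .LAYERS),
                        target_layer = paste0("L", .LAYERS))
    list(mean = m, count = cnt / n_shuffles)
  }
  structure(list(
    mean_same = mk(acc_same, acc_same_n, cnt_same),
    mean_other = mk(acc_other, acc_other_n, cnt_other),
    ratio_same = ratio_same,
    ratio_other = ratio_other,
    channel_totals = tabulate(lab0, .N_CHANNELS),
    n_shuffles = n_shuffles,
    seed = as.integer(seed),
    max_delay_ms = max_delay_ms
  ), class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, digits = 3, ...) {
  cat("Label-shuffle control:", x$n_shuffles, "shuffles (seed", x$seed, ")\n")
  cat("  delay ratio, same S1 : mean", round(mean(x$ratio_same, na.rm = TRUE),
                                             digits),
      " 95% range", paste(round(stats::quantile(x$ratio_same,
                                                c(.025, .975), na.rm = TRUE),
                                digits), collapse = "-"), "\n")
  cat("  delay ratio, other S1: mean", round(mean(x$ratio_other, na.rm = TRUE),
                                             digits), "\n")
  invisible(x)
}

#' Animal-level nonparametric bootstrap of a paired difference
#'
#' Resamples animals with replacement (keeping each animal's paired values
#' together), computes the mean difference per resample, and reports the
#' percentile 95% confidence interval.  The contrast is deemed significant
#' when the interval excludes zero.
#'
#' @param a,b paired per-animal values (equal length, n >= 2).
#' @param n_boot bootstrap resamples (study default 5000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return an object of class `bootstrap_result`: `mean_difference` (M),
#'   `ci` (percentile interval), `significant`, `n_boot`, `n`, `seed`, and
#'   the resampled means in `boot_means`.
#' @examples
#' set.seed(1)
#' up <- rnorm(6, 1.5, 0.4); down <- rnorm(6, 0.8, 0.1)
#' bootstrap_diff(up, down, n_boot = 1000, seed = 2)
#' @export
bootstrap_diff <- function(a, b, n_boot = 5000, seed = 1L, conf = 0.95) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired", call. = FALSE)
  keep <- is.finite(a) & is.finite(b)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " pair(s) with missing values")
    a <- a[keep]; b <- b[keep]
  }
  n <- length(a)
  if (n < 2) stop("need at least 2 paired values to resample", call. = FALSE)
  if (n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  d <- a - b
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  bm <- rowMeans(matrix(d[idx], n_boot, n))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(bm, c(alpha, 1 - alpha)))
  structure(list(mean_difference = mean(d), ci = ci, conf = conf,
                 significant = ci[1] > 0 || ci[2] < 0,
                 n_boot = as.integer(n_boot), n = n,
                 seed = as.integer(seed), boot_means = bm),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, digits = 3, ...) {
  cat("Bootstrap contrast (n = ", x$n, " animals, ", x$n_boot,
      " resamples)\n", sep = "")
  cat("  M = ", round(x$mean_difference, digits), ", ",
      100 * x$conf, "% CI [", round(x$ci[1], digits), ", ",
      round(x$ci[2], digits), "]",
      if (x$significant) "  (excludes 0)" else "", "\n", sep = "")
  invisible(x)
}
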