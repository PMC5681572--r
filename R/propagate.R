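# Propagation velocity from delay-versus-depth least squares, and layer
# versus depth model comparison via BIC-approximated Bayes factors.

.targets_for <- function(spike_layer, reference) {
  if (reference == "same_S1") {
    if (is.null(spike_layer) || !spike_layer %in% 4:6)
      stop("same_S1 fits use spike layers L4-L6 (only upward targets exist)",
           call. = FALSE)
    seq_len(spike_layer - 1L)
  } else {
    1:6
  }
}

#' Fit upward propagation velocity from a delay row
#'
#' Ordinary least-squares fit of mean next-spike delay (ms) on cortical
#' depth (mm) over the target layers of one spike layer.  Within the spike
#' hemisphere only targets strictly above the spike layer are used (so only
#' spike layers L4-L6 admit the >= 3 points a fit needs); for the other
#' hemisphere all six target layers are used.  The spike layer's own point
#' (delay 0 at its own depth) is never included.
#'
#' A slope in ms/mm is not itself a velocity; the propagation velocity is
#' reported as the reciprocal of its magnitude (mm/ms, numerically equal to
#' m/s).  Depths default to the equally spaced per-layer model depths
#' (0.28 mm spacing) and can be overridden, e.g. with
#' `layer_geometry()$recording_depths_model`.
#'
#' @param delay_row numeric length-6 vector of mean delays onto target
#'   layers L1..L6, ms (`NA` allowed; at least 3 defined target points).
#' @param spike_layer the layer the delays follow (4-6 for `same_S1`).
#' @param reference `"same_S1"` or `"other_S1"`.
#' @param depths optional length-6 depth vector (mm) indexed by layer.
#' @param geometry a [layer_geometry()] supplying the default depths.
#' @return an object of class `velocity_fit`: `spike_layer`, `reference`,
#'   `slope` (ms/mm), `intercept` (ms), `velocity` (m/s; `NA` and flagged
#'   if the slope is 0), `n_points`, `rss` (ms^2).
#' @examples
#' fit_velocity(c(1.2, 0.8, 0.4, NA, NA, NA), spike_layer = 4,
#'              reference = "same_S1")
#' @export
fit_velocity <- function(delay_row, spike_layer = NULL,
                         reference = c("same_S1", "other_S1"),
                         depths = NULL, geometry = layer_geometry()) {
  reference <- match.arg(reference)
  targets <- .targets_for(spike_layer, reference)
  if (is.null(depths)) depths <- geometry$layer_depths_model
  stopifnot(length(delay_row) == 6L, length(depths) == 6L)
  y <- as.numeric(delay_row[targets])
  x <- depths[targets]
  ok <- is.finite(y)
  if (sum(ok) < 3L)
    stop("need >= 3 defined target delays to fit (got ", sum(ok), ")",
         call. = FALSE)
  fit <- stats::lm(y[ok] ~ x[ok])
  slope <- unname(stats::coef(fit)[2L])
  tol <- 1e-9 * max(1, mean(abs(y[ok])))
  vel <- if (abs(slope) > tol) 1 / abs(slope) else NA_real_
  structure(list(spike_layer = spike_layer, reference = reference,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 velocity = vel,
                 zero_slope = is.na(vel),
                 n_points = sum(ok),
                 rss = sum(stats::residuals(fit)^2)),
            class = "velocity_fit")
}

#' @export
print.velocity_fit <- function(x, digits = 3, ...) {
  cat("Velocity fit (", x$reference, ", spikes in L", x$spike_layer, "): ",
      sep = "")
  if (x$zero_slope) cat("zero slope, velocity undefined\n")
  else cat(round(x$velocity, digits), "m/s  (slope",
           round(x$slope, digits), "ms/mm,", x$n_points, "points)\n")
  invisible(x)
}

#' @export
coef.velocity_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Least-squares linear fit with BIC under a Gaussian residual model
#'
#' `BIC = n * log(rss / n) + k * log(n)` with `k = 2` (slope and intercept).
#' Both competing propagation models share this complexity, so constant
#' terms cancel in BIC differences and the residual variance is the only
#' discriminator.
#'
#' @param y response (delays, ms).
#' @param x predictor (depths, mm); same length as `y`, n >= 3.
#' @return list with `rss`, `bic` (`-Inf`, flagged via attribute
#'   `"perfect_fit"`, when the fit is exact), and `coef`.
#' @export
bic_linear_fit <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n <= 2L)
    stop("need more points than parameters (k = 2); got n = ", n,
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  if (rss < (sum(y^2) + 1) * 1e-25) {
    bic <- -Inf
    attr(bic, "perfect_fit") <- TRUE
  } else {
    bic <- n * log(rss / n) + 2 * log(n)
  }
  list(rss = rss, bic = bic, coef = stats::coef(fit))
}

#' Bayes factor for layer versus depth propagation
#'
#' Fits the delay row twice by least squares: once against the equally
#' spaced per-layer model depths (step-wise layer model, M1) and once
#' against the unequally spaced actual recording depths (continuous depth
#' model, M2), and approximates the Bayes factor from their BIC values as
#' `B12 = exp(-(BIC1 - BIC2) / 2)` (models equally likely a priori).
#' `B12 > 1` favors the layer model; values above 3 are conventionally
#' positive evidence, below 1/3 positive evidence for the depth model.
#'
#' @inheritParams fit_velocity
#' @return an object of class `bayes_factor_result`: `spike_layer`,
#'   `reference`, `bic_layer`, `bic_depth`, `bf`, `n_points`.
#' @seealso [bayes_factor_summary()] for the per-animal average.
#' @export
bayes_factor <- function(delay_row, spike_layer = NULL,
                         reference = c("other_S1", "same_S1"),
                         geometry = layer_geometry()) {
  reference <- match.arg(reference)
  targets <- .targets_for(spike_layer, reference)
  y <- as.numeric(delay_row[targets])
  f1 <- bic_linear_fit(y, geometry$layer_depths_model[targets])
  f2 <- bic_linear_fit(y, geometry$recording_depths_model[targets])
  structure(list(spike_layer = spike_layer, reference = reference,
                 bic_layer = f1$bic, bic_depth = f2$bic,
                 bf = exp(-(f1$bic - f2$bic) / 2),
                 n_points = sum(is.finite(y))),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, digits = 3, ...) {
  cat("Bayes factor (", x$reference,
      if (!is.null(x$spike_layer)) paste0(", spikes in L", x$spike_layer),
      "): B12 = ", signif(x$bf, digits),
      "  [BIC layer ", round(x$bic_layer, 2),
      ", BIC depth ", round(x$bic_depth, 2), "]\n", sep = "")
  invisible(x)
}

#' Per-animal Bayes factors and their average
#'
#' Applies [bayes_factor()] to one delay row per animal and averages the
#' per-animal Bayes factors arithmetically (averaging the BF values rather
#' than the BICs limits the influence of outlying animals).
#'
#' @param delay_rows matrix animals x 6 of mean delays onto target layers.
#' @inheritParams fit_velocity
#' @return an object of class `bayes_factor_summary`: `per_animal_bf`,
#'   `mean_bf`, plus the per-animal `bic_layer` / `bic_depth`.
#' @export
bayes_factor_summary <- function(delay_rows, spike_layer = NULL,
                                 reference = c("other_S1", "same_S1"),
                                 geometry = layer_geometry()) {
  reference <- match.arg(reference)
  delay_rows <- as.matrix(delay_rows)
  res <- apply(delay_rows, 1L, bayes_factor, spike_layer = spike_layer,
               reference = reference, geometry = geometry)
  bf <- vapply(res, `[[`, 0, "bf")
  structure(list(spike_layer = spike_layer, reference = reference,
                 per_animal_bf = bf, mean_bf = mean(bf),
                 bic_layer = vapply(res, `[[`, 0, "bic_layer"),
                 bic_depth = vapply(res, `[[`, 0, "bic_depth")),
            class = "bayes_factor_summary")
}

#' @export
print.bayes_factor_summary <- function(x, digits = 3, ...) {
  cat("Mean Bayes factor over ", length(x$per_animal_bf), " animals (",
      x$reference,
      if (!is.null(x$spike_layer)) paste0(", spikes in L", x$spike_layer),
      "): ", signif(x$mean_bf, digits), "\n", sep = "")
  invisible(x)
}
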