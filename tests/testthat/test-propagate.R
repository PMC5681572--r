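# Velocity fits and BIC / Bayes-factor model comparison.

test_that("exact linear delay rows recover the implied velocity", {
  # delays rise 1 ms per 0.28 mm step toward the surface: slope 1/0.28 ms/mm
  row <- c(5, 4, 3, 2, 1, NA)
  fit <- fit_velocity(row, spike_layer = 6, reference = "same_S1")
  expect_equal(fit$velocity, 0.28, tolerance = 1e-10)
  expect_equal(abs(fit$slope), 1 / 0.28, tolerance = 1e-10)
  expect_equal(fit$n_points, 5)
  expect_lt(fit$rss, 1e-20)
  # 0.5 ms per layer step on 0.28 mm spacing -> 0.56 m/s
  row2 <- c(1.5, 1.0, 0.5, NA, NA, NA)
  fit2 <- fit_velocity(row2, spike_layer = 4, reference = "same_S1")
  expect_equal(fit2$velocity, 0.56, tolerance = 1e-10)
})

test_that("velocity fits demand enough points and flag zero slopes", {
  expect_error(fit_velocity(c(1, 2, NA, NA, NA, NA), spike_layer = 4,
                            reference = "same_S1"), ">= 3")
  expect_error(fit_velocity(c(1, 2, 3, NA, NA, NA), spike_layer = 3,
                            reference = "same_S1"), "L4-L6")
  flat <- fit_velocity(rep(2, 6), spike_layer = NULL, reference = "other_S1")
  expect_true(flat$zero_slope)
  expect_true(is.na(flat$velocity))
})

test_that("velocity is recovered from a jittered cascade simulation", {
  # layer-step sweep at 0.56 ms per 0.28 mm step: true velocity 0.5 m/s
  cfg <- clean_cascade_config(lag = 0.56, jitter = 0.1, n_epochs = 60,
                              seed = 15)
  ev <- generate_events(cfg)
  truth <- attr(ev, "ground_truth")$velocity_m_s
  expect_equal(truth, 0.5)
  cl <- collapse_references(next_spike_delays(ev))
  v <- vapply(4:6, function(L) {
    fit_velocity(cl$same$mean[L, ], spike_layer = L,
                 reference = "same_S1")$velocity
  }, 0)
  expect_lt(abs(mean(v) - truth) / truth, 0.2)
})

test_that("BIC matches an independent hand-coded evaluation", {
  set.seed(22)
  for (i in 1:5) {
    y <- rnorm(6, 10, 2)
    x <- layer_geometry()$recording_depths_model
    got <- bic_linear_fit(y, x)
    # normal-equations oracle
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    rss <- sum((y - X %*% beta)^2)
    expect_equal(got$rss, rss, tolerance = 1e-10)
    expect_equal(got$bic, 6 * log(rss / 6) + 2 * log(6), tolerance = 1e-10)
  }
})

test_that("BIC differences agree with stats::BIC on the same fits", {
  # both models share n and k, so the constant terms cancel in the difference
  set.seed(23)
  y <- rnorm(6, 10, 1)
  g <- layer_geometry()
  d_own <- bic_linear_fit(y, g$layer_depths_model)$bic -
    bic_linear_fit(y, g$recording_depths_model)$bic
  d_ref <- stats::BIC(stats::lm(y ~ g$layer_depths_model)) -
    stats::BIC(stats::lm(y ~ g$recording_depths_model))
  expect_equal(d_own, d_ref, tolerance = 1e-8)
})

test_that("degenerate BIC inputs are rejected or flagged", {
  expect_error(bic_linear_fit(c(1, 2), c(0, 1)), "more points")
  perfect <- bic_linear_fit(c(1, 2, 3, 4), c(0, 1, 2, 3))
  expect_identical(perfect$bic, structure(-Inf, perfect_fit = TRUE))
  a <- bic_linear_fit(c(1, 3, 2, 5), c(0, 1, 2, 3))
  b <- bic_linear_fit(c(1, 3, 2, 5), c(0, 1, 2, 3))
  expect_identical(a$bic, b$bic)
})

test_that("the Bayes factor is exp(-dBIC/2), symmetric, and 1 at equal fits", {
  set.seed(24)
  for (i in 1:5) {
    y <- rnorm(6, 10, 1)
    r <- bayes_factor(y, reference = "other_S1")
    expect_identical(r$bf, exp(-(r$bic_layer - r$bic_depth) / 2))
    # swapping the predictor sets inverts the Bayes factor exactly
    g <- layer_geometry()
    gswap <- layer_geometry(g$recording_depths_model, g$layer_depths_model)
    r2 <- bayes_factor(y, reference = "other_S1", geometry = gswap)
    expect_equal(r2$bf, 1 / r$bf, tolerance = 1e-12)
  }
  # identical predictor sets: dBIC = 0, BF = 1 exactly
  gsame <- layer_geometry()
  gsame$recording_depths_model <- gsame$layer_depths_model
  expect_identical(bayes_factor(rnorm(6, 5), geometry = gsame,
                                reference = "other_S1")$bf, 1)
})

test_that("model selection separates layer-spaced from depth-spaced rows", {
  layer_rows <- generate_delay_rows(20, "layer", noise_sd = 0.1, seed = 31)
  depth_rows <- generate_delay_rows(20, "depth", noise_sd = 0.1, seed = 32)
  bf_layer <- bayes_factor_summary(layer_rows, reference = "other_S1")
  bf_depth <- bayes_factor_summary(depth_rows, reference = "other_S1")
  expect_gt(bf_layer$mean_bf, 3)
  expect_lt(bf_depth$mean_bf, 1 / 3)
  # consistency: less noise gives more extreme evidence
  bf_layer_lo <- bayes_factor_summary(
    generate_delay_rows(20, "layer", noise_sd = 0.02, seed = 33),
    reference = "other_S1")
  expect_gt(bf_layer_lo$mean_bf, bf_layer$mean_bf)
  bf_depth_lo <- bayes_factor_summary(
    generate_delay_rows(20, "depth", noise_sd = 0.02, seed = 34),
    reference = "other_S1")
  expect_lt(bf_depth_lo$mean_bf, bf_depth$mean_bf)
})

test_that("same-hemisphere Bayes factors use only upward targets", {
  row <- c(1.2, 0.9, 0.6, NA, NA, NA)
  r <- bayes_factor(row, spike_layer = 4, reference = "same_S1")
  expect_equal(r$n_points, 3)
  expect_error(bayes_factor(row, spike_layer = 2, reference = "same_S1"),
               "L4-L6")
})
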