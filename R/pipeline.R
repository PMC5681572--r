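# End-to-end pipeline driver: generation (or supplied events) -> delay
# matrices -> summaries -> shuffle control -> bootstrap contrasts ->
# velocities -> Bayes factors, with full seed-based reproducibility.

#' Pipeline configuration
#'
#' Bundles the two regime scenarios with the analysis parameters.  `seed`
#' governs every random stage (generation, shuffles, bootstrap); the
#' scenario seeds are derived from it, so a `run_config` plus its seed fully
#' determines the report.
#'
#' @param scenario_evoked,scenario_spontaneous [scenario_config()]s for the
#'   two regimes (defaults are the paper-like study conditions).
#' @param evoked_window_ms analysis window applied to evoked epochs,
#'   half-open, ms.
#' @param max_delay_ms next-spike delay horizon, ms.
#' @param n_shuffles label shuffles per animal (evoked regime).
#' @param n_boot bootstrap resamples per contrast.
#' @param bin_ms bin width of the spike-likelihood profile.
#' @param geometry a [layer_geometry()].
#' @param seed master RNG seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenario_evoked = scenario_config("evoked"),
                       scenario_spontaneous = scenario_config("spontaneous"),
                       evoked_window_ms = c(5, 60),
                       max_delay_ms = 30,
                       n_shuffles = 1000,
                       n_boot = 5000,
                       bin_ms = 1,
                       geometry = layer_geometry(),
                       seed = 1L) {
  stopifnot(inherits(scenario_evoked, "scenario_config"),
            inherits(scenario_spontaneous, "scenario_config"),
            scenario_evoked$regime == "evoked",
            scenario_spontaneous$regime == "spontaneous",
            scenario_evoked$n_animals == scenario_spontaneous$n_animals)
  scenario_evoked$seed <- .epoch_seed(seed, 0L, 0L, salt = 3)
  scenario_spontaneous$seed <- .epoch_seed(seed, 0L, 0L, salt = 4)
  structure(list(scenario_evoked = scenario_evoked,
                 scenario_spontaneous = scenario_spontaneous,
                 evoked_window_ms = evoked_window_ms,
                 max_delay_ms = max_delay_ms,
                 n_shuffles = as.integer(n_shuffles),
                 n_boot = as.integer(n_boot),
                 bin_ms = bin_ms,
                 geometry = geometry,
                 seed = as.integer(seed)),
            class = "run_config")
}

.window_events <- function(events, lo, hi) {
  .as_spike_events(events[events$time_ms >= lo & events$time_ms < hi, ,
                          drop = FALSE])
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# per-animal scalar summaries used by the bootstrap contrasts
.animal_stats_row <- function(animal, regime, cl, shuffle = NULL) {
  s <- suppressWarnings(summarize_delays(cl))
  data.frame(
    animal_id = animal, regime = regime,
    upward_mean = s$upward_mean, downward_mean = s$downward_mean,
    deep_mean = s$deep_mean, superficial_mean = s$superficial_mean,
    ratio_same = unname(s$delay_ratio["same_S1"]),
    ratio_other = unname(s$delay_ratio["other_S1"]),
    same_overall = .cell_mean(cl$same$mean),
    other_overall = .cell_mean(cl$other$mean),
    shuffle_ratio_same = if (is.null(shuffle)) NA_real_
                         else mean(shuffle$ratio_same, na.rm = TRUE),
    shuffle_ratio_other = if (is.null(shuffle)) NA_real_
                          else mean(shuffle$ratio_other, na.rm = TRUE))
}

.grand_matrix <- function(cl_list, ref) {
  means <- lapply(cl_list, function(cl) cl[[ref]]$mean)
  counts <- lapply(cl_list, function(cl) cl[[ref]]$count)
  stack <- simplify2array(means)
  m <- apply(stack, 1:2, mean, na.rm = TRUE)
  m[!is.finite(m)] <- NA_real_
  list(mean = m, count = Reduce(`+`, counts))
}

#' Run the full delay-analysis pipeline on synthetic data
#'
#' Generates both regimes for every animal, computes per-animal next-spike
#' delay matrices (contra- and ipsi-referenced, then collapsed), triangle
#' and interhemispheric summaries, the evoked label-shuffle control,
#' animal-level bootstrap contrasts, per-animal propagation velocities
#' (spike layers L4-L6), and layer-versus-depth Bayes factors, and returns
#' everything in one report.  Identical `(config, seed)` reproduce the
#' report bit-for-bit at the serialized level (see [write_report()]).
#'
#' @param config a [run_config()].
#' @param verbose print per-stage progress?
#' @return an object of class `laminar_report`.
#' @seealso [write_report()], [summary.laminar_report()]
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  n_animals <- config$scenario_evoked$n_animals
  t0 <- Sys.time()

  say("generating events (", n_animals, " animals x 2 regimes)")
  ev_all <- .window_events(generate_events(config$scenario_evoked),
                           config$evoked_window_ms[1],
                           config$evoked_window_ms[2])
  sp_all <- generate_events(config$scenario_spontaneous)

  per_animal <- list()
  stats_rows <- list()
  shuffles <- list()
  vel_rows <- list()
  bf_rows <- list()  # delay rows for bayes_factor_summary, keyed later
  cl_store <- list(evoked = list(), spontaneous = list())

  for (a in seq_len(n_animals)) {
    say("animal ", a, ": delay matrices")
    ev_a <- ev_all[ev_all$animal_id == a, , drop = FALSE]
    sp_a <- sp_all[sp_all$animal_id == a, , drop = FALSE]
    dm <- list(evoked = next_spike_delays(ev_a, config$max_delay_ms),
               spontaneous = next_spike_delays(sp_a, config$max_delay_ms))
    cl <- lapply(dm, collapse_references)
    cl_store$evoked[[a]] <- cl$evoked
    cl_store$spontaneous[[a]] <- cl$spontaneous

    say("animal ", a, ": shuffle control (", config$n_shuffles, " shuffles)")
    sh <- shuffle_labels(ev_a, n_shuffles = config$n_shuffles,
                         seed = .epoch_seed(config$seed, a, 0L, salt = 7),
                         max_delay_ms = config$max_delay_ms)
    shuffles[[a]] <- sh

    for (rg in c("evoked", "spontaneous")) {
      stats_rows[[paste(a, rg)]] <-
        .animal_stats_row(a, rg, cl[[rg]],
                          shuffle = if (rg == "evoked") sh else NULL)
      # velocities: spikes in L4-L6, both references, rows from the
      # reference-collapsed matrices (contra/ipsi averaged within animal)
      for (ref in c("same_S1", "other_S1")) {
        mref <- if (ref == "same_S1") cl[[rg]]$same$mean else cl[[rg]]$other$mean
        for (L in 4:6) {
          fit <- try(fit_velocity(mref[L, ], spike_layer = L, reference = ref,
                                  geometry = config$geometry), silent = TRUE)
          if (!inherits(fit, "try-error"))
            vel_rows[[length(vel_rows) + 1L]] <- data.frame(
              animal_id = a, regime = rg, reference = ref, spike_layer = L,
              slope_ms_per_mm = fit$slope, intercept_ms = fit$intercept,
              velocity_m_s = fit$velocity, n_points = fit$n_points,
              rss = fit$rss)
        }
        layers <- if (ref == "same_S1") 4:6 else 1:6
        for (L in layers) {
          bf_rows[[paste(rg, ref, L, sep = "|")]] <-
            rbind(bf_rows[[paste(rg, ref, L, sep = "|")]], mref[L, ])
        }
      }
    }
    per_animal[[a]] <- list(matrices = dm, collapsed = cl)
  }

  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL

  say("bootstrap contrasts (n_boot = ", config$n_boot, ")")
  st <- function(rg) stats[stats$regime == rg, , drop = FALSE]
  bseed <- function(i) .epoch_seed(config$seed, 0L, i, salt = 8)
  e <- st("evoked"); s <- st("spontaneous")
  boots <- list(
    evoked_up_vs_down = bootstrap_diff(e$upward_mean, e$downward_mean,
                                       config$n_boot, bseed(1)),
    spontaneous_up_vs_down = bootstrap_diff(s$upward_mean, s$downward_mean,
                                            config$n_boot, bseed(2)),
    evoked_superficial_vs_deep = bootstrap_diff(e$superficial_mean,
                                                e$deep_mean,
                                                config$n_boot, bseed(3)),
    spontaneous_superficial_vs_deep = bootstrap_diff(s$superficial_mean,
                                                     s$deep_mean,
                                                     config$n_boot, bseed(4)),
    evoked_ratio_vs_shuffle_same = bootstrap_diff(e$ratio_same,
                                                  e$shuffle_ratio_same,
                                                  config$n_boot, bseed(5)),
    spontaneous_ratio_vs_shuffle_same = bootstrap_diff(s$ratio_same,
                                                       e$shuffle_ratio_same,
                                                       config$n_boot,
                                                       bseed(6)),
    evoked_ratio_vs_shuffle_other = bootstrap_diff(e$ratio_other,
                                                   e$shuffle_ratio_other,
                                                   config$n_boot, bseed(7)),
    spontaneous_ratio_vs_shuffle_other = bootstrap_diff(s$ratio_other,
                                                        e$shuffle_ratio_other,
                                                        config$n_boot,
                                                        bseed(8)),
    spontaneous_vs_evoked_same_overall = bootstrap_diff(s$same_overall,
                                                        e$same_overall,
                                                        config$n_boot,
                                                        bseed(9)),
    evoked_vs_spontaneous_other_overall = bootstrap_diff(e$other_overall,
                                                         s$other_overall,
                                                         config$n_boot,
                                                         bseed(10)))

  say("velocities and Bayes factors")
  velocities <- do.call(rbind, vel_rows)
  rownames(velocities) <- NULL
  vel_summary <- stats::aggregate(velocity_m_s ~ regime + reference,
                                  data = velocities, FUN = mean)

  bf_list <- list()
  bf_tab <- list()
  for (key in names(bf_rows)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    bfs <- bayes_factor_summary(bf_rows[[key]],
                                spike_layer = as.integer(parts[3L]),
                                reference = parts[2L],
                                geometry = config$geometry)
    bf_list[[key]] <- bfs
    bf_tab[[key]] <- data.frame(reference = parts[2L], regime = parts[1L],
                                spike_layer = as.integer(parts[3L]),
                                mean_bf = bfs$mean_bf)
  }
  bayes_factors <- do.call(rbind, bf_tab)
  rownames(bayes_factors) <- NULL
  bayes_factors <- bayes_factors[order(bayes_factors$reference,
                                       bayes_factors$regime,
                                       bayes_factors$spike_layer), ]
  rownames(bayes_factors) <- NULL

  say("spike likelihood profiles")
  lik_list <- lapply(seq_len(n_animals), function(a) {
    spike_likelihood(ev_all[ev_all$animal_id == a, , drop = FALSE],
                     bin_ms = config$bin_ms,
                     n_trials = config$scenario_evoked$n_epochs,
                     window_ms = c(0, config$evoked_window_ms[2]))
  })
  lik_grand <- Reduce(`+`, lapply(lik_list, `[[`, "likelihood")) / n_animals
  peaks <- do.call(rbind, lapply(lik_list, `[[`, "peak_latency_ms"))

  grand <- lapply(cl_store, function(cls) {
    list(same = .grand_matrix(cls, "same"), other = .grand_matrix(cls, "other"))
  })

  structure(list(
    config = config,
    n_animals = n_animals,
    stats = stats,
    per_animal = per_animal,
    shuffles = shuffles,
    grand = grand,
    bootstrap = boots,
    velocities = velocities,
    velocity_summary = vel_summary,
    bayes_factors = bayes_factors,
    bayes_factor_details = bf_list,
    likelihood = list(grand = lik_grand,
                      bin_edges = lik_list[[1L]]$bin_edges,
                      peak_latency_ms = colMeans(peaks, na.rm = TRUE)),
    provenance = list(seed = config$seed,
                      config_hash = .config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("lamidelay"))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "laminar_report")
}

.regime_means <- function(stats, rg) {
  s <- stats[stats$regime == rg, , drop = FALSE]
  vapply(s[, !(names(s) %in% c("animal_id", "regime")), drop = FALSE],
         mean, 0, na.rm = TRUE)
}

#' @export
print.laminar_report <- function(x, digits = 3, ...) {
  cat("Laminar delay analysis report (", x$n_animals, " animals, seed ",
      x$config$seed, ")\n", sep = "")
  for (rg in c("evoked", "spontaneous")) {
    m <- .regime_means(x$stats, rg)
    cat(sprintf("  %-11s upward %.2f ms, downward %.2f ms; other S1 deep %.2f, superficial %.2f ms\n",
                rg, m["upward_mean"], m["downward_mean"], m["deep_mean"],
                m["superficial_mean"]))
    cat(sprintf("              delay ratio same %.2f / other %.2f",
                m["ratio_same"], m["ratio_other"]))
    if (rg == "evoked")
      cat(sprintf("  (shuffled %.2f / %.2f)", m["shuffle_ratio_same"],
                  m["shuffle_ratio_other"]))
    cat("\n")
  }
  cat("  mean velocities (m/s):\n")
  vs <- x$velocity_summary
  for (i in seq_len(nrow(vs)))
    cat(sprintf("    %-12s %-9s %.3f\n", vs$regime[i], vs$reference[i],
                vs$velocity_m_s[i]))
  cat("  mean Bayes factors (layer vs depth model), spike S1 L4-L6:\n")
  bt <- x$bayes_factors
  same <- bt[bt$reference == "same_S1", ]
  for (i in seq_len(nrow(same)))
    cat(sprintf("    %-12s L%d  %.2f\n", same$regime[i], same$spike_layer[i],
                same$mean_bf[i]))
  invisible(x)
}

#' Summarize a pipeline report
#'
#' @param object a `laminar_report`.
#' @param ... unused.
#' @return a list with per-regime means across animals, bootstrap contrast
#'   table, velocity summary and Bayes-factor table.
#' @export
summary.laminar_report <- function(object, ...) {
  boots <- do.call(rbind, lapply(names(object$bootstrap), function(nm) {
    b <- object$bootstrap[[nm]]
    data.frame(contrast = nm, M = b$mean_difference,
               ci_low = b$ci[1], ci_high = b$ci[2],
               significant = b$significant)
  }))
  out <- list(regime_means = rbind(evoked = .regime_means(object$stats,
                                                          "evoked"),
                                   spontaneous = .regime_means(object$stats,
                                                               "spontaneous")),
              bootstrap = boots,
              velocity_summary = object$velocity_summary,
              bayes_factors = object$bayes_factors,
              provenance = object$provenance)
  class(out) <- "summary.laminar_report"
  out
}

#' @export
print.summary.laminar_report <- function(x, ...) {
  cat("Regime means across animals:\n")
  print(round(x$regime_means, 3))
  cat("\nBootstrap contrasts:\n")
  print(transform(x$bootstrap, M = round(M, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3)), row.names = FALSE)
  cat("\nVelocity summary (m/s):\n")
  print(x$velocity_summary, row.names = FALSE)
  cat("\nBayes factors:\n")
  print(x$bayes_factors, row.names = FALSE)
  invisible(x)
}

#' Serialize a report to a directory of text artifacts
#'
#' Writes `summary_stats.tsv` (per-animal scalar summaries),
#' `delay_matrices.tsv` (long-format per-animal and grand-average cells),
#' `velocities.csv`, `bayes_factors.csv`, `bootstrap.json` and
#' `report.json` (headline numbers plus provenance: seed, config hash,
#' package version).  Output is deterministic: rerunning the pipeline with
#' the same config and seed reproduces every file byte for byte.
#'
#' @param report a `laminar_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "laminar_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  utils::write.table(report$stats, p("summary_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  long <- list()
  for (a in seq_len(report$n_animals)) {
    for (rg in c("evoked", "spontaneous")) {
      long[[paste(a, rg)]] <-
        delay_matrix_long(report$per_animal[[a]]$collapsed[[rg]],
                          animal_id = a, regime = rg)
    }
  }
  for (rg in c("evoked", "spontaneous")) {
    g <- report$grand[[rg]]
    long[[paste("grand", rg)]] <-
      delay_matrix_long(structure(list(same = g$same, other = g$other),
                                  class = "delay_matrices_collapsed"),
                        animal_id = "grand", regime = rg)
  }
  long <- do.call(rbind, long)
  long$mean_delay_ms <- round(long$mean_delay_ms, 6)
  utils::write.table(long, p("delay_matrices.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  utils::write.csv(report$velocities, p("velocities.csv"), row.names = FALSE)
  utils::write.csv(report$bayes_factors, p("bayes_factors.csv"),
                   row.names = FALSE)

  boots <- lapply(report$bootstrap, function(b) {
    list(M = b$mean_difference, ci_95 = b$ci, n_boot = b$n_boot,
         n = b$n, seed = b$seed, significant = b$significant)
  })
  jsonlite::write_json(boots, p("bootstrap.json"), auto_unbox = TRUE,
                       digits = NA)

  sm <- summary(report)
  head_json <- list(
    provenance = report$provenance,
    regime_means = as.list(as.data.frame(t(sm$regime_means))),
    velocity_summary = sm$velocity_summary,
    bayes_factors = sm$bayes_factors)
  jsonlite::write_json(head_json, p("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
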