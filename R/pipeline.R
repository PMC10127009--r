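#' Build a synthetic cohort specification
#'
#' Creates `n` ground-truth cells sharing a species morphology and nominal
#' kinematics, with per-cell speeds drawn around the cohort mean and
#' per-cell seeds derived deterministically from the cohort seed.
#'
#' @param name Cohort label used in reports.
#' @param n Number of cells (default 26).
#' @param morphology A [sperm_morphology()].
#' @param mean_speed Cohort mean swimming speed, um/s.
#' @param sd_speed Between-cell speed standard deviation, um/s (default 15).
#' @param frequency Beat frequency, Hz.
#' @param heading_rate Heading change rate, deg/s (0 = straight swimmers).
#' @param duration Per-cell recording duration, s (default 0.4).
#' @param fps Frame rate (default 150).
#' @param noise_sd Coordinate noise sd, um (default 0).
#' @param seed Cohort seed; cell i uses `seed * 1000 + i`.
#' @param ... Further arguments passed to [beat_parameters()].
#' @return A list of class `cohort_spec` with `name` and `truths`.
#' @export
make_cohort <- function(name, n = 26, morphology, mean_speed = 250,
                        sd_speed = 15, frequency = 50, heading_rate = 0,
                        duration = 0.4, fps = 150, noise_sd = 0, seed = 1,
                        ...) {
  stopifnot(n >= 1)
  speeds <- with_seed(seed, pmax(1, rnorm(n, mean_speed, sd_speed)))
  truths <- lapply(seq_len(n), function(i)
    ground_truth(morphology,
                 beat_parameters(frequency = frequency, noise_sd = noise_sd,
                                 ...),
                 swim_parameters(speed = speeds[i],
                                 heading_rate = heading_rate,
                                 duration = duration, fps = fps,
                                 seed = seed * 1000 + i)))
  structure(list(name = name, truths = truths), class = "cohort_spec")
}

#' Run a full synthetic experiment
#'
#' Simulates every cell of every cohort, runs the kinematics, waveform and
#' statistics stages, and assembles an experiment report: per-cell and
#' per-cohort kinematics (VCL, beat frequency, motion labels), a
#' Mann-Whitney comparison of the first two cohorts' VCLs, per-part
#' straight-versus-turn significance profiles built by pooling each cell's
#' windows according to its motion labels, and ground-truth recovery
#' deltas. Deterministic given the seeds carried by the cohort truths.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param cohorts List of [make_cohort()] specifications (>= 1).
#' @param output_dir Optional directory; when given, summary CSV, profile
#'   CSVs, a JSON summary and a plain-text report are written there.
#' @return An object of class `experiment_report`.
#' @export
run_synthetic_experiment <- function(config, cohorts, output_dir = NULL) {
  stopifnot(length(cohorts) >= 1)
  for (co in cohorts) {
    fps_all <- vapply(co$truths, function(tr) tr$swim$fps, numeric(1))
    if (any(fps_all != config$fps))
      stop("cohort '", co$name, "' fps (", fps_all[1],
           ") conflicts with config fps (", config$fps, ")", call. = FALSE)
  }
  cells <- list()
  straight_pool <- list()
  turn_pool <- list()
  for (co in cohorts) {
    for (i in seq_along(co$truths)) {
      truth <- co$truths[[i]]
      sim <- simulate_sperm(truth)
      ks <- kinematics_summary(sim$trace, sim$track, config)
      cell_id <- sprintf("%s_%02d", gsub("\\s+", "_", co$name), i)
      labs <- ks$motion$label
      cells[[cell_id]] <- list(
        cohort = co$name, cell_id = cell_id, truth = truth,
        vcl = ks$vcl, beat = ks$beat_frequency,
        n_straight = sum(labs == "straight"), n_turn = sum(labs == "turn"))
      # pool 10-frame windows into the straight or turn curvature sample
      for (w in seq_len(nrow(ks$motion))) {
        if (labs[w] == "immotile") next
        for (part in c("head", "tail")) {
          ser <- collect_series(sim$trace, part,
                                start_frame = ks$motion$start_frame[w],
                                window_frames = config$window_frames,
                                spacing = config$station_spacing,
                                condition_label = labs[w])
          slot <- paste(co$name, part, sep = "|")
          if (labs[w] == "straight")
            straight_pool[[slot]] <- c(straight_pool[[slot]], list(ser))
          else turn_pool[[slot]] <- c(turn_pool[[slot]], list(ser))
        }
      }
    }
  }
  cell_df <- do.call(rbind, lapply(cells, function(cl)
    data.frame(cell_id = cl$cell_id, cohort = cl$cohort,
               species = cl$truth$morphology$species_label,
               vcl_um_s = cl$vcl, beat_hz = cl$beat,
               true_speed_um_s = cl$truth$swim$speed,
               true_beat_hz = cl$truth$beat$frequency,
               n_windows_straight = cl$n_straight,
               n_windows_turn = cl$n_turn)))
  rownames(cell_df) <- NULL
  cohort_df <- do.call(rbind, lapply(cohorts, function(co) {
    sub <- cell_df[cell_df$cohort == co$name, ]
    data.frame(cohort = co$name, n = nrow(sub),
               mean_vcl_um_s = mean(sub$vcl_um_s),
               mean_beat_hz = mean(sub$beat_hz),
               mean_true_speed_um_s = mean(sub$true_speed_um_s),
               mean_abs_vcl_delta = mean(abs(sub$vcl_um_s -
                                             sub$true_speed_um_s)),
               mean_abs_beat_delta = mean(abs(sub$beat_hz -
                                              sub$true_beat_hz)))
  }))
  rownames(cohort_df) <- NULL

  speed_test <- NULL
  if (length(cohorts) >= 2) {
    va <- cell_df$vcl_um_s[cell_df$cohort == cohorts[[1]]$name]
    vb <- cell_df$vcl_um_s[cell_df$cohort == cohorts[[2]]$name]
    speed_test <- mann_whitney_exact(va, vb)
  }

  profiles <- list()
  for (slot in union(names(straight_pool), names(turn_pool))) {
    sp <- straight_pool[[slot]]
    tp <- turn_pool[[slot]]
    if (is.null(sp) || is.null(tp)) next
    parts <- strsplit(slot, "|", fixed = TRUE)[[1]]
    profiles[[slot]] <- station_significance(
      merge_series(sp, paste(parts[1], parts[2], "straight")),
      merge_series(tp, paste(parts[1], parts[2], "turn")),
      alpha = config$alpha)
  }

  report <- structure(list(cells = cell_df, cohorts = cohort_df,
                           speed_test = speed_test, profiles = profiles,
                           config = config),
                      class = "experiment_report")
  if (!is.null(output_dir)) write_experiment(report, output_dir)
  report
}

# concatenate the frame columns of compatible station series, truncating to
# the shortest common station range
merge_series <- function(series_list, label) {
  k <- min(vapply(series_list, function(s) length(s$stations), integer(1)))
  first <- series_list[[1]]
  samples <- do.call(cbind, lapply(series_list, function(s)
    s$samples[1:k, , drop = FALSE]))
  structure(list(part = first$part, stations = first$stations[1:k],
                 samples = samples, window_frames = first$window_frames,
                 condition_label = label, spacing = first$spacing),
            class = "station_series")
}

write_experiment <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cells,
                   file.path(output_dir, "cells_summary.csv"),
                   row.names = FALSE)
  for (slot in names(report$profiles)) {
    fn <- paste0("profile_", gsub("[^A-Za-z0-9]+", "_", slot), ".csv")
    utils::write.csv(report$profiles[[slot]]$table,
                     file.path(output_dir, fn), row.names = FALSE)
  }
  summ <- list(
    cohorts = report$cohorts,
    speed_test = if (!is.null(report$speed_test))
      list(u = report$speed_test$statistic,
           p_value = report$speed_test$p_value,
           method = report$speed_test$method),
    profiles = lapply(report$profiles, function(pr)
      list(comparison = pr$comparison,
           percent_significant = pr$percent_significant,
           n_stations = pr$n_stations, alpha = pr$alpha)))
  jsonlite::write_json(summ, file.path(output_dir, "experiment_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(output_dir, "report.txt"))
  invisible(output_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Synthetic sperm-motility experiment\n")
  cat("===================================\n\n")
  cat("Cohorts:\n")
  print(x$cohorts, row.names = FALSE, digits = 6)
  if (!is.null(x$speed_test)) {
    cat("\nVCL comparison (first two cohorts):\n")
    print(x$speed_test)
  }
  if (length(x$profiles)) {
    cat("\nStraight-vs-turn curvature profiles:\n")
    for (pr in x$profiles) print(pr)
  }
  invisible(x)
}
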