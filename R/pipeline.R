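# End-to-end analysis pipeline and structured configuration.

#' Default analysis configuration
#'
#' Collects every tunable parameter of the pipeline with its default:
#' lap length and count, the 4 m elevation-difference threshold, the 5 m
#' distance grid, the 5 Hz low-pass cut-off, k = 5 neighbours, 0.25 m/s speed
#' bins, and one master seed for all randomness.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    lap_length = 2465, n_laps = 4, min_elev_diff = 4, grid_m = 5,
    smooth_window_s = 1.0, profile_smooth_m = 15, hysteresis_m = 20,
    cutoff_hz = 5, filter_order = 4, k = 5, bin_width = 0.25,
    bin_min = 2, bin_max = 11, seed = 1,
    gnss = NULL, imu = NULL, reference_gnss = character(0),
    out_dir = NULL, skip_classification = FALSE, make_plots = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("Unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (key in c("lap_length", "n_laps", "min_elev_diff", "grid_m", "cutoff_hz",
                "filter_order", "k", "bin_width")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("Config key '", key, "' must be a positive number.")
    }
  }
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' Flat key-value YAML; every key overrides its [analysis_config()] default.
#'
#' @param path YAML file path.
#' @return A config list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

load_and_derive <- function(path_or_df, cfg) {
  traj <- if (is.character(path_or_df)) read_gnss(path_or_df) else as_trajectory(path_or_df)
  traj <- smooth_positions(traj, cfg$smooth_window_s)
  traj <- derive_speed(traj, cfg$smooth_window_s)
  cumulative_distance(traj)
}

#' Run the full analysis pipeline
#'
#' From a GNSS track (and optionally an IMU stream and reference tracks):
#' derives kinematics, builds the course model, splits and resamples laps,
#' compares the skier to the reference group, classifies sub-techniques and
#' computes their speed-binned distribution. When `out_dir` is set, writes
#' `course.json`, `comparison.csv`, `labels.csv`, `distribution.csv` (and
#' figures if `make_plots`). Stage errors propagate with a stage-named
#' message and nothing is written on failure.
#'
#' @param config From [analysis_config()] or [read_config()]. The skier track
#'   is `config$gnss` (path or data frame of fixes), the IMU stream
#'   `config$imu` (path or tibble), reference tracks `config$reference_gnss`
#'   (paths or list of data frames).
#' @param course Optional pre-built `ski_course` model; otherwise segmented
#'   from the skier's own track.
#' @param train Optional [training_set()]; defaults to the packaged
#'   simulator-generated set.
#' @return A `ski_report` list: `course`, `skier_series`, `reference`,
#'   `comparison`, `labels`, `distribution`, `config`.
#' @export
run_pipeline <- function(config = analysis_config(), course = NULL, train = NULL) {
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  traj <- stage("track_io", {
    if (is.null(cfg$gnss)) stop("config$gnss is required")
    t <- load_and_derive(cfg$gnss, cfg)
    pipeline_log("track_io", "%d fixes, %.0f m total", nrow(t), max(t$cum_dist))
    t
  })
  course <- stage("course_segmentation", {
    if (is.null(course)) {
      prof <- build_profile(traj, cfg$lap_length, cfg$grid_m, cfg$profile_smooth_m)
      course <- detect_segments(prof, cfg$min_elev_diff, cfg$hysteresis_m)
    }
    pipeline_log("course_segmentation", "%d segments", nrow(course$segments))
    course
  })
  skier_series <- stage("lap_performance", {
    laps <- split_laps(traj, cfg$lap_length, cfg$n_laps)
    s <- interpolate_by_distance(laps, cfg$lap_length, cfg$grid_m)
    pipeline_log("lap_performance", "%d laps onto %d grid points",
                 length(laps), length(s$d))
    s
  })
  reference <- comparison <- NULL
  if (length(cfg$reference_gnss)) {
    comparison <- stage("lap_performance", {
      members <- lapply(cfg$reference_gnss, function(p) {
        rt <- load_and_derive(p, cfg)
        interpolate_by_distance(split_laps(rt, cfg$lap_length, cfg$n_laps),
                                cfg$lap_length, cfg$grid_m)
      })
      reference <- group_reference(members)
      compare_to_reference(skier_series, reference, course)
    })
  }
  labels <- distribution <- NULL
  if (!is.null(cfg$imu) && !isTRUE(cfg$skip_classification)) {
    labels <- stage("subtechnique", {
      imu <- if (is.character(cfg$imu)) read_imu(cfg$imu) else cfg$imu
      imu <- align_imu(imu, traj)
      w <- make_windows(imu, filter_spec(cfg$cutoff_hz, cfg$filter_order))
      if (is.null(train)) train <- default_training_set()
      w <- classify_windows(w, train, k = cfg$k)
      pipeline_log("subtechnique", "%d windows classified", nrow(w))
      labels_to_distance(w, seq(0, cfg$lap_length, by = cfg$grid_m),
                         lap_length = cfg$lap_length)
    })
    distribution <- stage("distribution", {
      binning <- speed_binning(seq(cfg$bin_min, cfg$bin_max, by = cfg$bin_width))
      bin_by_speed(labels, skier_series, binning)
    })
  }
  report <- structure(
    list(course = course, skier_series = skier_series, reference = reference,
         comparison = comparison, labels = labels,
         distribution = distribution, config = cfg),
    class = "ski_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write a report bundle to a directory
#'
#' @param report A `ski_report` from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_course_json(report$course, file.path(dir, "course.json"))
  if (!is.null(report$comparison)) {
    readr::write_csv(tidy(report$comparison), file.path(dir, "comparison.csv"))
  }
  if (!is.null(report$labels)) {
    readr::write_csv(
      dplyr::mutate(report$labels, label = as.character(.data$label)),
      file.path(dir, "labels.csv")
    )
  }
  if (!is.null(report$distribution)) {
    readr::write_csv(tibble::as_tibble(report$distribution),
                     file.path(dir, "distribution.csv"))
  }
  if (isTRUE(report$config$make_plots)) {
    save_plot <- function(p, name) {
      ggplot2::ggsave(file.path(dir, name), p, width = 8, height = 6, dpi = 150)
    }
    if (!is.null(report$comparison)) save_plot(autoplot(report$comparison), "comparison.png")
    if (!is.null(report$distribution)) save_plot(autoplot(report$distribution), "distribution.png")
  }
  invisible(dir)
}

#' @export
print.ski_report <- function(x, ...) {
  cat("<ski_report>\n")
  cat("  course: ", nrow(x$course$segments), " segments\n", sep = "")
  if (!is.null(x$comparison)) print(tidy(x$comparison))
  if (!is.null(x$distribution)) print(range_summary(x$distribution))
  invisible(x)
}
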