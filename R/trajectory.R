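# GNSS / IMU ingest, local projection and kinematic derivation.
#
# A trajectory is a tibble with one row per GNSS fix and columns
#   t    seconds since session start (strictly increasing)
#   lat, lon  degrees WGS84
#   alt  metres
#   x, y metres in a local planar projection centred on the track
# plus, after derivation, `speed` (m/s) and `cum_dist` (m).

EARTH_RADIUS_M <- 6378137

new_trajectory <- function(df, origin) {
  df <- tibble::as_tibble(df)
  attr(df, "origin") <- origin
  class(df) <- c("ski_trajectory", class(df))
  df
}

#' Read a GNSS track
#'
#' Reads a GPX 1.1 file (`trkpt` latitude/longitude/elevation/time) or a CSV
#' file with columns `t, lat, lon, alt` into a trajectory tibble. Fixes are
#' sorted by time, duplicate timestamps collapsed (first kept, with a warning),
#' the time base rebased to seconds since the first fix, and local planar
#' coordinates `x, y` computed from a tangent-plane projection centred on the
#' track's median fix.
#'
#' @param path Path to the GPX or CSV file.
#' @param format `"gpx"`, `"csv"`, or `"auto"` (by file extension).
#' @return A trajectory tibble with columns `t, lat, lon, alt, x, y`.
#' @examples
#' \dontrun{
#' traj <- read_gnss("race.gpx") |> derive_speed() |> cumulative_distance()
#' }
#' @export
read_gnss <- function(path, format = c("auto", "gpx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else "csv"
  }
  if (!file.exists(path)) stop("GNSS file not found: ", path)
  raw <- if (format == "gpx") parse_gpx(path) else parse_gnss_csv(path)
  as_trajectory(raw)
}

parse_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0) stop("GPX file contains no track points: ", path)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  ele <- xml2::xml_text(xml2::xml_find_first(pts, "./ele"))
  tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  if (anyNA(ele) || any(ele == "")) {
    stop("GPX track points lack <ele> elevation; altitude is required.")
  }
  t <- as.numeric(as.POSIXct(tim, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  if (anyNA(t)) stop("GPX track points carry unparseable <time> stamps.")
  tibble::tibble(t = t, lat = lat, lon = lon, alt = as.numeric(ele))
}

parse_gnss_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t", "lat", "lon", "alt")
  miss <- setdiff(need, names(df))
  if ("alt" %in% miss) stop("GNSS CSV lacks the required 'alt' column.")
  if (length(miss)) stop("GNSS CSV lacks required columns: ", paste(miss, collapse = ", "))
  dplyr::select(df, dplyr::all_of(need))
}

#' Build a trajectory from a data frame of fixes
#'
#' Validates, time-sorts and deduplicates raw fixes and attaches local planar
#' coordinates. Exposed so simulated or externally parsed fixes enter the same
#' pipeline as file reads.
#'
#' @param df Data frame with columns `t, lat, lon, alt`.
#' @return A trajectory tibble.
#' @export
as_trajectory <- function(df) {
  df <- tibble::as_tibble(df)[c("t", "lat", "lon", "alt")]
  if (nrow(df) < 2) stop("A trajectory needs at least 2 fixes.")
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180)) {
    stop("Latitude/longitude outside valid WGS84 range.")
  }
  df <- dplyr::arrange(df, .data$t)
  dup <- duplicated(df$t)
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) collapsed (first fix kept).")
    df <- df[!dup, ]
  }
  if (nrow(df) < 2) stop("A trajectory needs at least 2 distinct fixes.")
  df$t <- df$t - df$t[1]
  origin <- c(lat = stats::median(df$lat), lon = stats::median(df$lon))
  xy <- project_local(df$lat, df$lon, origin)
  df$x <- xy$x
  df$y <- xy$y
  new_trajectory(df, origin)
}

# Local tangent-plane projection centred on (origin lat, lon): metres east/north.
project_local <- function(lat, lon, origin) {
  k <- pi / 180 * EARTH_RADIUS_M
  list(
    x = (lon - origin[["lon"]]) * k * cos(origin[["lat"]] * pi / 180),
    y = (lat - origin[["lat"]]) * k
  )
}

unproject_local <- function(x, y, origin) {
  k <- pi / 180 * EARTH_RADIUS_M
  list(
    lat = origin[["lat"]] + y / k,
    lon = origin[["lon"]] + x / (k * cos(origin[["lat"]] * pi / 180))
  )
}

# Centred moving average with shrinking windows at the ends, O(n) via cumsum.
moving_average <- function(x, half) {
  n <- length(x)
  if (half <= 0 || n < 3) return(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1)
  hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth planar positions
#'
#' Applies a centred moving average over `window_s` seconds to the projected
#' `x`, `y` (and `alt`) coordinates. Recommended before [cumulative_distance()]
#' on real receiver data: summing raw noisy steps inflates distance, while a
#' short positional smooth removes the high-frequency error without biasing a
#' 2.5 km lap.
#'
#' @param traj Trajectory tibble.
#' @param window_s Smoothing window in seconds (default 1.0).
#' @return The trajectory with smoothed `x`, `y`, `alt`.
#' @export
smooth_positions <- function(traj, window_s = 1.0) {
  stopifnot(nrow(traj) >= 3)
  dt <- stats::median(diff(traj$t))
  half <- max(floor(window_s / dt / 2), 0)
  traj$x <- moving_average(traj$x, half)
  traj$y <- moving_average(traj$y, half)
  traj$alt <- moving_average(traj$alt, half)
  traj
}

#' Derive horizontal speed by time differentiation of position
#'
#' Speed at each fix is the magnitude of the central finite difference of the
#' planar coordinates with respect to time (one-sided at the endpoints),
#' followed by a centred moving average over `smooth_window_s`.
#'
#' @param traj Trajectory tibble with `x`, `y`.
#' @param smooth_window_s Moving-average window in seconds (default 1.0);
#'   0 disables smoothing.
#' @return The trajectory with a `speed` column (m/s).
#' @export
derive_speed <- function(traj, smooth_window_s = 1.0) {
  n <- nrow(traj)
  if (n < 3) stop("derive_speed needs at least 3 fixes.")
  if (any(diff(traj$t) <= 0)) stop("Trajectory time must be strictly increasing.")
  t <- traj$t
  vx <- numeric(n)
  vy <- numeric(n)
  i <- 2:(n - 1)
  vx[i] <- (traj$x[i + 1] - traj$x[i - 1]) / (t[i + 1] - t[i - 1])
  vy[i] <- (traj$y[i + 1] - traj$y[i - 1]) / (t[i + 1] - t[i - 1])
  vx[1] <- (traj$x[2] - traj$x[1]) / (t[2] - t[1])
  vy[1] <- (traj$y[2] - traj$y[1]) / (t[2] - t[1])
  vx[n] <- (traj$x[n] - traj$x[n - 1]) / (t[n] - t[n - 1])
  vy[n] <- (traj$y[n] - traj$y[n - 1]) / (t[n] - t[n - 1])
  speed <- sqrt(vx^2 + vy^2)
  if (smooth_window_s > 0) {
    dt <- stats::median(diff(t))
    speed <- moving_average(speed, max(floor(smooth_window_s / dt / 2), 0))
  }
  traj$speed <- speed
  traj
}

#' Cumulative horizontal distance along a trajectory
#'
#' `cum_dist[1] = 0`; each subsequent value adds the Euclidean planar step
#' length from the previous fix.
#'
#' @param traj Trajectory tibble with `x`, `y`.
#' @return The trajectory with a `cum_dist` column (m).
#' @export
cumulative_distance <- function(traj) {
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  traj$cum_dist <- c(0, cumsum(steps))
  traj
}

#' Read a 100 Hz IMU stream
#'
#' CSV with columns `t, ax, ay, az, gx, gy, gz`: time in seconds on the GNSS
#' clock, accelerations in m/s^2, angular rates in rad/s. Rows are sorted by
#' time. The z axis points in the skier's frontal direction.
#'
#' @param path Path to the IMU CSV file.
#' @return A tibble of IMU samples.
#' @export
read_imu <- function(path) {
  if (!file.exists(path)) stop("IMU file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("IMU CSV lacks required columns: ", paste(miss, collapse = ", "))
  df <- dplyr::arrange(dplyr::select(df, dplyr::all_of(need)), .data$t)
  if (any(diff(df$t) <= 0)) {
    warning("Duplicate IMU timestamps collapsed (first sample kept).")
    df <- df[!duplicated(df$t), ]
  }
  df
}

#' Align an IMU stream to a GNSS trajectory
#'
#' Trims IMU samples outside the GNSS time span and attaches a linearly
#' interpolated `speed` and `cum_dist` to every remaining sample. Both streams
#' must share the session clock.
#'
#' @param imu IMU sample tibble (from [read_imu()] or the simulator).
#' @param traj Trajectory with `speed` and `cum_dist` derived.
#' @return The trimmed IMU tibble with `speed` and `cum_dist` columns.
#' @export
align_imu <- function(imu, traj) {
  if (!all(c("speed", "cum_dist") %in% names(traj))) {
    stop("Trajectory must carry derived speed and cum_dist before alignment.")
  }
  lo <- min(traj$t)
  hi <- max(traj$t)
  if (max(imu$t) < lo || min(imu$t) > hi) {
    stop("IMU and GNSS time ranges are disjoint; streams cannot be aligned.")
  }
  imu <- dplyr::filter(imu, .data$t >= lo, .data$t <= hi)
  imu$speed <- stats::approx(traj$t, traj$speed, xout = imu$t, rule = 2)$y
  imu$cum_dist <- stats::approx(traj$t, traj$cum_dist, xout = imu$t, rule = 2)$y
  imu
}

#' Bundle one athlete's race recording
#'
#' A light container pairing a derived trajectory with its aligned IMU stream
#' and athlete metadata.
#'
#' @param trajectory Trajectory tibble (speed and cumulative distance derived).
#' @param imu Aligned IMU tibble, or `NULL` when only GNSS analysis is wanted.
#' @param athlete_id Identifier string.
#' @param group `"PARA"` or `"AB"`.
#' @param sex `"F"` or `"M"`.
#' @param class_label Para classification label (e.g. `"LW4"`, `"B3"`), or `""`.
#' @param n_laps Number of laps raced (>= 1).
#' @return A `ski_session` list.
#' @export
ski_session <- function(trajectory, imu = NULL, athlete_id = "athlete",
                        group = c("AB", "PARA"), sex = c("F", "M"),
                        class_label = "", n_laps = 1) {
  group <- match.arg(group)
  sex <- match.arg(sex)
  stopifnot(n_laps >= 1)
  structure(
    list(
      athlete_id = athlete_id, group = group, sex = sex,
      class_label = class_label, trajectory = trajectory, imu = imu,
      n_laps = as.integer(n_laps)
    ),
    class = "ski_session"
  )
}

#' Write a trajectory as CSV
#'
#' Emits the package CSV dialect (`t, lat, lon, alt` plus any derived columns).
#'
#' @param traj Trajectory tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gnss_csv <- function(traj, path) {
  keep <- intersect(c("t", "lat", "lon", "alt", "speed", "cum_dist"), names(traj))
  readr::write_csv(tibble::as_tibble(traj)[keep], path)
  invisible(path)
}

#' Write a GPX 1.1 track
#'
#' @param traj Trajectory tibble.
#' @param path Output path.
#' @param start_time POSIXct session start used to stamp `<time>` elements.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(traj, path, start_time = as.POSIXct("2026-01-15 10:00:00", tz = "UTC")) {
  # %OS truncates fractional seconds; nudge by half the printed resolution
  stamp <- format(start_time + traj$t + 5e-4, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  pts <- sprintf(
    '    <trkpt lat="%.8f" lon="%.8f"><ele>%.3f</ele><time>%s</time></trkpt>',
    traj$lat, traj$lon, traj$alt, stamp
  )
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="skitrax" xmlns="http://www.topografix.com/GPX/1/1">',
    "  <trk><trkseg>", pts, "  </trkseg></trk>", "</gpx>"
  ), path)
  invisible(path)
}
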