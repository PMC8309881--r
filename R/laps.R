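# Lap splitting, distance interpolation and between-skier comparison.
#
# A lap series is a tibble(d, speed, time): speed and elapsed time on a common
# lap distance grid, averaged over a skier's laps. Per-lap matrices are kept in
# attributes for across-lap dispersion.

#' Split a recording into laps
#'
#' Lap boundaries are placed where cumulative distance crosses each multiple
#' of `lap_length`, with the crossing time found by linear interpolation. Each
#' lap trace is re-zeroed: `d` runs from 0 and `time` from 0 at the lap start.
#'
#' @param traj Trajectory with `speed` and `cum_dist`.
#' @param lap_length Lap length in metres.
#' @param n_laps Number of laps; default `floor(total distance / lap_length)`.
#' @return List of lap tibbles, each with columns `t`, `d`, `speed`, `time`.
#' @export
split_laps <- function(traj, lap_length, n_laps = NULL) {
  if (!all(c("speed", "cum_dist") %in% names(traj))) {
    stop("Trajectory must carry derived speed and cum_dist.")
  }
  total <- max(traj$cum_dist)
  if (is.null(n_laps)) n_laps <- max(floor(total / lap_length), 1)
  if (total < 0.95 * n_laps * lap_length) {
    stop(sprintf("Recording covers %.0f m; incomplete for %d laps of %.0f m.",
                 total, n_laps, lap_length))
  }
  bounds <- lap_length * seq_len(n_laps - 1)
  t_bounds <- if (length(bounds)) {
    stats::approx(traj$cum_dist, traj$t, xout = bounds, ties = "ordered")$y
  } else numeric(0)
  starts <- c(min(traj$t), t_bounds)
  ends <- c(t_bounds, max(traj$t))
  lapply(seq_len(n_laps), function(k) {
    lo <- starts[k]
    hi <- ends[k]
    inside <- traj$t > lo & traj$t < hi
    t_k <- c(lo, traj$t[inside], hi)
    d_k <- stats::approx(traj$t, traj$cum_dist, xout = t_k, ties = "ordered")$y
    v_k <- stats::approx(traj$t, traj$speed, xout = t_k, ties = "ordered")$y
    tibble::tibble(
      t = t_k,
      d = d_k - (k - 1) * lap_length,
      speed = v_k,
      time = t_k - lo
    )
  })
}

#' Resample laps onto a common distance grid
#'
#' Speed and elapsed time are linearly interpolated onto the grid for each
#' lap, then averaged pointwise across laps.
#'
#' A measured lap rarely covers the nominal length exactly; grid points past
#' a lap's last sample are filled by constant-speed extrapolation as long as
#' the shortfall stays within `tol_frac` of the lap length, and are an error
#' beyond that.
#'
#' @param laps List of lap tibbles from [split_laps()] (columns `d`, `speed`,
#'   `time`), or analytically constructed traces.
#' @param lap_length Lap length in metres; the grid spans `[0, lap_length]`.
#' @param grid_m Grid spacing in metres (default 5).
#' @param tol_frac Maximum tolerated lap shortfall as a fraction of
#'   `lap_length` (default 0.02).
#' @return A `ski_lap_series` tibble with columns `d`, `speed`, `time` and
#'   per-lap matrices in attributes `speed_laps`, `time_laps`.
#' @export
interpolate_by_distance <- function(laps, lap_length, grid_m = 5,
                                    tol_frac = 0.02) {
  if (!length(laps)) stop("At least one lap is required.")
  d_grid <- seq(0, lap_length, by = grid_m)
  shortest <- min(vapply(laps, function(l) max(l$d), numeric(1)))
  if (max(d_grid) > shortest + tol_frac * lap_length) {
    stop(sprintf("Grid extends to %.1f m but shortest lap covers %.1f m.",
                 max(d_grid), shortest))
  }
  sp <- vapply(laps, function(l) {
    stats::approx(l$d, l$speed, xout = d_grid, ties = "ordered", rule = 2)$y
  }, numeric(length(d_grid)))
  tm <- vapply(laps, function(l) {
    tt <- stats::approx(l$d, l$time, xout = d_grid, ties = "ordered")$y
    over <- is.na(tt) & d_grid > max(l$d)
    if (any(over)) {
      n_l <- nrow(l)
      tt[over] <- l$time[n_l] + (d_grid[over] - l$d[n_l]) / l$speed[n_l]
    }
    tt
  }, numeric(length(d_grid)))
  sp <- matrix(sp, nrow = length(d_grid))
  tm <- matrix(tm, nrow = length(d_grid))
  out <- tibble::tibble(d = d_grid, speed = rowMeans(sp), time = rowMeans(tm))
  attr(out, "speed_laps") <- sp
  attr(out, "time_laps") <- tm
  attr(out, "grid_m") <- grid_m
  class(out) <- c("ski_lap_series", class(out))
  out
}

#' Pointwise group reference from several skiers' lap series
#'
#' @param members List of `ski_lap_series` on identical grids.
#' @return Tibble with `d`, `mean_speed`, `sd_speed`, `mean_time`, `sd_time`
#'   (sample SD, `n - 1`; 0 for a single member).
#' @export
group_reference <- function(members) {
  if (!length(members)) stop("Group must contain at least one member.")
  d <- members[[1]]$d
  for (m in members) {
    if (length(m$d) != length(d) || any(abs(m$d - d) > 1e-9)) {
      stop("All group members must share the same distance grid.")
    }
  }
  sp <- vapply(members, function(m) m$speed, numeric(length(d)))
  tm <- vapply(members, function(m) m$time, numeric(length(d)))
  sp <- matrix(sp, nrow = length(d))
  tm <- matrix(tm, nrow = length(d))
  sd0 <- function(m) {
    if (ncol(m) < 2) return(rep(0, nrow(m)))
    apply(m, 1, stats::sd)
  }
  out <- tibble::tibble(
    d = d,
    mean_speed = rowMeans(sp), sd_speed = sd0(sp),
    mean_time = rowMeans(tm), sd_time = sd0(tm)
  )
  attr(out, "n_members") <- length(members)
  class(out) <- c("ski_group_reference", class(out))
  out
}

# terrain label of the grid cell [d_i, d_{i+1}): from the segment containing
# the cell midpoint; NA for cells inside the gap.
cell_terrain <- function(d_grid, course) {
  mids <- (d_grid[-length(d_grid)] + d_grid[-1]) / 2
  seg <- course$segments
  idx <- findInterval(mids, c(seg$start_m, seg$end_m[nrow(seg)]),
                      rightmost.closed = TRUE)
  idx[idx < 1 | idx > nrow(seg)] <- NA
  terr <- seg$terrain[idx]
  if (!is.null(course$gap)) {
    terr[mids >= course$gap[1] & mids < course$gap[2]] <- NA
  }
  terr
}

#' Compare a skier to a group reference over a course
#'
#' Computes the continuous comparison curves (absolute and relative speed
#' difference, accumulated time difference) and the per-terrain summary:
#' distance-weighted mean speed, relative speed difference (mean and SD of the
#' pointwise percentage difference) and time loss per lap, aggregated over the
#' grid cells each terrain segment contains. Positive differences mean the
#' skier is slower than the reference. Cells inside the course gap are
#' excluded from all aggregates.
#'
#' @param skier A `ski_lap_series`.
#' @param ref A group reference from [group_reference()].
#' @param course A `ski_course` model covering the grid.
#' @return A `ski_comparison` object: list with `grid` (continuous curves),
#'   `per_terrain` (summary rows per terrain plus `OVERALL`) and
#'   `time_in_terrain`.
#' @export
compare_to_reference <- function(skier, ref, course) {
  if (length(skier$d) != length(ref$d) || any(abs(skier$d - ref$d) > 1e-9)) {
    stop("Skier and reference must share the same distance grid.")
  }
  d <- skier$d
  grid <- tibble::tibble(
    d = d,
    skier_speed = skier$speed,
    ref_speed = ref$mean_speed,
    abs_speed_diff = ref$mean_speed - skier$speed,
    rel_speed_diff = 100 * (ref$mean_speed - skier$speed) / ref$mean_speed,
    skier_time = skier$time,
    ref_time = ref$mean_time,
    accum_time_diff = skier$time - ref$mean_time
  )
  terr <- cell_terrain(d, course)
  n_cell <- length(d) - 1
  cells <- tibble::tibble(
    terrain = terr,
    len = diff(d),
    skier_dwell = diff(skier$time),
    ref_dwell = diff(ref$mean_time),
    speed = (skier$speed[-1] + skier$speed[-length(d)]) / 2,
    rel = (grid$rel_speed_diff[-1] + grid$rel_speed_diff[-(n_cell + 1)]) / 2
  )
  cells <- cells[!is.na(cells$terrain), ]
  per_terrain <- dplyr::summarise(
    dplyr::group_by(cells, .data$terrain, .drop = FALSE),
    mean_speed = sum(.data$speed * .data$len) / sum(.data$len),
    rel_speed_diff = mean(.data$rel),
    rel_speed_diff_sd = stats::sd(.data$rel),
    time_loss_s = sum(.data$skier_dwell - .data$ref_dwell),
    .groups = "drop"
  )
  overall <- dplyr::summarise(
    cells,
    terrain = factor(NA, levels = TERRAIN_LEVELS),
    mean_speed = sum(.data$speed * .data$len) / sum(.data$len),
    rel_speed_diff = mean(.data$rel),
    rel_speed_diff_sd = stats::sd(.data$rel),
    time_loss_s = sum(.data$skier_dwell - .data$ref_dwell)
  )
  per_terrain <- dplyr::bind_rows(per_terrain, overall)
  per_terrain$level <- c(as.character(per_terrain$terrain[-nrow(per_terrain)]), "OVERALL")
  per_terrain <- per_terrain[c("level", "mean_speed", "rel_speed_diff",
                               "rel_speed_diff_sd", "time_loss_s")]
  structure(
    list(
      grid = grid,
      per_terrain = per_terrain,
      time_in_terrain = time_in_terrain(skier, course),
      course = course
    ),
    class = "ski_comparison"
  )
}

#' Proportion of skiing time spent in each terrain
#'
#' Elapsed time accrued in the grid cells of each terrain divided by the total
#' lap time, as a percentage. Gap cells are excluded.
#'
#' @param skier A `ski_lap_series`.
#' @param course A `ski_course` model.
#' @return Tibble with `terrain`, `seconds`, `pct`.
#' @export
time_in_terrain <- function(skier, course) {
  terr <- cell_terrain(skier$d, course)
  cells <- tibble::tibble(terrain = terr, dwell = diff(skier$time))
  cells <- cells[!is.na(cells$terrain), ]
  out <- dplyr::summarise(
    dplyr::group_by(cells, .data$terrain, .drop = FALSE),
    seconds = sum(.data$dwell), .groups = "drop"
  )
  out$pct <- 100 * out$seconds / sum(out$seconds)
  out
}

#' @export
print.ski_comparison <- function(x, ...) {
  cat("<ski_comparison>\n")
  print(x$per_terrain)
  invisible(x)
}

#' Tidy a comparison result
#'
#' One row per terrain plus an overall row, mirroring a race report table:
#' distance-weighted mean speed, relative speed difference (% of the
#' reference, mean and SD over grid points), time loss per lap (s) and the
#' proportion of skiing time in the terrain (%).
#'
#' @param x A `ski_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @rdname tidy
#' @method tidy ski_comparison
#' @export
tidy.ski_comparison <- function(x, ...) {
  tt <- x$time_in_terrain
  out <- x$per_terrain
  out$time_pct <- c(tt$pct[match(out$level[-nrow(out)], as.character(tt$terrain))], 100)
  out
}

#' @rdname glance
#' @method glance ski_comparison
#' @export
glance.ski_comparison <- function(x, ...) {
  ov <- x$per_terrain[x$per_terrain$level == "OVERALL", ]
  tibble::tibble(
    mean_speed = ov$mean_speed,
    rel_speed_diff = ov$rel_speed_diff,
    time_loss_s = ov$time_loss_s,
    lap_time_s = max(x$grid$skier_time),
    ref_lap_time_s = max(x$grid$ref_time)
  )
}

#' Race comparison plot
#'
#' Speed, relative speed difference and accumulated time difference versus lap
#' distance, with terrain segments shaded.
#'
#' @param object A `ski_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ski_comparison
#' @export
autoplot.ski_comparison <- function(object, ...) {
  g <- object$grid
  long <- dplyr::bind_rows(
    tibble::tibble(d = g$d, value = g$skier_speed, panel = "speed (m/s)", series = "skier"),
    tibble::tibble(d = g$d, value = g$ref_speed, panel = "speed (m/s)", series = "reference"),
    tibble::tibble(d = g$d, value = g$rel_speed_diff, panel = "relative speed diff (%)", series = "skier"),
    tibble::tibble(d = g$d, value = g$accum_time_diff, panel = "accumulated time diff (s)", series = "skier")
  )
  seg <- object$course$segments
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d, y = .data$value)) +
    ggplot2::geom_rect(
      data = seg, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_m, xmax = .data$end_m,
                   ymin = -Inf, ymax = Inf, fill = .data$terrain),
      alpha = 0.15
    ) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$series)) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(UPHILL = "grey20", FLAT = "grey55", DOWNHILL = "grey85"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "Lap distance (m)", y = NULL) +
    ggplot2::theme_minimal()
}
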