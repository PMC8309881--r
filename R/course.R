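# Course elevation profile and terrain segmentation.
#
# A course model is a list with
#   segments   tibble(segment, start_m, end_m, terrain, elev_diff,
#                     incline_min, incline_max, length_m, actual_length)
#   lap_length metres
#   turns      numeric lap distances (config metadata, never detected)
#   gap        optional c(start_m, end_m) interval excluded from analyses
# Terrain labels follow the 4 m elevation-difference rule: a segment is
# UPHILL/DOWNHILL only if its start-to-end elevation change is at least
# `min_elev_diff_m` in magnitude with the matching sign, otherwise FLAT.

new_course_model <- function(segments, lap_length, turns = numeric(0), gap = NULL) {
  segments$terrain <- factor(as.character(segments$terrain), levels = TERRAIN_LEVELS)
  segments$length_m <- segments$end_m - segments$start_m
  segments$actual_length <- actual_distance(segments)
  segments$segment <- seq_len(nrow(segments))
  structure(
    list(
      segments = tibble::as_tibble(segments)[
        c("segment", "start_m", "end_m", "terrain", "elev_diff",
          "incline_min", "incline_max", "length_m", "actual_length")
      ],
      lap_length = lap_length, turns = turns, gap = gap
    ),
    class = "ski_course"
  )
}

#' Build a reference elevation profile of one lap
#'
#' Folds a (possibly multi-lap) trajectory onto the lap distance axis,
#' averages the altitude of all fixes falling at each grid distance, fills
#' any empty grid point by linear interpolation, and smooths the result with a
#' centred moving average (default window 15 m; wider windows round crests
#' and troughs and bias segment elevation differences low). Averaging across laps
#' suppresses receiver altitude drift that a single pass cannot; a linear
#' aggregate is used because slowly drifting receiver bias then cancels in
#' elevation differences, whereas a pooled median can jump between per-lap
#' error clusters and decouple the two ends of a segment.
#'
#' @param traj Trajectory with `cum_dist` and `alt`.
#' @param lap_length Lap length in metres.
#' @param grid_m Grid spacing in metres (default 5).
#' @param smooth_m Moving-average window in metres (default 15).
#' @return An elevation profile tibble with columns `d`, `z` and attributes
#'   `lap_length`, `grid_m`.
#' @export
build_profile <- function(traj, lap_length, grid_m = 5, smooth_m = 15) {
  if (lap_length <= 0) stop("lap_length must be positive.")
  if (!"cum_dist" %in% names(traj)) stop("Run cumulative_distance() first.")
  d_grid <- seq(0, lap_length, by = grid_m)
  pos <- traj$cum_dist %% lap_length
  idx <- round(pos / grid_m) + 1
  idx[idx > length(d_grid)] <- 1L  # wrap: the last grid point is the lap start
  z <- rep(NA_real_, length(d_grid))
  agg <- tapply(traj$alt, idx, mean)
  z[as.integer(names(agg))] <- agg
  if (anyNA(z)) {
    known <- which(!is.na(z))
    if (length(known) < 2) stop("Too few fixes to build an elevation profile.")
    z <- stats::approx(d_grid[known], z[known], xout = d_grid, rule = 2)$y
  }
  half <- max(floor(smooth_m / grid_m / 2), 0)
  z <- moving_average(z, half)
  out <- tibble::tibble(d = d_grid, z = z)
  attr(out, "lap_length") <- lap_length
  attr(out, "grid_m") <- grid_m
  attr(out, "smooth_m") <- smooth_m
  class(out) <- c("ski_profile", class(out))
  out
}

#' Partition an elevation profile into terrain segments
#'
#' Candidate breakpoints are placed where the smoothed elevation gradient
#' changes sign and the new sign persists for at least `hysteresis_m`
#' (an operational reading of "an evident change in the gradient"). Each
#' breakpoint is refined to the local elevation extremum within the hysteresis
#' window, so the endpoint elevation difference is read off the actual crest or
#' trough rather than the rounded shoulder the profile smoothing leaves.
#' Candidate segments are labelled by the elevation-difference rule
#' (`|elev_diff| >= min_elev_diff_m` with matching sign, else FLAT), and
#' sub-threshold undulating runs are merged into single flat segments via
#' [merge_undulating()].
#'
#' @param profile Elevation profile from [build_profile()].
#' @param min_elev_diff_m Minimum start-to-end elevation difference in metres
#'   for a segment to count as uphill or downhill (default 4).
#' @param hysteresis_m Minimum persistence of a gradient sign for a breakpoint
#'   to register (default 20 m).
#' @param turns Lap distances of course turns (metadata carried through).
#' @param gap Optional `c(start_m, end_m)` interval excluded from analyses.
#' @return A `ski_course` model.
#' @export
detect_segments <- function(profile, min_elev_diff_m = 4, hysteresis_m = 20,
                            turns = numeric(0), gap = NULL) {
  d <- profile$d
  z <- profile$z
  n <- length(d)
  grid_m <- d[2] - d[1]
  if (d[n] - d[1] < 2 * hysteresis_m) {
    stop("Profile shorter than twice the hysteresis distance.")
  }
  grad <- profile_gradient(d, z)
  # Detection gradient: wide-baseline slope, further smoothed. Receiver
  # altitude error drifts slowly, so the per-step gradient is noise-dominated
  # wherever the true grade is small; sign detection needs the wider view.
  base_k <- max(ceiling(hysteresis_m / grid_m / 2), 1)
  n_idx <- seq_len(n)
  lo_i <- pmax(n_idx - base_k, 1)
  hi_i <- pmin(n_idx + base_k, n)
  grad_det <- (z[hi_i] - z[lo_i]) / (d[hi_i] - d[lo_i])
  grad_det <- moving_average(grad_det, max(ceiling(hysteresis_m / grid_m / 2), 1))
  sgn <- sign(grad_det)
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  if (sgn[1] == 0) sgn[1] <- sgn[which(sgn != 0)[1]]
  r <- rle(sgn)
  min_run <- max(ceiling(hysteresis_m / grid_m), 1)
  # Absorb runs shorter than the hysteresis into the preceding run.
  keep_val <- r$values
  keep_len <- r$lengths
  repeat {
    short <- which(keep_len < min_run)
    short <- short[short > 1]
    if (!length(short)) break
    j <- short[1]
    keep_len[j - 1] <- keep_len[j - 1] + keep_len[j]
    keep_val <- keep_val[-j]
    keep_len <- keep_len[-j]
    r2 <- rle(keep_val)
    keep_len <- as.numeric(tapply(keep_len, rep(seq_along(r2$values), r2$lengths), sum))
    keep_val <- r2$values
  }
  ends <- cumsum(keep_len)
  brk_idx <- ends[-length(ends)] + 1  # first index of each new confirmed run
  # Refine each breakpoint to the elevation extremum nearby. The window is
  # twice the hysteresis: gradient smoothing displaces the sign crossing by
  # up to half its span when a steep leg meets a near-level one, and the
  # crest/trough must stay reachable.
  win <- max(ceiling(2 * hysteresis_m / grid_m), 1)
  brk_idx <- vapply(seq_along(brk_idx), function(k) {
    i <- brk_idx[k]
    lo <- max(i - win, 2)
    hi <- min(i + win, n - 1)
    f <- if (keep_val[k + 1] < 0) which.max(z[lo:hi]) else which.min(z[lo:hi])
    as.integer(lo + f - 1)
  }, integer(1))
  brk_idx <- sort(unique(c(1, brk_idx, n)))
  segs <- tibble::tibble(
    start_m = d[brk_idx[-length(brk_idx)]],
    end_m = d[brk_idx[-1]],
    z_start = z[brk_idx[-length(brk_idx)]],
    z_end = z[brk_idx[-1]]
  )
  segs$elev_diff <- segs$z_end - segs$z_start
  segs$terrain <- label_terrain(segs$elev_diff, min_elev_diff_m)
  segs <- merge_undulating(segs[c("start_m", "end_m", "elev_diff", "terrain")],
                           min_elev_diff_m)
  inc <- segment_inclines(segs, d, grad)
  segs$incline_min <- inc$incline_min
  segs$incline_max <- inc$incline_max
  new_course_model(segs, lap_length = attr(profile, "lap_length") %||% d[n],
                   turns = turns, gap = gap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

profile_gradient <- function(d, z) {
  n <- length(d)
  g <- numeric(n)
  i <- 2:(n - 1)
  g[i] <- (z[i + 1] - z[i - 1]) / (d[i + 1] - d[i - 1])
  g[1] <- (z[2] - z[1]) / (d[2] - d[1])
  g[n] <- (z[n] - z[n - 1]) / (d[n] - d[n - 1])
  g
}

label_terrain <- function(elev_diff, min_elev_diff_m) {
  factor(
    ifelse(elev_diff >= min_elev_diff_m, "UPHILL",
           ifelse(elev_diff <= -min_elev_diff_m, "DOWNHILL", "FLAT")),
    levels = TERRAIN_LEVELS
  )
}

segment_inclines <- function(segs, d, grad) {
  incline_min <- numeric(nrow(segs))
  incline_max <- numeric(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    sel <- d >= segs$start_m[i] & d <= segs$end_m[i]
    incline_min[i] <- 100 * min(grad[sel])
    incline_max[i] <- 100 * max(grad[sel])
  }
  list(incline_min = incline_min, incline_max = incline_max)
}

#' Merge undulating sub-threshold segments into flat terrain
#'
#' Maximal runs of consecutive segments whose elevation difference is below
#' the threshold in magnitude are replaced by one flat segment spanning the
#' run; adjacent segments that end up with the same label are collapsed; and
#' every surviving segment's label is re-checked against the threshold. The
#' pass iterates until stable.
#'
#' @param segments Tibble with `start_m`, `end_m`, `elev_diff` (and optionally
#'   `terrain`) for ordered, contiguous segments.
#' @param min_elev_diff_m Threshold in metres (default 4).
#' @return A tibble of merged segments with refreshed `terrain` labels.
#' @export
merge_undulating <- function(segments, min_elev_diff_m = 4) {
  seg <- tibble::as_tibble(segments)[c("start_m", "end_m", "elev_diff")]
  repeat {
    sub <- abs(seg$elev_diff) < min_elev_diff_m
    # one group per maximal sub-threshold run; above-threshold rows stay alone
    run <- cumsum(c(TRUE, diff(sub) != 0))
    grp <- ifelse(sub, paste0("r", run), paste0("s", seq_len(nrow(seg))))
    merged <- dplyr::summarise(
      dplyr::group_by(seg, grp = grp),
      start_m = min(.data$start_m), end_m = max(.data$end_m),
      elev_diff = sum(.data$elev_diff), .groups = "drop"
    )
    merged <- dplyr::arrange(merged, .data$start_m)
    merged$terrain <- label_terrain(merged$elev_diff, min_elev_diff_m)
    # collapse adjacent same-label neighbours
    grp2 <- cumsum(c(TRUE, diff(as.integer(merged$terrain)) != 0))
    out <- dplyr::summarise(
      dplyr::group_by(merged, grp2 = grp2),
      start_m = min(.data$start_m), end_m = max(.data$end_m),
      elev_diff = sum(.data$elev_diff), .groups = "drop"
    )
    out <- dplyr::arrange(out[c("start_m", "end_m", "elev_diff")], .data$start_m)
    if (nrow(out) == nrow(seg) &&
        all(abs(out$elev_diff - seg$elev_diff) < 1e-12)) {
      out$terrain <- label_terrain(out$elev_diff, min_elev_diff_m)
      return(out)
    }
    seg <- out
  }
}

#' Actual (slope) distance of a segment
#'
#' The 3-D length computed from a segment's horizontal length and its
#' start-to-end elevation difference:
#' `sqrt((end_m - start_m)^2 + elev_diff^2)`.
#'
#' @param seg A segment tibble (rows with `start_m`, `end_m`, `elev_diff`).
#' @return Numeric vector of slope lengths in metres.
#' @export
actual_distance <- function(seg) {
  sqrt((seg$end_m - seg$start_m)^2 + seg$elev_diff^2)
}

#' Terrain composition of a course
#'
#' Horizontal length and fraction of the segmented course in each terrain
#' type. Fractions are computed on horizontal lengths and sum to 1; the gap
#' interval, if any, is excluded.
#'
#' @param course A `ski_course` model.
#' @return Tibble with `terrain`, `length_m`, `fraction`.
#' @export
terrain_composition <- function(course) {
  seg <- course$segments
  if (nrow(seg) == 0) stop("Course model has no segments.")
  len <- seg$length_m
  if (!is.null(course$gap)) {
    g <- course$gap
    len <- len - pmax(0, pmin(seg$end_m, g[2]) - pmax(seg$start_m, g[1]))
  }
  comp <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(terrain = seg$terrain, len = len), .data$terrain,
                    .drop = FALSE),
    length_m = sum(.data$len), .groups = "drop"
  )
  comp$fraction <- comp$length_m / sum(comp$length_m)
  comp
}

#' @export
print.ski_course <- function(x, ...) {
  cat(sprintf("<ski_course> lap %.0f m, %d segments (%s)\n",
              x$lap_length, nrow(x$segments),
              paste(table(x$segments$terrain), names(table(x$segments$terrain)),
                    collapse = ", ")))
  print(x$segments)
  invisible(x)
}

#' @rdname tidy
#' @method tidy ski_course
#' @export
tidy.ski_course <- function(x, ...) x$segments

#' @rdname glance
#' @method glance ski_course
#' @export
glance.ski_course <- function(x, ...) {
  comp <- terrain_composition(x)
  tibble::tibble(
    lap_length = x$lap_length,
    n_segments = nrow(x$segments),
    n_uphill = sum(x$segments$terrain == "UPHILL"),
    n_flat = sum(x$segments$terrain == "FLAT"),
    n_downhill = sum(x$segments$terrain == "DOWNHILL"),
    pct_uphill = 100 * comp$fraction[comp$terrain == "UPHILL"],
    pct_flat = 100 * comp$fraction[comp$terrain == "FLAT"],
    pct_downhill = 100 * comp$fraction[comp$terrain == "DOWNHILL"]
  )
}

#' Serialize a course model to JSON
#'
#' @param course A `ski_course` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_course_json <- function(course, path) {
  obj <- list(
    lap_length = course$lap_length,
    turns = course$turns,
    gap = course$gap,
    segments = dplyr::mutate(course$segments, terrain = as.character(.data$terrain))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a course model from JSON
#'
#' @param path Path written by [write_course_json()].
#' @return A `ski_course` model.
#' @export
read_course_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- tibble::as_tibble(obj$segments)
  gap <- if (is.null(obj$gap) || !length(obj$gap)) NULL else as.numeric(obj$gap)
  new_course_model(seg, obj$lap_length, as.numeric(obj$turns %||% numeric(0)), gap)
}

#' Terrain segmentation plot
#'
#' Elevation profile coloured by terrain segment, with turns marked.
#'
#' @param object A `ski_course` model.
#' @param profile Optional elevation profile to draw under the segments.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ski_course
#' @export
autoplot.ski_course <- function(object, profile = NULL, ...) {
  seg <- object$segments
  p <- ggplot2::ggplot()
  if (!is.null(profile)) {
    ymin <- min(profile$z)
    ymax <- max(profile$z)
    p <- p +
      ggplot2::geom_rect(
        data = seg,
        ggplot2::aes(xmin = .data$start_m, xmax = .data$end_m,
                     ymin = ymin, ymax = ymax, fill = .data$terrain),
        alpha = 0.35
      ) +
      ggplot2::geom_line(data = profile, ggplot2::aes(x = .data$d, y = .data$z))
  } else {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start_m, xend = .data$end_m,
                   y = .data$terrain, yend = .data$terrain,
                   colour = .data$terrain),
      linewidth = 3
    )
  }
  if (length(object$turns)) {
    p <- p + ggplot2::geom_vline(xintercept = object$turns, linetype = "dashed",
                                 colour = "red", alpha = 0.6)
  }
  p + ggplot2::scale_fill_manual(
    values = c(UPHILL = "grey20", FLAT = "grey55", DOWNHILL = "grey85"),
    drop = FALSE, aesthetics = c("fill", "colour")
  ) +
    ggplot2::labs(x = "Lap distance (m)", y = "Elevation (m)") +
    ggplot2::theme_minimal()
}
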