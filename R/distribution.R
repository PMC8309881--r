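# Sub-technique usage across speed bins, per distance and per time.

#' Speed binning specification
#'
#' Default bins of 0.25 m/s from 2 to 11 m/s, chosen so the customary low
#' (2.75-4.75 m/s) and high (7-10 m/s) range endpoints all fall on bin edges.
#'
#' @param edges Strictly increasing bin edges in m/s.
#' @param low_range,high_range Two-element ranges summarised by
#'   [range_summary()].
#' @return A `ski_binning` list.
#' @export
speed_binning <- function(edges = seq(2, 11, by = 0.25),
                          low_range = c(2.75, 4.75),
                          high_range = c(7, 10)) {
  stopifnot(all(diff(edges) > 0), length(low_range) == 2, length(high_range) == 2)
  structure(list(edges = edges, low_range = low_range, high_range = high_range),
            class = "ski_binning")
}

#' Sub-technique distribution over speed bins
#'
#' Each grid cell contributes its length to the distance weighting and its
#' dwell time to the time weighting of the speed bin containing the cell's
#' (midpoint) speed. Within each occupied bin the class percentages sum to
#' 100 under both weightings. Bins holding less than `min_occupancy_m` of
#' distance are flagged unused (`used = FALSE`, percentages `NA`) — the blank
#' sections of a distribution chart — rather than zero-filled. Speeds outside
#' the binning are clamped into the end bins with a warning.
#'
#' @param labels Per-cell label tibble from [labels_to_distance()] (`d`,
#'   `label`), on the same grid as `series`.
#' @param series A `ski_lap_series` (grid `d`, `speed`, `time`).
#' @param binning A [speed_binning()].
#' @param min_occupancy_m Distance below which a bin is flagged unused
#'   (default 5 m).
#' @return A `ski_distribution`: tidy tibble with one row per bin and class
#'   (`bin`, `bin_low`, `bin_high`, `class`, `pct_distance`, `pct_time`,
#'   `meters`, `seconds`, `used`), binning kept as an attribute.
#' @export
bin_by_speed <- function(labels, series, binning = speed_binning(),
                         min_occupancy_m = 5) {
  n <- length(series$d)
  if (nrow(labels) != n - 1 || any(abs(labels$d - series$d[-n]) > 1e-9)) {
    stop("Labels and lap series must share the same distance grid.")
  }
  edges <- binning$edges
  cells <- tibble::tibble(
    label = factor(as.character(labels$label), levels = SUBTECH_LEVELS),
    len = diff(series$d),
    dwell = diff(series$time),
    speed = (series$speed[-1] + series$speed[-n]) / 2
  )
  if (any(cells$speed < edges[1] | cells$speed >= edges[length(edges)])) {
    warning("Speeds outside the binning were clamped into the end bins.")
    cells$speed <- pmin(pmax(cells$speed, edges[1]),
                        edges[length(edges)] - 1e-9)
  }
  cells$bin <- findInterval(cells$speed, edges, rightmost.closed = TRUE)
  sums <- dplyr::summarise(
    dplyr::group_by(cells, .data$bin, class = .data$label, .drop = FALSE),
    meters = sum(.data$len), seconds = sum(.data$dwell), .groups = "drop"
  )
  sums <- sums[sums$bin %in% seq_len(length(edges) - 1), ]
  occ <- dplyr::summarise(
    dplyr::group_by(sums, .data$bin),
    occ_m = sum(.data$meters), occ_s = sum(.data$seconds), .groups = "drop"
  )
  out <- dplyr::left_join(sums, occ, by = "bin")
  out$used <- out$occ_m >= min_occupancy_m
  out$pct_distance <- ifelse(out$used, 100 * out$meters / out$occ_m, NA_real_)
  out$pct_time <- ifelse(out$used & out$occ_s > 0, 100 * out$seconds / out$occ_s, NA_real_)
  out$bin_low <- edges[out$bin]
  out$bin_high <- edges[out$bin + 1]
  out <- out[c("bin", "bin_low", "bin_high", "class", "pct_distance",
               "pct_time", "meters", "seconds", "used")]
  attr(out, "binning") <- binning
  class(out) <- c("ski_distribution", class(out))
  out
}

#' Summarise a distribution over the low and high speed ranges
#'
#' Aggregates the bins inside each named range with occupancy (distance)
#' weighting: summed metres per class over summed metres in the range. A range
#' with zero occupancy is flagged missing (`used = FALSE`, `pct` `NA`).
#'
#' @param dist A `ski_distribution`.
#' @param binning Binning to read the ranges from; defaults to the one stored
#'   on `dist`.
#' @return Tibble with `range` (`"low"`/`"high"`), `class`, `pct_distance`,
#'   `meters`, `used`.
#' @export
range_summary <- function(dist, binning = NULL) {
  binning <- binning %||% attr(dist, "binning")
  ranges <- list(low = binning$low_range, high = binning$high_range)
  purrr::map_dfr(names(ranges), function(nm) {
    r <- ranges[[nm]]
    sel <- dist[dist$bin_low >= r[1] & dist$bin_high <= r[2], ]
    by_class <- dplyr::summarise(
      dplyr::group_by(sel, .data$class, .drop = FALSE),
      meters = sum(.data$meters), .groups = "drop"
    )
    tot <- sum(by_class$meters)
    tibble::tibble(
      range = nm,
      class = by_class$class,
      pct_distance = if (tot > 0) 100 * by_class$meters / tot else NA_real_,
      meters = by_class$meters,
      used = tot > 0
    )
  })
}

#' Average distributions across skiers
#'
#' Unweighted mean of member percentages per bin and class; a bin empty for a
#' member is excluded from that member's contribution (it does not drag the
#' average down as a zero).
#'
#' @param members List of `ski_distribution` objects on identical binnings.
#' @return A `ski_distribution`-shaped tibble of averaged percentages, with
#'   `meters`/`seconds` summed across members.
#' @export
group_distribution <- function(members) {
  if (!length(members)) stop("Group must contain at least one member.")
  b0 <- attr(members[[1]], "binning")
  for (m in members) {
    b <- attr(m, "binning")
    if (length(b$edges) != length(b0$edges) || any(b$edges != b0$edges)) {
      stop("All members must share the same speed binning.")
    }
  }
  all <- dplyr::bind_rows(lapply(seq_along(members), function(i) {
    m <- tibble::as_tibble(members[[i]])
    m$member <- i
    m
  }))
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$bin, .data$bin_low, .data$bin_high, .data$class),
    pct_distance = if (any(.data$used)) mean(.data$pct_distance[.data$used]) else NA_real_,
    pct_time = if (any(.data$used)) mean(.data$pct_time[.data$used]) else NA_real_,
    meters = sum(.data$meters), seconds = sum(.data$seconds),
    used = any(.data$used), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$bin, .data$class)
  attr(out, "binning") <- b0
  class(out) <- c("ski_distribution", class(out))
  out
}

#' @rdname glance
#' @method glance ski_distribution
#' @export
glance.ski_distribution <- function(x, ...) {
  rs <- range_summary(x)
  tidyr::pivot_wider(
    rs[c("range", "class", "pct_distance")],
    names_from = c("range", "class"), values_from = "pct_distance",
    names_glue = "{range}_{class}"
  )
}

#' Stacked sub-technique distribution plot
#'
#' Stacked class percentages per speed bin, facetted by weighting (distance
#' and time). Unused bins are left blank.
#'
#' @param object A `ski_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ski_distribution
#' @export
autoplot.ski_distribution <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[object$used, ],
    cols = c("pct_distance", "pct_time"),
    names_to = "weighting", values_to = "pct"
  )
  long$weighting <- ifelse(long$weighting == "pct_distance",
                           "per distance", "per time")
  ggplot2::ggplot(long, ggplot2::aes(
    x = (.data$bin_low + .data$bin_high) / 2,
    y = .data$pct, fill = .data$class
  )) +
    ggplot2::geom_col(width = 0.24, position = "stack") +
    ggplot2::facet_wrap(~weighting, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(
      DP = "#2c7bb6", DK = "#1a9641", DIA = "#d7191c", OTHER = "grey60"
    )) +
    ggplot2::labs(x = "Speed (m/s)", y = "Share (%)", fill = "Sub-technique") +
    ggplot2::theme_minimal()
}
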