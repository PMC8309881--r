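# Shared fixture builders. Geographic conversion here is written from the
# equirectangular formulas directly so trajectory tests do not lean on the
# package's own projection code.

K_DEG <- pi / 180 * 6378137

xy_to_ll <- function(x, y, lat0 = 63.4, lon0 = 10.4) {
  list(
    lat = lat0 + y / K_DEG,
    lon = lon0 + x / (K_DEG * cos(lat0 * pi / 180))
  )
}

make_fixes <- function(x, y, t, alt = 100) {
  ll <- xy_to_ll(x, y)
  tibble::tibble(t = t, lat = ll$lat, lon = ll$lon, alt = alt)
}

# fixes along the x axis at constant speed
line_fixes <- function(n = 50, v = 10, dt = 0.1) {
  t <- dt * (seq_len(n) - 1)
  make_fixes(x = v * t, y = 0, t = t)
}

make_profile <- function(d, z, lap_length = max(d)) {
  out <- tibble::tibble(d = d, z = z)
  attr(out, "lap_length") <- lap_length
  attr(out, "grid_m") <- d[2] - d[1]
  class(out) <- c("ski_profile", class(out))
  out
}

# lap series with constant speed
const_series <- function(v, lap_length = 2465, grid_m = 5) {
  d <- seq(0, lap_length, by = grid_m)
  out <- tibble::tibble(d = d, speed = v, time = d / v)
  class(out) <- c("ski_lap_series", class(out))
  out
}

# lap series from per-cell speeds (speed[i] applies to cell [d_i, d_{i+1}))
cell_series <- function(cell_speed, grid_m = 5) {
  n <- length(cell_speed)
  d <- grid_m * (0:n)
  out <- tibble::tibble(
    d = d,
    speed = c(cell_speed, cell_speed[n]),
    time = cumsum(c(0, grid_m / cell_speed))
  )
  class(out) <- c("ski_lap_series", class(out))
  out
}

label_tbl <- function(labels, grid_m = 5) {
  tibble::tibble(
    d = grid_m * (seq_along(labels) - 1),
    label = factor(labels, levels = c("DP", "DK", "DIA", "OTHER"))
  )
}

write_test_gpx <- function(path, t, lat, lon, ele = NULL) {
  stamp <- format(as.POSIXct("2026-01-15 10:00:00", tz = "UTC") + t + 5e-4,
                  "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  ele_tag <- if (is.null(ele)) "" else sprintf("<ele>%.3f</ele>", ele)
  pts <- sprintf('<trkpt lat="%.8f" lon="%.8f">%s<time>%s</time></trkpt>',
                 lat, lon, ele_tag, stamp)
  writeLines(c(
    '<?xml version="1.0"?>',
    '<gpx version="1.1" xmlns="http://www.topografix.com/GPX/1/1"><trk><trkseg>',
    pts, "</trkseg></trk></gpx>"
  ), path)
  path
}

# brute-force KNN with the package's tie rules, written independently:
# plain loops over sorted distances.
knn_oracle <- function(X_train, labels, query, k) {
  lv <- c("DP", "DK", "DIA", "OTHER")
  d <- sqrt(colSums((t(X_train) - query)^2))
  nn <- order(d)[seq_len(k)]
  counts <- sapply(lv, function(cl) sum(labels[nn] == cl))
  best <- lv[counts == max(counts)]
  if (length(best) > 1) {
    md <- sapply(best, function(cl) mean(d[nn[labels[nn] == cl]]))
    best <- best[md == min(md)]
  }
  best[1]
}
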