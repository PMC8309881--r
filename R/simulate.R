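# Synthetic race generator: course, skier speed dynamics, GNSS track and
# technique-specific cyclic IMU signals, all with known ground truth and all
# pure functions of their seed.

#' Course specification from leg lengths and inclines
#'
#' A course is a sequence of legs, each with a horizontal length and a
#' constant percent grade (when built from a printed incline range, the
#' midpoint is used).
#'
#' @param legs Data frame with `length_m` and either `incline_pct` or a pair
#'   `incline_lo`/`incline_hi` (midpoint taken).
#' @param turns Lap distances of turns in metres (metadata only).
#' @return A `ski_course_spec` list with `legs`, `turns`, `lap_length`.
#' @export
course_spec <- function(legs, turns = numeric(0)) {
  legs <- tibble::as_tibble(legs)
  if (!"incline_pct" %in% names(legs)) {
    legs$incline_pct <- (legs$incline_lo + legs$incline_hi) / 2
  }
  stopifnot(all(legs$length_m > 0), all(abs(legs$incline_pct) <= 20))
  legs$start_m <- cumsum(c(0, legs$length_m[-nrow(legs)]))
  legs$end_m <- cumsum(legs$length_m)
  legs$elev_diff <- legs$length_m * legs$incline_pct / 100
  structure(
    list(legs = legs, turns = turns, lap_length = sum(legs$length_m)),
    class = "ski_course_spec"
  )
}

#' The ten-leg 2.5 km reference course
#'
#' A 2465 m undulating lap built from ten printed leg lengths and incline
#' ranges (midpoints used): a long climb and descent followed by shorter
#' rolling sections. Under the 4 m rule it contains three uphill, three flat
#' and four downhill segments making up 37/15/48% of the course. Six turns
#' are carried as metadata.
#'
#' @return A `ski_course_spec`.
#' @export
fig1_course <- function() {
  course_spec(
    tibble::tibble(
      length_m = c(131, 543, 509, 100, 156, 166, 339, 200, 183, 138),
      incline_lo = c(-2.6, 1.7, -11.7, 0.7, -6.0, 1.3, -8.5, 1.2, -10.1, 0.0),
      incline_hi = c(1.6, 12.4, 0.2, 2.8, 0.0, 12.7, -0.4, 16.0, -1.0, 1.6)
    ),
    turns = c(200, 650, 1150, 1550, 1950, 2300)
  )
}

#' Simulate a course: elevation profile and ground-truth terrain model
#'
#' Elevation is piecewise linear from the leg inclines. Ground-truth terrain
#' labels come from the elevation-difference rule applied to the legs
#' followed by the undulating-merge pass.
#'
#' When `close_loop` is `TRUE` (the default) the elevation is uniformly
#' de-trended so one lap ends at its starting altitude: a real closed lap has
#' zero net climb, while leg-wise incline estimates rarely sum to exactly
#' zero, and an open loop would put an altitude cliff at every lap boundary.
#' The de-trend shifts every grade by the same small constant and changes no
#' terrain label of the reference course.
#'
#' @param spec A [course_spec()].
#' @param grid_m Profile grid spacing in metres (default 5).
#' @param min_elev_diff_m Threshold for the terrain rule (default 4).
#' @param z0 Base elevation in metres (default 150).
#' @param close_loop De-trend elevation to close the lap (default `TRUE`).
#'   Set to `FALSE` to keep each leg's elevation change exactly
#'   `length * incline`.
#' @return A `ski_course_sim` list: `profile` (tibble `d`, `z` on the grid),
#'   `z_fine`/`grade_fine` (1 m resolution), `truth` (a `ski_course` model),
#'   `spec`.
#' @export
simulate_course <- function(spec, grid_m = 5, min_elev_diff_m = 4, z0 = 150,
                            close_loop = TRUE) {
  legs <- spec$legs
  L <- spec$lap_length
  if (close_loop) {
    tilt <- 100 * sum(legs$elev_diff) / L
    legs$incline_pct <- legs$incline_pct - tilt
    legs$elev_diff <- legs$length_m * legs$incline_pct / 100
  }
  s_fine <- seq(0, L, by = 1)
  node_d <- c(0, legs$end_m)
  node_z <- z0 + cumsum(c(0, legs$elev_diff))
  z_fine <- stats::approx(node_d, node_z, xout = s_fine)$y
  leg_idx <- pmin(findInterval(s_fine, node_d, rightmost.closed = TRUE),
                  nrow(legs))
  grade_fine <- legs$incline_pct[leg_idx]
  d_grid <- seq(0, L, by = grid_m)
  profile <- tibble::tibble(d = d_grid,
                            z = stats::approx(s_fine, z_fine, xout = d_grid)$y)
  attr(profile, "lap_length") <- L
  attr(profile, "grid_m") <- grid_m
  segs <- merge_undulating(
    legs[c("start_m", "end_m", "elev_diff")], min_elev_diff_m
  )
  inc <- lapply(seq_len(nrow(segs)), function(i) {
    sel <- legs$start_m >= segs$start_m[i] - 1e-9 & legs$end_m <= segs$end_m[i] + 1e-9
    range(legs$incline_pct[sel])
  })
  segs$incline_min <- vapply(inc, `[`, numeric(1), 1)
  segs$incline_max <- vapply(inc, `[`, numeric(1), 2)
  truth <- new_course_model(segs, L, turns = spec$turns)
  structure(
    list(profile = profile, s_fine = s_fine, z_fine = z_fine,
         grade_fine = grade_fine, truth = truth, spec = spec),
    class = "ski_course_sim"
  )
}

#' Skier specification for the simulator
#'
#' The deterministic speed model is
#' `v(s) = clamp(flat_speed - uphill_sensitivity * grade(s), 0.5, downhill_cap)`
#' with the grade in percent (negative grades speed the skier up until the
#' cap), plus AR(1) noise (coefficient 0.9, innovation SD `speed_noise_sd`)
#' on a 1 m grid. The technique rule maps deterministic speed and grade to a
#' sub-technique: tuck (OTHER) on sustained downhills at speed, diagonal
#' stride on steep slow climbs, kick double poling in the uphill transition
#' band, double poling elsewhere.
#'
#' @param flat_speed Speed on level ground, m/s (default 7.2).
#' @param uphill_sensitivity Speed lost per percent grade, m/s per % (default 0.45).
#' @param downhill_cap Maximum (terminal) speed, m/s (default 10).
#' @param speed_noise_sd AR(1) innovation SD, m/s (default 0.1).
#' @param technique_rule Named list of thresholds: `tuck_grade` (%),
#'   `tuck_speed`, `uphill_grade` (%), `dia_speed`, `dk_speed` (m/s).
#' @param cadence Named cycle rates in Hz per technique.
#' @param imu_noise_sd Additive IMU noise SD (m/s^2 and rad/s; default 0.3).
#' @param amp_jitter Relative per-cycle amplitude jitter (default 0.1).
#' @return A `ski_skier_spec` list.
#' @export
skier_spec <- function(flat_speed = 7.2, uphill_sensitivity = 0.45,
                       downhill_cap = 10, speed_noise_sd = 0.1,
                       technique_rule = list(
                         tuck_grade = -3, tuck_speed = 6.5,
                         uphill_grade = 2, dia_speed = 4.5, dk_speed = 5.5
                       ),
                       cadence = c(DP = 0.9, DK = 0.8, DIA = 1.5, OTHER = 0.3),
                       imu_noise_sd = 0.3, amp_jitter = 0.1) {
  stopifnot(flat_speed > 0, downhill_cap > 0,
            technique_rule$dia_speed < technique_rule$dk_speed)
  structure(
    list(flat_speed = flat_speed, uphill_sensitivity = uphill_sensitivity,
         downhill_cap = downhill_cap, speed_noise_sd = speed_noise_sd,
         technique_rule = technique_rule, cadence = cadence,
         imu_noise_sd = imu_noise_sd, amp_jitter = amp_jitter),
    class = "ski_skier_spec"
  )
}

technique_from_rule <- function(speed, grade, rule) {
  lab <- rep("DP", length(speed))
  lab[grade >= rule$uphill_grade & speed < rule$dk_speed] <- "DK"
  lab[grade >= rule$uphill_grade & speed < rule$dia_speed] <- "DIA"
  lab[grade <= rule$tuck_grade & speed >= rule$tuck_speed] <- "OTHER"
  factor(lab, levels = SUBTECH_LEVELS)
}

#' Simulate a skier's speed profile and motion over a race
#'
#' Builds the deterministic speed from the (40 m circularly smoothed) course
#' grade, adds seeded AR(1) noise, derives ground-truth technique labels from
#' the deterministic speed, and integrates distance against time at 100 Hz.
#'
#' @param course A `ski_course_sim`.
#' @param skier A [skier_spec()].
#' @param n_laps Number of laps (default 4).
#' @param seed Integer seed.
#' @param fs Integration rate in Hz (default 100, the IMU rate).
#' @param grade_smooth_m Window for circular grade smoothing (default 40 m),
#'   representing the skier's inertia through gradient changes.
#' @return A `ski_skier_sim` list: per-metre lap arrays (`v_det`, `grade`,
#'   `label`), race arrays (`s_race`, `v_race`), the 100 Hz trace tibble
#'   (`t`, `s`, `speed`, `label`), ground-truth lap times and inputs.
#' @export
simulate_skier <- function(course, skier = skier_spec(), n_laps = 4,
                           seed = 1, fs = 100, grade_smooth_m = 40) {
  L <- course$spec$lap_length
  g <- course$grade_fine[-length(course$grade_fine)]  # 1 m cells, drop wrap
  g <- circular_ma(g, half = floor(grade_smooth_m / 2))
  v_det <- pmin(pmax(skier$flat_speed - skier$uphill_sensitivity * g, 0.5),
                skier$downhill_cap)
  label <- technique_from_rule(v_det, g, skier$technique_rule)
  n_race <- length(v_det) * n_laps
  noise <- withr::with_seed(seed, ar1_noise(n_race, 0.9, skier$speed_noise_sd))
  v_race <- pmax(rep(v_det, n_laps) + noise, 0.5)
  s_grid <- seq_len(n_race) - 1  # metre grid over the race (cell left edges)
  total <- n_race
  # integrate ds/dt = v(s) at the IMU rate
  dt <- 1 / fs
  est_n <- ceiling(total / min(v_race) / dt) + fs
  t_out <- numeric(est_n)
  s_out <- numeric(est_n)
  k <- 1L
  s <- 0
  while (s < total) {
    t_out[k] <- (k - 1L) * dt
    s_out[k] <- s
    v <- v_race[min(floor(s) + 1L, n_race)]
    s <- s + v * dt
    k <- k + 1L
  }
  n_t <- k - 1L
  trace <- tibble::tibble(t = t_out[seq_len(n_t)], s = s_out[seq_len(n_t)])
  trace$speed <- v_race[pmin(floor(trace$s) + 1L, n_race)]
  lap_pos <- trace$s %% L
  trace$label <- label[pmin(floor(lap_pos) + 1L, length(label))]
  lap_times <- if (n_laps > 1) {
    b <- stats::approx(trace$s, trace$t, xout = L * seq_len(n_laps - 1))$y
    diff(c(0, b, max(trace$t)))
  } else {
    max(trace$t)
  }
  structure(
    list(
      v_det = v_det, grade = g, label = label, lap_length = L,
      n_laps = n_laps, s_race = s_grid, v_race = v_race,
      trace = trace, lap_times = lap_times, skier = skier, seed = seed, fs = fs
    ),
    class = "ski_skier_sim"
  )
}

circular_ma <- function(x, half) {
  if (half <= 0) return(x)
  n <- length(x)
  xx <- c(x[(n - half + 1):n], x, x[1:half])
  moving_average(xx, half)[(half + 1):(half + n)]
}

ar1_noise <- function(n, rho, innov_sd) {
  if (innov_sd <= 0) return(numeric(n))
  e <- stats::rnorm(n, sd = innov_sd)
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

# Stationary AR(1) with given stationary SD and per-step correlation rho.
gauss_markov <- function(n, rho, stat_sd) {
  if (stat_sd <= 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n) * c(stat_sd, rep(stat_sd * sqrt(1 - rho^2), n - 1))
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Render a GNSS track from a simulated skier
#'
#' Lays the lap out as a smooth closed loop of the right circumference,
#' samples the 100 Hz motion trace down to the GNSS rate, reads altitude off
#' the course profile, and adds first-order Gauss-Markov receiver noise
#' (stationary SDs `pos_noise_sd_m` per horizontal axis and `alt_noise_sd_m`
#' vertically, with 60 s / 300 s correlation times — receiver error drifts
#' rather than flickering fix to fix). Turns remain course metadata; no
#' computed quantity depends on plan-view turn geometry.
#'
#' @param course A `ski_course_sim`.
#' @param skier_sim A `ski_skier_sim`.
#' @param rate_hz GNSS rate (default 10).
#' @param pos_noise_sd_m Horizontal noise SD per axis, metres (default 0.5).
#' @param alt_noise_sd_m Vertical noise SD, metres (default 1.0).
#' @param seed Integer seed.
#' @param origin Latitude/longitude the loop is centred on.
#' @return A tibble of raw fixes (`t`, `lat`, `lon`, `alt`) ready for
#'   [as_trajectory()].
#' @export
render_gnss <- function(course, skier_sim, rate_hz = 10,
                        pos_noise_sd_m = 0.5, alt_noise_sd_m = 1.0, seed = 1,
                        origin = c(lat = 63.40, lon = 10.40)) {
  stopifnot(skier_sim$fs %% rate_hz == 0)
  L <- course$spec$lap_length
  trace <- skier_sim$trace
  pick <- seq(1, nrow(trace), by = skier_sim$fs / rate_hz)
  t <- trace$t[pick]
  s <- trace$s[pick]
  R <- L / (2 * pi)
  theta <- 2 * pi * (s %% L) / L
  x <- R * sin(theta)
  y <- R * cos(theta) - R
  n <- length(t)
  dt <- 1 / rate_hz
  noise <- withr::with_seed(seed, list(
    x = gauss_markov(n, exp(-dt / 60), pos_noise_sd_m),
    y = gauss_markov(n, exp(-dt / 60), pos_noise_sd_m),
    z = gauss_markov(n, exp(-dt / 300), alt_noise_sd_m)
  ))
  z <- stats::approx(course$s_fine, course$z_fine, xout = s %% L, rule = 2)$y
  ll <- unproject_local(x + noise$x, y + noise$y, origin)
  tibble::tibble(t = t, lat = ll$lat, lon = ll$lon, alt = z + noise$z)
}

subtech_templates <- function(phase, label_chr) {
  frac <- phase %% 1
  acc <- numeric(length(phase))
  gyr <- numeric(length(phase))
  dp <- label_chr == "DP"
  dk <- label_chr == "DK"
  dia <- label_chr == "DIA"
  oth <- label_chr == "OTHER"
  # DP: synchronized biphasic pole pulse on both channels
  acc[dp] <- 2.0 * sin(2 * pi * phase[dp]) + 0.8 * sin(4 * pi * phase[dp])
  gyr[dp] <- 1.0 * sin(2 * pi * phase[dp] + 0.3)
  # DK: DP plus one leg-kick pulse per cycle
  kick <- exp(-((frac[dk] - 0.6) / 0.08)^2)
  acc[dk] <- 2.0 * sin(2 * pi * phase[dk]) + 0.8 * sin(4 * pi * phase[dk]) + 1.8 * kick
  gyr[dk] <- 1.0 * sin(2 * pi * phase[dk] + 0.3) + 0.9 * kick
  # DIA: alternating antiphase strides; gyro fundamental at half the cadence
  acc[dia] <- 1.2 * sin(2 * pi * phase[dia])
  gyr[dia] <- 1.6 * sin(pi * phase[dia])
  # OTHER/tuck: near-zero cyclic content
  acc[oth] <- 0.1 * sin(2 * pi * phase[oth])
  gyr[oth] <- 0.1 * sin(pi * phase[oth])
  list(acc = acc, gyr = gyr)
}

#' Render IMU signals for a labelled motion trace
#'
#' Builds technique-specific cyclic acc_z/gyr_z signatures: double poling as
#' synchronized biphasic pulses on both channels, kick double poling as the
#' same plus one leg-kick pulse per cycle, diagonal stride as alternating
#' antiphase strides (gyroscope sign alternating cycle to cycle), and
#' tuck/OTHER as near-zero cyclic content. Per-cycle amplitude jitter and
#' additive Gaussian noise are applied; x/y channels carry gravity plus noise.
#'
#' @param skier_sim A `ski_skier_sim` (its 100 Hz trace provides per-sample
#'   labels), or a tibble with columns `t` and `label` at the IMU rate.
#' @param skier A [skier_spec()] (cadence, noise and jitter settings); when
#'   `skier_sim` is a `ski_skier_sim`, defaults to its own spec.
#' @param seed Integer seed.
#' @return An IMU tibble (`t`, `ax`, `ay`, `az`, `gx`, `gy`, `gz`).
#' @export
render_imu <- function(skier_sim, skier = NULL, seed = 1) {
  if (inherits(skier_sim, "ski_skier_sim")) {
    trace <- skier_sim$trace
    skier <- skier %||% skier_sim$skier
  } else {
    trace <- skier_sim
    skier <- skier %||% skier_spec()
  }
  lab <- as.character(trace$label)
  if (anyNA(lab) || !all(lab %in% SUBTECH_LEVELS)) {
    stop("Unknown sub-technique label in trace.")
  }
  n <- nrow(trace)
  dt <- c(diff(trace$t), stats::median(diff(trace$t)))
  cad <- unname(skier$cadence[lab])
  # phase accumulates within each run of constant label and resets at changes
  run <- cumsum(c(TRUE, lab[-1] != lab[-n]))
  cum <- cumsum(cad * dt)
  run_start <- which(c(TRUE, lab[-1] != lab[-n]))
  phase <- cum - rep(c(0, cum[run_start[-1] - 1]), times = diff(c(run_start, n + 1)))
  sig <- subtech_templates(phase, lab)
  withr::with_seed(seed, {
    cyc <- cumsum(c(TRUE, diff(floor(phase)) != 0 | run[-1] != run[-n]))
    jit <- 1 + skier$amp_jitter * stats::rnorm(max(cyc))
    az <- sig$acc * jit[cyc] + stats::rnorm(n, sd = skier$imu_noise_sd)
    gz <- sig$gyr * jit[cyc] + stats::rnorm(n, sd = skier$imu_noise_sd)
    tibble::tibble(
      t = trace$t,
      ax = 9.81 + stats::rnorm(n, sd = skier$imu_noise_sd),
      ay = stats::rnorm(n, sd = skier$imu_noise_sd),
      az = az,
      gx = stats::rnorm(n, sd = 0.5 * skier$imu_noise_sd),
      gy = stats::rnorm(n, sd = 0.5 * skier$imu_noise_sd),
      gz = gz
    )
  })
}

#' Simulate a complete race with ground truth
#'
#' Chains [simulate_course()], [simulate_skier()], [render_gnss()] and
#' [render_imu()] under sub-seeds derived from one master seed, and collects
#' the ground truth every pipeline stage can be checked against.
#'
#' @param course A [course_spec()] (default [fig1_course()]).
#' @param skier A [skier_spec()].
#' @param n_laps Number of laps (default 4).
#' @param seed Master integer seed.
#' @param pos_noise_sd_m,alt_noise_sd_m GNSS noise SDs (defaults 0.5/1.0 m).
#' @param grid_m Truth/label grid spacing (default 5 m).
#' @return A `ski_race_sim` list: `gnss` (raw fixes), `imu`, and `truth`
#'   (course model, terrain composition, per-cell labels on the lap grid,
#'   per-cell deterministic speed, lap times and lap length).
#' @export
simulate_race <- function(course = fig1_course(), skier = skier_spec(),
                          n_laps = 4, seed = 1,
                          pos_noise_sd_m = 0.5, alt_noise_sd_m = 1.0,
                          grid_m = 5) {
  cs <- simulate_course(course, grid_m = grid_m)
  sk <- simulate_skier(cs, skier, n_laps = n_laps, seed = seed)
  gnss <- render_gnss(cs, sk, pos_noise_sd_m = pos_noise_sd_m,
                      alt_noise_sd_m = alt_noise_sd_m, seed = seed + 1)
  imu <- render_imu(sk, seed = seed + 2)
  L <- cs$spec$lap_length
  d_grid <- seq(0, L, by = grid_m)
  mid <- pmin(floor((d_grid[-length(d_grid)] + grid_m / 2)) + 1L, length(sk$label))
  truth_labels <- tibble::tibble(d = d_grid[-length(d_grid)],
                                 label = sk$label[mid])
  truth_speed <- tibble::tibble(d = d_grid[-length(d_grid)],
                                speed = sk$v_det[mid])
  structure(
    list(
      gnss = gnss, imu = imu, course_sim = cs, skier_sim = sk,
      truth = list(
        course = cs$truth,
        composition = terrain_composition(cs$truth),
        labels = truth_labels,
        speed = truth_speed,
        lap_times = sk$lap_times,
        lap_length = L,
        grid_m = grid_m
      )
    ),
    class = "ski_race_sim"
  )
}

#' Ground-truth sub-technique distribution of a simulated race
#'
#' Computed directly from the simulator's deterministic per-cell speed and
#' labels (dwell time `grid_m / v`), bypassing the sensing pipeline.
#'
#' @param sim A `ski_race_sim`.
#' @param binning A [speed_binning()].
#' @return A `ski_distribution`.
#' @export
truth_distribution <- function(sim, binning = speed_binning()) {
  tr <- sim$truth
  n <- nrow(tr$speed)
  grid_m <- tr$grid_m
  d <- c(tr$speed$d, tr$lap_length)
  v_edge <- c(tr$speed$speed, tr$speed$speed[n])
  series <- tibble::tibble(
    d = d,
    speed = v_edge,
    time = cumsum(c(0, grid_m / tr$speed$speed))
  )
  class(series) <- c("ski_lap_series", class(series))
  bin_by_speed(tr$labels, series, binning)
}

#' Default KNN training windows generated by the simulator
#'
#' For each sub-technique the set mixes two kinds of exemplars, sampled down
#' to `n_per_class` windows per class (seed 42 by default, so the packaged
#' classifier is reproducible): pure windows cut from long constant-technique
#' runs rendered with per-run cadence variation, and transition windows that
#' straddle a technique change, labelled by the technique at the window
#' centre. A 2 s sliding window inevitably mixes two signatures around every
#' transition; without such exemplars those mixtures fall nearest whichever
#' pure class happens to sit between the two in feature space. Users with
#' labelled field data can supply their own [training_set()] instead.
#'
#' @param n_per_class Windows per class (default 60).
#' @param seed Integer seed (default 42).
#' @param skier A [skier_spec()] providing noise and jitter levels.
#' @param spec A [filter_spec()] applied before windowing.
#' @param transition_frac Fraction of each class drawn from
#'   transition-straddling windows (default 0.3).
#' @return A `ski_training_set`.
#' @export
default_training_set <- function(n_per_class = 60, seed = 42,
                                 skier = skier_spec(), spec = filter_spec(),
                                 transition_frac = 0.3) {
  fs <- 100
  n_trans <- round(n_per_class * transition_frac)
  n_pure <- n_per_class - n_trans
  pure <- list()
  for (ci in seq_along(SUBTECH_LEVELS)) {
    cl <- SUBTECH_LEVELS[ci]
    runs <- lapply(1:3, function(r) {
      cad0 <- unname(skier$cadence[cl]) * (0.70 + 0.15 * r)
      sk <- skier
      sk$cadence[cl] <- cad0
      n <- round((ceiling(n_per_class / 3) * 0.1 + 4) * fs)
      trace <- tibble::tibble(
        t = (seq_len(n) - 1) / fs,
        label = factor(cl, levels = SUBTECH_LEVELS)
      )
      featurize(make_windows(render_imu(trace, sk, seed = seed + 10 * ci + r),
                             spec, fs = fs))
    })
    f <- dplyr::bind_rows(runs)
    keep <- withr::with_seed(seed + ci, sample(nrow(f), n_pure))
    pure[[cl]] <- f[keep, ]
  }
  # transition exemplars: 4 s of one technique then 4 s of another
  pairs <- expand.grid(a = SUBTECH_LEVELS, b = SUBTECH_LEVELS,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  tfeat <- list()
  tlab <- character(0)
  for (p in seq_len(nrow(pairs))) {
    a <- pairs$a[p]
    b <- pairs$b[p]
    n_half <- 4 * fs
    trace <- tibble::tibble(
      t = (seq_len(2 * n_half) - 1) / fs,
      label = factor(rep(c(a, b), each = n_half), levels = SUBTECH_LEVELS)
    )
    imu <- render_imu(trace, skier, seed = seed + 100 + p)
    w <- make_windows(imu, spec, fs = fs)
    centre <- w$start_idx + 100
    straddle <- w$start_idx < n_half & (w$start_idx + 199) > n_half
    f <- featurize(w)[straddle, ]
    tfeat[[p]] <- f
    tlab <- c(tlab, ifelse(centre[straddle] <= n_half, a, b))
  }
  tfeat <- dplyr::bind_rows(tfeat)
  feats <- list()
  labs <- character(0)
  for (ci in seq_along(SUBTECH_LEVELS)) {
    cl <- SUBTECH_LEVELS[ci]
    avail <- which(tlab == cl)
    keep <- withr::with_seed(seed + 50 + ci,
                             sample(avail, min(n_trans, length(avail))))
    feats[[cl]] <- dplyr::bind_rows(pure[[cl]], tfeat[keep, ])
    labs <- c(labs, rep(cl, nrow(feats[[cl]])))
  }
  training_set(dplyr::bind_rows(feats), labs)
}

#' Write simulator outputs to disk
#'
#' Emits `gnss.gpx`, `imu.csv`, `truth_labels.csv` and `truth_course.json`
#' into a directory.
#'
#' @param sim A `ski_race_sim`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj <- sim$gnss
  write_gpx(as_trajectory(traj), file.path(dir, "gnss.gpx"))
  readr::write_csv(sim$imu, file.path(dir, "imu.csv"))
  readr::write_csv(
    dplyr::mutate(sim$truth$labels, label = as.character(.data$label)),
    file.path(dir, "truth_labels.csv")
  )
  write_course_json(sim$truth$course, file.path(dir, "truth_course.json"))
  invisible(dir)
}
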