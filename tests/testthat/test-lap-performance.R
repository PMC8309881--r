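# Lap splitting, distance interpolation and comparison metrics.

test_that("lap boundaries fall at closed-form crossing times", {
  t <- seq(0, 400, by = 0.1)
  traj <- tibble::tibble(t = t, speed = 5, cum_dist = 5 * t)
  laps <- split_laps(traj, 1000, 2)
  expect_length(laps, 2)
  expect_equal(max(laps[[1]]$t), 200, tolerance = 1e-9)
  expect_equal(max(laps[[2]]$t), 400, tolerance = 1e-9)
  expect_equal(max(laps[[1]]$d), 1000, tolerance = 1e-9)
  expect_equal(laps[[2]]$d[1], 0, tolerance = 1e-9)
  expect_equal(laps[[2]]$time[1], 0)

  one <- split_laps(traj, 2000, 1)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]), length(t))
})

test_that("incomplete recordings are rejected", {
  t <- seq(0, 100, by = 0.1)
  traj <- tibble::tibble(t = t, speed = 5, cum_dist = 5 * t)
  expect_error(split_laps(traj, 1000, 2), "incomplete|covers")
})

test_that("per-lap times match a quadrature oracle for variable speed", {
  L <- 1000
  v_of_s <- function(s) 5 + 2 * sin(2 * pi * s / 500)
  # fine integration of the motion (oracle path)
  dt <- 0.005
  s <- 0
  t <- 0
  ss <- tt <- numeric(0)
  while (s < 2 * L) {
    ss <- c(ss, s)
    tt <- c(tt, t)
    s <- s + v_of_s(s) * dt
    t <- t + dt
  }
  keep <- seq(1, length(tt), by = 20)  # 10 Hz fixes
  traj <- tibble::tibble(t = tt[keep], speed = v_of_s(ss[keep]), cum_dist = ss[keep])
  laps <- split_laps(traj, L, 2)
  # oracle lap times: integral of ds / v(s)
  ds <- 0.01
  grid1 <- seq(0, L - ds, by = ds) + ds / 2
  oracle1 <- sum(ds / v_of_s(grid1))
  oracle2 <- sum(ds / v_of_s(grid1 + L))
  expect_equal(max(laps[[1]]$time), oracle1, tolerance = 0.1)
  expect_equal(max(laps[[2]]$time) , oracle2, tolerance = 0.1)
})

test_that("distance interpolation averages laps pointwise", {
  lap_at <- function(v, L = 1000) {
    d <- seq(0, L, by = 10)
    tibble::tibble(t = d / v, d = d, speed = v, time = d / v)
  }
  one <- interpolate_by_distance(list(lap_at(5)), 1000, 5)
  expect_equal(one$speed, rep(5, 201))
  expect_equal(one$time, one$d / 5, tolerance = 1e-9)

  two <- interpolate_by_distance(list(lap_at(4), lap_at(6)), 1000, 5)
  expect_equal(two$speed, rep(5, 201))
  expect_equal(two$time, (two$d / 4 + two$d / 6) / 2, tolerance = 1e-9)
})

test_that("piecewise-constant speed interpolates to the analytic elapsed time", {
  # 4 m/s for the first 500 m, 6 m/s after
  d_pts <- c(seq(0, 500, by = 2.5), seq(502.5, 1000, by = 2.5))
  time_pts <- ifelse(d_pts <= 500, d_pts / 4, 125 + (d_pts - 500) / 6)
  lap <- tibble::tibble(t = time_pts, d = d_pts,
                        speed = ifelse(d_pts <= 500, 4, 6), time = time_pts)
  series <- interpolate_by_distance(list(lap), 1000, 5)
  analytic <- ifelse(series$d <= 500, series$d / 4, 125 + (series$d - 500) / 6)
  expect_equal(series$time, analytic, tolerance = 1e-6)
})

test_that("group reference computes pointwise mean and n-1 SD", {
  single <- group_reference(list(const_series(5, 100)))
  expect_equal(single$mean_speed, rep(5, 21))
  expect_equal(single$sd_speed, rep(0, 21))

  two <- group_reference(list(const_series(4, 100), const_series(6, 100)))
  expect_equal(two$mean_speed, rep(5, 21))
  expect_equal(two$sd_speed, rep(sqrt(2), 21), tolerance = 1e-12)

  withr::local_seed(3)
  members <- lapply(1:5, function(i) {
    s <- const_series(5, 100)
    s$speed <- runif(21, 3, 9)
    s$time <- cumsum(c(0, 5 / s$speed[-21]))
    s
  })
  ref <- group_reference(members)
  sp <- sapply(members, function(m) m$speed)
  expect_equal(ref$mean_speed, apply(sp, 1, mean), tolerance = 1e-12)
  expect_equal(ref$sd_speed, apply(sp, 1, sd), tolerance = 1e-12)

  expect_error(group_reference(list()), "at least one")
  short <- const_series(5, 90)
  expect_error(group_reference(list(const_series(5, 100), short)), "grid")
})

test_that("comparing a skier against itself is identically zero", {
  cs <- simulate_course(fig1_course(), close_loop = FALSE)
  course <- detect_segments(cs$profile)
  me <- const_series(5)
  cmp <- compare_to_reference(me, group_reference(list(me)), course)
  expect_equal(max(abs(cmp$grid$abs_speed_diff)), 0)
  expect_equal(max(abs(cmp$grid$accum_time_diff)), 0)
  expect_equal(max(abs(cmp$per_terrain$time_loss_s)), 0)
})

test_that("constant-speed skiers give the closed-form accumulated time difference", {
  cs <- simulate_course(fig1_course(), close_loop = FALSE)
  course <- detect_segments(cs$profile)
  cmp <- compare_to_reference(const_series(4), group_reference(list(const_series(5))),
                              course)
  expect_equal(cmp$grid$accum_time_diff[length(cmp$grid$d)],
               2465 * (1 / 4 - 1 / 5), tolerance = 1e-3)
  expect_equal(cmp$grid$accum_time_diff[1], 0)
})

test_that("per-terrain time losses are conserved and match construction", {
  cs <- simulate_course(fig1_course(), close_loop = FALSE)
  course <- detect_segments(cs$profile)
  terr <- skitrax:::cell_terrain(seq(0, 2465, 5), course)
  v_sk <- c(UPHILL = 4, FLAT = 6, DOWNHILL = 8)[as.character(terr)]
  v_rf <- c(UPHILL = 5, FLAT = 6.5, DOWNHILL = 9)[as.character(terr)]
  skier <- cell_series(v_sk)
  ref <- group_reference(list(cell_series(v_rf)))
  cmp <- compare_to_reference(skier, ref, course)
  pt <- cmp$per_terrain
  overall <- pt$time_loss_s[pt$level == "OVERALL"]
  expect_equal(sum(pt$time_loss_s[pt$level != "OVERALL"]), overall,
               tolerance = 0.1)
  for (tt in c("UPHILL", "FLAT", "DOWNHILL")) {
    built <- sum((5 / v_sk - 5 / v_rf)[as.character(terr) == tt])
    got <- pt$time_loss_s[pt$level == tt]
    expect_equal(got, built, tolerance = 0.02 * abs(built) + 1e-6)
  }
  # positive = slower than reference
  expect_true(all(pt$time_loss_s >= 0))
  expect_true(pt$rel_speed_diff[pt$level == "UPHILL"] > 0)
})

test_that("time in terrain follows speed, and percentages sum to 100", {
  half <- skitrax:::new_course_model(
    tibble::tibble(start_m = c(0, 500), end_m = c(500, 1000),
                   elev_diff = c(10, -10), terrain = c("UPHILL", "DOWNHILL"),
                   incline_min = c(2, -2), incline_max = c(2, -2)),
    lap_length = 1000
  )
  even <- time_in_terrain(const_series(5, 1000), half)
  expect_equal(even$pct[even$terrain == "UPHILL"], 50, tolerance = 1e-9)

  v <- ifelse(seq(0, 995, 5) < 500, 3, 9)  # slower uphill
  slow_up <- time_in_terrain(cell_series(v), half)
  expect_gt(slow_up$pct[slow_up$terrain == "UPHILL"], 50)
  expect_equal(sum(slow_up$pct), 100, tolerance = 0.1)
})

test_that("comparison tidiers expose the report quantities", {
  cs <- simulate_course(fig1_course(), close_loop = FALSE)
  course <- detect_segments(cs$profile)
  cmp <- compare_to_reference(const_series(4), group_reference(list(const_series(5))),
                              course)
  td <- tidy(cmp)
  expect_equal(td$level, c("UPHILL", "FLAT", "DOWNHILL", "OVERALL"))
  expect_equal(td$rel_speed_diff, rep(20, 4), tolerance = 1e-9)
  expect_equal(td$time_pct[4], 100)
  gl <- glance(cmp)
  expect_equal(gl$rel_speed_diff, 20, tolerance = 1e-9)
  expect_equal(gl$time_loss_s, 2465 * (1 / 4 - 1 / 5), tolerance = 1e-3)
})
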