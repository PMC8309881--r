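# Elevation profile construction and terrain segmentation.

test_that("profile of a flat course is flat and has floor(L/grid)+1 points", {
  traj <- tibble::tibble(cum_dist = seq(0, 2 * 2465, by = 0.5), alt = 100)
  prof <- build_profile(traj, lap_length = 2465, grid_m = 5)
  expect_equal(nrow(prof), floor(2465 / 5) + 1)
  expect_equal(nrow(prof), 494)
  expect_equal(prof$z, rep(100, 494), tolerance = 1e-9)
  expect_error(build_profile(traj, lap_length = -1), "positive")
})

test_that("multi-lap aggregation beats a single noisy pass", {
  L <- 1000
  s <- seq(0, 4 * L, by = 0.5)
  z_true <- function(d) 100 + 10 * sin(2 * pi * d / L)
  grid <- seq(0, L, by = 5)
  rmse_multi <- rmse_single <- numeric(20)
  withr::local_seed(42)
  for (r in 1:20) {
    alt4 <- z_true(s %% L) + rnorm(length(s), sd = 2)
    p4 <- build_profile(tibble::tibble(cum_dist = s, alt = alt4), L)
    s1 <- s[s <= L]
    alt1 <- z_true(s1) + rnorm(length(s1), sd = 2)
    p1 <- build_profile(tibble::tibble(cum_dist = s1, alt = alt1), L)
    rmse_multi[r] <- sqrt(mean((p4$z - z_true(grid))^2))
    rmse_single[r] <- sqrt(mean((p1$z - z_true(grid))^2))
  }
  expect_lt(mean(rmse_multi), mean(rmse_single))
})

test_that("a monotone ramp is one uphill segment", {
  d <- seq(0, 500, by = 5)
  course <- detect_segments(make_profile(d, 100 + 0.04 * d))
  expect_equal(nrow(course$segments), 1)
  expect_equal(as.character(course$segments$terrain), "UPHILL")
  expect_equal(course$segments$start_m, 0)
  expect_equal(course$segments$end_m, 500)
})

test_that("sawtooth breakpoints land at the construction corners", {
  legs <- 10
  node_d <- 200 * (0:legs)
  node_z <- 100 + 10 * (cumsum(c(0, rep(c(1, -1), legs / 2))))
  d <- seq(0, 2000, by = 5)
  z <- approx(node_d, node_z, xout = d)$y
  course <- detect_segments(make_profile(d, z))
  expect_equal(nrow(course$segments), legs)
  expect_equal(as.character(course$segments$terrain),
               rep(c("UPHILL", "DOWNHILL"), legs / 2))
  inner <- course$segments$start_m[-1]
  expect_lt(max(abs(inner - node_d[2:legs])), 10 + 1e-9)
})

test_that("the ten-leg reference course yields 3 uphill / 3 flat / 4 downhill at 37/15/48%", {
  cs <- simulate_course(fig1_course(), close_loop = FALSE)
  course <- detect_segments(cs$profile)
  counts <- table(course$segments$terrain)
  expect_equal(unname(counts[c("UPHILL", "FLAT", "DOWNHILL")]), c(3L, 3L, 4L),
               ignore_attr = TRUE)
  comp <- terrain_composition(course)
  expect_equal(round(100 * comp$fraction), c(37, 15, 48))
})

test_that("undulating merge matches a brute-force oracle on random sequences", {
  merge_oracle <- function(ed, thr = 4) {
    repeat {
      n <- length(ed)
      sub <- abs(ed) < thr
      # merge first maximal sub-threshold run longer than itself
      merged <- FALSE
      i <- 1
      out <- c()
      while (i <= n) {
        if (sub[i]) {
          j <- i
          while (j < n && sub[j + 1]) j <- j + 1
          out <- c(out, sum(ed[i:j]))
          if (j > i) merged <- TRUE
          i <- j + 1
        } else {
          out <- c(out, ed[i])
          i <- i + 1
        }
      }
      # collapse adjacent same-label neighbours
      lab <- function(e) ifelse(e >= thr, "U", ifelse(e <= -thr, "D", "F"))
      out2 <- out[1]
      for (k in seq_len(length(out) - 1) + 1) {
        if (lab(out2[length(out2)]) == lab(out[k])) {
          out2[length(out2)] <- out2[length(out2)] + out[k]
          merged <- TRUE
        } else {
          out2 <- c(out2, out[k])
        }
      }
      if (!merged) return(out2)
      ed <- out2
    }
  }
  withr::local_seed(99)
  for (rep in 1:50) {
    ed <- runif(20, -8, 8)
    bounds <- cumsum(c(0, runif(20, 50, 300)))
    seg <- tibble::tibble(start_m = bounds[1:20], end_m = bounds[2:21], elev_diff = ed)
    got <- merge_undulating(seg, 4)
    expect_equal(got$elev_diff, merge_oracle(ed), tolerance = 1e-9)
    expect_equal(got$start_m[1], 0)
    expect_equal(got$end_m[nrow(got)], bounds[21])
  }
})

test_that("merge is the identity when nothing is sub-threshold", {
  seg <- tibble::tibble(start_m = c(0, 100, 200), end_m = c(100, 200, 300),
                        elev_diff = c(6, -5, 8))
  expect_equal(merge_undulating(seg, 4)$elev_diff, seg$elev_diff)
  bumps <- tibble::tibble(start_m = c(0, 100, 200), end_m = c(100, 200, 300),
                          elev_diff = c(3, -2, 2))
  out <- merge_undulating(bumps, 4)
  expect_equal(nrow(out), 1)
  expect_equal(as.character(out$terrain), "FLAT")
  # a sub-threshold run whose net climb reaches the threshold is re-labelled,
  # keeping the invariant that flat segments change elevation by < 4 m
  net <- merge_undulating(
    tibble::tibble(start_m = c(0, 100, 200), end_m = c(100, 200, 300),
                   elev_diff = c(3, -1, 3)), 4
  )
  expect_equal(as.character(net$terrain), "UPHILL")
})

test_that("actual distance is the slope hypotenuse", {
  seg <- tibble::tibble(start_m = c(0, 0, 0), end_m = c(100, 4, 543),
                        elev_diff = c(0, 3, 38))
  expect_equal(actual_distance(seg),
               c(100, 5, 543 * sqrt(1 + (38 / 543)^2)), tolerance = 1e-9)
})

test_that("terrain composition sums horizontal lengths per terrain", {
  one <- skitrax:::new_course_model(
    tibble::tibble(start_m = 0, end_m = 500, elev_diff = 1,
                   terrain = "FLAT", incline_min = 0, incline_max = 0.5),
    lap_length = 500
  )
  comp <- terrain_composition(one)
  expect_equal(comp$fraction[comp$terrain == "FLAT"], 1)

  withr::local_seed(5)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    bounds <- sort(c(0, runif(n - 1, 0, 1000), 1000))
    ed <- runif(n, -10, 10)
    seg <- tibble::tibble(
      start_m = bounds[-(n + 1)], end_m = bounds[-1], elev_diff = ed,
      terrain = as.character(skitrax:::label_terrain(ed, 4)),
      incline_min = 0, incline_max = 0
    )
    model <- skitrax:::new_course_model(seg, 1000)
    comp <- terrain_composition(model)
    for (tt in c("UPHILL", "FLAT", "DOWNHILL")) {
      oracle <- sum((bounds[-1] - bounds[-(n + 1)])[seg$terrain == tt]) / 1000
      expect_equal(comp$fraction[comp$terrain == tt], oracle, tolerance = 1e-9)
    }
    expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
  }
})

test_that("segments tile the lap and labels obey the threshold on random profiles", {
  withr::local_seed(21)
  for (rep in 1:100) {
    L <- 1000
    d <- seq(0, L, by = 5)
    z <- 100 + cumsum(rnorm(length(d), sd = 0.8))
    z <- skitrax:::moving_average(z, 4)
    course <- detect_segments(make_profile(d, z))
    seg <- course$segments
    expect_equal(seg$start_m[1], 0)
    expect_equal(seg$end_m[nrow(seg)], L)
    if (nrow(seg) > 1) {
      expect_equal(seg$start_m[-1], seg$end_m[-nrow(seg)], tolerance = 1e-6)
      expect_true(all(seg$terrain[-1] != seg$terrain[-nrow(seg)]))
    }
    up <- seg$terrain == "UPHILL"
    dn <- seg$terrain == "DOWNHILL"
    fl <- seg$terrain == "FLAT"
    expect_true(all(seg$elev_diff[up] >= 4))
    expect_true(all(seg$elev_diff[dn] <= -4))
    expect_true(all(abs(seg$elev_diff[fl]) < 4))
  }
})

test_that("segmentation is deterministic and stable on its own reconstruction", {
  withr::local_seed(31)
  for (r in 1:5) {
    d <- seq(0, 2000, by = 5)
    z <- 100 + skitrax:::moving_average(cumsum(rnorm(length(d), sd = 1)), 6)
    prof <- make_profile(d, z)
    c1 <- detect_segments(prof)
    c2 <- detect_segments(prof)
    expect_identical(c1$segments, c2$segments)
  }
  # the analytic reference course survives a rebuild from its own segments
  prof <- simulate_course(fig1_course(), close_loop = FALSE)$profile
  c1 <- detect_segments(prof)
  nodes_d <- c(c1$segments$start_m, c1$segments$end_m[nrow(c1$segments)])
  nodes_z <- 100 + cumsum(c(0, c1$segments$elev_diff))
  c2 <- detect_segments(make_profile(prof$d, approx(nodes_d, nodes_z, xout = prof$d)$y))
  expect_equal(as.character(c2$segments$terrain), as.character(c1$segments$terrain))
  expect_lt(max(abs(c2$segments$start_m - c1$segments$start_m)), 10 + 1e-9)
})

test_that("course JSON round-trips and the gap is excluded from composition", {
  cs <- simulate_course(fig1_course(), close_loop = FALSE)
  course <- detect_segments(cs$profile, turns = fig1_course()$turns,
                            gap = c(2400, 2465))
  f <- withr::local_tempfile(fileext = ".json")
  write_course_json(course, f)
  back <- read_course_json(f)
  expect_equal(back$segments$start_m, course$segments$start_m)
  expect_equal(as.character(back$segments$terrain),
               as.character(course$segments$terrain))
  expect_equal(back$turns, course$turns)
  comp_gap <- terrain_composition(course)
  expect_equal(sum(comp_gap$length_m), 2465 - 65, tolerance = 5)
})
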