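test_that("window clipping drops the release day and out-of-window fixes", {
  t0 <- as.POSIXct("2014-05-01 00:00:00", tz = "UTC")
  tr <- make_track(seq(0, 990, by = 10), rep(0, 100), t0 = t0,
                   release_time = t0 - 12 * 3600)   # released 12 h before first fix
  end <- t0 + 50 * 7200
  params <- screening_params("dingo", window_end = end)
  out <- clip_window(tr, params)
  st <- out$fixes$status
  # first 6 fixes fall within 24 h of release (12 h lead + 2-h schedule)
  expect_true(all(st[1:6] == "removed_window"))
  expect_equal(st[7], "raw")
  # fixes at and beyond window_end removed (half-open interval)
  expect_true(all(st[51:100] == "removed_window"))
  expect_equal(st[50], "raw")
  # oracle: interval membership
  keep <- tr$fixes$timestamp >= (tr$release_time + 24 * 3600) & tr$fixes$timestamp < end
  expect_equal(st == "raw", keep)
})

test_that("speed filter removes gallop violations and sustained trot", {
  # dingo moving 34 km in 2 h = 17 km/h > 16 gallop
  tr <- make_track(c(0, 34000, 34010), c(0, 0, 0))
  out <- speed_filter(tr, screening_params("dingo"))
  expect_equal(out$fixes$status, c("raw", "removed_speed", "raw"))
  # 8.0 km/h into and out of a fix: below the 8.75 trot threshold, retained
  tr2 <- make_track(c(0, 16000, 32000), c(0, 0, 0))
  out2 <- speed_filter(tr2, screening_params("dingo"))
  expect_true(all(out2$fixes$status == "raw"))
  # 9 km/h both sides exceeds sustained trot even though below gallop
  tr3 <- make_track(c(0, 18000, 36000), c(0, 0, 0))
  out3 <- speed_filter(tr3, screening_params("dingo"))
  expect_equal(out3$fixes$status[2L], "removed_speed")
})

test_that("injected spikes are exactly the fixes the speed filter removes", {
  set.seed(5)
  n <- 120
  x <- cumsum(runif(n, -400, 400)); y <- cumsum(runif(n, -400, 400))
  spikes <- c(20, 45, 60, 88, 101)
  x[spikes] <- x[spikes] + 40000   # 20 km/h at the 2-h schedule
  tr <- make_track(x, y)
  out <- speed_filter(tr, screening_params("dingo"))
  expect_equal(which(out$fixes$status == "removed_speed"), spikes)
  fx <- retained_fixes(out)
  sp <- sqrt(diff(fx$x)^2 + diff(fx$y)^2) / 1000 /
    as.numeric(diff(fx$timestamp), units = "hours")
  expect_true(all(sp <= 16))
})

test_that("elevation filter uses the 100 m tolerance and keeps missing values", {
  tr <- make_track(1:4 * 100, rep(0, 4), elevation = c(650, 599.9, NA, 380))
  out <- elevation_filter(tr, 500, screening_params("dingo"))
  expect_equal(out$fixes$status, c("removed_elev", "raw", "raw", "removed_elev"))
  expect_equal(attr(out, "n_missing_elev"), 1L)
  set.seed(9)
  ele <- runif(200, 300, 700)
  tr2 <- make_track(seq_len(200) * 50, rep(0, 200), elevation = ele)
  out2 <- elevation_filter(tr2, 500, screening_params("dingo"))
  expect_equal(out2$fixes$status == "removed_elev", abs(ele - 500) > 100)
})

test_that("movement classification is a strict displacement rule", {
  # cat cutoff is 35 m: 36 m moves, exactly 35.0 rests
  tr <- make_track(c(0, 36, 71, 200), rep(0, 4), species = "cat")
  out <- classify_movement(tr, screening_params("cat"))
  expect_equal(out$fixes$status, c("moving", "moving", "resting", "moving"))
  expect_equal(attr(out, "prop_moving"), 2 / 3)
})

test_that("movement labels recover constructed rest bouts", {
  set.seed(31)
  moving <- rep(c(TRUE, FALSE), times = c(60, 20))[sample.int(80)]
  x <- numeric(80); y <- numeric(80)
  for (i in 2:80) {
    d <- if (moving[i]) runif(1, 50, 400) else runif(1, 0, 15)
    a <- runif(1, -pi, pi)
    x[i] <- x[i - 1] + d * cos(a); y[i] <- y[i - 1] + d * sin(a)
  }
  tr <- classify_movement(make_track(x, y), screening_params("dingo"))
  expect_equal(tr$fixes$status[-1L] == "moving", moving[-1L])
})

test_that("steps form only across single nominal intervals and carry turns", {
  # three collinear fixes at the exact schedule: two steps, turn 0
  tr <- classify_movement(make_track(c(0, 100, 200), c(0, 0, 0)),
                          screening_params("dingo"))
  st <- build_steps(tr)
  expect_equal(nrow(st), 2L)
  expect_equal(st$turn, c(NA, 0))
  expect_equal(st$length_m, c(100, 100))
  # a 3-interval gap breaks the sequence
  t0 <- as.POSIXct("2014-05-01 00:00:00", tz = "UTC")
  fx <- data.frame(timestamp = t0 + c(0, 2, 4, 10, 12) * 3600,
                   x = c(0, 100, 200, 300, 400), y = 0, elevation = 500)
  tr2 <- gps_track(fx, "a2", "dingo", fix_interval_h = 2, release_time = t0 - 86400)
  tr2 <- classify_movement(tr2, screening_params("dingo"))
  st2 <- build_steps(tr2)
  expect_equal(nrow(st2), 3L)   # no step spans the 6-h gap
  expect_equal(attr(st2, "n_gaps"), 1L)
  # seeded track: step count equals an interval-difference scan
  set.seed(13)
  keep <- sort(sample(1:50, 35))
  fx3 <- data.frame(timestamp = t0 + keep * 7200,
                    x = cumsum(runif(35, 30, 200)), y = 0, elevation = 500)
  tr3 <- gps_track(fx3, "a3", "dingo", fix_interval_h = 2, release_time = t0 - 86400)
  tr3 <- classify_movement(tr3, screening_params("dingo"))
  expect_equal(nrow(build_steps(tr3)), sum(diff(keep) == 1L))
})

test_that("the full screen is idempotent and ordered", {
  set.seed(77)
  n <- 150
  x <- cumsum(runif(n, -300, 300)); y <- cumsum(runif(n, -300, 300))
  x[c(30, 90)] <- x[c(30, 90)] + 50000
  ele <- rep(500, n); ele[c(10, 120)] <- 700
  t0 <- as.POSIXct("2014-05-01 00:00:00", tz = "UTC")
  tr <- make_track(x, y, elevation = ele, t0 = t0)
  params <- screening_params("dingo", window_end = t0 + n * 7200)
  s1 <- screen_track(tr, params, 500)
  s2 <- screen_track(s1, params, 500)
  expect_identical(s1$fixes$status, s2$fixes$status)
  rep1 <- attr(s1, "screening_report")
  expect_equal(rep1$n_removed_speed, 2L)
  expect_equal(rep1$n_removed_elev, 2L)
})
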