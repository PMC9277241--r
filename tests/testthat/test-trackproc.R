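t0 <- as.POSIXct("2021-06-21 00:00:00", tz = "UTC")

test_that("interpolation fills midpoints, leaves exact tracks alone, splits long gaps", {
  fx <- data.frame(bird_id = "b1", timestamp = t0 + c(0, 600),
                   lon = c(0, 0.10), lat = c(51, 51))
  seg <- interpolate_track(fx)[[1]]
  expect_equal(nrow(seg), 3)
  expect_equal(seg$lon[2], 0.05)
  expect_true(seg$interpolated[2])
  expect_false(any(seg$interpolated[c(1, 3)]))

  fx2 <- data.frame(bird_id = "b1", timestamp = t0 + seq(0, 1500, 300),
                    lon = seq(0, 0.5, 0.1), lat = 51)
  seg2 <- interpolate_track(fx2)[[1]]
  expect_equal(seg2$lon, fx2$lon)
  expect_false(any(seg2$interpolated))

  ## a 4000 s gap is never interpolated across
  fx3 <- data.frame(bird_id = "b1",
                    timestamp = t0 + c(seq(0, 900, 300), 4900 + seq(0, 900, 300)),
                    lon = c(seq(0, 0.3, 0.1), seq(1, 1.3, 0.1)), lat = 51)
  segs <- interpolate_track(fx3)
  expect_length(segs, 2)
  expect_true(all(segs[[1]]$lon <= 0.3))
  expect_true(all(segs[[2]]$lon >= 1))
})

test_that("interpolation never extrapolates and a would-be singleton is dropped", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(5:15, 1)
    fx <- data.frame(bird_id = "b1",
                     timestamp = t0 + cumsum(c(0, runif(n - 1, 60, 900))),
                     lon = cumsum(rnorm(n, 0, 0.02)),
                     lat = 51 + cumsum(rnorm(n, 0, 0.01)))
    segs <- suppressWarnings(interpolate_track(fx))
    for (s in segs) {
      expect_gte(min(as.numeric(s$timestamp)), min(as.numeric(fx$timestamp)))
      expect_lte(max(as.numeric(s$timestamp)), max(as.numeric(fx$timestamp)))
    }
  }
  fx <- data.frame(bird_id = "b1", timestamp = t0 + c(0, 300, 5000),
                   lon = c(0, 0.1, 0.2), lat = 51)
  expect_warning(segs <- interpolate_track(fx), "dropped")
  expect_length(segs, 1)
})

test_that("coarse interpolation is never longer than a finer one (triangle inequality)", {
  set.seed(32)
  for (i in 1:5) {
    n <- 8
    fx <- data.frame(bird_id = "b1",
                     timestamp = t0 + seq(0, by = 600, length.out = n),
                     lon = cumsum(rnorm(n, 0, 0.05)),
                     lat = 51 + cumsum(rnorm(n, 0, 0.03)))
    coarse <- steps_turns(interpolate_track(fx, interval_s = 600)[[1]])
    fine <- steps_turns(interpolate_track(fx, interval_s = 60)[[1]])
    expect_lte(sum(coarse$step_km, na.rm = TRUE),
               sum(fine$step_km, na.rm = TRUE) + 1e-9)
  }
})

test_that("steps and turns match the haversine oracle and sign conventions", {
  seg <- data.frame(timestamp = t0 + c(0, 300),
                    lon = c(-6, -6), lat = c(52, 52.08993))
  st <- steps_turns(seg)
  expect_equal(st$step_km[1], 10.00, tolerance = 0.01)

  ## collinear equally spaced points -> zero turn
  seg2 <- data.frame(timestamp = t0 + (0:2) * 300,
                     lon = c(-6, -5.9, -5.8), lat = c(52, 52, 52))
  expect_equal(steps_turns(seg2)$turn_rad[2], 0, tolerance = 1e-8)

  ## exact reversal (out and back along a meridian) -> |turn| = pi
  seg3 <- data.frame(timestamp = t0 + (0:2) * 300,
                     lon = c(-6, -6, -6), lat = c(52, 52.1, 52))
  expect_equal(abs(steps_turns(seg3)$turn_rad[2]), pi, tolerance = 1e-8)

  ## left (counter-clockwise) turn is positive
  seg4 <- data.frame(timestamp = t0 + (0:2) * 300,
                     lon = c(-6, -5.9, -5.9), lat = c(52, 52, 52.1))
  expect_gt(steps_turns(seg4)$turn_rad[2], 0)

  ## coincident points give zero step and a missing turn
  seg5 <- data.frame(timestamp = t0 + (0:2) * 300,
                     lon = c(-6, -6, -5.9), lat = c(52, 52, 52))
  st5 <- steps_turns(seg5)
  expect_equal(st5$step_km[1], 0)
  expect_true(is.na(st5$turn_rad[2]))
})

test_that("trip segmentation applies both distance and duration thresholds", {
  colony <- c(-6.586, 52.138)
  mk <- function(dist, hours) {
    interpolate_track(loop_track(colony, dist, hours))
  }
  t1 <- segment_trips(mk(10, 8), colony)
  expect_equal(nrow(t1), 1)
  expect_gt(t1$max_range_km, 5)
  expect_gte(t1$duration_h, 6)
  expect_equal(nrow(segment_trips(mk(10, 4), colony)), 0)
  expect_equal(nrow(segment_trips(mk(3, 10), colony)), 0)
})

test_that("trip segmentation is idempotent on a trip's own points", {
  colony <- c(-6.586, 52.138)
  segs <- interpolate_track(loop_track(colony, 12, 9))
  trips <- segment_trips(segs, colony)
  pts <- attr(trips, "points")[[trips$trip_id[1]]]
  again <- segment_trips(list(pts), colony)
  expect_equal(nrow(again), 1)
  expect_equal(again$n_points, trips$n_points)
  expect_equal(again$start, trips$start)
  expect_equal(again$end, trips$end)
})
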