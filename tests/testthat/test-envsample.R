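test_that("solar elevation is near 90 deg at the equator at equinox solar noon", {
  day <- as.POSIXct("2021-03-20 00:00:00", tz = "UTC")
  els <- solar_angle(day + seq(0, 86100, by = 120), 0, 0)
  expect_gt(max(els), 89)
  ## antipodal: 12 h after the peak the sun is near the nadir
  peak <- which.max(els)
  t_noon <- day + (peak - 1) * 120
  expect_lt(solar_angle(t_noon + 12 * 3600, 0, 0), -88.5)
})

test_that("solar elevation matches an independent ephemeris within 0.5 deg", {
  set.seed(81)
  times <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC") +
    runif(20, 0, 364 * 86400)
  lon <- runif(20, -180, 180)
  lat <- runif(20, -65, 65)
  expect_lt(max(abs(solar_angle(times, lon, lat) -
                      solar_oracle(times, lon, lat))), 0.5)
})

test_that("solar elevation is 24 h-periodic within 1 deg over a week", {
  t0 <- as.POSIXct("2021-06-21 09:00:00", tz = "UTC")
  els <- solar_angle(t0 + (0:6) * 86400, -6.586, 52.138)
  expect_lt(diff(range(els)), 1)
})

test_that("time of day and cyclic distance behave on the 24 h circle", {
  tt <- as.POSIXct(c("2021-06-21 00:00:00", "2021-06-21 18:30:00"), tz = "UTC")
  expect_equal(time_of_day(tt), c(0, 18.5))
  expect_equal(cyclic_hours_dist(23, 1), 2)
  expect_equal(cyclic_hours_dist(23.5, 0.5), 1)
  expect_equal(cyclic_hours_dist(6, 18), 12)
})

make_field <- function(vals, n = 4, time = NULL) {
  env_field(lon = seq(-2, 1, length.out = n), lat = seq(50, 53, length.out = n),
            values = vals, time = time, name = "test")
}

test_that("sample_field returns constants, bilinear midpoints, and stays bounded", {
  f <- make_field(array(7, c(4, 4, 1)))
  expect_equal(sample_field(f, NULL, c(-1.9, 0.3), c(50.2, 52.7),
                            "nearest", "static"), c(7, 7))
  expect_equal(sample_field(f, NULL, -0.4, 51.8, "bilinear", "static"), 7)

  ## 2x2 grid with values 0,0 (south row) and 10,10 (north row): centre -> 5
  f2 <- env_field(c(0, 1), c(0, 1), array(c(0, 0, 10, 10), c(2, 2, 1)))
  expect_equal(sample_field(f2, NULL, 0.5, 0.5, "bilinear", "static"), 5)

  ## bilinear output bounded by the 4 surrounding cell values
  set.seed(5)
  f3 <- make_field(array(rnorm(16), c(4, 4, 1)))
  for (i in 1:25) {
    qlon <- runif(1, -2, 1); qlat <- runif(1, 50, 53)
    v <- sample_field(f3, NULL, qlon, qlat, "bilinear", "static")
    i0 <- findInterval(qlon, f3$lon); j0 <- findInterval(qlat, f3$lat)
    i0 <- min(max(i0, 1), 3); j0 <- min(max(j0, 1), 3)
    nb <- f3$values[i0:(i0 + 1), j0:(j0 + 1), 1]
    expect_gte(v, min(nb) - 1e-12)
    expect_lte(v, max(nb) + 1e-12)
  }
})

test_that("daily fields use calendar-day matching across midnight", {
  days <- as.Date(c("2021-06-21", "2021-06-22"))
  vals <- array(0, c(4, 4, 2)); vals[, , 2] <- 1
  f <- make_field(vals, time = days)
  before <- as.POSIXct("2021-06-21 23:59:00", tz = "UTC")
  after <- as.POSIXct("2021-06-22 00:01:00", tz = "UTC")
  expect_equal(sample_field(f, before, 0, 51, "nearest", "nearest-day"), 0)
  expect_equal(sample_field(f, after, 0, 51, "nearest", "nearest-day"), 1)
})

test_that("out-of-domain queries yield NA with a warning and annotation keeps rows", {
  f <- make_field(array(7, c(4, 4, 1)))
  expect_warning(v <- sample_field(f, NULL, c(0, 99), c(51, 51),
                                   "nearest", "static"), "outside")
  expect_equal(v, c(7, NA))

  cfg <- sim_config(seed = 2, n_birds = 1, days_per_trip = 1)
  env <- gen_env_fields(cfg)
  tr <- gen_tracks(cfg, env)
  ann <- annotate_points(tr, env)
  expect_identical(nrow(ann), nrow(tr))
  expect_true(all(c("zsd_m", "cloud_pct", "solar_deg", "time_of_day_h",
                    "water_depth_m", "env_missing") %in% names(ann)))
})

test_that("long-CSV field round-trip preserves grids and values", {
  cfg <- sim_config(seed = 7, n_birds = 1, days_per_trip = 1)
  env <- gen_env_fields(cfg)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(env$zsd, tmp)
  back <- read_field_csv(tmp, name = "zsd")
  expect_equal(back$lon, env$zsd$lon)
  expect_equal(as.Date(back$time), env$zsd$time)
  expect_equal(back$values, env$zsd$values, tolerance = 1e-12)
})
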