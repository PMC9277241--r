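## GPS track regularization, foraging-trip segmentation, and step/turn
## derivation (the observation symbols of the movement HMM).

EARTH_RADIUS_M <- 6371000 # mean Earth radius; all great-circle distances use it

gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M) / 1000
}

#' Regularize a GPS track to a fixed interval
#'
#' Linearly interpolates raw fixes (independently in lon and lat) onto a grid
#' of exact `interval_s` multiples anchored at each segment's first fix. Raw
#' gaps longer than `max_gap_s` split the track into segments so that no
#' interpolation spans them; would-be segments with fewer than 2 fixes are
#' dropped with a warning. Interpolation never extrapolates: output times lie
#' within the raw time span of their segment.
#'
#' @param fixes data.frame with `bird_id`, `timestamp` (POSIXct UTC), `lon`,
#'   `lat`, sorted by time within bird, no duplicate timestamps.
#' @param interval_s output fix interval (seconds; default 300 = 5 min).
#' @param max_gap_s raw gaps longer than this are not interpolated across
#'   (default 3600 = 1 h).
#' @return list of track segments: data.frames with `bird_id`, `seg_id`,
#'   `timestamp`, `lon`, `lat`, `interpolated` (logical).
#' @export
interpolate_track <- function(fixes, interval_s = 300, max_gap_s = 3600) {
  stopifnot(all(c("bird_id", "timestamp", "lon", "lat") %in% names(fixes)))
  out <- list()
  for (bird in unique(fixes$bird_id)) {
    fb <- fixes[fixes$bird_id == bird, , drop = FALSE]
    tt <- as.numeric(fb$timestamp)
    if (is.unsorted(tt, strictly = TRUE)) stop("fixes must be strictly time-sorted per bird")
    brk <- cumsum(c(0, diff(tt) > max_gap_s))
    for (s in unique(brk)) {
      fs <- fb[brk == s, , drop = FALSE]
      if (nrow(fs) < 2) {
        warning(sprintf("bird %s: segment with <2 fixes dropped", bird))
        next
      }
      ts0 <- as.numeric(fs$timestamp)
      grid <- seq(ts0[1], ts0[length(ts0)], by = interval_s)
      seg <- data.frame(
        bird_id = bird,
        seg_id = sprintf("%s_%02d", bird, s + 1),
        timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
        lon = approx(ts0, fs$lon, xout = grid)$y,
        lat = approx(ts0, fs$lat, xout = grid)$y,
        interpolated = !(grid %in% ts0),
        stringsAsFactors = FALSE
      )
      out[[length(out) + 1]] <- seg
    }
  }
  out
}

#' Segment foraging trips
#'
#' A foraging trip is a maximal run of consecutive track points further than
#' `dist_km` from the colony lasting at least `min_away_h` hours. Points
#' within `colony_radius_km` of the colony are removed before segmentation.
#' Brief returns inside the distance threshold end a trip (no bridging rule
#' is applied).
#'
#' @param segments list of track segments from [interpolate_track()].
#' @param colony c(lon, lat) of the colony.
#' @param min_away_h minimum trip duration (hours; default 6).
#' @param dist_km distance-from-colony threshold (km; default 5).
#' @param colony_radius_km points closer than this are dropped (default 1).
#' @return data.frame of trips: `trip_id`, `bird_id`, `seg_id`, `start`,
#'   `end`, `duration_h`, `max_range_km`, `n_points`, plus the trip point
#'   tables in `attr(, "points")` keyed by `trip_id`.
#' @export
segment_trips <- function(segments, colony, min_away_h = 6, dist_km = 5,
                          colony_radius_km = 1) {
  stopifnot(length(colony) == 2, is.finite(colony[1]), is.finite(colony[2]))
  trips <- list(); pts <- list()
  for (seg in segments) {
    d <- gc_dist_km(seg$lon, seg$lat, colony[1], colony[2])
    seg <- seg[d > colony_radius_km, , drop = FALSE]
    d <- d[d > colony_radius_km]
    if (nrow(seg) < 2) next
    away <- d > dist_km
    r <- rle(away)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      dur_h <- (as.numeric(seg$timestamp[max(idx)]) -
                  as.numeric(seg$timestamp[min(idx)])) / 3600
      if (dur_h < min_away_h) next
      trip_id <- sprintf("%s_trip%02d", seg$seg_id[1], length(pts) + 1)
      tp <- seg[idx, , drop = FALSE]
      tp$trip_id <- trip_id
      pts[[trip_id]] <- tp
      trips[[length(trips) + 1]] <- data.frame(
        trip_id = trip_id, bird_id = seg$bird_id[1], seg_id = seg$seg_id[1],
        start = tp$timestamp[1], end = tp$timestamp[nrow(tp)],
        duration_h = dur_h, max_range_km = max(d[idx]),
        n_points = length(idx), stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(trips)) do.call(rbind, trips) else
    data.frame(trip_id = character(), bird_id = character(), seg_id = character(),
               start = as.POSIXct(character(), tz = "UTC"),
               end = as.POSIXct(character(), tz = "UTC"),
               duration_h = numeric(), max_range_km = numeric(),
               n_points = integer(), stringsAsFactors = FALSE)
  attr(out, "points") <- pts
  out
}

wrap_angle <- function(x) {
  ## wrap to (-pi, pi]
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Derive step lengths and turning angles
#'
#' `step_km` at point t is the great-circle distance (haversine, R = 6371 km)
#' from point t to point t+1; the last point has no step. `turn_rad` at an
#' interior point is the signed change in bearing between the incoming and
#' outgoing legs, positive counter-clockwise (left turn), in (-pi, pi]; the
#' first and last points have no turn. The von Mises turn distributions used
#' downstream are symmetric in the mean so the sign convention does not
#' affect fits. Coincident consecutive points give step 0 and an undefined
#' (NA) turn at that vertex.
#'
#' @param segment a track segment data.frame (`timestamp`, `lon`, `lat`).
#' @return segment with `step_km` and `turn_rad` columns appended.
#' @export
steps_turns <- function(segment) {
  n <- nrow(segment)
  step <- rep(NA_real_, n); turn <- rep(NA_real_, n)
  if (n >= 2) {
    p <- cbind(segment$lon, segment$lat)
    step[-n] <- geosphere::distHaversine(p[-n, , drop = FALSE],
                                         p[-1, , drop = FALSE],
                                         r = EARTH_RADIUS_M) / 1000
    brg <- geosphere::bearing(p[-n, , drop = FALSE], p[-1, , drop = FALSE]) * pi / 180
    if (n >= 3) {
      ## bearing is clockwise from north; negate the difference so that
      ## positive turn = counter-clockwise
      turn[2:(n - 1)] <- -wrap_angle(brg[-1] - brg[-(n - 1)])
      zero <- step[1:(n - 2)] == 0 | step[2:(n - 1)] == 0
      turn[2:(n - 1)][zero] <- NA_real_
    }
  }
  segment$step_km <- step
  segment$turn_rad <- turn
  segment
}

#' Build the HMM observation table from trip points
#'
#' One observation row per track point that has a step (i.e. all but the last
#' point of each trip): step length, turning angle (NA at trip starts), and
#' the trip identifier that delimits forward recursions.
#'
#' @param trips output of [segment_trips()].
#' @return data.frame with `trip_id`, `bird_id`, `timestamp`, `lon`, `lat`,
#'   `step_km`, `turn_rad`.
#' @export
hmm_obs_table <- function(trips) {
  pts <- attr(trips, "points")
  obs <- lapply(pts, function(tp) {
    tp <- steps_turns(tp)
    tp[-nrow(tp), c("trip_id", "bird_id", "timestamp", "lon", "lat",
                    "step_km", "turn_rad")]
  })
  do.call(rbind, c(obs, list(make.row.names = FALSE)))
}
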