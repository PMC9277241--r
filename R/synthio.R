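## Seeded synthetic biologging generator: gridded visibility fields, a
## three-state movement process whose transitions depend on local Secchi
## depth, daylight-gated dives whose rate and depth depend on solar angle x
## Secchi depth, and 0.5 Hz depth traces with bout structure — plus the
## ground-truth tables needed for parameter-recovery studies.

substream_seed <- function(seed, name) {
  k <- match(name, c("env", "track", "dive", "misc"))
  stopifnot(!is.na(k))
  as.integer((as.numeric(seed) * 7 + k * 1000003) %% 2147483647)
}

#' Simulation configuration
#'
#' Bundles the generator's ground truth: colony, sampling rates, the
#' movement-HMM parameters, the dive-rate and dive-depth predictors, the
#' two-process inter-dive mixture, and the environmental field parameters.
#' Defaults describe a summer colony on the Irish south coast: 5-min GPS
#' fixes, 0.5 Hz depth sampling, Secchi fields with mean 7.5 m and s.d.
#' 2.6 m, dives gated to daylight (solar angle >= -6 deg) and capped at
#' 42 m, and a fast/slow inter-dive mixture (p = 0.7, 1/20 s^-1, 1/600
#' s^-1).
#'
#' @param seed root seed; all randomness flows from it through named
#'   substreams (env, track, dive), so the same config is byte-reproducible.
#' @param colony c(lon, lat) of the colony (deg E, deg N).
#' @param n_birds number of birds.
#' @param trips_per_bird foraging trips per bird.
#' @param days_per_trip trip duration (days).
#' @param start_date first trip date (UTC).
#' @param fix_interval_s GPS fix interval (seconds).
#' @param tdr_hz depth sampling rate (Hz).
#' @param hmm_truth [hmm_params()]; slopes act on standardized Secchi depth
#'   `(zsd - zsd_mean) / zsd_sd`.
#' @param dive_rate_truth log-link dive-count predictor: intercept `b0`,
#'   solar x Secchi surface (`amp`, `solar_peak`, `solar_width`, `z_gain`),
#'   cyclic time-of-day effect (`tau_amp`, `tau_peak_h`), per-bird intercept
#'   s.d. `bird_sd`, negative-binomial `theta`, per-state rate multipliers
#'   `state_mult`, daylight gate `gate_deg`.
#' @param depth_truth identity-link max-depth predictor: intercept `d0`,
#'   solar x Secchi surface (`amp`, `z_gain`), cloud slope per %
#'   (`cloud_coef`), per-state offsets (m), per-bird s.d., residual
#'   `noise_sd`, truncation `floor_m`/`cap_m`.
#' @param bout_truth inter-dive interval mixture: fast fraction `p`, rates
#'   `lambda_f > lambda_s` (per second), minimum surface gap `min_gap_s`.
#' @param env_truth field parameters: Secchi mean/s.d. and spatial
#'   correlation length (cells), grid size and padding (deg), cloud temporal
#'   AR coefficient, bathymetry ramp.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       colony = c(lon = -6.586, lat = 52.138),
                       n_birds = 8, trips_per_bird = 1, days_per_trip = 2,
                       start_date = "2021-06-21",
                       fix_interval_s = 300, tdr_hz = 0.5,
                       hmm_truth = hmm_params(
                         mu = c(0.05, 0.4, 2.5), sigma = c(0.04, 0.3, 1.0),
                         pi0 = c(0, 0, 0), turn_mean = c(0, pi, 0),
                         kappa = c(1, 0.7, 8),
                         beta0 = rep(-2.2, 6),
                         betaz = c(0, 0, 0, -0.5, 0, 0.5)),
                       dive_rate_truth = list(
                         b0 = -1.2, amp = 1.2, solar_peak = 20,
                         solar_width = 25, z_gain = 0.5,
                         tau_amp = 0.25, tau_peak_h = 16, bird_sd = 0.3,
                         theta = 2,
                         state_mult = c(rest = 0.1, ARS = 1, transit = 0.15),
                         gate_deg = -6),
                       depth_truth = list(
                         d0 = 6, amp = 5, z_gain = 0.5, cloud_coef = -0.015,
                         state_offset = c(rest = 0, ARS = 0, transit = -3),
                         bird_sd = 1, noise_sd = 4, floor_m = 1.5, cap_m = 42),
                       bout_truth = list(p = 0.7, lambda_f = 1 / 20,
                                         lambda_s = 1 / 600, min_gap_s = 6),
                       env_truth = list(
                         zsd_mean = 7.5, zsd_sd = 2.6, corr_cells = 5,
                         grid_n = 50, lon_pad = 2.2, lat_pad = 1.3,
                         cloud_ar = 0.95, bathy_base = 15, bathy_slope = 1,
                         bathy_noise = 5)) {
  stopifnot(inherits(hmm_truth, "hmm_params"),
            bout_truth$p > 0, bout_truth$p < 1,
            bout_truth$lambda_f > bout_truth$lambda_s,
            bout_truth$lambda_s > 0,
            dive_rate_truth$theta > 0, env_truth$zsd_mean > 0)
  structure(list(seed = seed, colony = colony, n_birds = n_birds,
                 trips_per_bird = trips_per_bird,
                 days_per_trip = days_per_trip, start_date = start_date,
                 fix_interval_s = fix_interval_s, tdr_hz = tdr_hz,
                 hmm_truth = hmm_truth, dive_rate_truth = dive_rate_truth,
                 depth_truth = depth_truth, bout_truth = bout_truth,
                 env_truth = env_truth),
            class = "sim_config")
}

## true solar x Secchi surface of the dive-rate predictor (log-link scale);
## zs is standardized Secchi depth
rate_surface_truth <- function(cfg, solar_deg, zs) {
  tr <- cfg$dive_rate_truth
  tr$amp * exp(-0.5 * ((solar_deg - tr$solar_peak) / tr$solar_width)^2) *
    (1 + tr$z_gain * tanh(zs))
}

## true solar x Secchi surface of the depth predictor (metres)
depth_surface_truth <- function(cfg, solar_deg, zs) {
  tr <- cfg$depth_truth
  tr$amp * plogis(solar_deg / 20) * (1 + tr$z_gain * tanh(zs))
}

gauss_kernel_mat <- function(n, len) {
  if (len <= 0) return(diag(n))
  K <- exp(-0.5 * (outer(seq_len(n), seq_len(n), "-") / len)^2)
  K / rowSums(K)
}

smooth_field <- function(W, len) {
  if (len <= 0) return(W)
  K <- gauss_kernel_mat(nrow(W), len)
  S <- K %*% W %*% t(gauss_kernel_mat(ncol(W), len))
  (S - mean(S)) / sd(S)
}

#' Generate gridded environmental fields
#'
#' Builds daily Secchi-disc depth, hourly cloud cover, and a static
#' bathymetry grid over an extent padding the colony. Secchi fields are
#' lognormal transforms of spatially smoothed Gaussian noise with the
#' configured mean and s.d. (a correlation length of 0 gives per-cell
#' independent noise); cloud is an AR(1)-in-time, spatially smooth logit
#' field mapped to \[0, 100\]; bathymetry (water depth, positive down,
#' metres) ramps with distance from the colony plus smooth noise.
#'
#' @param config a [sim_config()].
#' @return list with `zsd`, `cloud`, `bathymetry` ([env_field]s).
#' @export
gen_env_fields <- function(config) {
  et <- config$env_truth
  set.seed(substream_seed(config$seed, "env"))
  n <- et$grid_n
  lon <- seq(config$colony["lon"] - et$lon_pad,
             config$colony["lon"] + et$lon_pad, length.out = n)
  lat <- seq(config$colony["lat"] - et$lat_pad,
             config$colony["lat"] + et$lat_pad, length.out = n)
  day0 <- as.Date(config$start_date) - 1
  days <- seq(day0, by = 1, length.out = config$days_per_trip + 2)

  ## lognormal moments matching the target mean and s.d.
  cv2 <- (et$zsd_sd / et$zsd_mean)^2
  sd_ln <- sqrt(log(1 + cv2))
  mu_ln <- log(et$zsd_mean) - sd_ln^2 / 2
  zsd_vals <- array(NA_real_, c(n, n, length(days)))
  for (d in seq_along(days)) {
    X <- smooth_field(matrix(rnorm(n * n), n, n), et$corr_cells)
    zsd_vals[, , d] <- exp(mu_ln + sd_ln * X)
  }
  zsd <- env_field(lon, lat, zsd_vals, time = days, name = "zsd")

  hours <- seq(as.POSIXct(paste(day0, "00:00:00"), tz = "UTC"),
               as.POSIXct(paste(days[length(days)], "23:00:00"), tz = "UTC"),
               by = 3600)
  cloud_vals <- array(NA_real_, c(n, n, length(hours)))
  Xc <- smooth_field(matrix(rnorm(n * n), n, n), et$corr_cells)
  for (h in seq_along(hours)) {
    if (h > 1) {
      innov <- smooth_field(matrix(rnorm(n * n), n, n), et$corr_cells)
      Xc <- et$cloud_ar * Xc + sqrt(1 - et$cloud_ar^2) * innov
    }
    cloud_vals[, , h] <- 100 * plogis(1.2 * Xc)
  }
  cloud <- env_field(lon, lat, cloud_vals, time = hours, name = "cloud")

  dist <- outer(lon, lat, function(x, y)
    gc_dist_km(x, y, config$colony["lon"], config$colony["lat"]))
  bath_vals <- pmax(et$bathy_base + et$bathy_slope * dist +
                      et$bathy_noise * smooth_field(matrix(rnorm(n * n), n, n),
                                                    et$corr_cells), 5)
  bathymetry <- env_field(lon, lat, bath_vals, name = "bathymetry")

  list(zsd = zsd, cloud = cloud, bathymetry = bathymetry)
}

#' Assert that a field's extent covers a set of points
#'
#' @param field an [env_field].
#' @param lon,lat point coordinates.
#' @return invisibly TRUE; errors if any point falls outside the grid.
#' @export
assert_extent_covers <- function(field, lon, lat) {
  if (any(lon < min(field$lon) | lon > max(field$lon) |
            lat < min(field$lat) | lat > max(field$lat))) {
    stop(sprintf("field '%s' extent does not cover the track bounding box",
                 field$name))
  }
  invisible(TRUE)
}

## advance a position by step_km along bearing (radians, clockwise from N)
## on the local tangent plane — adequate at few-km steps
advance_position <- function(lon, lat, step_km, bearing) {
  lat2 <- lat + step_km * cos(bearing) / 110.574
  lon2 <- lon + step_km * sin(bearing) / (111.320 * cos(lat * pi / 180))
  c(lon2, lat2)
}

#' Simulate GPS tracks from the movement truth
#'
#' For each bird and trip, draws a state sequence from the Markov chain
#' whose transition matrix is evaluated at the local, current-day Secchi
#' depth (standardized by the configured field mean/s.d.), then emits steps
#' (gamma) and turns (von Mises) and advances the position on the local
#' tangent plane. Trips start 15-25 km from the colony in a random
#' direction; tracks reflect back toward the colony at the field margin so
#' the grid always covers them. Fixes are exactly `fix_interval_s` apart.
#'
#' @param config a [sim_config()].
#' @param env fields from [gen_env_fields()].
#' @return data.frame with `bird_id`, `trip_id`, `timestamp`, `lon`, `lat`,
#'   `state` (true state 1-3), `zsd_true`.
#' @export
gen_tracks <- function(config, env) {
  set.seed(substream_seed(config$seed, "track"))
  p <- config$hmm_truth
  et <- config$env_truth
  shape <- (p$mu / p$sigma)^2
  rate <- p$mu / p$sigma^2
  n_fix <- config$days_per_trip * 86400 / config$fix_interval_s
  lon_lim <- range(env$zsd$lon) + c(1, -1) * 0.1
  lat_lim <- range(env$zsd$lat) + c(1, -1) * 0.05
  out <- list()
  if (config$n_birds == 0) {
    return(data.frame(bird_id = character(), trip_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric(), state = integer(),
                      zsd_true = numeric()))
  }
  for (b in seq_len(config$n_birds)) {
    bird <- sprintf("bird%02d", b)
    for (tr in seq_len(config$trips_per_bird)) {
      t0 <- as.POSIXct(paste(as.Date(config$start_date) +
                               (tr - 1) * config$days_per_trip, "00:00:00"),
                       tz = "UTC")
      times <- t0 + (seq_len(n_fix) - 1) * config$fix_interval_s
      lon <- numeric(n_fix); lat <- numeric(n_fix)
      state <- integer(n_fix); ztrue <- numeric(n_fix)
      ang <- runif(1, 0, 2 * pi)
      start <- advance_position(config$colony["lon"], config$colony["lat"],
                                15 + runif(1, 0, 10), ang)
      lon[1] <- min(max(start[1], lon_lim[1]), lon_lim[2])
      lat[1] <- min(max(start[2], lat_lim[1]), lat_lim[2])
      bearing <- runif(1, 0, 2 * pi)
      z1 <- sample_field(env$zsd, times[1], lon[1], lat[1],
                         "nearest", "nearest-day")
      ztrue[1] <- z1
      zs <- (z1 - et$zsd_mean) / et$zsd_sd
      state[1] <- sample(1:3, 1, prob = stationary_dist(
        transition_matrix(p, zs)))
      for (t in 2:n_fix) {
        zprev <- (ztrue[t - 1] - et$zsd_mean) / et$zsd_sd
        G <- transition_matrix(p, zprev)
        state[t] <- sample(1:3, 1, prob = G[state[t - 1], ])
        s <- state[t]
        step <- rgamma(1, shape = shape[s], rate = rate[s])
        if (p$pi0[s] > 0 && runif(1) < p$pi0[s]) step <- 0
        turn <- rvonmises(1, p$turn_mean[s], p$kappa[s])
        bearing <- bearing + turn
        pos <- advance_position(lon[t - 1], lat[t - 1], step, bearing)
        if (pos[1] < lon_lim[1] || pos[1] > lon_lim[2] ||
              pos[2] < lat_lim[1] || pos[2] > lat_lim[2]) {
          ## steer back toward the colony
          dx <- config$colony["lon"] - lon[t - 1]
          dy <- config$colony["lat"] - lat[t - 1]
          bearing <- atan2(dx, dy) + rnorm(1, 0, 0.3)
          pos <- advance_position(lon[t - 1], lat[t - 1], step, bearing)
        }
        lon[t] <- pos[1]; lat[t] <- pos[2]
        ztrue[t] <- sample_field(env$zsd, times[t], lon[t], lat[t],
                                 "nearest", "nearest-day")
      }
      out[[length(out) + 1]] <- data.frame(
        bird_id = bird, trip_id = sprintf("%s_t%02d", bird, tr),
        timestamp = times, lon = lon, lat = lat, state = state,
        zsd_true = ztrue, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

draw_mixture_gap <- function(n, bt) {
  fast <- runif(n) < bt$p
  gap <- ifelse(fast, rexp(n, bt$lambda_f), rexp(n, bt$lambda_s))
  pmax(bt$min_gap_s, gap)
}

#' Simulate dives and render 0.5 Hz depth traces
#'
#' For each 5-min fix the dive count is negative binomial with a log-link
#' predictor in the true solar x Secchi surface, a cyclic time-of-day
#' effect, a per-bird intercept and a per-state rate multiplier; counts are
#' forced to zero below the daylight gate (solar angle < -6 deg by
#' default). Scheduled dives get maximum depths from the identity-link
#' depth predictor (Gaussian noise truncated to (floor, cap\]), durations
#' increasing with depth, and inter-dive gaps drawn from the two-process
#' mixture (slow draws that do not fit the 5-min window are realized as
#' silence until the next diving window). Each dive is rendered as a
#' symmetric triangular excursion in the 0.5 Hz trace whose samples all
#' exceed 1 m, so threshold detection recovers the true list exactly.
#'
#' @param config a [sim_config()].
#' @param tracks from [gen_tracks()].
#' @param env from [gen_env_fields()].
#' @return list: `fix_table` (per-fix covariates, true state, `n_dives`),
#'   `dives` (true dive list), `tdr` (per-bird depth series, 0.5 Hz),
#'   `bird_effects` (true per-bird intercepts).
#' @export
gen_dives_and_tdr <- function(config, tracks, env) {
  set.seed(substream_seed(config$seed, "dive"))
  rt <- config$dive_rate_truth
  dt <- config$depth_truth
  bt <- config$bout_truth
  et <- config$env_truth
  assert_extent_covers(env$zsd, tracks$lon, tracks$lat)

  fx <- annotate_points(tracks, env)
  fx$zs <- (fx$zsd_m - et$zsd_mean) / et$zsd_sd
  birds <- unique(fx$bird_id)
  re_rate <- setNames(rnorm(length(birds), 0, rt$bird_sd), birds)
  re_depth <- setNames(rnorm(length(birds), 0, dt$bird_sd), birds)

  lp <- rt$b0 + rate_surface_truth(config, fx$solar_deg, fx$zs) +
    rt$tau_amp * cos(2 * pi * (fx$time_of_day_h - rt$tau_peak_h) / 24) +
    re_rate[fx$bird_id] + log(rt$state_mult[fx$state])
  if (any(!is.finite(lp))) {
    stop("dive-rate predictor produced non-finite rates; check b0/amp/state_mult")
  }
  gated <- fx$solar_deg < rt$gate_deg
  counts <- integer(nrow(fx))
  counts[!gated] <- rnbinom(sum(!gated), mu = exp(lp[!gated]), size = rt$theta)

  dt_samp <- 1 / config$tdr_hz
  window <- config$fix_interval_s
  dives <- vector("list", sum(counts > 0))
  di <- 0L
  n_real <- integer(nrow(fx))
  for (i in which(counts > 0)) {
    k <- counts[i]
    mu_d <- dt$d0 + depth_surface_truth(config, fx$solar_deg[i], fx$zs[i]) +
      dt$cloud_coef * (fx$cloud_pct[i] - 50) +
      dt$state_offset[fx$state[i]] + re_depth[fx$bird_id[i]]
    depth <- pmin(dt$cap_m, pmax(dt$floor_m, mu_d + rnorm(k, 0, dt$noise_sd)))
    n_samp <- pmax(9, round(6 + 1.2 * depth))
    n_samp <- n_samp + (n_samp %% 2 == 0) # odd sample count, apex on grid
    dur <- n_samp * dt_samp
    offs <- c(dt_samp * round(runif(1, 4, 20) / dt_samp),
              if (k > 1) draw_mixture_gap(k - 1, bt) else numeric(0))
    start_rel <- cumsum(offs) + c(0, cumsum(dur))[seq_len(k)]
    keep <- which(start_rel + dur <= window - dt_samp)
    if (!length(keep)) next
    start_rel <- dt_samp * round(start_rel[keep] / dt_samp)
    n_real[i] <- length(keep)
    di <- di + 1L
    dives[[di]] <- data.frame(
      bird_id = fx$bird_id[i],
      start = fx$timestamp[i] + start_rel,
      duration_s = dur[keep], max_depth_m = depth[keep],
      n_samples = n_samp[keep], state = fx$state[i],
      fix_time = fx$timestamp[i], stringsAsFactors = FALSE)
  }
  dives <- if (di > 0) do.call(rbind, dives[seq_len(di)]) else
    data.frame(bird_id = character(), start = as.POSIXct(character(), tz = "UTC"),
               duration_s = numeric(), max_depth_m = numeric(),
               n_samples = integer(), state = integer(),
               fix_time = as.POSIXct(character(), tz = "UTC"))
  if (nrow(dives)) dives$end <- dives$start + dives$duration_s - dt_samp

  fx$n_dives <- n_real
  tdr <- list()
  for (bird in birds) {
    tb <- fx[fx$bird_id == bird, ]
    t0 <- min(as.numeric(tb$timestamp))
    t1 <- max(as.numeric(tb$timestamp)) + window
    tt <- seq(t0, t1, by = dt_samp)
    depth <- numeric(length(tt))
    db <- dives[dives$bird_id == bird, , drop = FALSE]
    for (j in seq_len(nrow(db))) {
      i0 <- round((as.numeric(db$start[j]) - t0) / dt_samp) + 1L
      ns <- db$n_samples[j]
      m <- (ns - 1) / 2
      prof <- 1 + (db$max_depth_m[j] - 1) * (1 - abs(seq_len(ns) - 1 - m) / (m + 1))
      depth[i0:(i0 + ns - 1L)] <- prof
    }
    tdr[[bird]] <- data.frame(
      bird_id = bird,
      timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
      depth_m = depth, stringsAsFactors = FALSE)
  }
  list(fix_table = fx, dives = dives, tdr = tdr,
       bird_effects = list(rate = re_rate, depth = re_depth))
}

#' Simulate a covariate-level fix table
#'
#' Direct sampler for smooth-model recovery studies: draws times of day
#' uniformly across a breeding season (`season_days` from the start date)
#' and positions across the field extent, derives the solar angle at each
#' fix (so time of day and solar angle are coupled the way real multi-week,
#' multi-location tracking data couple them), draws Secchi depth from the
#' configured lognormal, cloud uniform on \[0, 100\], and emits
#' negative-binomial counts from the true log-link predictor without state
#' gating (state multiplier 1) — isolating the smooth structure from
#' movement and rendering effects.
#'
#' @param config a [sim_config()].
#' @param n number of fixes.
#' @param n_birds birds to spread fixes over (default config's).
#' @param season_days span of simulated dates (default 70, June-August).
#' @return data.frame with covariates, `n_dives`, `trip_id`, plus the true
#'   link-scale surface in `lp_true`.
#' @export
gen_fix_table <- function(config, n, n_birds = config$n_birds,
                          season_days = 70) {
  rt <- config$dive_rate_truth
  et <- config$env_truth
  tau <- runif(n, 0, 24)
  date0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  times <- date0 + sample.int(season_days, n, replace = TRUE) * 86400 +
    tau * 3600
  lon <- runif(n, config$colony["lon"] - et$lon_pad,
               config$colony["lon"] + et$lon_pad)
  lat <- runif(n, config$colony["lat"] - et$lat_pad,
               config$colony["lat"] + et$lat_pad)
  solar <- solar_angle(times, lon, lat)
  cv2 <- (et$zsd_sd / et$zsd_mean)^2
  sd_ln <- sqrt(log(1 + cv2)); mu_ln <- log(et$zsd_mean) - sd_ln^2 / 2
  zsd <- exp(rnorm(n, mu_ln, sd_ln))
  zs <- (zsd - et$zsd_mean) / et$zsd_sd
  cloud <- runif(n, 0, 100)
  bird <- sprintf("bird%02d", sample.int(n_birds, n, replace = TRUE))
  re <- setNames(rnorm(n_birds, 0, rt$bird_sd), sprintf("bird%02d", 1:n_birds))
  lp <- rt$b0 + rate_surface_truth(config, solar, zs) +
    rt$tau_amp * cos(2 * pi * (tau - rt$tau_peak_h) / 24) + re[bird]
  counts <- integer(n)
  ok <- solar >= rt$gate_deg
  counts[ok] <- rnbinom(sum(ok), mu = exp(lp[ok]), size = rt$theta)
  data.frame(bird_id = bird, trip_id = bird, timestamp = times,
             solar_deg = solar, zsd_m = zsd, cloud_pct = cloud,
             time_of_day_h = tau, n_dives = counts, lp_true = lp,
             stringsAsFactors = FALSE)
}

#' Simulate a covariate-level bout table
#'
#' Direct sampler for depth-model recovery: covariates as in
#' [gen_fix_table()] restricted to daylight, water depth uniform (no true
#' effect), behavioural states drawn with rest/ARS/transit mix, and bout
#' maximum depths from the true identity-link predictor with truncated
#' Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param n number of bouts.
#' @param state_prob state mixture (default c(0.25, 0.55, 0.2)).
#' @return data.frame with covariates, `hmm_state`, `max_depth_m` and the
#'   true mean `mu_true`.
#' @export
gen_bout_table <- function(config, n, state_prob = c(0.25, 0.55, 0.2)) {
  dt <- config$depth_truth
  et <- config$env_truth
  rt <- config$dive_rate_truth
  tau <- runif(3 * n, 0, 24)
  date0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  times <- date0 + tau * 3600
  solar <- solar_angle(times, config$colony["lon"], config$colony["lat"])
  keep <- which(solar >= rt$gate_deg)[seq_len(n)]
  tau <- tau[keep]; times <- times[keep]; solar <- solar[keep]
  cv2 <- (et$zsd_sd / et$zsd_mean)^2
  sd_ln <- sqrt(log(1 + cv2)); mu_ln <- log(et$zsd_mean) - sd_ln^2 / 2
  zsd <- exp(rnorm(n, mu_ln, sd_ln))
  zs <- (zsd - et$zsd_mean) / et$zsd_sd
  cloud <- runif(n, 0, 100)
  wdepth <- runif(n, 10, 100)
  bird <- sprintf("bird%02d", sample.int(config$n_birds, n, replace = TRUE))
  re <- setNames(rnorm(config$n_birds, 0, dt$bird_sd),
                 sprintf("bird%02d", 1:config$n_birds))
  state <- sample(1:3, n, replace = TRUE, prob = state_prob)
  mu_d <- dt$d0 + depth_surface_truth(config, solar, zs) +
    dt$cloud_coef * (cloud - 50) + dt$state_offset[state] + re[bird]
  depth <- pmin(dt$cap_m, pmax(dt$floor_m, mu_d + rnorm(n, 0, dt$noise_sd)))
  data.frame(bird_id = bird, timestamp = times, solar_deg = solar,
             zsd_m = zsd, cloud_pct = cloud, time_of_day_h = tau,
             water_depth_m = wdepth,
             hmm_state = factor(c("rest", "ARS", "transit")[state],
                                levels = c("rest", "ARS", "transit")),
             max_depth_m = depth, mu_true = mu_d, stringsAsFactors = FALSE)
}

#' Simulate a full synthetic dataset
#'
#' Runs the environmental, track and dive generators from one root seed and
#' returns data plus ground truth (true states, true dive list, true
#' coefficients) for recovery testing.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_output`: `config`, `env`, `tracks`, `gps`
#'   (clean GPS table), `tdr`, `dives`, `fix_table`, `bird_effects`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  env <- gen_env_fields(config)
  tracks <- gen_tracks(config, env)
  dv <- gen_dives_and_tdr(config, tracks, env)
  structure(list(config = config, env = env, tracks = tracks,
                 gps = tracks[, c("bird_id", "timestamp", "lon", "lat")],
                 tdr = dv$tdr, dives = dv$dives, fix_table = dv$fix_table,
                 bird_effects = dv$bird_effects),
            class = "sim_output")
}

#' Write a simulated dataset as CSV files
#'
#' GPS dialect: `bird_id`, `timestamp` (ISO 8601 UTC), `lon`, `lat`. TDR:
#' `bird_id`, `timestamp`, `depth_m` (positive down). Grids: long CSV
#' (`time`, `lat`, `lon`, `value`). Truth tables as CSV.
#'
#' @param sim a `sim_output`.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_sim_csvs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  gps <- sim$gps; gps$timestamp <- fmt(gps$timestamp)
  write.csv(gps, file.path(dir, "gps.csv"), row.names = FALSE)
  tdr <- do.call(rbind, sim$tdr); tdr$timestamp <- fmt(tdr$timestamp)
  write.csv(tdr, file.path(dir, "tdr.csv"), row.names = FALSE)
  write_field_csv(sim$env$zsd, file.path(dir, "zsd.csv"))
  write_field_csv(sim$env$cloud, file.path(dir, "cloud.csv"))
  write_field_csv(sim$env$bathymetry, file.path(dir, "bathymetry.csv"))
  truth <- sim$tracks; truth$timestamp <- fmt(truth$timestamp)
  write.csv(truth, file.path(dir, "truth_states.csv"), row.names = FALSE)
  dd <- sim$dives
  if (nrow(dd)) {
    dd$start <- fmt(dd$start); dd$end <- fmt(dd$end); dd$fix_time <- fmt(dd$fix_time)
  }
  write.csv(dd, file.path(dir, "truth_dives.csv"), row.names = FALSE)
  invisible(dir)
}
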