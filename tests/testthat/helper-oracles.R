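# Independent oracles used across tests.

# Michalsky (1988) Astronomical Almanac solar position (valid 1950-2050);
# an independent formulation (ecliptic longitude -> right ascension ->
# sidereal hour angle) from the package's Fourier-series ephemeris.
solar_oracle <- function(time, lon, lat) {
  lt <- as.POSIXlt(time, tz = "UTC")
  hour_ut <- lt$hour + lt$min / 60 + lt$sec / 3600
  jd <- as.numeric(as.Date(format(time, "%Y-%m-%d", tz = "UTC"))) +
    2440587.5 + hour_ut / 24
  n <- jd - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  lam <- ((L + 1.915 * sin(g) + 0.020 * sin(2 * g)) %% 360) * pi / 180
  eps <- (23.439 - 4e-7 * n) * pi / 180
  dec <- asin(sin(eps) * sin(lam))
  ra <- atan2(cos(eps) * sin(lam), cos(lam))
  gmst <- (6.697375 + 0.0657098242 * n + hour_ut) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- lmst * 15 * pi / 180 - ra
  latr <- lat * pi / 180
  asin(sin(dec) * sin(latr) + cos(dec) * cos(latr) * cos(ha)) * 180 / pi
}

# brute-force HMM log-likelihood and MAP path: explicit sum / max over all
# 3^T state paths (emissions and per-step transition matrices precomputed)
brute_loglik <- function(p, obs) {
  d <- obs
  T <- nrow(d)
  dvm <- function(x, m, k) exp(k * cos(x - m)) / (2 * pi * besselI(k, 0))
  em <- matrix(0, T, 3)
  for (s in 1:3) {
    sh <- (p$mu[s] / p$sigma[s])^2
    rt <- p$mu[s] / p$sigma[s]^2
    e <- ifelse(d$step_km == 0, p$pi0[s],
                (1 - p$pi0[s]) * dgamma(d$step_km, sh, rt))
    vm <- ifelse(is.na(d$turn_rad), 1,
                 dvm(d$turn_rad, p$turn_mean[s], p$kappa[s]))
    em[, s] <- e * vm
  }
  G <- lapply(seq_len(T), function(t) transition_matrix(p, d$z[t]))
  delta <- turbidive:::delta_of(p)
  paths <- as.matrix(expand.grid(rep(list(1:3), T)))
  tot <- 0
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- delta[s[1]] * em[1, s[1]]
    for (t in seq_len(T)[-1]) pr <- pr * G[[t]][s[t - 1], s[t]] * em[t, s[t]]
    tot <- tot + pr
    if (pr > 0 && log(pr) > best) {
      best <- log(pr)
      best_path <- as.integer(unname(s))
    }
  }
  list(loglik = log(tot), map_path = best_path)
}

random_hmm_params <- function() {
  hmm_params(mu = runif(3, 0.1, 3), sigma = runif(3, 0.1, 1),
             pi0 = c(0, 0, 0), turn_mean = runif(3, -pi, pi),
             kappa = runif(3, 0.1, 5), beta0 = rnorm(6, -1, 0.8),
             betaz = rnorm(6, 0, 0.5))
}

# standardized AR(1) covariate series (unit marginal variance)
ar1_series <- function(n, phi = 0.9) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + sqrt(1 - phi^2) * rnorm(1)
  x
}

# small regular GPS track circling a colony at (approximately) constant range
loop_track <- function(colony, dist_km, hours, interval_s = 300,
                       bird = "b1", t0 = as.POSIXct("2021-06-21 06:00:00", tz = "UTC")) {
  n <- as.integer(hours * 3600 / interval_s) + 1L
  ang <- seq(0, 2 * pi, length.out = n)
  dlat <- dist_km / 110.574
  dlon <- dist_km / (111.320 * cos(colony[2] * pi / 180))
  data.frame(bird_id = bird,
             timestamp = t0 + (seq_len(n) - 1) * interval_s,
             lon = colony[1] + dlon * cos(ang),
             lat = colony[2] + dlat * sin(ang),
             stringsAsFactors = FALSE)
}
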