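test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, n_birds = 2, days_per_trip = 1)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$env$zsd$values, b$env$zsd$values)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$dives, b$dives)
  expect_identical(a$tdr, b$tdr)
})

test_that("Secchi fields match the configured moments on a 50x50 grid", {
  cfg <- sim_config(seed = 12)
  env <- gen_env_fields(cfg)
  v <- env$zsd$values
  expect_equal(dim(v)[1:2], c(50, 50))
  expect_lt(abs(mean(v) - 7.5), 0.3)
  expect_lt(abs(sd(v) - 2.6), 0.5)
  expect_true(all(v > 0))
  expect_true(all(env$cloud$values >= 0 & env$cloud$values <= 100))
  expect_true(all(env$bathymetry$values > 0)) # water depth positive down
})

test_that("zero correlation length gives per-cell independent noise", {
  cfg <- sim_config(seed = 13)
  cfg$env_truth$corr_cells <- 0
  env <- gen_env_fields(cfg)
  x <- env$zsd$values[, , 1]
  lag1 <- cor(as.vector(x[-1, ]), as.vector(x[-nrow(x), ]))
  expect_lt(abs(lag1), 0.1)
})

test_that("intercept-only transitions reproduce the analytic matrix empirically", {
  cfg <- sim_config(seed = 14)
  p <- cfg$hmm_truth
  p$betaz <- rep(0, 6)
  set.seed(140)
  obs <- simulate_hmm_obs(p, seg_len = 10000)
  G <- transition_matrix(p, 0)
  emp <- table(factor(obs$state[-10000], 1:3), factor(obs$state[-1], 1:3))
  for (i in 1:3) {
    n_i <- sum(emp[i, ])
    for (j in 1:3) {
      se <- sqrt(G[i, j] * (1 - G[i, j]) / n_i)
      expect_lt(abs(emp[i, j] / n_i - G[i, j]), 3 * se + 1e-3)
    }
  }
})

test_that("simulated step-length ordering follows the configured states", {
  cfg <- sim_config(seed = 15, n_birds = 2, days_per_trip = 1)
  env <- gen_env_fields(cfg)
  tr <- gen_tracks(cfg, env)
  st <- steps_turns(tr[tr$trip_id == tr$trip_id[1], ])
  ## the state drawn at point t emits the step arriving at t, i.e. step_km[t-1]
  states <- tr$state[tr$trip_id == tr$trip_id[1]]
  by_state <- tapply(st$step_km[-nrow(st)], states[-1], mean)
  expect_true(all(diff(by_state[order(as.integer(names(by_state)))]) > 0))
})

test_that("zero birds give empty tables without error", {
  cfg <- sim_config(seed = 16, n_birds = 0)
  env <- gen_env_fields(cfg)
  tr <- gen_tracks(cfg, env)
  expect_equal(nrow(tr), 0)
})

test_that("dives are gated to daylight and capped in depth", {
  cfg <- sim_config(seed = 17, n_birds = 3, days_per_trip = 2)
  sim <- simulate_dataset(cfg)
  fx <- sim$fix_table
  ## the gate applies to the fix-level solar angle: no dives below -6 deg
  expect_equal(sum(fx$n_dives[fx$solar_deg < -6]), 0)
  expect_gt(sum(fx$n_dives), 0)
  expect_true(all(sim$dives$max_depth_m <= cfg$depth_truth$cap_m))
  expect_true(all(sim$dives$max_depth_m > 1))
  ## every dive lies inside its bird's simulated trip
  for (b in names(sim$tdr)) {
    db <- sim$dives[sim$dives$bird_id == b, ]
    expect_true(all(db$start >= min(sim$tdr[[b]]$timestamp)))
    expect_true(all(db$end <= max(sim$tdr[[b]]$timestamp)))
  }
})

test_that("per-bird-day dive counts sit in the field band", {
  cfg <- sim_config(seed = 18, n_birds = 10, days_per_trip = 2)
  sim <- simulate_dataset(cfg)
  per_day <- with(sim$dives,
                  tapply(max_depth_m, list(bird_id, as.Date(start, tz = "UTC")),
                         length))
  expect_gte(sum(!is.na(per_day)), 20)
  m <- mean(per_day, na.rm = TRUE)
  expect_gte(m, 34); expect_lte(m, 100)
})

test_that("rendered depth traces exceed 1 m exactly during true dives", {
  cfg <- sim_config(seed = 19, n_birds = 2, days_per_trip = 1)
  sim <- simulate_dataset(cfg)
  for (b in names(sim$tdr)) {
    tdr <- sim$tdr[[b]]
    db <- sim$dives[sim$dives$bird_id == b, ]
    in_dive <- rep(FALSE, nrow(tdr))
    tt <- as.numeric(tdr$timestamp)
    for (j in seq_len(nrow(db))) {
      in_dive <- in_dive | (tt >= as.numeric(db$start[j]) &
                              tt <= as.numeric(db$end[j]))
    }
    expect_identical(tdr$depth_m > 1, in_dive)
  }
})

test_that("a non-finite rate predictor fails loudly", {
  cfg <- sim_config(seed = 20, n_birds = 1, days_per_trip = 1)
  cfg$dive_rate_truth$state_mult <- c(rest = 0, ARS = 1, transit = 0.15)
  env <- gen_env_fields(cfg)
  tr <- gen_tracks(cfg, env)
  expect_error(gen_dives_and_tdr(cfg, tr, env), "non-finite")
})

test_that("fields must cover the track bounding box", {
  cfg <- sim_config(seed = 21, n_birds = 1, days_per_trip = 1)
  env <- gen_env_fields(cfg)
  tr <- gen_tracks(cfg, env)
  tr$lon[1] <- min(env$zsd$lon) - 1
  expect_error(gen_dives_and_tdr(cfg, tr, env), "does not cover")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(bout_truth = list(p = 0.7, lambda_f = 1 / 600,
                                            lambda_s = 1 / 20, min_gap_s = 6)))
  expect_error(sim_config(bout_truth = list(p = 1.2, lambda_f = 1 / 20,
                                            lambda_s = 1 / 600, min_gap_s = 6)))
})
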