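test_that("transition matrix is a multinomial logit with diagonal reference", {
  b0 <- list(beta0 = rep(0, 6), betaz = rep(0, 6))
  expect_equal(transition_matrix(b0, 0), matrix(1 / 3, 3, 3))

  near_id <- transition_matrix(list(beta0 = rep(-20, 6), betaz = rep(0, 6)), 0)
  expect_lt(max(abs(near_id - diag(3))), 1e-8)

  set.seed(21)
  for (i in 1:20) {
    G <- transition_matrix(list(beta0 = rnorm(6, 0, 2), betaz = rnorm(6)),
                           rnorm(1))
    expect_lt(max(abs(rowSums(G) - 1)), 1e-12)
    expect_true(all(G > 0))
  }
  expect_error(transition_matrix(b0, NA), "non-finite")
})

test_that("stationary distribution is the left unit-eigenvector", {
  expect_equal(stationary_dist(matrix(1 / 3, 3, 3)), rep(1 / 3, 3))

  ## doubly stochastic -> uniform
  ds <- matrix(c(0.5, 0.3, 0.2, 0.2, 0.5, 0.3, 0.3, 0.2, 0.5), 3, 3,
               byrow = TRUE)
  expect_equal(stationary_dist(ds), rep(1 / 3, 3), tolerance = 1e-10)

  set.seed(22)
  for (i in 1:20) {
    G <- matrix(rgamma(9, 1), 3, 3)
    G <- G / rowSums(G)
    Gp <- G
    for (k in 1:10) Gp <- Gp %*% Gp # G^1024
    expect_lt(max(abs(stationary_dist(G) - Gp[1, ])), 1e-8)
  }
  expect_error(stationary_dist(diag(3)), "reducible")
})

test_that("forward log-likelihood matches brute-force enumeration", {
  set.seed(23)
  for (i in 1:20) {
    p <- random_hmm_params()
    T <- sample(3:7, 1)
    obs <- simulate_hmm_obs(p, seg_len = T, z = rnorm(T))
    expect_equal(hmm_loglik(p, obs), brute_loglik(p, obs)$loglik,
                 tolerance = 1e-8)
  }
})

test_that("with identical emissions in every state the likelihood collapses", {
  p <- hmm_params(mu = rep(0.5, 3), sigma = rep(0.3, 3), kappa = rep(1, 3),
                  beta0 = rnorm(6))
  obs <- data.frame(step_km = 0.4, turn_rad = NA, z = 0, seg = 1)
  expect_equal(hmm_loglik(p, obs),
               dgamma(0.4, (0.5 / 0.3)^2, 0.5 / 0.3^2, log = TRUE))
})

test_that("likelihood is invariant to state relabelling", {
  set.seed(24)
  p <- random_hmm_params()
  obs <- simulate_hmm_obs(p, seg_len = c(40, 40), z = rnorm(80))
  perm <- c(2, 3, 1)
  eta0 <- matrix(0, 3, 3); etaz <- matrix(0, 3, 3)
  pairs <- turbidive:::OFFDIAG_PAIRS
  eta0[pairs] <- p$beta0; etaz[pairs] <- p$betaz
  p2 <- hmm_params(p$mu[perm], p$sigma[perm], p$pi0[perm], p$turn_mean[perm],
                   p$kappa[perm], eta0[perm, perm][pairs],
                   etaz[perm, perm][pairs])
  expect_equal(hmm_loglik(p, obs), hmm_loglik(p2, obs), tolerance = 1e-10)
})

test_that("Viterbi matches brute-force path enumeration and limiting cases", {
  set.seed(25)
  for (i in 1:20) {
    p <- random_hmm_params()
    obs <- simulate_hmm_obs(p, seg_len = 6, z = rnorm(6))
    fit <- list(params = p, data = turbidive:::hmm_prepare(obs),
                zs = obs$z, z_center = 0, z_scale = 1)
    class(fit) <- "hmm_fit"
    expect_equal(as.integer(viterbi(fit)), brute_loglik(p, obs)$map_path)
  }

  ## one state's emission dominates everywhere -> constant path
  p <- hmm_params(mu = c(0.01, 5, 50), sigma = c(0.005, 0.5, 5),
                  kappa = c(1, 1, 1), beta0 = rep(0, 6))
  obs <- data.frame(step_km = rgamma(30, 100, 20), turn_rad = NA,
                    z = 0, seg = 1) # steps ~ 5
  fit <- list(params = p, data = turbidive:::hmm_prepare(obs), zs = obs$z,
              z_center = 0, z_scale = 1)
  class(fit) <- "hmm_fit"
  expect_true(all(viterbi(fit) == 2L))
})

test_that("with zero covariate slopes the models coincide (nested at betaz = 0)", {
  set.seed(26)
  p <- random_hmm_params()
  p$betaz <- rep(0, 6)
  obs <- simulate_hmm_obs(p, seg_len = c(50, 50), z = rnorm(100))
  ## the covariate must then be irrelevant: shuffling z leaves the
  ## likelihood unchanged, and it equals the no-covariate evaluation
  obs_shuf <- obs; obs_shuf$z <- sample(obs$z)
  obs_zero <- obs; obs_zero$z <- 0
  expect_equal(hmm_loglik(p, obs), hmm_loglik(p, obs_shuf), tolerance = 1e-10)
  expect_equal(hmm_loglik(p, obs), hmm_loglik(p, obs_zero), tolerance = 1e-10)
})

test_that("fitting from the truth cannot do worse than the truth (MLE dominance)", {
  set.seed(27)
  cfg <- sim_config()
  truth <- cfg$hmm_truth
  obs <- simulate_hmm_obs(truth, seg_len = rep(250, 4), z = ar1_series(1000))
  fit <- fit_hmm(obs, formula = "zsd", inits = truth, n_restarts = 1,
                 z_center = 0, z_scale = 1, hessian = FALSE)
  expect_gte(fit$loglik, hmm_loglik(truth, obs) - 1e-6)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  expect_lt(max(abs(rowSums(fit$posterior) - 1)), 1e-10)
  ## canonical labelling: step means ascending
  expect_true(all(diff(fit$params$mu) > 0))
})

test_that("zero-step observations require and use the zero-mass component", {
  set.seed(28)
  p <- hmm_params(mu = c(0.1, 1, 3), sigma = c(0.1, 0.5, 1),
                  pi0 = c(0.3, 0, 0), kappa = c(1, 1, 1), beta0 = rep(-2, 6))
  obs <- simulate_hmm_obs(p, seg_len = 400)
  expect_gt(sum(obs$step_km == 0), 0)
  p_no <- p; p_no$pi0 <- c(0, 0, 0)
  expect_error(hmm_loglik(p_no, obs), "zero step lengths")
  expect_true(is.finite(hmm_loglik(p, obs)))
  ## brute-force agreement with a zero-inflated emission
  obs7 <- obs[1:7, ]; obs7$step_km[3] <- 0
  expect_equal(hmm_loglik(p, obs7), brute_loglik(p, obs7)$loglik,
               tolerance = 1e-8)
})

test_that("transition curves are monotone in a single positive slope and CIs cover", {
  set.seed(29)
  cfg <- sim_config()
  obs <- simulate_hmm_obs(cfg$hmm_truth, seg_len = rep(300, 10),
                          z = ar1_series(3000))
  fit <- fit_hmm(obs, formula = "zsd", inits = cfg$hmm_truth, n_restarts = 1,
                 z_center = 0, z_scale = 1)
  cv <- transition_curves(fit, z_grid = seq(-1.5, 1.5, length.out = 15))
  ta <- cv$transitions[cv$transitions$from == "transit" &
                         cv$transitions$to == "ARS", ]
  expect_true(all(diff(ta$p) > 0)) # positive slope -> increasing curve
  expect_true(all(cv$transitions$lo <= cv$transitions$p + 1e-12))
  expect_true(all(cv$transitions$hi >= cv$transitions$p - 1e-12))
  expect_true(all(cv$stationary$lo <= cv$stationary$p + 1e-12))
})

test_that("bootstrap and delta-method intervals broadly agree on a clean fit", {
  set.seed(30)
  cfg <- sim_config()
  obs <- simulate_hmm_obs(cfg$hmm_truth, seg_len = rep(150, 8),
                          z = ar1_series(1200))
  fit <- fit_hmm(obs, formula = "zsd", inits = cfg$hmm_truth, n_restarts = 1,
                 z_center = 0, z_scale = 1)
  zg <- c(-1, 0, 1)
  cd <- transition_curves(fit, zg, ci = "delta")
  cb <- transition_curves(fit, zg, ci = "bootstrap", n_boot = 15)
  wd <- cd$transitions$hi - cd$transitions$lo
  wb <- cb$transitions$hi - cb$transitions$lo
  ## compare interval widths where the delta interval is non-degenerate
  sel <- wd > 0.02
  expect_true(any(sel))
  expect_lt(median(abs(wb[sel] - wd[sel]) / wd[sel]), 0.5)
})

test_that("model comparison reports agreement, hits, misses and precision", {
  set.seed(33)
  cfg <- sim_config()
  obs <- simulate_hmm_obs(cfg$hmm_truth, seg_len = rep(200, 2))
  f <- fit_hmm(obs, formula = "null", inits = cfg$hmm_truth, n_restarts = 1,
               hessian = FALSE)
  same <- compare_models(f, f, dive_presence = obs$state == 2)
  expect_equal(same$agreement, 1)

  ## hand-built decodings: dives at every ARS point and nowhere else
  dec <- rep(c(1L, 2L, 3L), length.out = nrow(obs))
  perfect <- compare_models(f, f, dive_presence = dec == 2L,
                            decoded_a = dec, decoded_b = dec)
  expect_equal(perfect$metrics$hit, c(1, 1))
  expect_equal(perfect$metrics$miss, c(0, 0))
  expect_equal(perfect$metrics$precision, c(1, 1))

  ## constructed 2x2 table: dives 40 ARS / 10 not; non-dives 20 ARS / 130 not
  dec2 <- c(rep(2L, 40), rep(1L, 10), rep(2L, 20), rep(1L, 130))
  dive <- c(rep(TRUE, 50), rep(FALSE, 150))
  tab <- compare_models(f, f, dive_presence = dive,
                        decoded_a = dec2, decoded_b = dec2)
  expect_equal(tab$metrics$hit[1], 0.8)
  expect_equal(tab$metrics$miss[1], 0.2)
  expect_equal(tab$metrics$precision[1], 40 / 60)

  expect_error(compare_models(f, f, dive_presence = c(TRUE, FALSE),
                              decoded_a = dec2, decoded_b = dec2),
               "equal length")
})

test_that("simulated transition frequencies converge to the analytic matrix", {
  set.seed(34)
  p <- hmm_params(mu = c(0.1, 0.5, 2), sigma = c(0.1, 0.4, 1),
                  kappa = c(1, 1, 4), beta0 = rnorm(6, -1.5, 0.5),
                  betaz = rep(0, 6))
  obs <- simulate_hmm_obs(p, seg_len = 10000)
  G <- transition_matrix(p, 0)
  emp <- table(factor(obs$state[-nrow(obs)], 1:3),
               factor(obs$state[-1], 1:3))
  for (i in 1:3) {
    n_i <- sum(emp[i, ])
    for (j in 1:3) {
      se <- sqrt(G[i, j] * (1 - G[i, j]) / n_i)
      expect_lt(abs(emp[i, j] / n_i - G[i, j]), 3 * se + 1e-3)
    }
  }
})

test_that("AIC selects the covariate model only when the covariate matters", {
  cfg <- sim_config()
  truth <- cfg$hmm_truth
  null_truth <- truth; null_truth$betaz <- rep(0, 6)
  prefers_zsd <- prefers_null <- logical(10)
  for (r in 1:10) {
    set.seed(600 + r)
    z <- as.vector(replicate(12, ar1_series(300, 0.9)))
    obs_a <- simulate_hmm_obs(truth, seg_len = rep(300, 12), z = z)
    obs_b <- simulate_hmm_obs(null_truth, seg_len = rep(300, 12), z = z)
    fit_of <- function(o, f) fit_hmm(o, formula = f, n_restarts = 1,
                                     z_center = 0, z_scale = 1,
                                     hessian = FALSE)$aic
    prefers_zsd[r] <- fit_of(obs_a, "zsd") < fit_of(obs_a, "null")
    prefers_null[r] <- fit_of(obs_b, "null") < fit_of(obs_b, "zsd")
  }
  expect_gte(sum(prefers_zsd), 9)
  ## AIC is known to over-select the richer model under the null
  expect_gte(sum(prefers_null), 6)
})
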