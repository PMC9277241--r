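test_that("smooth bases have the advertised structure", {
  set.seed(41)
  d <- data.frame(x = runif(60, 0, 24), y = runif(60), id = rep(letters[1:6], 10))

  cyc <- build_basis("cyclic-cubic-1d", d, "x", k = 8)
  ends <- data.frame(x = c(0, 24))
  Xe <- mgcv::PredictMat(cyc$term, ends)
  expect_equal(Xe[1, ], Xe[2, ], tolerance = 1e-10) # f(0) = f(24)

  ten <- build_basis("tensor-2d", d, c("x", "y"), k = 5)
  expect_equal(ncol(ten$X), 25)
  expect_length(ten$S, 2) # one penalty per margin

  shr <- build_basis("shrinkage-spline-1d", d, "x", k = 10)
  expect_length(shr$S, 1)
  ev <- eigen(shr$S[[1]], symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0) # null space shrunk: penalty positive definite

  ri <- build_basis("random-intercept", d, "id")
  expect_equal(ncol(ri$X), 6)
})

test_that("pooled lag-1 rho: white noise ~ 0, AR(1) recovered, constant flagged", {
  set.seed(42)
  g <- rep(1:10, each = 500)
  expect_lt(abs(estimate_rho(rnorm(5000), g)), 0.05)

  ar <- as.vector(replicate(10, ar1_series(500, phi = 0.5)))
  r <- estimate_rho(ar, g)
  expect_gt(r, 0.45); expect_lt(r, 0.55)

  expect_warning(r0 <- estimate_rho(rep(2, 100), rep(1, 100)), "constant")
  expect_equal(r0, 0)
})

test_that("unpenalized fit equals OLS; infinite penalty collapses the smooth", {
  set.seed(43)
  n <- 150
  d <- data.frame(x = runif(n), y = rnorm(n))
  d$y <- sin(2 * pi * d$x) + rnorm(n, 0, 0.3)

  g0 <- mgcv::gam(y ~ s(x, bs = "ts", k = 8), data = d, sp = 0)
  X <- predict(g0, type = "lpmatrix")
  ols <- lm.fit(X, d$y)
  expect_lt(max(abs(fitted(g0) - ols$fitted.values)), 1e-8)

  ginf <- mgcv::gam(y ~ s(x, bs = "ts", k = 8), data = d, sp = 1e10)
  expect_lt(sum(summary(ginf)$s.table[, "edf"]), 0.01)
  expect_lt(diff(range(fitted(ginf))), 1e-3) # shrunk to the constant
})

test_that("fit_gam recovers a known signal and reports deviance explained", {
  set.seed(44)
  n <- 2000
  d <- data.frame(x = runif(n))
  d$y <- 2 * sin(d$x * 2 * pi) + rnorm(n)
  f <- fit_gam(y ~ s(x, bs = "ts", k = 10), d)
  expect_gt(cor(f$fitted, 2 * sin(d$x * 2 * pi)), 0.98)
  expect_gt(f$dev_expl, 0.5)

  ## intercept-only model explains no deviance by definition
  f0 <- fit_gam(y ~ 1, d)
  expect_equal(f0$dev_expl, 0)

  ## a pure-noise covariate is shrunk away
  d$junk <- runif(n)
  fj <- fit_gam(y ~ s(x, bs = "ts", k = 10) + s(junk, bs = "ts", k = 10), d)
  expect_lt(fj$table$edf[fj$table$term == "s(junk)"], 0.5)
})

test_that("deviance explained is non-decreasing when a term is added at fixed lambda", {
  set.seed(45)
  n <- 400
  d <- data.frame(x1 = runif(n), x2 = runif(n))
  d$y <- sin(2 * pi * d$x1) + 0.5 * d$x2 + rnorm(n, 0, 0.4)
  g1 <- mgcv::gam(y ~ s(x1, bs = "ts", k = 8), data = d, sp = 1)
  g2 <- mgcv::gam(y ~ s(x1, bs = "ts", k = 8) + s(x2, bs = "ts", k = 8),
                  data = d, sp = c(1, 1))
  de <- function(g) 1 - g$deviance / g$null.deviance
  expect_gte(de(g2), de(g1) - 1e-10)
})

test_that("negative binomial with huge theta approaches the Poisson fit", {
  set.seed(46)
  n <- 500
  d <- data.frame(x = runif(n))
  d$y <- rpois(n, exp(0.5 + sin(2 * pi * d$x)))
  gp <- mgcv::gam(y ~ s(x, bs = "ts"), data = d, family = poisson(),
                  method = "REML")
  gn <- mgcv::gam(y ~ s(x, bs = "ts"), data = d,
                  family = mgcv::negbin(1e5), method = "REML")
  expect_lt(max(abs(fitted(gp) - fitted(gn))), 1e-3)
})

test_that("rank AUC equals the Mann-Whitney statistic and behaves at the limits", {
  set.seed(47)
  score <- rnorm(200)
  label <- runif(200) < 0.4
  u <- wilcox.test(score[label], score[!label], exact = FALSE)$statistic
  expect_equal(turbidive:::auc_rank(score, label),
               as.numeric(u) / (sum(label) * sum(!label)), tolerance = 1e-10)

  expect_equal(turbidive:::auc_rank(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE)), 1)

  big <- rnorm(5000)
  expect_equal(turbidive:::auc_rank(big, runif(5000) < 0.5), 0.5,
               tolerance = 0.03)
  expect_warning(a <- turbidive:::auc_rank(score, rep(TRUE, 200)), "absent")
  expect_true(is.na(a))
})

test_that("the dive-rate model wires terms, AR(1) and AUC together", {
  cfg <- sim_config(seed = 6)
  set.seed(48)
  fx <- gen_fix_table(cfg, 2500)
  fit <- fit_dive_rate_model(fx)
  expect_s3_class(fit, "gam_fit")
  expect_setequal(fit$table$term,
                  c("te(solar_deg,zsd_m)", "s(cloud_pct)",
                    "s(time_of_day_h)", "s(bird_id)"))
  expect_true(is.finite(fit$auc))
  expect_gt(fit$auc, 0.6)
  expect_true(is.numeric(fit$rho))
  expect_gt(fit$dev_expl, 0)
  expect_error(fit_dive_rate_model(transform(fx, n_dives = 0)), "all dive counts")
})

test_that("tensor interaction truth prefers the tensor over two 1-d splines by AIC", {
  cfg <- sim_config(seed = 6)
  cfg$dive_rate_truth$z_gain <- 1 # pronounced solar x Secchi interaction
  set.seed(49)
  fx <- gen_fix_table(cfg, 6000)
  fx <- fx[fx$solar_deg >= -6, ]
  fx$bird_id <- factor(fx$bird_id)
  kn <- list(time_of_day_h = c(0, 24))
  te_fit <- mgcv::gam(n_dives ~ te(solar_deg, zsd_m, bs = c("ts", "ts"),
                                   k = c(5, 5)) + s(bird_id, bs = "re"),
                      data = fx, family = mgcv::nb(), method = "REML",
                      gamma = 1.2, knots = kn)
  add_fit <- mgcv::gam(n_dives ~ s(solar_deg, bs = "ts", k = 10) +
                         s(zsd_m, bs = "ts", k = 10) + s(bird_id, bs = "re"),
                       data = fx, family = mgcv::nb(), method = "REML",
                       gamma = 1.2, knots = kn)
  expect_lt(AIC(te_fit), AIC(add_fit))
})

test_that("the dive-depth model recovers state contrasts and shrinks null terms", {
  cfg <- sim_config(seed = 6)
  set.seed(50)
  bt <- gen_bout_table(cfg, 1500)
  fit <- fit_dive_depth_model(bt)
  tc <- fit$state_contrasts
  expect_equal(tc$estimate_m[tc$level == "transit"], -3, tolerance = 1)
  expect_lt(abs(tc$estimate_m[tc$level == "ARS"]), 1) # no rest/ARS difference
  expect_lt(fit$table$edf[fit$table$term == "s(water_depth_m)"], 0.5)
})

test_that("per-individual tensor surfaces agree under homogeneous truth", {
  cfg <- sim_config(seed = 6, n_birds = 3)
  set.seed(51)
  bt <- gen_bout_table(cfg, 1800)
  fit <- fit_dive_depth_model(bt, per_individual = TRUE)
  g <- fit$gam
  lev <- levels(fit$data$bird_id)
  grid <- expand.grid(solar_deg = seq(0, 50, length.out = 8),
                      zsd_m = seq(4, 12, length.out = 8))
  grid$cloud_pct <- 50; grid$time_of_day_h <- 12; grid$water_depth_m <- 50
  grid$hmm_state <- factor("ARS", levels = levels(fit$data$hmm_state))
  surf <- sapply(lev, function(b) {
    gb <- grid; gb$bird_id <- factor(b, levels = lev)
    pt <- predict(g, newdata = gb, type = "terms")
    rowSums(pt[, grep("te(", colnames(pt), fixed = TRUE), drop = FALSE])
  })
  cc <- cor(surf)
  expect_gt(min(cc[upper.tri(cc)]), 0.8)
})
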