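## Three-state hidden Markov movement model (rest / ARS / transit) for step
## and turning-angle series, with transition probabilities depending on
## Secchi-disc depth through a multinomial logit. Fitting is direct numerical
## maximization of the forward log-likelihood on a working (unconstrained)
## scale; the forward recursions run in compiled code.

## Off-diagonal coefficient order used throughout, rows = source state:
## (1->2),(1->3),(2->1),(2->3),(3->1),(3->2); states ordered by ascending
## step mean: 1 = rest, 2 = ARS, 3 = transit.
OFFDIAG_PAIRS <- cbind(i = c(1, 1, 2, 2, 3, 3), j = c(2, 3, 1, 3, 1, 2))

#' Construct HMM parameters
#'
#' @param mu,sigma step-length gamma mean and s.d. per state (km, > 0).
#' @param pi0 zero-step-length point mass per state, in \[0, 1).
#' @param turn_mean von Mises turn mean per state, in (-pi, pi\].
#' @param kappa von Mises concentration per state (>= 0).
#' @param beta0 transition intercepts, length 6, off-diagonal order
#'   (1,2),(1,3),(2,1),(2,3),(3,1),(3,2).
#' @param betaz transition slopes on (standardized) Secchi depth, length 6.
#' @param delta initial state distribution (simplex); `NULL` = stationary at
#'   covariate 0.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(mu, sigma, pi0 = c(0, 0, 0), turn_mean = c(0, 0, 0),
                       kappa, beta0, betaz = rep(0, 6), delta = NULL) {
  stopifnot(length(mu) == 3, length(sigma) == 3, all(mu > 0), all(sigma > 0),
            all(pi0 >= 0), all(pi0 < 1), all(kappa >= 0),
            length(beta0) == 6, length(betaz) == 6)
  if (!is.null(delta)) stopifnot(length(delta) == 3, abs(sum(delta) - 1) < 1e-8)
  structure(list(mu = mu, sigma = sigma, pi0 = pi0,
                 turn_mean = wrap_angle(turn_mean), kappa = kappa,
                 beta0 = beta0, betaz = betaz, delta = delta),
            class = "hmm_params")
}

#' Covariate-dependent transition matrix
#'
#' Multinomial-logit transition probabilities with the diagonal as reference:
#' `G[i,j]` proportional to `exp(beta0_ij + betaz_ij * z)` for `i != j` and
#' to 1 for `i == j`; rows sum to 1.
#'
#' @param beta list with `beta0`, `betaz` (each length 6, see
#'   [hmm_params()]), or an `hmm_params` object.
#' @param z scalar covariate value (standardized Secchi depth).
#' @return 3x3 row-stochastic matrix.
#' @export
transition_matrix <- function(beta, z) {
  if (!is.finite(z)) stop("non-finite covariate value")
  eta <- beta$beta0 + beta$betaz * z
  if (any(!is.finite(eta))) stop("non-finite transition coefficients")
  E <- diag(3)
  E[OFFDIAG_PAIRS] <- exp(eta)
  E / rowSums(E)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi = pi G` with the normalization `sum(pi) = 1` (equivalently the
#' left unit-eigenvector). Fails for reducible chains.
#'
#' @param G row-stochastic matrix.
#' @return probability vector.
#' @export
stationary_dist <- function(G) {
  n <- nrow(G)
  stopifnot(ncol(G) == n, all(abs(rowSums(G) - 1) < 1e-8))
  A <- t(diag(n) - G)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  p <- tryCatch(solve(A, b), error = function(e)
    stop("transition matrix appears reducible: ", conditionMessage(e)))
  if (any(p < -1e-8)) stop("transition matrix appears reducible (negative stationary mass)")
  p <- pmax(p, 0)
  p / sum(p)
}

hmm_prepare <- function(obs) {
  stopifnot("step_km" %in% names(obs),
            any(c("seg", "trip_id") %in% names(obs)))
  seg <- if ("seg" %in% names(obs)) obs$seg else obs$trip_id
  seg <- as.integer(factor(seg, levels = unique(seg)))
  step <- obs$step_km
  if (any(!is.finite(step)) || any(step < 0)) stop("steps must be finite and >= 0")
  turn <- if ("turn_rad" %in% names(obs)) obs$turn_rad else rep(NA_real_, length(step))
  z <- if ("z" %in% names(obs)) obs$z else
    if ("zsd_m" %in% names(obs)) obs$zsd_m else rep(0, length(step))
  list(step = step, turn = turn, z = z,
       seg_start = c(TRUE, diff(seg) != 0))
}

delta_of <- function(p) {
  if (!is.null(p$delta)) return(p$delta)
  tryCatch(stationary_dist(transition_matrix(p, 0)),
           error = function(e) rep(1 / 3, 3))
}

#' HMM forward log-likelihood
#'
#' Scaled forward recursion over one or more track segments, with a
#' per-transition matrix `G(z_t)` evaluated at the local covariate. Emission
#' densities: gamma for step length (with optional zero-step mass) times von
#' Mises for turning angle, the latter omitted where the turn is missing
#' (segment starts). Computed with per-step scaling, so series of 10^4+
#' points do not underflow.
#'
#' @param params an [hmm_params()] object.
#' @param obs data.frame with `step_km`, `turn_rad` (NA allowed), covariate
#'   `z` (standardized; 0 if absent) and segment id `seg` (or `trip_id`).
#' @return log-likelihood (scalar).
#' @export
hmm_loglik <- function(params, obs) {
  d <- hmm_prepare(obs)
  if (any(d$step == 0) && all(params$pi0 == 0)) {
    stop("zero step lengths present but zero-step mass pi0 is 0 in every state")
  }
  hmm_fwd_cpp(d$step, d$turn, d$z, d$seg_start, params$mu, params$sigma,
              params$pi0, params$turn_mean, params$kappa, params$beta0,
              params$betaz, delta_of(params))
}

## ---- working-scale parametrization -----------------------------------------

pack_wpar <- function(p, zsd, zero_mass) {
  w <- c(log(p$mu), log(p$sigma), p$turn_mean, log(pmax(p$kappa, 1e-4)), p$beta0)
  if (zsd) w <- c(w, p$betaz)
  if (zero_mass) w <- c(w, qlogis(pmin(pmax(p$pi0, 1e-6), 1 - 1e-6)))
  w
}

unpack_wpar <- function(w, zsd, zero_mass) {
  mu <- exp(w[1:3]); sigma <- exp(w[4:6])
  tmu <- wrap_angle(w[7:9]); kappa <- exp(w[10:12])
  beta0 <- w[13:18]
  k <- 18
  betaz <- if (zsd) { k <- 24; w[19:24] } else rep(0, 6)
  pi0 <- if (zero_mass) plogis(w[(k + 1):(k + 3)]) else c(0, 0, 0)
  hmm_params(mu, sigma, pi0, tmu, kappa, beta0, betaz)
}

moment_inits <- function(step, turn) {
  pos <- step[step > 0]
  q <- quantile(pos, c(1 / 3, 2 / 3))
  grp <- findInterval(pos, q) + 1
  mu <- tapply(pos, grp, mean)
  sigma <- pmax(tapply(pos, grp, sd), mu * 0.2, na.rm = TRUE)
  sigma[is.na(sigma)] <- mu[is.na(sigma)] * 0.5
  hmm_params(as.numeric(mu), as.numeric(sigma), c(0, 0, 0), c(0, 0, 0),
             c(1, 1, 1), rep(-2, 6), rep(0, 6))
}

canonicalize <- function(p) {
  ord <- order(p$mu)
  if (all(ord == 1:3)) return(p)
  eta0 <- matrix(0, 3, 3); etaz <- matrix(0, 3, 3)
  eta0[OFFDIAG_PAIRS] <- p$beta0
  etaz[OFFDIAG_PAIRS] <- p$betaz
  eta0 <- eta0[ord, ord]; etaz <- etaz[ord, ord]
  hmm_params(p$mu[ord], p$sigma[ord], p$pi0[ord], p$turn_mean[ord],
             p$kappa[ord], eta0[OFFDIAG_PAIRS], etaz[OFFDIAG_PAIRS])
}

#' Fit the three-state movement HMM
#'
#' Maximizes the forward log-likelihood by quasi-Newton (BFGS) on a working
#' scale (log for means, s.d.s and concentrations; logit for zero-step mass;
#' identity for transition coefficients), taking the best of `n_restarts`
#' jittered starts around moment-based initial values. The Secchi covariate
#' is centred and scaled internally for optimizer conditioning; fitted slopes
#' are reported both per standardized unit (`betaz`) and per metre
#' (`betaz_per_m`). States are relabelled post-fit by ascending step mean
#' (rest < ARS < transit). The initial state distribution is tied to the
#' stationary distribution at the mean covariate and is not counted as a free
#' parameter.
#'
#' @param obs observation table (`step_km`, `turn_rad`, `zsd_m` or `z`,
#'   segment id `seg`/`trip_id`).
#' @param formula `"null"` (intercept-only transitions) or `"zsd"`.
#' @param inits optional [hmm_params()] starting values.
#' @param n_restarts number of jittered starts (default 3).
#' @param zero_mass estimate a zero-step point mass; default `TRUE` only when
#'   zero steps are present.
#' @param z_center,z_scale standardization constants for the covariate;
#'   default data mean / s.d.
#' @param hessian compute the working-scale covariance (needed for
#'   delta-method transition CIs).
#' @return object of class `hmm_fit`: `params`, `loglik`, `n_params`, `aic`,
#'   `viterbi` (decoded states), `posterior` (per-point state probability
#'   matrix), `formula`, `convergence`, `z_center`, `z_scale`, `vcov_beta`.
#' @export
fit_hmm <- function(obs, formula = c("null", "zsd"), inits = NULL,
                    n_restarts = 3, zero_mass = NULL,
                    z_center = NULL, z_scale = NULL, hessian = TRUE) {
  formula <- match.arg(formula)
  d <- hmm_prepare(obs)
  if (sum(!d$seg_start) < 2) stop("need at least one segment with >= 3 points")
  zsd <- formula == "zsd"
  if (is.null(zero_mass)) zero_mass <- any(d$step == 0)
  if (is.null(z_center)) z_center <- mean(d$z)
  if (is.null(z_scale)) z_scale <- if (sd(d$z) > 0) sd(d$z) else 1
  zs <- (d$z - z_center) / z_scale

  nll <- function(w) {
    p <- tryCatch(unpack_wpar(w, zsd, zero_mass), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- hmm_fwd_cpp(d$step, d$turn, zs, d$seg_start, p$mu, p$sigma, p$pi0,
                      p$turn_mean, p$kappa, p$beta0, p$betaz, delta_of(p))
    if (!is.finite(ll)) 1e10 else -ll
  }

  if (is.null(inits)) inits <- moment_inits(d$step, d$turn)
  if (zero_mass && all(inits$pi0 == 0)) {
    inits$pi0 <- rep(max(mean(d$step == 0), 1e-3), 3)
  }
  w0 <- pack_wpar(inits, zsd, zero_mass)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    w <- if (r == 1) w0 else w0 + rnorm(length(w0), 0, 0.3)
    opt <- tryCatch(
      optim(w, nll, method = "BFGS",
            control = list(maxit = 400, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all HMM restarts failed to converge")

  p_hat <- canonicalize(unpack_wpar(best$par, zsd, zero_mass))
  w_hat <- pack_wpar(p_hat, zsd, zero_mass)
  ll <- -nll(w_hat)
  n_par <- length(w_hat)

  vcov_beta <- NULL
  if (hessian) {
    H <- tryCatch(stats::optimHess(w_hat, nll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        bidx <- if (zsd) 13:24 else 13:18
        vcov_beta <- V[bidx, bidx, drop = FALSE]
      }
    }
  }

  fit <- structure(list(
    params = p_hat, loglik = ll, n_params = n_par,
    aic = 2 * n_par - 2 * ll, formula = formula,
    convergence = best$convergence, z_center = z_center, z_scale = z_scale,
    betaz_per_m = p_hat$betaz / z_scale, vcov_beta = vcov_beta,
    zero_mass = zero_mass, data = d, zs = zs
  ), class = "hmm_fit")
  fit$viterbi <- viterbi(fit)
  fb <- hmm_fb_cpp(d$step, d$turn, zs, d$seg_start, p_hat$mu, p_hat$sigma,
                   p_hat$pi0, p_hat$turn_mean, p_hat$kappa, p_hat$beta0,
                   p_hat$betaz, delta_of(p_hat))
  fit$posterior <- fb$posterior
  fit
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> formula=%s  loglik=%.2f  AIC=%.2f  (k=%d)\n",
              x$formula, x$loglik, x$aic, x$n_params))
  m <- rbind(step_mean_km = x$params$mu, step_sd_km = x$params$sigma,
             turn_mean = x$params$turn_mean, turn_kappa = x$params$kappa)
  colnames(m) <- c("rest", "ARS", "transit")
  print(round(m, 4))
  invisible(x)
}

#' Viterbi decoding
#'
#' Most probable state path given fitted parameters, by dynamic programming;
#' ties resolved toward the lowest state index. States: 1 rest, 2 ARS,
#' 3 transit.
#'
#' @param fit an `hmm_fit`.
#' @param obs optional new observation table (defaults to the fitted data).
#' @return integer state vector.
#' @export
viterbi <- function(fit, obs = NULL) {
  d <- if (is.null(obs)) fit$data else hmm_prepare(obs)
  zs <- if (is.null(obs)) fit$zs else (d$z - fit$z_center) / fit$z_scale
  p <- fit$params
  hmm_viterbi_cpp(d$step, d$turn, zs, d$seg_start, p$mu, p$sigma, p$pi0,
                  p$turn_mean, p$kappa, p$beta0, p$betaz, delta_of(p))
}

#' Transition-probability and stationary curves over Secchi depth
#'
#' Evaluates every off-diagonal transition probability and the stationary
#' state probabilities over a grid of (natural-scale, metres) Secchi depths,
#' with pointwise confidence intervals. Intervals come from the delta method
#' on the working-scale covariance by default; a parametric bootstrap
#' (resimulate from the fit and refit) is available.
#'
#' @param fit an `hmm_fit` with `formula = "zsd"` (intercept-only allowed;
#'   curves are then flat).
#' @param z_grid Secchi depths (m).
#' @param level confidence level (default 0.95).
#' @param ci "delta" or "bootstrap".
#' @param n_boot bootstrap replicates (default 30).
#' @return list with `transitions` (data.frame: z, from, to, p, lo, hi) and
#'   `stationary` (z, state, p, lo, hi).
#' @export
transition_curves <- function(fit, z_grid, level = 0.95,
                              ci = c("delta", "bootstrap"), n_boot = 30) {
  ci <- match.arg(ci)
  zr <- range(fit$data$z)
  if (any(z_grid < zr[1] | z_grid > zr[2])) {
    warning("z_grid extends beyond the fitted covariate range")
  }
  zs_grid <- (z_grid - fit$z_center) / fit$z_scale
  zsd <- fit$formula == "zsd"
  bvec <- if (zsd) c(fit$params$beta0, fit$params$betaz) else fit$params$beta0
  gamma_fun <- function(b, zval) {
    beta <- list(beta0 = b[1:6], betaz = if (zsd) b[7:12] else rep(0, 6))
    transition_matrix(beta, zval)
  }
  zcrit <- stats::qnorm(1 - (1 - level) / 2)

  eval_curves <- function(b) {
    tr <- list(); st <- list()
    for (k in seq_along(zs_grid)) {
      G <- gamma_fun(b, zs_grid[k])
      tr[[k]] <- G[OFFDIAG_PAIRS]
      st[[k]] <- stationary_dist(G)
    }
    list(tr = do.call(rbind, tr), st = do.call(rbind, st))
  }
  pt <- eval_curves(bvec)

  if (ci == "delta" && !is.null(fit$vcov_beta)) {
    np <- length(bvec)
    se_tr <- matrix(0, length(zs_grid), 6)
    se_st <- matrix(0, length(zs_grid), 3)
    h <- 1e-5
    grads_tr <- array(0, c(length(zs_grid), 6, np))
    grads_st <- array(0, c(length(zs_grid), 3, np))
    for (p in seq_len(np)) {
      bp <- bvec; bp[p] <- bp[p] + h
      bm <- bvec; bm[p] <- bm[p] - h
      cp <- eval_curves(bp); cm <- eval_curves(bm)
      grads_tr[, , p] <- (cp$tr - cm$tr) / (2 * h)
      grads_st[, , p] <- (cp$st - cm$st) / (2 * h)
    }
    for (k in seq_along(zs_grid)) {
      for (q in 1:6) {
        g <- grads_tr[k, q, ]
        se_tr[k, q] <- sqrt(max(0, t(g) %*% fit$vcov_beta %*% g))
      }
      for (q in 1:3) {
        g <- grads_st[k, q, ]
        se_st[k, q] <- sqrt(max(0, t(g) %*% fit$vcov_beta %*% g))
      }
    }
    lo_tr <- pmax(pt$tr - zcrit * se_tr, 0); hi_tr <- pmin(pt$tr + zcrit * se_tr, 1)
    lo_st <- pmax(pt$st - zcrit * se_st, 0); hi_st <- pmin(pt$st + zcrit * se_st, 1)
  } else {
    ## parametric bootstrap: resimulate series of the fitted length from the
    ## fitted parameters and refit with the estimate as start
    boots_tr <- array(NA_real_, c(length(zs_grid), 6, n_boot))
    boots_st <- array(NA_real_, c(length(zs_grid), 3, n_boot))
    seg_len <- rle(cumsum(fit$data$seg_start))$lengths
    for (b in seq_len(n_boot)) {
      sim <- simulate_hmm_obs(fit$params, seg_len, z = fit$zs)
      rf <- tryCatch(
        fit_hmm(sim, formula = fit$formula, inits = fit$params,
                n_restarts = 1, hessian = FALSE,
                z_center = 0, z_scale = 1),
        error = function(e) NULL
      )
      if (is.null(rf)) next
      bb <- if (zsd) c(rf$params$beta0, rf$params$betaz) else rf$params$beta0
      cb <- eval_curves(bb)
      boots_tr[, , b] <- cb$tr
      boots_st[, , b] <- cb$st
    }
    qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    lo_tr <- apply(boots_tr, c(1, 2), quantile, qs[1], na.rm = TRUE)
    hi_tr <- apply(boots_tr, c(1, 2), quantile, qs[2], na.rm = TRUE)
    lo_st <- apply(boots_st, c(1, 2), quantile, qs[1], na.rm = TRUE)
    hi_st <- apply(boots_st, c(1, 2), quantile, qs[2], na.rm = TRUE)
    ## intervals must contain the point estimate
    lo_tr <- pmin(lo_tr, pt$tr); hi_tr <- pmax(hi_tr, pt$tr)
    lo_st <- pmin(lo_st, pt$st); hi_st <- pmax(hi_st, pt$st)
  }

  states <- c("rest", "ARS", "transit")
  transitions <- data.frame(
    z = rep(z_grid, each = 6),
    from = states[OFFDIAG_PAIRS[, "i"]], to = states[OFFDIAG_PAIRS[, "j"]],
    p = as.vector(t(pt$tr)), lo = as.vector(t(lo_tr)), hi = as.vector(t(hi_tr))
  )
  stationary <- data.frame(
    z = rep(z_grid, each = 3), state = states,
    p = as.vector(t(pt$st)), lo = as.vector(t(lo_st)), hi = as.vector(t(hi_st))
  )
  list(transitions = transitions, stationary = stationary)
}

#' Simulate observations from HMM parameters
#'
#' Draws a state sequence from the Markov chain `G(z_t)` and emits steps
#' (gamma, with optional zero mass) and turns (von Mises); the first turn of
#' each segment is missing, as in real track segments. Used for
#' parameter-recovery studies and the parametric bootstrap.
#'
#' @param params [hmm_params()].
#' @param seg_len vector of segment lengths (number of observations each).
#' @param z covariate series (standardized scale), length `sum(seg_len)`;
#'   default all 0.
#' @return data.frame with `step_km`, `turn_rad`, `z`, `seg`, `state`.
#' @export
simulate_hmm_obs <- function(params, seg_len, z = NULL) {
  n <- sum(seg_len)
  if (is.null(z)) z <- rep(0, n)
  stopifnot(length(z) == n)
  seg <- rep(seq_along(seg_len), seg_len)
  seg_start <- c(TRUE, diff(seg) != 0)
  ## precompute cumulative transition rows for each t
  eta <- outer(z, params$betaz) + matrix(params$beta0, n, 6, byrow = TRUE)
  E <- exp(eta)
  rows <- list(
    cbind(1, E[, 1], E[, 2]), # from state 1: (1->1, 1->2, 1->3)
    cbind(E[, 3], 1, E[, 4]),
    cbind(E[, 5], E[, 6], 1)
  )
  cum <- lapply(rows, function(R) {
    R <- R / rowSums(R)
    cbind(R[, 1], R[, 1] + R[, 2])
  })
  delta <- delta_of(params)
  state <- integer(n)
  u <- runif(n)
  for (t in seq_len(n)) {
    if (seg_start[t]) {
      state[t] <- findInterval(u[t], cumsum(delta)) + 1L
      state[t] <- min(state[t], 3L)
    } else {
      cr <- cum[[state[t - 1]]]
      state[t] <- 1L + (u[t] > cr[t, 1]) + (u[t] > cr[t, 2])
    }
  }
  shape <- (params$mu / params$sigma)^2
  rate <- params$mu / params$sigma^2
  step <- rgamma(n, shape = shape[state], rate = rate[state])
  if (any(params$pi0 > 0)) {
    step[runif(n) < params$pi0[state]] <- 0
  }
  turn <- rep(NA_real_, n)
  for (s in 1:3) {
    idx <- which(state == s & !seg_start)
    if (length(idx)) turn[idx] <- rvonmises(length(idx), params$turn_mean[s],
                                            params$kappa[s])
  }
  data.frame(step_km = step, turn_rad = turn, z = z, seg = seg, state = state)
}

#' Von Mises random deviates
#'
#' Best-Fisher (1979) rejection sampler; for concentrations near zero the
#' distribution is uniform on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return radians in (-pi, pi\].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-7) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    zc <- cos(pi * u1)
    f <- (1 + r * zc) / (r + zc)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nn <- sum(ok)
    if (nn) {
      out[(got + 1):(got + nn)] <-
        wrap_angle(mu + sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok]))))
      got <- got + nn
    }
  }
  out
}

#' Compare two HMM fits as dive predictors
#'
#' Reports the AIC difference, the fraction of points decoded identically,
#' and—treating a decoded ARS point as a predicted dive—hit rate
#' `P(ARS | dive present)`, miss rate `P(not ARS | dive present)` and
#' precision `P(dive present | ARS)` for each model.
#'
#' @param fit_a,fit_b `hmm_fit`s of the same data (e.g. with and without the
#'   Secchi covariate).
#' @param dive_presence logical vector per observation point.
#' @param decoded_a,decoded_b optional decoded state vectors (default the
#'   fits' Viterbi paths).
#' @param ars_state state index counted as ARS (default 2).
#' @return list with `delta_aic` (AIC_a - AIC_b), `agreement`, and a
#'   `metrics` data.frame (model, hit, miss, precision).
#' @export
compare_models <- function(fit_a, fit_b, dive_presence,
                           decoded_a = NULL, decoded_b = NULL, ars_state = 2L) {
  if (is.null(decoded_a)) decoded_a <- fit_a$viterbi
  if (is.null(decoded_b)) decoded_b <- fit_b$viterbi
  if (length(decoded_a) != length(decoded_b) ||
      length(decoded_a) != length(dive_presence)) {
    stop("decoded state and dive presence vectors must have equal length")
  }
  one <- function(dec) {
    ars <- dec == ars_state
    hit <- mean(ars[dive_presence])
    data.frame(hit = hit, miss = 1 - hit,
               precision = if (any(ars)) mean(dive_presence[ars]) else NA_real_)
  }
  metrics <- rbind(cbind(model = "a", one(decoded_a)),
                   cbind(model = "b", one(decoded_b)))
  list(delta_aic = fit_a$aic - fit_b$aic,
       agreement = mean(decoded_a == decoded_b),
       metrics = metrics)
}
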